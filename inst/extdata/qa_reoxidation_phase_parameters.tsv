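label	strain	condition	hours	dcmu	tau1_us	tau1_sd_us	a1_pct	a1_sd_pct	tau2_ms	tau2_sd_ms	a2_pct	a2_sd_pct	tau3_s	tau3_sd_s	a3_pct	a3_sd_pct
WT 1 PA	WT 1	PA	0	0	309.31	43.00	73.1	3.0	3.11	0.99	18.8	3.2	8.05	0.92	8.1	0.3
WT 1 PM 24 h	WT 1	PM	24	0	296.48	31.22	69.4	1.7	2.40	0.47	21.7	0.4	10.33	0.99	8.0	1.4
WT 1 PM 48 h	WT 1	PM	48	0	295.97	25.16	70.8	2.5	2.26	0.26	21.6	2.8	4.85	0.42	7.6	0.2
WT 1 PM 72 h	WT 1	PM	72	0	545.30	107.31	9.9	1.9	28.32	23.55	5.9	0.8	1.05	0.06	84.3	2.4
WT 1 PA + DCMU	WT 1	PA	0	1	764.18	100.36	2.3	0.2	NA	NA	NA	NA	0.53	0.01	97.7	0.2
WT 1 PM + DCMU 24 h	WT 1	PM	24	1	919.96	306.04	2.2	0.3	NA	NA	NA	NA	0.53	0.01	97.8	0.3
WT 1 PM + DCMU 48 h	WT 1	PM	48	1	734.72	27.52	2.8	0.5	NA	NA	NA	NA	0.61	0.02	97.2	0.5
WT 1 PM + DCMU 72 h	WT 1	PM	72	1	1513.32	718.22	9.0	0.7	NA	NA	NA	NA	0.83	0.03	91.0	0.7
WT 3 PA	WT 3	PA	0	0	273.50	11.44	70.9	1.8	2.14	0.15	21.2	1.7	6.70	0.65	7.9	0.2
WT 3 PM 24 h	WT 3	PM	24	0	275.60	17.36	67.2	0.4	2.28	0.10	24.8	0.5	10.33	1.51	8.0	0.4
WT 3 PM 48 h	WT 3	PM	48	0	364.61	9.91	66.3	4.4	3.13	0.25	19.4	3.1	3.57	2.86	14.3	6.9
WT 3 PM 72 h	WT 3	PM	72	0	449.33	72.98	53.4	2.0	6.20	1.61	15.6	1.3	0.97	0.17	31.0	2.3
WT 3 PA + DCMU	WT 3	PA	0	1	785.02	182.62	2.8	0.2	NA	NA	NA	NA	0.59	0.01	97.2	0.2
WT 3 PM + DCMU 72 h	WT 3	PM	72	1	4793.33	1775.79	3.8	0.8	NA	NA	NA	NA	0.53	0.05	96.2	0.8
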