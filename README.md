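# qarelax

Deconvolution of flash-induced chlorophyll-fluorescence relaxation — the
kinetics of Q<sub>A</sub><sup>−</sup> reoxidation in photosystem II (PSII).

## The problem

After a single-turnover saturating flash, the primary quinone acceptor of
PSII is reduced (Q<sub>A</sub><sup>−</sup>) and variable chlorophyll
fluorescence is maximal. The fluorescence then relaxes as
Q<sub>A</sub><sup>−</sup> is reoxidized through three routes with very
different time scales:

* a **fast phase** (τ₁ ≈ 300–500 μs) — forward electron transfer to a bound
  Q<sub>B</sub> quinone;
* a **middle phase** (τ₂ ≈ 2–30 ms) — reoxidation limited by binding of an
  oxidized plastoquinone to an empty Q<sub>B</sub> site;
* a **slow phase** (τ₃ ≈ 0.5–20 s) — charge recombination
  (*back reaction*) between the PSII acceptor side and the S₂/S₃ states of
  the donor side.

The decay is modelled as a baseline plus a sum of exponential and hyperbolic
components,

F(t) = F₀ + A₁·e^(−t/τ₁) + A₂·e^(−t/τ₂) + A₃/(1 + t/τ₃),

with amplitudes reported as percentages of the total variable yield
F_v = ΣAᵢ. The slow-phase relative amplitude A₃ (%) is read directly as the
fraction of PSII centers that reopen by back reaction rather than forward
transport. With the Q<sub>B</sub>-site inhibitor DCMU the decay collapses to
one exponential plus one hyperbola (S₂Q<sub>A</sub><sup>−</sup>
recombination), and the two-component form is used instead.

`qarelax` provides the model, a bounded multi-start nonlinear least-squares
deconvolution of measured or simulated traces, a seeded synthetic-trace
generator with biological replicate scatter (no raw fluorometer data are
required), aggregation of replicate fits into a mean ± SD table with
pairwise *t*-test significance marks, and small helpers for the surrounding
scalar quantities: PAM quantum yields Y(II) = (F_m′ − F_s)/F_m′ and
Y(I) = (P_m′ − P)/P_m, O₂-rate fold changes and percent reductions, and
relative qPCR quantification 2^(−ΔΔCt).

## Worked example

Simulate one noisy trace from the packaged phase parameters of a
photomixotrophically grown wild-type strain (72 h, strongly blocked
Q<sub>A</sub><sup>−</sup>→Q<sub>B</sub> transfer), then deconvolve it:

```r
library(qarelax)

tbl   <- load_table1()                       # 14 published parameter rows
truth <- row_to_model(tbl[tbl$label == "WT 1 PM 72 h", ])
trace <- generate_trace(truth, noise_sigma = 0.02, seed = 42)
fit   <- fit_relaxation(trace, model_form = "three_phase",
                        n_starts = 16, seed = 1)
fit
#> <relaxation_fit> form = three_phase  rmse = 0.01746  start 6 of 16
#> # A tibble: 3 × 7
#>   phase  kind           tau_s amplitude rel_amp_pct tau_report report_unit
#>   <chr>  <chr>          <dbl>     <dbl>       <dbl>      <dbl> <chr>
#> 1 fast   exponential 0.000369    0.129        12.5      369.   us
#> 2 middle exponential 0.0368      0.0614        5.97      36.8  ms
#> 3 slow   hyperbolic  1.04        0.839        81.5        1.04 s

back_reaction_fraction(fit)
#> [1] 81.5
```

Under 2% multiplicative noise the fit recovers the generating slow phase
(τ₃ = 1.05 s, A₃ = 84.3%) to within a few percent: about 82% of PSII
centers in this condition reopen by charge recombination instead of forward
electron transfer. The fast phase, which carries only ~10% of the variable
yield here, is recovered with correspondingly larger scatter.

The full study-level pipeline — replicates, fits, mean ± SD table with
between-strain (`star_*`) and versus-photoautotrophy (`hash_*`) significance
marks — is one call:

```r
res <- run_batch(seed = 7)        # 14 rows x 3 replicates, 2% noise
res$report                        # Table-1-style tibble
plot_relaxation(res$fits)         # log-time panels, fits overlaid
```

Scalar helpers reproduce the printed effect sizes, e.g. the DCBQ rescue of
gross O₂ evolution under photomixotrophy:

```r
fold_change(65.1, 2.9)       # 22.4  (~22-fold)
percent_reduction(19.0, 65.1) # 70.8  (DMBQ ~70% lower than DCBQ)
```

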