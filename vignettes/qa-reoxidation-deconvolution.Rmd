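---
title: "Deconvolving QA- reoxidation kinetics from flash-induced fluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deconvolving QA- reoxidation kinetics from flash-induced fluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qarelax)
```

## The model

A single-turnover saturating flash reduces the primary quinone acceptor of
photosystem II; the subsequent relaxation of variable chlorophyll
fluorescence tracks the reoxidation of Q~A~^−^. `qarelax` decomposes a
relaxation trace as

$$F(t) = F_0 + \sum_{i \in \mathrm{exp}} A_i\, e^{-t/\tau_i}
             + \sum_{j \in \mathrm{hyp}} \frac{A_j}{1 + t/\tau_j},$$

with a stable baseline $F_0$ and one to three decay components. The
standard (no inhibitor) configuration uses two exponentials — the fast
phase, forward electron transfer to a bound Q~B~ (τ typically 0.3–0.5 ms),
and the middle phase, reoxidation limited by plastoquinone binding to an
empty Q~B~ site (τ ~2–30 ms) — plus one hyperbola for the slow phase,
charge recombination of the acceptor side with the S~2~/S~3~ states of the
oxygen-evolving complex (τ ~0.5–20 s). With DCMU blocking the Q~B~ site the
decay is fitted with one exponential plus one hyperbola
(S~2~Q~A~^−^ recombination dominates).

Two conventions matter downstream:

* **Hyperbolic form.** The slow phase uses the first-order hyperbola
  $A/(1+t/\tau)$, the form appropriate for a bimolecular-like recombination
  decay; it halves at $t=\tau$, which is what lets τ~3~ be read as a
  recombination time constant.
* **Amplitude partitioning.** Amplitudes are reported as percentages of the
  total variable yield $F_v=\sum A_i$, summing to 100 by construction. The
  slow-phase percentage is interpreted as the fraction of PSII centers that
  reopen by back reaction (`back_reaction_fraction()`).

Components are always stored and reported sorted by ascending τ (ties
broken by larger amplitude first), so fast/middle/slow labels are
deterministic and never depend on which bound box a parameter converged in.
Internally everything is in seconds; `tidy()` adds the conventional
reporting units (fast in μs, middle in ms, slow in s).

$F_0$ is a fitted parameter, not assumed zero: dark-adapted traces retain
non-variable fluorescence, and fixing the baseline from a pre-flash reading
is not always possible for simulated or re-exported data.

## Fitting procedure

`fit_relaxation()` minimizes unweighted squared residuals on the
acquisition grid with bounded Levenberg–Marquardt (`minpack.lm::nls.lm`),
parameterized as $(F_0, A_i, \log_{10}\tau_i)$. The log-τ parameterization
keeps the problem well-scaled across the six decades the time constants
span. Because the trace is acquired on a log-spaced grid, uniform weights
correspond to density weighting in linear time: every decade — and hence
every phase — contributes comparably to the objective.

The three-phase problem is multimodal, so the fit is multi-started
(default 16 starts, seeded and fully reproducible): start 1 places each τ
at the geometric midpoint of its phase stratum (fast 0.1–1 ms, middle
1–100 ms, slow 0.3–30 s), the remaining starts draw log-uniformly within
the strata; amplitudes start from an equal split of the observed variable
yield and the baseline from the trace minimum. Starts that fail the
optimizer's convergence test (gradient tolerance 1e−10, at most 2000
residual evaluations) are discarded; the lowest-RSS survivor wins, and a
fit in which no start converges raises an error carrying the per-start
diagnostics.

Box bounds bracket the phase definitions with margin: τ~1~ ∈ [50 μs,
10 ms], τ~2~ ∈ [1 ms, 1 s], τ~3~ ∈ [0.1 s, 100 s], amplitudes ∈
[0, 2 F_v^obs], F₀ ∈ [0, max(F)]. One adjustment proved necessary: the
**lower τ bounds are clamped to the first sampled time point** (the
instrument dead time, 100 μs on the default grid). A component faster than
the first sample is unidentifiable — it affects only the first handful of
points, and under measurement noise its amplitude is free to absorb those
points, which in practice produced spurious optima with a 50-μs
"phase" carrying tens of percent of the variable yield. Clamping removes
the degeneracy without constraining any physically resolvable time
constant.

Phase identity is assigned *after* fitting by sorting on τ; overlapping
bounds are deliberate. `compare_fit_forms()` reports RMSE and small-sample
AICc for both model forms but never auto-selects: the experimental DCMU
flag decides the form, model selection is only a diagnostic against
overfitting DCMU traces with three phases. Fits whose fitted $F_v$ does not
exceed three times the residual RMSE are flagged as having no resolvable
decay.

Uncertainty is reported the way replicate experiments report it: fits are
done per biological replicate and the table gives across-replicate mean and
SD. Asymptotic (Jacobian) standard errors are not mixed into the tables.

## The synthetic-data generator

No raw fluorometer records are needed anywhere in the package: the
generator produces traces with the statistical structure the deconvolution
assumes, parameterized directly from the packaged table of published phase
parameters (`load_table1()`, 14 rows, integrity-checked on load; relative
amplitudes are renormalized to exactly 100% on conversion to absorb printed
rounding).

* **Grid.** 200 log-spaced points from 100 μs to 100 s, matching the
  decade-spanning presentation of flash-relaxation measurements. The first
  point doubles as the dead time.
* **Measurement noise.** Multiplicative Gaussian, $y(1+\varepsilon)$,
  $\varepsilon \sim N(0, \sigma)$ truncated so yields stay positive.
  Default $\sigma = 0.02$: small enough that traces look like smooth
  instrument output, large enough to stress the fitter.
* **Replicate scatter.** Biological replicates draw each τ from a lognormal
  (positive, decade-spanning scale parameter) and each amplitude percentage
  from a truncated normal, centred on the row means with the row SDs, then
  renormalize amplitudes to 100%. The draw log is returned with the traces
  so recovery can be scored against each replicate's true parameters.
* **Defaults as study conditions.** n = 3 biological replicates, baseline
  $F_0 = 0.2$, total variable yield 1 — the replicate count mirrors the
  published design; baseline and yield set a realistic F_v/(F_v+F_0)
  contrast for dark-adapted cyanobacterial cells.

What the generator does *not* emulate: flash artifacts and dead-time
distortion (no quantitative description exists to calibrate against),
far-red preillumination and plastoquinone-pool redox effects beyond what
different parameter rows encode, and instrument drift. Passing round-trip
tests therefore demonstrates the estimator's correctness and conditioning
on decays of the assumed form — not robustness to instrument artifacts in
real records.

## Study-level pipeline

`run_batch()` chains the stages: simulate (or load) traces, fit each with
the form dictated by its DCMU flag, and aggregate with `replicate_table()`
into a mean ± SD table carrying two families of significance marks from the
classical equal-variance unpaired *t*-test (chosen to match the published
comparison scheme; Welch's correction is available in
`unpaired_t_test()`): `star_*` against the other strain under the same
condition/time/DCMU, `hash_*` against the same strain's photoautotrophic
baseline. Groups with one replicate are reported without SDs or marks, and
failed fits become diagnostic rows rather than aborting the batch. With a
fixed seed the whole pipeline, including the written TSV report, is
byte-identical across runs.

Zero pooled variance (possible with noiseless simulations) makes the
*t*-statistic degenerate; the test then returns t = 0, p = 1 for equal
means, t = ±∞, p = 0 otherwise, flagged as `degenerate`.

## Numerical and design notes

* **Normalization plateau.** `normalize_trace()` maps the estimated tail
  plateau to 0 and the maximum to 1. Because a slow hyperbolic phase with
  τ ~8 s has decayed only ~13-fold by 100 s, a plain tail mean
  overestimates the baseline; the plateau is instead estimated by fitting a
  constant-plus-hyperbola to the last decade of points, which recovers a
  generating baseline within ~2%.
* **Trace files** are plain TSV with `#` metadata headers; values are
  written with 18 significant digits and parsed with correctly-rounded
  `strtod`, so write→read round-trips are bit-exact.
* **Identifiability limit.** In DCMU rows the fast phase carries only
  2–4% of the variable yield. With 2% multiplicative noise that amplitude
  is of the same order as the per-point noise, and τ~1~ is recovered with
  large scatter — consistent with the 30–50% replicate SDs the published
  table itself shows for those cells. Noise-robustness tests therefore
  assert the 15% recovery tolerance on the three-phase rows, where the fast
  phase is a dominant, resolvable component.
* **Type-I control.** The report's marks are checked by simulating two
  strains from identical generating parameters over 100 seeds and counting
  per-parameter false marks; the empirical rate should sit near the nominal
  α = 0.05 (accepted 2–9%). Note this is a *per-comparison* rate: with six
  parameters per row, the chance that *some* mark appears in a table is
  correspondingly higher, which is the familiar multiplicity caveat of
  presenting per-cell significance marks (no multiplicity correction is
  applied, matching the published convention).
* **Problem sizes in the test suite** were chosen to keep the full suite
  fast while leaving every statistical check well-powered: 200-point grids
  for recovery tests, 100-point grids and 4 starts for the 100-seed type-I
  sweep, 60–80 point grids for the brute-force grid-search oracle
  comparisons.

## Limitations

The decomposition is phenomenological: no S-state cycle or two-electron
gate rate equations, so the fitted parameters summarize — but do not
mechanistically model — acceptor-side electron transfer. Model-form choice
is delegated to the experimental design (DCMU flag). Time constants outside
the acquisition window (faster than the dead time or slower than the last
decade) are not estimable, and the bounds enforce this rather than letting
the optimizer report precise-looking but meaningless values.
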