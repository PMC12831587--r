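#' Effective quantum yield of photosystem II
#'
#' Saturating-pulse PAM fluorometry yield, `Y(II) = (Fm' - Fs) / Fm'`, where
#' `Fs` is the steady-state fluorescence in actinic light and `Fm'` the
#' maximum reached during a saturating pulse. Vectorized; scale-invariant in
#' the readings. A negative yield (transient `Fm' < Fs`, seen in noisy
#' measurements) is returned as-is with a warning rather than an error.
#'
#' @param fs,fm_prime Fluorescence readings; `fm_prime` must be `> 0`.
#' @return Numeric yield(s) in `(-Inf, 1]`.
#' @examples
#' psii_yield(fs = 0.6, fm_prime = 1.0)
#' @export
psii_yield <- function(fs, fm_prime) {
  if (any(!is.finite(fm_prime)) || any(fm_prime <= 0)) {
    abort("`fm_prime` must be finite and > 0.", class = "qarelax_invalid_input")
  }
  y <- (fm_prime - fs) / fm_prime
  if (any(y < 0)) warn("non-physical Y(II) < 0 (Fs > Fm'); returned unchanged.")
  y
}

#' Effective quantum yield of photosystem I
#'
#' P700-absorbance yield, `Y(I) = (Pm' - P) / Pm`, where `P` is the current
#' P700 oxidation level, `Pm` the maximal oxidation (saturating pulse on
#' far-red background) and `Pm'` the maximal oxidation during illumination.
#'
#' @param p,pm_prime,pm P700 signal readings; `pm` must be `> 0`.
#' @return Numeric yield(s).
#' @examples
#' psi_yield(p = 0.25, pm_prime = 0.75, pm = 1.0)
#' @export
psi_yield <- function(p, pm_prime, pm) {
  if (any(!is.finite(pm)) || any(pm <= 0)) {
    abort("`pm` must be finite and > 0.", class = "qarelax_invalid_input")
  }
  (pm_prime - p) / pm
}

#' Add PAM quantum yields to a table of readings
#'
#' Data-frame interface over [psii_yield()] and [psi_yield()]: computes
#' `y_ii` from columns `fs` and `fm_prime` and, when the P700 columns `p`,
#' `pm_prime`, `pm` are present, `y_i` as well.
#'
#' @param readings A data frame of per-sample readings.
#' @return The input as a tibble with yield columns appended.
#' @export
pam_yields <- function(readings) {
  readings <- tibble::as_tibble(readings)
  if (!all(c("fs", "fm_prime") %in% names(readings))) {
    abort("`readings` needs columns `fs` and `fm_prime`.",
          class = "qarelax_invalid_input")
  }
  out <- dplyr::mutate(readings, y_ii = psii_yield(.data$fs, .data$fm_prime))
  if (all(c("p", "pm_prime", "pm") %in% names(readings))) {
    out <- dplyr::mutate(out, y_i = psi_yield(.data$p, .data$pm_prime, .data$pm))
  }
  out
}

#' Ratio of two rates
#'
#' `fold_change(a, b) = a / b` — e.g. the rescue of gross O2 evolution by an
#' artificial electron acceptor relative to the unamended rate.
#'
#' @param rate_a Numerator rate(s), `>= 0`.
#' @param rate_b Denominator/reference rate(s), `> 0`.
#' @return Numeric ratio(s).
#' @examples
#' fold_change(65.1, 2.9)  # ~22-fold DCBQ rescue
#' @export
fold_change <- function(rate_a, rate_b) {
  if (any(!is.finite(rate_b)) || any(rate_b <= 0)) {
    abort("`rate_b` must be finite and > 0.", class = "qarelax_invalid_input")
  }
  rate_a / rate_b
}

#' Percent reduction of a rate relative to a reference
#'
#' `(rate_b - rate_a) / rate_b * 100` — e.g. how much lower the DMBQ-supported
#' O2 rate is than the DCBQ-supported one.
#'
#' @inheritParams fold_change
#' @return Percentage(s).
#' @examples
#' percent_reduction(19.0, 65.1)  # DMBQ vs DCBQ, ~70%
#' @export
percent_reduction <- function(rate_a, rate_b) {
  if (any(!is.finite(rate_b)) || any(rate_b <= 0)) {
    abort("`rate_b` must be finite and > 0.", class = "qarelax_invalid_input")
  }
  (rate_b - rate_a) / rate_b * 100
}

#' Rate comparisons over a table of rate pairs
#'
#' @param rates A data frame with columns `rate_a` and `rate_b`.
#' @return The input as a tibble with `fold_change` and
#'   `percent_reduction` columns appended.
#' @export
rate_comparisons <- function(rates) {
  rates <- tibble::as_tibble(rates)
  if (!all(c("rate_a", "rate_b") %in% names(rates))) {
    abort("`rates` needs columns `rate_a` and `rate_b`.",
          class = "qarelax_invalid_input")
  }
  dplyr::mutate(rates,
                fold_change = fold_change(.data$rate_a, .data$rate_b),
                percent_reduction = percent_reduction(.data$rate_a, .data$rate_b))
}

#' Relative qPCR quantification (2^-ddCt)
#'
#' `ddCt = (Ct_target,sample - Ct_ref,sample) -
#' (Ct_target,calibrator - Ct_ref,calibrator)`; the fold change is
#' `2^-ddCt`. Shifting all four Ct values by a constant leaves the result
#' unchanged.
#'
#' @param ct_target_sample,ct_ref_sample Target- and reference-gene cycle
#'   thresholds in the sample of interest.
#' @param ct_target_calibrator,ct_ref_calibrator The same in the calibrator
#'   condition.
#' @return Fold change(s), dimensionless.
#' @examples
#' ddct_fold_change(24, 18, 26, 18)  # ddCt = -2 -> 4-fold
#' @export
ddct_fold_change <- function(ct_target_sample, ct_ref_sample,
                             ct_target_calibrator, ct_ref_calibrator) {
  cts <- cbind(ct_target_sample, ct_ref_sample,
               ct_target_calibrator, ct_ref_calibrator)
  if (any(!is.finite(cts))) {
    abort("all Ct values must be finite.", class = "qarelax_invalid_input")
  }
  ddct <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-ddct)
}

#' Unpaired two-sample Student's t-test
#'
#' Classical equal-variance unpaired t-test (Welch's correction available via
#' `var_equal = FALSE`), two-sided, as used for the pairwise strain and
#' condition comparisons of the replicate tables. When the pooled variance is
#' zero the statistic is degenerate: identical means give `t = 0, p = 1`,
#' different means give `t = +/-Inf, p = 0`, and the row is flagged.
#'
#' @param x,y Numeric vectors, each of length `>= 2`.
#' @param var_equal Assume equal variances (classical Student) — the default.
#' @param alpha Significance level for the `significant` flag.
#' @return A one-row tibble: `t`, `df`, `p_value`, `significant`,
#'   `degenerate`.
#' @examples
#' unpaired_t_test(c(1, 2, 3), c(2, 3, 4))
#' @export
unpaired_t_test <- function(x, y, var_equal = TRUE, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group needs n >= 2.", class = "qarelax_invalid_input")
  }
  pooled_var <- (sum((x - mean(x))^2) + sum((y - mean(y))^2)) /
    (length(x) + length(y) - 2)
  if (pooled_var == 0) {
    same <- isTRUE(all.equal(mean(x), mean(y)))
    return(tibble::tibble(
      t = if (same) 0 else sign(mean(x) - mean(y)) * Inf,
      df = length(x) + length(y) - 2,
      p_value = if (same) 1 else 0,
      significant = !same,
      degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = var_equal)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p_value = ht$p.value, significant = ht$p.value < alpha,
                 degenerate = FALSE)
}
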