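#' Simulate a flash-induced fluorescence trace
#'
#' Evaluates a relaxation model on a (by default log-spaced) time grid and
#' optionally applies multiplicative Gaussian measurement noise,
#' `y * (1 + e)` with `e ~ N(0, noise_sigma)` truncated so yields stay
#' positive. With `noise_sigma = 0` the trace equals [eval_relaxation()] on
#' the grid exactly; with a fixed `seed` the output is reproducible.
#'
#' @param model A [relaxation_model()] (the generating truth).
#' @param times_s Optional explicit time grid; otherwise built from
#'   `t_min_s`, `t_max_s`, `n_points`, `spacing` via [default_time_grid()].
#' @inheritParams default_time_grid
#' @param noise_sigma Relative noise SD, in `[0, 0.2]`.
#' @param seed Optional integer seed; the global RNG state is untouched.
#' @param ... Metadata passed to [fluorescence_trace()] (`strain`,
#'   `condition`, `hours`, `dcmu`, `fr_preillumination`, `replicate`).
#' @return A [fluorescence_trace()].
#' @examples
#' m <- row_to_model(load_table1()[1, ])
#' tr <- generate_trace(m, noise_sigma = 0.02, seed = 1)
#' @export
generate_trace <- function(model, times_s = NULL,
                           t_min_s = 1e-4, t_max_s = 100, n_points = 200L,
                           spacing = c("log", "linear"),
                           noise_sigma = 0, seed = NULL, ...) {
  stopifnot(inherits(model, "relaxation_model"))
  if (noise_sigma < 0 || noise_sigma > 0.2) {
    abort("`noise_sigma` must lie in [0, 0.2].", class = "qarelax_invalid_input")
  }
  times_s <- times_s %||%
    default_time_grid(t_min_s, t_max_s, n_points, match.arg(spacing))
  y <- eval_relaxation(model, times_s)
  if (noise_sigma > 0) {
    eps <- with_seed_if(seed, rnorm(length(y), sd = noise_sigma))
    eps <- pmax(eps, -0.999)  # keep yields positive
    y <- y * (1 + eps)
  }
  fluorescence_trace(times_s, y, ...)
}

with_seed_if <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# One replicate parameter draw around a row's printed means: time constants
# lognormal (positive, decade-spanning), relative amplitudes truncated normal
# at zero then renormalized to 100%.
draw_replicate_params <- function(means_tau, sds_tau, means_a, sds_a) {
  tau <- mapply(function(m, s) {
    if (s <= 0) return(m)
    cv <- s / m
    sdlog <- sqrt(log1p(cv^2))
    rlnorm(1, meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
  }, means_tau, sds_tau)
  a <- mapply(function(m, s) {
    if (s <= 0) return(m)
    x <- rnorm(1, m, s)
    while (x <= 0) x <- rnorm(1, m, s)
    x
  }, means_a, sds_a)
  list(tau_s = tau, a_pct = 100 * a / sum(a))
}

#' Simulate biological replicates of one strain/condition row
#'
#' Draws `n_replicates` per-replicate parameter sets around the printed means
#' of one [load_table1()] row — time constants from a lognormal with the
#' row's mean and SD, relative amplitudes from a truncated normal and
#' renormalized to 100% — then simulates one trace per draw. The draw log
#' (the generating parameters actually used) is returned alongside each
#' trace so recovery can be scored against the true per-replicate values.
#'
#' @param row One row of [load_table1()].
#' @param n_replicates Number of biological replicates (3 in the study design).
#' @param sd_scale Multiplier on the row's SD columns; 0 gives identical
#'   replicates at the printed means.
#' @param noise_sigma,seed,t_min_s,t_max_s,n_points,spacing Passed to
#'   [generate_trace()].
#' @param f0,fv Baseline and total variable yield of the generating models.
#' @return A tibble with one row per replicate: `replicate`, the generating
#'   parameter draw (`true_tau1_s`, `true_a1_pct`, ..., per the row's model
#'   form) and a `trace` list-column of [fluorescence_trace()] objects.
#'   Empty for `n_replicates = 0`.
#' @export
generate_replicates <- function(row, n_replicates = 3L, sd_scale = 1,
                                noise_sigma = 0.02, seed = NULL,
                                t_min_s = 1e-4, t_max_s = 100,
                                n_points = 200L, spacing = "log",
                                f0 = 0.2, fv = 1) {
  row <- tibble::as_tibble(row)
  stopifnot(nrow(row) == 1L)
  if (n_replicates == 0L) {
    return(tibble::tibble(replicate = integer(), trace = list()))
  }
  dcmu <- isTRUE(row$dcmu)
  if (!dcmu && !is.na(row$a3_pct) && row$a3_pct == 0) {
    warn("slow-phase amplitude is zero in a non-DCMU row.")
  }
  if (dcmu) {
    means_tau <- c(row$tau1_us * 1e-6, row$tau3_s)
    sds_tau <- sd_scale * c(row$tau1_sd_us * 1e-6, row$tau3_sd_s)
    means_a <- c(row$a1_pct, row$a3_pct)
    sds_a <- sd_scale * c(row$a1_sd_pct, row$a3_sd_pct)
    kinds <- c("exponential", "hyperbolic")
  } else {
    means_tau <- c(row$tau1_us * 1e-6, row$tau2_ms * 1e-3, row$tau3_s)
    sds_tau <- sd_scale * c(row$tau1_sd_us * 1e-6, row$tau2_sd_ms * 1e-3,
                            row$tau3_sd_s)
    means_a <- c(row$a1_pct, row$a2_pct, row$a3_pct)
    sds_a <- sd_scale * c(row$a1_sd_pct, row$a2_sd_pct, row$a3_sd_pct)
    kinds <- c("exponential", "exponential", "hyperbolic")
  }
  with_seed_if(seed, {
    purrr::map_dfr(seq_len(n_replicates), function(r) {
      p <- draw_replicate_params(means_tau, sds_tau, means_a, sds_a)
      model <- relaxation_model(f0 = f0, components = tibble::tibble(
        kind = kinds, amplitude = fv * p$a_pct / 100, tau_s = p$tau_s))
      trace <- generate_trace(
        model, t_min_s = t_min_s, t_max_s = t_max_s, n_points = n_points,
        spacing = spacing, noise_sigma = noise_sigma, seed = NULL,
        strain = row$strain, condition = row$condition, hours = row$hours,
        dcmu = dcmu, replicate = r)
      params <- setNames(
        as.list(c(p$tau_s, p$a_pct)),
        c(paste0("true_tau", if (dcmu) c(1, 3) else 1:3, "_s"),
          paste0("true_a", if (dcmu) c(1, 3) else 1:3, "_pct")))
      tibble::tibble(label = row$label, replicate = r,
                     !!!params, trace = list(trace))
    })
  })
}
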