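#' Decay components of the fluorescence relaxation model
#'
#' A component is one kinetic phase of the flash-induced variable-fluorescence
#' decay: either an exponential, `A * exp(-t / tau)`, describing forward
#' electron transfer out of QA-, or a first-order hyperbola,
#' `A / (1 + t / tau)`, describing charge recombination between the PSII
#' acceptor and donor sides. Both equal `A` at `t = 0` and decay to zero;
#' the hyperbola reaches `A / 2` at `t = tau`.
#'
#' @param kind `"exponential"` or `"hyperbolic"`.
#' @param amplitude Component amplitude in fluorescence units, `>= 0`.
#' @param tau_s Time constant in seconds, `> 0`.
#' @return A one-row tibble with columns `kind`, `amplitude`, `tau_s`.
#' @examples
#' decay_component("hyperbolic", amplitude = 0.8, tau_s = 8.05)
#' @export
decay_component <- function(kind = c("exponential", "hyperbolic"),
                            amplitude, tau_s) {
  kind <- match.arg(kind)
  if (!is.numeric(amplitude) || any(amplitude < 0) || any(!is.finite(amplitude))) {
    abort("`amplitude` must be finite and >= 0.", class = "qarelax_invalid_model")
  }
  if (!is.numeric(tau_s) || any(tau_s <= 0) || any(!is.finite(tau_s))) {
    abort("`tau_s` must be finite and > 0.", class = "qarelax_invalid_model")
  }
  tibble::tibble(kind = kind, amplitude = as.numeric(amplitude),
                 tau_s = as.numeric(tau_s))
}

#' Construct a fluorescence relaxation model
#'
#' The model is a stable baseline `f0` (non-variable fluorescence) plus one to
#' three [decay_component()]s. Components are stored sorted by ascending time
#' constant (ties broken by larger amplitude first) so that the fast / middle /
#' slow phase labels are deterministic. The model value at `t = 0` is
#' `f0 + sum(amplitudes)` — the flash-induced maximum — and tends to `f0` as
#' `t` grows; the summed amplitude is the total variable yield Fv.
#'
#' @param f0 Baseline fluorescence, `>= 0`.
#' @param components A tibble of components as produced by binding
#'   [decay_component()] rows (columns `kind`, `amplitude`, `tau_s`).
#' @return An object of class `relaxation_model`.
#' @examples
#' m <- relaxation_model(
#'   f0 = 0.2,
#'   components = rbind(
#'     decay_component("exponential", 0.55, 309e-6),
#'     decay_component("exponential", 0.15, 3.1e-3),
#'     decay_component("hyperbolic", 0.10, 8.05)
#'   )
#' )
#' eval_relaxation(m, c(0, 1e-3, 1))
#' @export
relaxation_model <- function(f0, components) {
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 < 0) {
    abort("`f0` must be a single finite number >= 0.", class = "qarelax_invalid_model")
  }
  components <- tibble::as_tibble(components)
  req <- c("kind", "amplitude", "tau_s")
  if (!all(req %in% names(components)) || nrow(components) < 1L ||
      nrow(components) > 3L) {
    abort("`components` needs columns kind/amplitude/tau_s and 1-3 rows.",
          class = "qarelax_invalid_model")
  }
  if (!all(components$kind %in% c("exponential", "hyperbolic"))) {
    abort("component `kind` must be exponential or hyperbolic.",
          class = "qarelax_invalid_model")
  }
  if (any(components$amplitude < 0) || any(components$tau_s <= 0) ||
      any(!is.finite(components$amplitude)) || any(!is.finite(components$tau_s))) {
    abort("components need amplitude >= 0 and tau_s > 0.",
          class = "qarelax_invalid_model")
  }
  components <- dplyr::arrange(components, .data$tau_s,
                               dplyr::desc(.data$amplitude))
  structure(list(f0 = as.numeric(f0), components = components),
            class = "relaxation_model")
}

#' @export
print.relaxation_model <- function(x, ...) {
  cat("<relaxation_model> f0 =", format(x$f0, digits = 4),
      " Fv =", format(sum(x$components$amplitude), digits = 4), "\n")
  print(x$components)
  invisible(x)
}

phase_labels <- function(n) {
  switch(as.character(n),
         "1" = "slow",
         "2" = c("fast", "slow"),
         "3" = c("fast", "middle", "slow"))
}

#' Evaluate a relaxation model on a time grid
#'
#' Computes `f0 + sum_exp A_i exp(-t/tau_i) + sum_hyp A_j / (1 + t/tau_j)`
#' element-wise.
#'
#' @param model A [relaxation_model()].
#' @param times_s Numeric vector of times in seconds, finite and `>= 0`.
#' @return Numeric vector of fluorescence values, same length as `times_s`.
#' @export
eval_relaxation <- function(model, times_s) {
  stopifnot(inherits(model, "relaxation_model"))
  if (!is.numeric(times_s) || any(!is.finite(times_s)) || any(times_s < 0)) {
    abort("`times_s` must be finite and >= 0.", class = "qarelax_invalid_input")
  }
  comp <- model$components
  y <- rep(model$f0, length(times_s))
  for (i in seq_len(nrow(comp))) {
    y <- y + if (comp$kind[i] == "exponential") {
      comp$amplitude[i] * exp(-times_s / comp$tau_s[i])
    } else {
      comp$amplitude[i] / (1 + times_s / comp$tau_s[i])
    }
  }
  y
}

#' @export
predict.relaxation_model <- function(object, times_s, ...) {
  eval_relaxation(object, times_s)
}

#' Tidy a relaxation model into one row per kinetic phase
#'
#' @param x A [relaxation_model()].
#' @param ... Unused.
#' @return A tibble with `phase`, `kind`, `amplitude`, `tau_s` and the
#'   relative amplitude in percent of the total variable yield.
#' @export
tidy.relaxation_model <- function(x, ...) {
  comp <- x$components
  dplyr::mutate(comp,
                phase = phase_labels(nrow(comp)),
                rel_amp_pct = 100 * .data$amplitude / sum(.data$amplitude),
                .before = 1L)
}

#' Default logarithmic measurement grid
#'
#' Log-spaced time points emulating the decade-spanning acquisition window of
#' a single-turnover-flash fluorometer: the first point sits after the
#' instrument dead time, the last beyond the slowest recombination phase.
#'
#' @param t_min_s,t_max_s Grid limits in seconds.
#' @param n_points Number of points (`>= 20`).
#' @param spacing `"log"` (default) or `"linear"`.
#' @return Numeric vector of times in seconds, strictly increasing.
#' @export
default_time_grid <- function(t_min_s = 1e-4, t_max_s = 100, n_points = 200L,
                              spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (t_min_s <= 0 || t_max_s <= t_min_s) {
    abort("need 0 < t_min_s < t_max_s.", class = "qarelax_invalid_input")
  }
  if (n_points < 20L) {
    abort("`n_points` must be >= 20.", class = "qarelax_invalid_input")
  }
  if (spacing == "log") {
    exp(seq(log(t_min_s), log(t_max_s), length.out = n_points))
  } else {
    seq(t_min_s, t_max_s, length.out = n_points)
  }
}
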