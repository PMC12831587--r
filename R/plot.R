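#' Plot fitted relaxation traces on a log time axis
#'
#' One panel per group label: measured yields as points, the fitted decay as
#' a line, time on a log10 axis spanning the acquisition decades — the
#' conventional presentation of flash-induced fluorescence relaxation.
#'
#' @param fits Output of [fit_traces()] (a tibble with `trace` and `fit`
#'   list-columns), or a study tibble plus a matching list of fits in `fit`.
#' @param fit Optional list of `relaxation_fit` objects aligned row-for-row
#'   with `fits`; lengths must match.
#' @param file Optional output path (`.png`, `.svg`, `.pdf`); written with
#'   fixed size for deterministic output.
#' @return The ggplot object, invisibly `NULL` for empty input (with a
#'   warning, and no file written).
#' @export
plot_relaxation <- function(fits, fit = NULL, file = NULL) {
  stopifnot(is.data.frame(fits))
  if (!is.null(fit)) {
    if (length(fit) != nrow(fits)) {
      abort("`fit` must align with the rows of `fits`.",
            class = "qarelax_invalid_input")
    }
    fits$fit <- fit
  }
  if (nrow(fits) == 0L) {
    warn("nothing to plot.")
    return(invisible(NULL))
  }
  if (!all(c("trace", "fit") %in% names(fits))) {
    abort("`fits` needs `trace` and `fit` list-columns.",
          class = "qarelax_invalid_input")
  }
  dat <- purrr::map_dfr(seq_len(nrow(fits)), function(i) {
    tr <- fits$trace[[i]]
    f <- fits$fit[[i]]
    m <- trace_meta(tr)
    lab <- if ("label" %in% names(fits)) fits$label[[i]] else label_for_meta(m)
    out <- tibble::as_tibble(tr)
    out$label <- lab
    out$replicate <- m$replicate
    out$.fitted <- if (inherits(f, "relaxation_fit")) {
      eval_relaxation(f$model, out$time_s)
    } else NA_real_
    out
  })
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$fluorescence,
                                     group = .data$replicate),
                        size = 0.6, alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted,
                                    group = .data$replicate),
                       colour = "#c0392b", na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "Time after flash (s)",
                  y = "Relative variable fluorescence") +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 8, height = 6, dpi = 150)
  }
  p
}

#' Plot one relaxation fit
#' @param object A `relaxation_fit`.
#' @param ... Unused.
#' @return A ggplot of the trace and fitted curve on a log time axis.
#' @export
autoplot.relaxation_fit <- function(object, ...) {
  dat <- augment(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_s)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$fluorescence),
                        size = 0.8, alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$.fitted), colour = "#c0392b") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Time after flash (s)", y = "Fluorescence yield") +
    ggplot2::theme_bw()
}
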