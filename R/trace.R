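#' Construct a fluorescence trace
#'
#' A trace is the digital record of one flash-induced decay: a tibble with
#' columns `time_s` (seconds, strictly increasing) and `fluorescence`
#' (relative yield), carrying the sample metadata as attributes.
#'
#' @param time_s Times in seconds, strictly increasing, all `> 0` (the first
#'   point follows the instrument dead time).
#' @param fluorescence Fluorescence yields, same length, finite.
#' @param strain Strain label, e.g. `"WT 1"`.
#' @param condition Trophic condition, `"PA"` (photoautotrophy) or `"PM"`
#'   (photomixotrophy).
#' @param hours Hours of growth under `condition` (0 for the PA reference).
#' @param dcmu Logical; was the QB-site inhibitor DCMU present?
#' @param fr_preillumination Logical; far-red preillumination before the flash?
#' @param replicate Biological replicate id.
#' @return A tibble of class `fluor_trace` with a `meta` attribute.
#' @export
fluorescence_trace <- function(time_s, fluorescence,
                               strain = NA_character_,
                               condition = NA_character_,
                               hours = NA_integer_,
                               dcmu = FALSE,
                               fr_preillumination = FALSE,
                               replicate = NA_integer_) {
  if (length(time_s) != length(fluorescence)) {
    abort("`time_s` and `fluorescence` must have equal length.",
          class = "qarelax_invalid_input")
  }
  if (length(time_s) < 20L) {
    abort("a trace needs at least 20 points.", class = "qarelax_invalid_input")
  }
  if (any(!is.finite(time_s)) || any(time_s <= 0) || any(diff(time_s) <= 0)) {
    abort("`time_s` must be positive, finite and strictly increasing.",
          class = "qarelax_invalid_input")
  }
  if (any(!is.finite(fluorescence))) {
    abort("`fluorescence` must be finite.", class = "qarelax_invalid_input")
  }
  if (!is.na(condition) && !condition %in% c("PA", "PM")) {
    abort('`condition` must be "PA" or "PM".', class = "qarelax_invalid_input")
  }
  out <- tibble::tibble(time_s = as.numeric(time_s),
                        fluorescence = as.numeric(fluorescence))
  attr(out, "meta") <- list(strain = strain, condition = condition,
                            hours = as.integer(hours), dcmu = isTRUE(dcmu),
                            fr_preillumination = isTRUE(fr_preillumination),
                            replicate = as.integer(replicate))
  class(out) <- c("fluor_trace", class(out))
  out
}

#' @export
print.fluor_trace <- function(x, ...) {
  m <- trace_meta(x)
  cat("<fluor_trace> ", nrow(x), " points, ",
      format(min(x$time_s)), "-", format(max(x$time_s)), " s",
      if (!is.na(m$strain)) paste0(" | ", m$strain, " ", m$condition,
                                   if (isTRUE(m$dcmu)) " +DCMU" else ""),
      "\n", sep = "")
  NextMethod()
}

#' Metadata of a trace
#' @param trace A [fluorescence_trace()].
#' @return Named list of sample metadata.
#' @export
trace_meta <- function(trace) {
  attr(trace, "meta") %||%
    list(strain = NA_character_, condition = NA_character_,
         hours = NA_integer_, dcmu = FALSE, fr_preillumination = FALSE,
         replicate = NA_integer_)
}

# Plateau of the trace tail: a constant + hyperbola fitted to the last decade
# of points. A tail mean is biased upward when a slow recombination phase has
# not fully decayed inside the window; the hyperbolic tail model removes most
# of that bias.
estimate_plateau <- function(trace) {
  tmax <- max(trace$time_s)
  tail_idx <- trace$time_s >= tmax / 10
  tt <- trace$time_s[tail_idx]
  yy <- trace$fluorescence[tail_idx]
  if (length(tt) < 4L || stats::var(yy) == 0) {
    return(mean(yy))
  }
  res_fn <- function(p) p[1] + p[2] / (1 + tt / p[3]) - yy
  fit <- try(minpack.lm::nls.lm(
    par = c(c0 = min(yy), a = max(yy) - min(yy), tau = tmax),
    lower = c(-Inf, 0, tmax / 100), upper = c(Inf, Inf, tmax * 100),
    fn = res_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) mean(yy) else unname(fit$par[1])
}

#' Normalize a trace to the variable-fluorescence scale
#'
#' Rescales the yields affinely so the estimated tail plateau maps to 0 and
#' the initial maximum maps to 1, i.e. onto the relative variable-yield scale
#' used for plotting flash-induced relaxation. The rescaling parameters are
#' recorded in the `normalization` attribute; applying the function twice
#' changes nothing further.
#'
#' @param trace A [fluorescence_trace()].
#' @return The rescaled trace.
#' @export
normalize_trace <- function(trace) {
  stopifnot(inherits(trace, "fluor_trace"))
  plateau <- estimate_plateau(trace)
  fmax <- max(trace$fluorescence)
  if (plateau >= fmax) {
    abort("degenerate trace: tail plateau >= initial maximum (no variable yield).",
          class = "qarelax_degenerate_trace")
  }
  meta <- trace_meta(trace)
  out <- trace
  out$fluorescence <- (trace$fluorescence - plateau) / (fmax - plateau)
  attr(out, "meta") <- meta
  attr(out, "normalization") <- list(plateau = plateau, fmax = fmax)
  out
}

#' Read and write traces as plain-text tables
#'
#' The on-disk format is a tab-separated table with columns `time_s` and
#' `fluorescence`, preceded by `#`-prefixed `key=value` metadata lines
#' (`# strain=WT 1`, `# condition=PM`, `# hours=72`, `# dcmu=0`,
#' `# fr_preillumination=0`, `# replicate=1`). Writing then reading a trace
#' reproduces it exactly.
#'
#' @param path File path.
#' @return `read_trace()` returns a [fluorescence_trace()];
#'   `write_trace()` returns `path` invisibly.
#' @export
read_trace <- function(path) {
  lines <- readr::read_lines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ln), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2L) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  # columns parsed via strtod (correctly rounded) so write/read is lossless
  body <- readr::read_tsv(I(lines[!grepl("^#", lines)]),
                          col_types = readr::cols(.default = "c"),
                          show_col_types = FALSE)
  fluorescence_trace(
    time_s = as.numeric(body$time_s),
    fluorescence = as.numeric(body$fluorescence),
    strain = meta$strain %||% NA_character_,
    condition = meta$condition %||% NA_character_,
    hours = as.integer(meta$hours %||% NA),
    dcmu = (meta$dcmu %||% "0") == "1",
    fr_preillumination = (meta$fr_preillumination %||% "0") == "1",
    replicate = as.integer(meta$replicate %||% NA))
}

#' @rdname read_trace
#' @param trace A [fluorescence_trace()] to write.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "fluor_trace"))
  m <- trace_meta(trace)
  hdr <- c(
    if (!is.na(m$strain)) paste0("# strain=", m$strain),
    if (!is.na(m$condition)) paste0("# condition=", m$condition),
    if (!is.na(m$hours)) paste0("# hours=", m$hours),
    paste0("# dcmu=", as.integer(isTRUE(m$dcmu))),
    paste0("# fr_preillumination=", as.integer(isTRUE(m$fr_preillumination))),
    if (!is.na(m$replicate)) paste0("# replicate=", m$replicate))
  body <- paste(sprintf("%.17e", trace$time_s),
                sprintf("%.17e", trace$fluorescence), sep = "\t")
  readr::write_lines(c(hdr, "time_s\tfluorescence", body), path)
  invisible(path)
}
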