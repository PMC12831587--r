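#' Simulate a full replicate study from phase-parameter rows
#'
#' Generates `n_replicates` synthetic traces per row of a [load_table1()]
#' style table, drawing per-replicate biological scatter from the row SDs and
#' applying multiplicative measurement noise (see [generate_replicates()]).
#'
#' @param rows Phase-parameter rows; defaults to the full packaged table.
#' @param n_replicates Replicates per row.
#' @param sd_scale Multiplier on the row SDs (0 = identical replicates).
#' @param noise_sigma Relative measurement noise SD.
#' @param seed Integer seed; the whole study is reproducible from it.
#' @param ... Grid/scale arguments passed to [generate_replicates()].
#' @return A tibble with one row per trace: grouping keys, replicate id, the
#'   generating parameter draw and a `trace` list-column.
#' @export
simulate_study <- function(rows = load_table1(), n_replicates = 3L,
                           sd_scale = 1, noise_sigma = 0.02, seed = 1L, ...) {
  with_seed_if(seed, {
    purrr::map_dfr(seq_len(nrow(rows)), function(i) {
      row <- rows[i, ]
      reps <- generate_replicates(row, n_replicates = n_replicates,
                                  sd_scale = sd_scale,
                                  noise_sigma = noise_sigma, seed = NULL, ...)
      if (nrow(reps) == 0L) return(reps)
      dplyr::mutate(reps, strain = row$strain, condition = row$condition,
                    hours = row$hours, dcmu = row$dcmu,
                    .after = "label")
    })
  })
}

# canonical group label from trace metadata, mirroring the published layout
label_for_meta <- function(m) {
  paste0(m$strain, " ", m$condition,
         if (isTRUE(m$dcmu)) " + DCMU" else "",
         if (!is.na(m$hours) && m$hours > 0) paste0(" ", m$hours, " h") else "")
}

# wide per-trace summary of one fit in reporting units
fit_to_wide <- function(fit) {
  td <- tidy(fit)
  g <- glance(fit)
  wide <- tibble::tibble(tau1_us = NA_real_, a1_pct = NA_real_,
                         tau2_ms = NA_real_, a2_pct = NA_real_,
                         tau3_s = NA_real_, a3_pct = NA_real_)
  for (i in seq_len(nrow(td))) {
    slot <- c(fast = 1L, middle = 2L, slow = 3L)[[td$phase[i]]]
    wide[[paste0("tau", slot, "_", c("us", "ms", "s")[slot])]] <- td$tau_report[i]
    wide[[paste0("a", slot, "_pct")]] <- td$rel_amp_pct[i]
  }
  dplyr::bind_cols(wide, g[c("rmse", "converged", "start_index", "f0", "fv")])
}

#' Fit every trace of a study table
#'
#' Maps [fit_relaxation()] over the `trace` list-column; the model form per
#' trace follows its DCMU flag (`dcmu_two_phase` when the trace was measured
#' with DCMU, `three_phase` otherwise). A trace whose fit fails is kept as a
#' diagnostic row (`converged = FALSE`, `NA` parameters) and the batch
#' continues.
#'
#' @param study A tibble with a `trace` list-column, e.g. from
#'   [simulate_study()].
#' @param n_starts,seed Passed to [fit_relaxation()].
#' @return The input plus a `fit` list-column and per-phase wide columns
#'   `tau1_us`, `a1_pct`, `tau2_ms`, `a2_pct`, `tau3_s`, `a3_pct`, `rmse`,
#'   `converged`.
#' @export
fit_traces <- function(study, n_starts = 16L, seed = 1L) {
  stopifnot(is.data.frame(study), "trace" %in% names(study))
  fits <- purrr::map(study$trace, function(tr) {
    form <- if (isTRUE(trace_meta(tr)$dcmu)) "dcmu_two_phase" else "three_phase"
    tryCatch(fit_relaxation(tr, model_form = form, n_starts = n_starts,
                            seed = seed),
             error = function(e) e)
  })
  wide <- purrr::map_dfr(fits, function(f) {
    if (inherits(f, "error")) {
      tibble::tibble(tau1_us = NA_real_, a1_pct = NA_real_,
                     tau2_ms = NA_real_, a2_pct = NA_real_,
                     tau3_s = NA_real_, a3_pct = NA_real_,
                     rmse = NA_real_, converged = FALSE,
                     start_index = NA_integer_, f0 = NA_real_, fv = NA_real_)
    } else {
      fit_to_wide(f)
    }
  })
  failed <- vapply(fits, inherits, logical(1), "error")
  if (any(failed)) {
    warn(paste(sum(failed), "trace(s) failed to fit; kept as diagnostic rows."))
  }
  dplyr::bind_cols(tibble::as_tibble(study), wide) |>
    dplyr::mutate(fit = fits)
}

report_params <- c("tau1_us", "a1_pct", "tau2_ms", "a2_pct", "tau3_s", "a3_pct")

#' Aggregate per-trace fits into a mean-and-SD replicate table
#'
#' Groups fitted traces by (strain, condition, hours, DCMU), computes the
#' across-replicate mean and SD of every phase parameter, and attaches two
#' families of pairwise significance marks from [unpaired_t_test()]:
#' `star_*` compares the group against the other strain under the same
#' condition/time/DCMU, `hash_*` against the same strain's photoautotrophic
#' baseline (PA, or PA + DCMU for DCMU groups). A mark column is `NA` when
#' the comparison group does not exist or either side has fewer than two
#' converged fits.
#'
#' @param fits Output of [fit_traces()].
#' @param alpha Significance level for the marks.
#' @return A tibble with one row per group, mirroring the fast/middle/slow
#'   layout: `<param>_mean`, `<param>_sd`, `n`, and logical `star_*` /
#'   `hash_*` columns per parameter.
#' @export
replicate_table <- function(fits, alpha = 0.05) {
  stopifnot(is.data.frame(fits))
  ok <- dplyr::filter(fits, .data$converged)
  groups <- dplyr::group_by(ok, .data$label, .data$strain, .data$condition,
                            .data$hours, .data$dcmu)
  summ <- dplyr::summarise(
    groups,
    n = dplyr::n(),
    dplyr::across(dplyr::all_of(report_params),
                  list(mean = ~mean(.x), sd = ~sd(.x))),
    .groups = "drop")
  single <- summ$n < 2L
  if (any(single)) {
    warn(paste("group(s) with a single replicate:",
               paste(summ$label[single], collapse = ", "),
               "- SDs and marks omitted."))
    summ[single, grep("_sd$", names(summ))] <- NA_real_
  }

  group_values <- function(strain, condition, hours, dcmu, param) {
    v <- ok[[param]][ok$strain == strain & ok$condition == condition &
                       ok$hours == hours & ok$dcmu == dcmu]
    v[is.finite(v)]
  }
  test_pair <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L) return(NA)
    unpaired_t_test(a, b, alpha = alpha)$significant
  }
  strains <- unique(summ$strain)
  marks <- purrr::map_dfr(seq_len(nrow(summ)), function(i) {
    g <- summ[i, ]
    other <- setdiff(strains, g$strain)
    out <- list()
    for (p in report_params) {
      own <- group_values(g$strain, g$condition, g$hours, g$dcmu, p)
      star <- if (length(other) == 1L) {
        test_pair(own, group_values(other, g$condition, g$hours, g$dcmu, p))
      } else NA
      is_baseline <- g$condition == "PA" && g$hours == 0
      hash <- if (!is_baseline) {
        test_pair(own, group_values(g$strain, "PA", 0L, g$dcmu, p))
      } else NA
      out[[paste0("star_", p)]] <- star
      out[[paste0("hash_", p)]] <- hash
    }
    tibble::as_tibble(out)
  })
  dplyr::bind_cols(summ, marks)
}

#' Run the full simulate-or-load / fit / report batch
#'
#' The end-to-end analysis: obtain traces (simulated from phase-parameter
#' rows, or loaded from trace files), deconvolve each, and aggregate into the
#' replicate table with significance marks. Fully reproducible from the seed.
#'
#' @param mode `"simulate"` (default) or `"load"`.
#' @param rows Phase-parameter rows for simulate mode.
#' @param trace_paths Character vector of trace files for load mode.
#' @param n_replicates,sd_scale,noise_sigma Simulation settings.
#' @param n_starts,fit_seed Fitting settings.
#' @param alpha Significance level for the report marks.
#' @param seed Master seed for trace generation.
#' @param out_dir Optional directory; when given, `report.tsv` and
#'   `fits.tsv` are written there.
#' @return A list with `report` (the [replicate_table()]) and `fits` (the
#'   per-trace [fit_traces()] table).
#' @export
run_batch <- function(mode = c("simulate", "load"), rows = load_table1(),
                      trace_paths = NULL, n_replicates = 3L, sd_scale = 1,
                      noise_sigma = 0.02, n_starts = 16L, fit_seed = 1L,
                      alpha = 0.05, seed = 1L, out_dir = NULL) {
  mode <- match.arg(mode)
  study <- if (mode == "simulate") {
    simulate_study(rows, n_replicates = n_replicates, sd_scale = sd_scale,
                   noise_sigma = noise_sigma, seed = seed)
  } else {
    if (is.null(trace_paths)) {
      abort("load mode needs `trace_paths`.", class = "qarelax_invalid_input")
    }
    traces <- lapply(trace_paths, read_trace)
    purrr::map_dfr(traces, function(tr) {
      m <- trace_meta(tr)
      tibble::tibble(label = label_for_meta(m), strain = m$strain,
                     condition = m$condition, hours = m$hours, dcmu = m$dcmu,
                     replicate = m$replicate, trace = list(tr))
    })
  }
  fits <- fit_traces(study, n_starts = n_starts, seed = fit_seed)
  report <- replicate_table(fits, alpha = alpha)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(report, file.path(out_dir, "report.tsv"))
    readr::write_tsv(dplyr::select(fits, -dplyr::any_of(c("trace", "fit"))),
                     file.path(out_dir, "fits.tsv"))
  }
  list(report = report, fits = fits)
}
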