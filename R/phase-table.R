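#' Published phase parameters for QA- reoxidation in Synechocystis WT strains
#'
#' Loads the packaged table of deconvolved phase parameters (mean and SD of
#' each time constant and relative amplitude, n = 3 biological replicates)
#' for two wild-type substrains under photoautotrophy (PA) and 0-72 h of
#' photomixotrophy (PM), with and without DCMU. Time constants are printed in
#' their reporting units (fast phase in microseconds, middle in milliseconds,
#' slow in seconds); relative amplitudes in percent of the total variable
#' yield. DCMU rows have no middle phase (`NA`).
#'
#' @return A tibble with 14 rows and columns `label`, `strain`, `condition`,
#'   `hours`, `dcmu`, and per phase `tau<i>_*`, `a<i>_pct`, `*_sd_*`.
#' @examples
#' load_table1()
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "qa_reoxidation_phase_parameters.tsv",
                      package = "qarelax", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, table1_md5)) {
    abort("packaged phase-parameter table failed its integrity check.",
          class = "qarelax_data_integrity")
  }
  tbl <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           label = "c", strain = "c", condition = "c",
                           hours = "i", dcmu = "i", .default = "d"))
  dplyr::mutate(tbl, dcmu = .data$dcmu == 1L)
}

# frozen checksum of the shipped fixture
table1_md5 <- "22c3689a4acd3f247624bf358a7ea9dc"

#' Turn one phase-parameter row into a generating model
#'
#' Converts the printed means of one row of [load_table1()] into a
#' [relaxation_model()]: time constants to seconds, relative amplitudes
#' (renormalized to sum to 100% to absorb printed rounding) to absolute
#' amplitudes scaled to a total variable yield `fv`. Non-DCMU rows give two
#' exponentials plus a hyperbola; DCMU rows one exponential plus a hyperbola.
#'
#' @param row A one-row tibble from [load_table1()] (or the same columns).
#' @param f0 Baseline fluorescence of the generated model.
#' @param fv Total variable yield (sum of component amplitudes).
#' @return A [relaxation_model()].
#' @export
row_to_model <- function(row, f0 = 0.2, fv = 1) {
  row <- tibble::as_tibble(row)
  stopifnot(nrow(row) == 1L)
  if (isTRUE(row$dcmu)) {
    taus <- c(row$tau1_us * 1e-6, row$tau3_s)
    amps <- c(row$a1_pct, row$a3_pct)
    kinds <- c("exponential", "hyperbolic")
  } else {
    taus <- c(row$tau1_us * 1e-6, row$tau2_ms * 1e-3, row$tau3_s)
    amps <- c(row$a1_pct, row$a2_pct, row$a3_pct)
    kinds <- c("exponential", "exponential", "hyperbolic")
  }
  if (anyNA(taus) || anyNA(amps)) {
    abort("row is missing phase parameters for its model form.",
          class = "qarelax_invalid_input")
  }
  amps <- fv * amps / sum(amps)
  relaxation_model(f0 = f0, components = tibble::tibble(
    kind = kinds, amplitude = amps, tau_s = taus))
}
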