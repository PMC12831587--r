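test_that("the noiseless pipeline reproduces the published table means", {
  res <- suppressWarnings(
    run_batch(rows = load_table1(), n_replicates = 2, sd_scale = 0,
              noise_sigma = 0, seed = 1))
  report <- res$report
  expect_equal(nrow(report), 14L)
  tbl <- load_table1()
  relaxed <- c("WT 1 PM 72 h", "WT 3 PM 72 h")
  for (i in seq_len(nrow(tbl))) {
    row <- tbl[i, ]
    got <- report[report$label == row$label, ]
    tol <- if (row$label %in% relaxed) 0.05 else 0.01
    expect_equal(got$tau1_us_mean, row$tau1_us, tolerance = tol,
                 label = paste(row$label, "tau1"))
    expect_equal(got$tau3_s_mean, row$tau3_s, tolerance = tol,
                 label = paste(row$label, "tau3"))
    asum <- sum(c(row$a1_pct, row$a2_pct, row$a3_pct), na.rm = TRUE)
    expect_equal(got$a3_pct_mean, 100 * row$a3_pct / asum, tolerance = tol,
                 label = paste(row$label, "A3"))
  }
})

test_that("report amplitude means sum to 100% within fit-noise tolerance", {
  rows <- load_table1()[c(1, 5, 12), ]
  res <- run_batch(rows = rows, n_replicates = 3, noise_sigma = 0.02,
                   seed = 11)
  asum <- rowSums(cbind(res$report$a1_pct_mean, res$report$a2_pct_mean,
                        res$report$a3_pct_mean), na.rm = TRUE)
  expect_true(all(abs(asum - 100) < 0.5))
})

test_that("load mode reproduces the simulate-mode report exactly", {
  rows <- load_table1()[c(1, 9), ]
  sim <- run_batch(rows = rows, n_replicates = 2, noise_sigma = 0.02,
                   seed = 5)
  dir <- withr::local_tempdir()
  paths <- character(0)
  for (i in seq_len(nrow(sim$fits))) {
    p <- file.path(dir, sprintf("trace%02d.tsv", i))
    write_trace(sim$fits$trace[[i]], p)
    paths <- c(paths, p)
  }
  loaded <- run_batch(mode = "load", trace_paths = paths, seed = 5)
  cols <- c("label", "n", "tau1_us_mean", "a1_pct_mean", "tau3_s_mean",
            "a3_pct_mean")
  expect_equal(loaded$report[cols], sim$report[cols])
})

test_that("the batch is deterministic: same seed, byte-identical report file", {
  rows <- load_table1()[c(1, 9), ]
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_batch(rows = rows, n_replicates = 2, noise_sigma = 0.02, seed = 8,
            out_dir = d1)
  run_batch(rows = rows, n_replicates = 2, noise_sigma = 0.02, seed = 8,
            out_dir = d2)
  expect_identical(readLines(file.path(d1, "report.tsv")),
                   readLines(file.path(d2, "report.tsv")))
  expect_identical(unname(tools::md5sum(file.path(d1, "fits.tsv"))),
                   unname(tools::md5sum(file.path(d2, "fits.tsv"))))
})

test_that("significance marks follow the two published comparison schemes", {
  rows <- load_table1()[c(1, 4, 9, 12), ]  # WT 1 / WT 3, PA and PM 72 h
  res <- run_batch(rows = rows, n_replicates = 3, noise_sigma = 0.02,
                   seed = 3)
  report <- res$report
  pa1 <- report[report$label == "WT 1 PA", ]
  pm1 <- report[report$label == "WT 1 PM 72 h", ]
  # the PA baseline rows carry no hash marks (nothing to compare against)
  expect_true(is.na(pa1$hash_a3_pct))
  # both schemes are populated for a non-baseline row with a partner strain
  expect_false(is.na(pm1$star_a3_pct))
  expect_false(is.na(pm1$hash_a3_pct))
  # the headline contrast: slow-phase amplitude 84% vs 8% must flag
  expect_true(pm1$hash_a3_pct)
  expect_true(pm1$star_a3_pct)
})

test_that("a single-replicate group is reported without SDs, with a warning", {
  rows <- load_table1()[1, ]
  expect_warning(
    res <- run_batch(rows = rows, n_replicates = 1, noise_sigma = 0.02,
                     seed = 2),
    "single replicate")
  expect_equal(res$report$n, 1L)
  expect_true(is.na(res$report$tau1_us_sd))
})

test_that("relaxation plots honour the grouping layout and write files", {
  rows <- load_table1()[c(1, 4, 9, 12), ]
  sim <- simulate_study(rows, n_replicates = 1, noise_sigma = 0.02, seed = 6)
  fits <- fit_traces(sim, n_starts = 6)
  p <- plot_relaxation(fits)
  built <- ggplot2::ggplot_build(p)
  expect_equal(length(unique(built$layout$layout$label)), 4L)

  f <- file.path(withr::local_tempdir(), "panels.png")
  plot_relaxation(fits, file = f)
  expect_true(file.exists(f) && file.size(f) > 0)

  expect_warning(out <- plot_relaxation(fits[0, ]), "nothing to plot")
  expect_null(out)
  expect_error(plot_relaxation(fits, fit = list(1)),
               class = "qarelax_invalid_input")
})

test_that("single fits plot with data and fitted curve overlaid", {
  fit <- fit_relaxation(generate_trace(wt1_pa_model()), n_starts = 4)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
  expect_equal(length(p$layers), 2L)
})
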