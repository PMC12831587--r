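# shared fixtures, built in code

one_exp_model <- function(f0 = 0, a = 1, tau = 1) {
  relaxation_model(f0, decay_component("exponential", a, tau))
}

one_hyp_model <- function(f0 = 0, a = 1, tau = 1) {
  relaxation_model(f0, decay_component("hyperbolic", a, tau))
}

wt1_pa_model <- function(f0 = 0.2) {
  row_to_model(dplyr::filter(load_table1(), label == "WT 1 PA"), f0 = f0)
}

table1_row <- function(lab) {
  dplyr::filter(load_table1(), label == lab)
}

random_model <- function() {
  k <- sample(1:3, 1)
  relaxation_model(
    f0 = runif(1, 0, 0.5),
    components = tibble::tibble(
      kind = sample(c("exponential", "hyperbolic"), k, replace = TRUE),
      amplitude = runif(k, 0.05, 1),
      tau_s = 10^runif(k, -4, 1.5)))
}

# brute-force least-squares oracle: grid over time constants, amplitudes and
# baseline solved exactly by linear least squares at each grid node
grid_search_oracle <- function(trace, kinds, tau_grids) {
  y <- trace$fluorescence
  tt <- trace$time_s
  basis <- function(kind, tau) {
    if (kind == "exponential") exp(-tt / tau) else 1 / (1 + tt / tau)
  }
  combos <- expand.grid(lapply(tau_grids, identity))
  best <- list(rss = Inf)
  for (i in seq_len(nrow(combos))) {
    taus <- as.numeric(combos[i, ])
    X <- cbind(1, mapply(basis, kinds, taus))
    cf <- qr.coef(qr(X), y)
    rss <- sum((y - X %*% cf)^2)
    if (rss < best$rss) {
      best <- list(rss = rss, tau = taus, f0 = cf[1], a = cf[-1])
    }
  }
  best
}
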