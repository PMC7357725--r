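# Shared fixtures and independent oracles.

# Minimal valid trial table built in code.
make_trials <- function(n = 3) {
  data.frame(
    study_id = sprintf("S%02d", seq_len(n)),
    site_id = sprintf("T%02d", seq_len(n)),
    region = rep(c("kenya", "ssa_other"), length.out = n),
    yield_t_mean = seq(2000, by = 500, length.out = n),
    yield_c_mean = seq(1000, by = 200, length.out = n),
    yield_t_sd = rep(300, n), yield_c_sd = rep(200, n),
    n_t = rep(3L, n), n_c = rep(3L, n),
    n_rate = rep(60, n),
    soil_ph = stats::runif(n, 4.5, 6.5),
    total_c = stats::runif(n, 5, 30),
    p_olsen = stats::runif(n, 2, 20),
    exch_k = stats::runif(n, 0.1, 1.5),
    clay = rep(30, n), sand = rep(40, n), silt = rep(30, n),
    rainfall = stats::runif(n, 500, 1200),
    nutrient_type = rep("N_only", n),
    manager = rep("farmer", n),
    stringsAsFactors = FALSE)
}

# Restricted log-likelihood of the intercept-only RE model (independent
# of the package internals).
reml_ll_oracle <- function(tau2, yi, vi) {
  wi <- 1 / (vi + tau2)
  mu <- sum(wi * yi) / sum(wi)
  -0.5 * (sum(log(vi + tau2)) + log(sum(wi)) + sum(wi * (yi - mu)^2))
}

# Two-stage dense grid search of the restricted likelihood over tau2.
reml_grid_oracle <- function(yi, vi) {
  upper <- max(10 * stats::var(yi), 10 * max(vi), 1e-6)
  grid <- seq(0, upper, length.out = 4001)
  ll <- vapply(grid, reml_ll_oracle, numeric(1), yi = yi, vi = vi)
  best <- grid[which.max(ll)]
  step <- grid[2] - grid[1]
  fine <- seq(max(0, best - step), best + step, length.out = 4001)
  llf <- vapply(fine, reml_ll_oracle, numeric(1), yi = yi, vi = vi)
  fine[which.max(llf)]
}

# Independent brute-force coding of the Duval-Tweedie L0 recursion,
# written directly from the published estimator: missing studies assumed
# on the left, so the largest effects are trimmed.
trimfill_l0_oracle <- function(yi, vi, max_iter = 100) {
  fe <- function(y, v) sum(y / v) / sum(1 / v)
  o <- order(yi)
  y <- yi[o]; v <- vi[o]
  n <- length(y)
  k0 <- 0
  repeat {
    max_iter <- max_iter - 1
    yt <- if (k0 > 0) y[1:(n - k0)] else y
    vt <- if (k0 > 0) v[1:(n - k0)] else v
    center <- fe(yt, vt)
    dev <- y - center
    rk <- rank(abs(dev), ties.method = "first")
    Tn <- sum(rk[dev > 0])
    l0 <- (4 * Tn - n * (n + 1)) / (2 * n - 1)
    k0_new <- min(n - 1, max(0, round(l0)))
    if (k0_new == k0 || max_iter <= 0) break
    k0 <- k0_new
  }
  k0
}
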