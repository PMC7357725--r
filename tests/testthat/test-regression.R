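# Standardized GLMs, PLS variable importance, and the power-law fit.

test_that("the log recipe transforms the skewed predictors only", {
  tab <- data.frame(p_olsen = 10, clay = 30, soil_ph = 5.5, rainfall = 900)
  out <- transform_predictors(tab)
  expect_equal(out$log_p_olsen, log(10), tolerance = 1e-12)
  expect_equal(out$log_rainfall, log(900))
  expect_equal(out$clay, 30)            # clay stays untransformed
  expect_equal(out$soil_ph, 5.5)        # pH stays untransformed
  expect_null(out$p_olsen)
  # non-positive values under log are rejected by default, NA on request
  tab$p_olsen <- 0
  expect_error(transform_predictors(tab), "non-positive")
  out2 <- transform_predictors(tab, on_nonpositive = "na")
  expect_true(is.na(out2$log_p_olsen))
})

test_that("standardize scales to unit sd without centering", {
  set.seed(26)
  tab <- data.frame(a = rnorm(50, 10, 3), b = rnorm(50, -2, 0.5))
  out <- standardize(tab)
  expect_equal(sd(out$a), 1)
  expect_equal(sd(out$b), 1)
  # no centering: the mean moves only by the scale factor
  expect_equal(mean(out$a), mean(tab$a) / sd(tab$a))
  expect_equal(unname(attr(out, "scales")), c(sd(tab$a), sd(tab$b)))
  expect_equal(standardize(data.frame(u = out$a))$u, out$a)  # sd = 1 unchanged
  expect_error(standardize(data.frame(k = rep(2, 10))), "constant")
})

test_that("scale-only standardization leaves slope t statistics unchanged", {
  set.seed(27)
  n <- 80
  X <- data.frame(a = rnorm(n, 5, 2), b = runif(n, 1, 9))
  y <- 0.4 * X$a - 0.2 * X$b + rnorm(n)
  raw <- summary(lm(y ~ ., data = X))$coefficients
  Xs <- standardize(X)
  std <- fit_glm(y, Xs)$coefficients
  expect_equal(std$t_value[std$predictor == "a"], raw["a", "t value"])
  expect_equal(std$p_value[std$predictor == "b"], raw["b", "Pr(>|t|)"])
  # coefficients rescale by the recorded factors
  expect_equal(std$estimate[std$predictor == "a"],
               raw["a", "Estimate"] * attr(Xs, "scales")[["a"]])
})

test_that("fit_glm matches brute-force normal equations and reports fit
          quality", {
  set.seed(28)
  n <- 60
  X <- data.frame(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n))
  y <- 1 + 2 * X$x1 - X$x2 + rnorm(n, 0, 0.5)
  fit <- fit_glm(y, X)
  A <- cbind(1, as.matrix(X))
  beta <- solve(t(A) %*% A, t(A) %*% y)
  expect_equal(fit$coefficients$estimate, drop(beta), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_lte(fit$adjusted_r2, fit$r2)
  # exact linear data: r2 = 1 ("perfect fit" lm warning expected)
  y2 <- 3 * X$x1 + 0.5
  expect_equal(suppressWarnings(fit_glm(y2, X))$r2, 1)
  # null simulation: r2 near 0, coefficients small
  set.seed(29)
  Xn <- data.frame(a = rnorm(1000), b = rnorm(1000))
  yn <- rnorm(1000)
  fn <- fit_glm(yn, Xn)
  expect_lt(fn$r2, 0.02)
  expect_true(all(abs(fn$coefficients$estimate[-1]) < 0.1))
})

test_that("the N application rate is barred from predicting N-AE", {
  set.seed(30)
  X <- data.frame(log_n_rate = rnorm(30), soil_ph = rnorm(30))
  expect_error(fit_glm(rnorm(30), X, response = "n_ae"), "must not predict")
  expect_s3_class(fit_glm(rnorm(30), X, response = "ln_fr"), "fr_glm")
})

test_that("VIP scores satisfy their algebraic identities", {
  set.seed(31)
  n <- 50
  # single predictor: VIP = 1 exactly
  X1 <- data.frame(x = rnorm(n))
  y <- 2 * X1$x + rnorm(n, 0, 0.3)
  v1 <- vip_scores(y, X1, n_components = 1)
  expect_equal(unname(v1$scores), 1, tolerance = 1e-10)
  # sum of squared VIPs equals p, for any p and component count
  for (p in c(3, 6)) {
    X <- as.data.frame(matrix(rnorm(n * p), n))
    yy <- rowSums(X[, 1:2]) + rnorm(n, 0, 0.5)
    for (a in c(1, 2, 3)) {
      v <- vip_scores(yy, X, n_components = a)
      expect_equal(sum(v$scores^2), p, tolerance = 1e-8)
    }
  }
})

test_that("with orthonormal X and a single informative predictor, VIP
          attains the closed form sqrt(p)", {
  set.seed(32)
  n <- 40; p <- 5
  M <- matrix(rnorm(n * p), n)
  M <- sweep(M, 2, colMeans(M))                # column space orthogonal to 1
  X <- qr.Q(qr(M))                             # orthonormal AND centered
  y <- 3 * X[, 1]                              # only x1 carries signal
  v <- vip_scores(y, as.data.frame(X), n_components = 1)
  expect_equal(unname(v$scores[1]), sqrt(p), tolerance = 1e-6)
  expect_equal(unname(v$scores[-1]), rep(0, p - 1), tolerance = 1e-6)
  expect_equal(v$important, colnames(as.data.frame(X))[1])
})

test_that("VIP ranking is invariant to predictor reordering and flags the
          signal carriers", {
  set.seed(33)
  n <- 120; p <- 6
  X <- as.data.frame(matrix(rnorm(n * p), n))
  names(X) <- paste0("v", 1:p)
  y <- 1.2 * X$v2 - 1.0 * X$v5 + rnorm(n, 0, 0.6)
  a <- vip_scores(y, X, n_components = 2)
  b <- vip_scores(y, X[, sample(p)], n_components = 2)
  expect_equal(a$scores[names(b$scores)], b$scores, tolerance = 1e-8)
  # the two signal carriers take the top-2 scores in most replicates
  top2 <- replicate(20, {
    Xr <- as.data.frame(matrix(rnorm(n * p), n))
    names(Xr) <- paste0("v", 1:p)
    yr <- 1.2 * Xr$v2 - 1.0 * Xr$v5 + rnorm(n, 0, 0.6)
    s <- sort(vip_scores(yr, Xr, n_components = 2)$scores, decreasing = TRUE)
    setequal(names(s)[1:2], c("v2", "v5"))
  })
  expect_gte(mean(top2), 0.9)
})

test_that("VIP agrees with an independent PLS implementation", {
  skip_if_not_installed("mixOmics")
  set.seed(34)
  n <- 60; p <- 4
  X <- as.data.frame(matrix(rnorm(n * p), n))
  y <- X[[1]] - 0.5 * X[[3]] + rnorm(n, 0, 0.4)
  ours <- vip_scores(y, X, n_components = 2)
  mo <- mixOmics::pls(scale(as.matrix(X), scale = FALSE), y, ncomp = 2,
                      scale = FALSE)
  theirs <- mixOmics::vip(mo)[, 2]
  expect_equal(unname(ours$scores), unname(theirs), tolerance = 1e-6)
})

test_that("the power law is recovered from noiseless and noisy data", {
  set.seed(35)
  cy <- exp(runif(50, 6, 9))
  fr <- 2 * cy^(-0.5)
  fit <- suppressWarnings(fit_power_law(fr, cy))  # exact fit warns in lm
  expect_equal(fit$a, 2, tolerance = 1e-8)
  expect_equal(fit$b, -0.5, tolerance = 1e-10)
  expect_equal(fit$r2, 1)
  # flat data: slope p-value large
  fr0 <- exp(rnorm(50, log(2), 0.3))
  fit0 <- fit_power_law(fr0, cy)
  expect_gt(fit0$p, 0.05)
  expect_error(fit_power_law(fr, rep(1000, 50)), "degenerate")
  # coverage: the slope CI catches the true exponent in >= 90% of reps
  hits <- replicate(200, {
    cyr <- exp(runif(200, 6, 9))
    frr <- 80 * cyr^(-0.5) * exp(rnorm(200, 0, 0.4))
    f <- fit_power_law(frr, cyr)
    se_b <- summary(f$lm)$coefficients[2, 2]
    abs(f$b - (-0.5)) < 2 * se_b
  })
  expect_gte(mean(hits), 0.9)
})
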