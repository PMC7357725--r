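# Random-effects meta-analysis: Q statistic, REML fit, subgroup means,
# and CI-based comparisons.

test_that("Q statistic matches hand computation and edge cases", {
  expect_equal(q_statistic(0.3, 0.1)$q_t, 0)
  expect_equal(q_statistic(0.3, 0.1)$df, 0L)
  q <- q_statistic(c(0, 1), c(1, 1))
  expect_equal(q$q_t, 0.5)
  expect_equal(q$df, 1L)
  expect_equal(q$p, stats::pchisq(0.5, 1, lower.tail = FALSE))
  # identical effects give zero heterogeneity regardless of variances
  expect_equal(q_statistic(rep(0.7, 5), runif(5, 0.1, 2))$q_t, 0)
  expect_error(q_statistic(c(0, 1), c(1, 0)), "> 0")
})

test_that("Q has the nominal chi-square type-I error under homogeneity", {
  set.seed(14)
  k <- 20
  reps <- 1000
  rej <- mean(replicate(reps, {
    vi <- runif(k, 0.05, 0.5)
    yi <- rnorm(k, 0.4, sqrt(vi))
    q_statistic(yi, vi)$p < 0.05
  }))
  expect_gte(rej, 0.03)
  expect_lte(rej, 0.08)
})

test_that("REML recovers the equal-variance closed form", {
  # equal sampling variances: tau2 = max(0, sample variance - v)
  fit <- rema(c(0, 2), c(1, 1))
  expect_equal(fit$tau2, 1, tolerance = 1e-6)
  expect_equal(fit$mu, 1, tolerance = 1e-10)
  # homogeneous data: tau2 = 0, mu = common value
  fit0 <- rema(rep(0.4, 5), runif(5, 0.1, 0.5))
  expect_equal(fit0$tau2, 0)
  expect_equal(fit0$mu, 0.4)
})

test_that("REML equals a dense grid search of the restricted likelihood", {
  set.seed(15)
  for (rep in 1:12) {
    k <- sample(3:10, 1)
    vi <- runif(k, 0.02, 0.4)
    yi <- rnorm(k, 0.5, sqrt(vi + 0.2))
    fit <- rema(yi, vi)
    expect_lt(abs(fit$tau2 - reml_grid_oracle(yi, vi)), 1e-6)
  }
})

test_that("REML fit is location-equivariant and matches metafor", {
  set.seed(16)
  k <- 15
  vi <- runif(k, 0.02, 0.3)
  yi <- rnorm(k, 0.6, sqrt(vi + 0.1))
  fit <- rema(yi, vi)
  shifted <- rema(yi + 3, vi)
  expect_equal(shifted$mu, fit$mu + 3, tolerance = 1e-8)
  expect_equal(shifted$tau2, fit$tau2, tolerance = 1e-8)
  skip_if_not_installed("metafor")
  mf <- metafor::rma(yi = yi, vi = vi, method = "REML")
  expect_equal(fit$mu, as.numeric(mf$beta), tolerance = 1e-5)
  expect_equal(fit$tau2, mf$tau2, tolerance = 1e-4)
  expect_equal(fit$q_t, mf$QE, tolerance = 1e-8)
})

test_that("rema object methods report the fit coherently", {
  set.seed(17)
  fit <- rema(rnorm(20, 0.5, 0.4), runif(20, 0.05, 0.2))
  expect_s3_class(fit, "rema")
  expect_named(coef(fit), c("mu", "tau2"))
  ci <- confint(fit)
  expect_lt(ci[1], fit$mu); expect_gt(ci[2], fit$mu)
  expect_equal(fit$df, fit$k - 1L)
  expect_output(print(fit), "pooled ln FR")
  expect_output(print(summary(fit)), "tau\\^2")
  fd <- funnel_data(fit)
  expect_equal(nrow(fd), fit$k)
  expect_equal(fd$se, sqrt(fit$vi))
})

test_that("95% CI for mu covers the truth at the nominal rate", {
  set.seed(18)
  true_mu <- 0.5; tau2 <- 0.1
  cover <- replicate(300, {
    k <- 25
    vi <- runif(k, 0.02, 0.2)
    yi <- rnorm(k, true_mu, sqrt(vi + tau2))
    fit <- rema(yi, vi)
    fit$ci_low <= true_mu && true_mu <= fit$ci_high
  })
  expect_gt(mean(cover), 0.90)
  expect_lt(mean(cover), 0.99)
})

test_that("subgroup weighted means implement inverse-variance weighting", {
  eff <- data.frame(ln_fr = c(log(2), log(4)), fr_var = c(0.1, 0.2),
                    grp = c("a", "a"))
  s <- subgroup_weighted_means(eff, "grp")
  w <- 1 / c(0.1, 0.2)
  expect_equal(s$ln_fr_w, sum(w * c(log(2), log(4))) / sum(w))
  expect_equal(s$ln_fr_w, 0.9242, tolerance = 1e-4)
  expect_equal(s$fr_w, exp(s$ln_fr_w))
  expect_equal(s$se_w, 1 / sqrt(sum(w)))
  expect_equal(s$ci_high - s$ln_fr_w, qnorm(0.975) * s$se_w)
  # equal weights reduce to the arithmetic mean (oracle: direct averaging)
  set.seed(19)
  eff2 <- data.frame(ln_fr = rnorm(12), fr_var = rep(0.2, 12),
                     grp = rep(c("x", "y"), 6))
  s2 <- subgroup_weighted_means(eff2, "grp")
  for (l in c("x", "y"))
    expect_equal(s2$ln_fr_w[s2$level == l],
                 mean(eff2$ln_fr[eff2$grp == l]))
  # single-record level: own value, CI from its own variance
  eff3 <- data.frame(ln_fr = 0.4, fr_var = 0.09, grp = "solo")
  s3 <- subgroup_weighted_means(eff3, "grp")
  expect_equal(s3$ln_fr_w, 0.4)
  expect_equal(s3$se_w, 0.3)
  # records with a missing level are excluded and counted
  eff4 <- rbind(eff2, data.frame(ln_fr = 0, fr_var = 0.1, grp = NA))
  s4 <- subgroup_weighted_means(eff4, "grp")
  expect_equal(attr(s4, "n_excluded"), 1L)
})

test_that("subgroup comparison uses CI exclusion rules", {
  s <- data.frame(variable = "v", level = c("a", "b", "c"),
                  ln_fr_w = c(0.5, 0.2, 0.65),
                  ci_low = c(0.2, -0.1, 0.4), ci_high = c(0.8, 0.5, 0.9),
                  differs_from_no_effect = c(TRUE, FALSE, TRUE))
  cmp <- compare_subgroups(s)
  expect_equal(cmp$vs_no_effect$differs, c(TRUE, FALSE, TRUE))
  pw <- cmp$pairwise
  # a [0.2,0.8] vs b [-0.1,0.5]: overlap -> no difference
  expect_false(pw$differ[pw$level_a == "a" & pw$level_b == "b"])
  # disjoint CIs differ
  s2 <- data.frame(variable = "v", level = c("lo", "hi"),
                   ln_fr_w = c(0.2, 0.65),
                   ci_low = c(0.1, 0.4), ci_high = c(0.3, 0.9),
                   differs_from_no_effect = TRUE)
  expect_true(compare_subgroups(s2)$pairwise$differ)
})

test_that("random-effects subgroup weighting is available as an option", {
  set.seed(20)
  eff <- data.frame(ln_fr = rnorm(30, 0.5, 0.5),
                    fr_var = runif(30, 0.02, 0.2),
                    grp = rep(c("a", "b"), 15))
  s_fe <- subgroup_weighted_means(eff, "grp", weights = "fixed")
  s_re <- subgroup_weighted_means(eff, "grp", weights = "random")
  expect_false(isTRUE(all.equal(s_fe$ln_fr_w, s_re$ln_fr_w)))
  expect_true(all(s_re$se_w >= s_fe$se_w))  # tau2 widens the weights
})
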