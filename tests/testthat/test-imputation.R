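# Missing-data cascade: sd recovery, the 1.5x rule, correlation-gated
# linear imputation, and predictive mean matching.

test_that("sd recovery follows the sd > se > cv precedence", {
  rec <- make_trials(1)
  rec$yield_t_sd <- NA; rec$yield_t_se <- 100
  expect_equal(recover_sd(rec, "treatment"), 100 * sqrt(3))  # se * sqrt(n), n = 3
  rec$n_t <- 4L
  expect_equal(recover_sd(rec, "treatment"), 200)            # 100 * sqrt(4)
  rec2 <- make_trials(1)
  rec2$yield_c_sd <- NA; rec2$yield_c_cv <- 10; rec2$yield_c_mean <- 2000
  expect_equal(recover_sd(rec2, "control"), 200)        # cv * mean / 100
  rec3 <- make_trials(1)
  rec3$yield_t_sd <- 150; rec3$yield_t_se <- 999
  expect_equal(recover_sd(rec3, "treatment"), 150)      # measured wins
  rec4 <- make_trials(1)
  rec4$yield_t_sd <- NA; rec4$yield_t_se <- -5
  expect_error(recover_sd(rec4, "treatment"), "negative")
})

test_that("missing sds get 1.5x the pooled mean of reported sds", {
  db <- make_trials(3)
  db$yield_t_sd <- c(100, NA, NA)
  db$yield_c_sd <- c(200, NA, NA)
  db$yield_t_se <- NA; db$yield_t_cv <- NA
  db$yield_c_se <- NA; db$yield_c_cv <- NA
  out <- impute_missing_sd(db)
  expect_equal(out$yield_t_sd[2], 1.5 * mean(c(100, 200)))  # 225
  expect_equal(out$yield_c_sd[3], 225)
  expect_equal(out$sd_imputed_flag, c(FALSE, TRUE, TRUE))
  # single reported sd of 80 -> all gaps get 120
  db2 <- db; db2$yield_t_sd <- c(80, NA, NA); db2$yield_c_sd <- NA
  out2 <- impute_missing_sd(db2)
  expect_equal(out2$yield_c_sd, rep(120, 3))
  # nothing missing -> unchanged
  db3 <- make_trials(2)
  expect_equal(impute_missing_sd(db3)$yield_t_sd, db3$yield_t_sd)
  # no sds anywhere -> hard error
  db4 <- db; db4$yield_t_sd <- NA; db4$yield_c_sd <- NA
  expect_error(impute_missing_sd(db4), "no reported")
})

test_that("pairwise correlations use pairwise-complete cases", {
  set.seed(5)
  db <- data.frame(a = rnorm(50))
  db$b <- 2 * db$a                         # exact line
  db$c <- rnorm(50)
  db$a[1:5] <- NA; db$c[6:8] <- NA
  r <- pairwise_correlations(db, c("a", "b", "c"))
  expect_equal(diag(r), c(a = 1, b = 1, c = 1))
  expect_equal(r["a", "b"], 1)
  expect_equal(r, t(r))
  # independent pair at large n stays near zero
  set.seed(6)
  big <- data.frame(x = rnorm(10000), y = rnorm(10000))
  expect_lt(abs(pairwise_correlations(big, c("x", "y"))["x", "y"]), 0.05)
  # too few complete pairs -> missing entry
  db$d <- c(1, 2, rep(NA, 48))
  r2 <- pairwise_correlations(db, c("a", "d"))
  expect_true(is.na(r2["a", "d"]))
})

test_that("the linear plan gates at r > 0.8, drops the gappier variable,
          and is greedy by |r|", {
  set.seed(7)
  n <- 60
  x <- rnorm(n)
  db <- data.frame(u = x + rnorm(n, 0, 0.2),    # r(u,v) ~ 0.97
                   v = x + rnorm(n, 0, 0.2),
                   w = x + rnorm(n, 0, 0.55),   # r(w, .) ~ 0.85: eligible
                   z = rnorm(n))                # uncorrelated
  db$v[1:10] <- NA                              # v has more gaps than u
  vars <- c("u", "v", "w", "z")
  corr <- pairwise_correlations(db, vars)
  miss <- vapply(db[vars], function(c) sum(is.na(c)), integer(1))
  expect_gt(corr["u", "v"], 0.8)
  expect_gt(corr["u", "w"], 0.8)
  plan <- plan_linear_imputation(corr, miss, db)
  # greedy: only the top pair enters; each variable in at most one pair
  expect_equal(nrow(plan$pairs), 1)
  expect_equal(plan$pairs$kept_var, "u")
  expect_equal(plan$pairs$dropped_var, "v")
  # sub-threshold pairs are excluded
  expect_false("z" %in% c(plan$pairs$kept_var, plan$pairs$dropped_var))
  # tie in missing counts drops the later variable in the ordering
  miss2 <- miss; miss2[] <- 0L
  plan2 <- plan_linear_imputation(corr, miss2, db)
  expect_equal(plan2$pairs$dropped_var[1], "v")
})

test_that("applying the plan fills kept-variable gaps from the partner
          and leaves double gaps for PMM", {
  db <- data.frame(u = c(NA, NA, 1, 2, 3, 4), v = c(10, NA, 1, 2, 3, 4))
  plan <- structure(list(
    pairs = data.frame(kept_var = "u", dropped_var = "v",
                       slope = 2, intercept = 1, r = 0.95),
    dropped_vars = "v", threshold_r = 0.8, use_abs_r = FALSE),
    class = "imputation_plan")
  out <- apply_linear_imputation(db, plan)
  expect_equal(out$u[1], 21)           # 2 * 10 + 1
  expect_true(is.na(out$u[2]))         # both missing: left for PMM
  expect_equal(out$u[3:6], db$u[3:6])  # observed untouched
  expect_equal(out$u_imputed, c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))
})

test_that("PMM imputes from the observed support, deterministically", {
  set.seed(8)
  n <- 120
  db <- data.frame(x = rnorm(n), y = rnorm(n))
  db$z <- 0.8 * db$x + rnorm(n, 0, 0.5)
  miss <- sample(n, 25)
  z_full <- db$z
  db$z[miss] <- NA
  cfg <- pmm_config(c("x", "y", "z"), seed = 42)
  out <- pmm_impute(db, cfg)
  expect_false(anyNA(out$z))
  expect_true(all(out$z[miss] %in% z_full[-miss]))  # donors are observed values
  expect_true(all(out$z_imputed[miss]))
  # support preserved
  expect_gte(min(out$z), min(db$z, na.rm = TRUE))
  expect_lte(max(out$z), max(db$z, na.rm = TRUE))
  # determinism under a fixed seed
  expect_identical(pmm_impute(db, cfg), out)
  # no missing values -> identity
  full <- data.frame(x = rnorm(10), y = rnorm(10))
  expect_equal(pmm_impute(full, pmm_config(c("x", "y")))[c("x", "y")], full)
  # fewer observed values than k -> error
  tiny <- data.frame(x = c(1, 2, 3, NA, NA), y = 1:5)
  expect_error(pmm_impute(tiny, pmm_config(c("x", "y"), k = 5)), "fewer than")
})

test_that("PMM recovers the mean of MCAR-deleted values on Gaussian data", {
  set.seed(9)
  n <- 500
  db <- data.frame(a = rnorm(n, 10, 2))
  db$b <- 0.7 * db$a + rnorm(n, 0, 1)
  db$c <- -0.5 * db$a + rnorm(n, 0, 1)
  miss <- sample(n, round(0.18 * n))
  removed <- db$b[miss]
  db$b[miss] <- NA
  out <- pmm_impute(db, pmm_config(c("a", "b", "c"), seed = 7))
  expect_lt(abs(mean(out$b[miss]) - mean(removed)), 0.15 * sd(db$b, na.rm = TRUE))
})

test_that("post-imputation marginals match pre-deletion marginals under MCAR", {
  set.seed(10)
  n <- 400
  db <- data.frame(a = rnorm(n))
  db$b <- 0.8 * db$a + rnorm(n, 0, 0.6)
  full_b <- db$b
  db$b[sample(n, 80)] <- NA
  out <- pmm_impute(db, pmm_config(c("a", "b"), seed = 3))
  ks <- suppressWarnings(stats::ks.test(out$b, full_b)$statistic)
  expect_lt(unname(ks), 0.1)
})

test_that("the full cascade runs in fixed order and is idempotent", {
  set.seed(11)
  g <- generate_trials(synthetic_config(n_studies = 12, seed = 5))
  db <- harmonize(g$db)
  res <- impute_cascade(db, pmm = pmm_config(character(0), seed = 1))
  soil <- setdiff(c("soil_ph", "total_c", "p_olsen", "exch_k", "clay",
                    "sand", "silt"), res$dropped_vars)
  for (v in soil) expect_false(anyNA(res$db[[v]]), label = v)
  expect_false(anyNA(res$db$yield_t_sd))
  expect_false(anyNA(res$db$yield_c_sd))
  # dropped variables are excluded from later analysis and flagged
  expect_true(all(res$dropped_vars %in% names(db)))
  # re-running the cascade on its own output changes nothing
  res2 <- impute_cascade(res$db, pmm = pmm_config(character(0), seed = 1))
  common <- intersect(names(res$db), names(res2$db))
  expect_equal(res2$db[common], res$db[common])
})
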