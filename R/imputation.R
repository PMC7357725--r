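# Missing-data cascade: variance recovery -> 1.5x sd rule ->
# correlation-gated linear imputation -> predictive mean matching.

#' Recover a yield standard deviation from alternative variance statistics
#'
#' Precedence: a reported sd is kept; otherwise sd = se * sqrt(n);
#' otherwise sd = cv * mean / 100; otherwise missing.
#'
#' @param record One-row data frame (or list) in the schema layout.
#' @param arm `"treatment"` or `"control"`.
#' @return sd in kg/ha, or `NA`.
#' @export
recover_sd <- function(record, arm = c("treatment", "control")) {
  arm <- match.arg(arm)
  a <- if (arm == "treatment") "t" else "c"
  g <- function(stub) {
    v <- record[[paste0("yield_", a, "_", stub)]]
    if (is.null(v) || !length(v)) NA_real_ else v
  }
  sd <- g("sd"); se <- g("se"); cv <- g("cv")
  if (!is.na(se) && se < 0) stop("negative standard error")
  if (!is.na(cv) && cv < 0) stop("negative coefficient of variation")
  if (!is.na(sd)) return(sd)
  n <- record[[paste0("n_", a)]]
  if (!is.na(se) && !is.na(n)) return(se * sqrt(n))
  if (!is.na(cv)) return(cv * g("mean") / 100)
  NA_real_
}

.recover_sds <- function(db) {
  for (arm in c("treatment", "control")) {
    col <- if (arm == "treatment") "yield_t_sd" else "yield_c_sd"
    if (is.null(db[[col]])) db[[col]] <- NA_real_
    db[[col]] <- vapply(seq_len(nrow(db)),
                        function(i) recover_sd(db[i, ], arm), numeric(1))
  }
  db
}

#' Impute missing yield standard deviations by the 1.5x-mean rule
#'
#' Records with no recoverable variance statistic receive
#' `multiplier` times the mean of all reported sds, pooled over the
#' treatment and control arms of the whole dataset. Applies
#' [recover_sd()] first so se/cv-derived sds count as reported.
#'
#' @param db Trial table (harmonized).
#' @param multiplier Penalty multiplier on the pooled mean sd (default 1.5).
#' @return The table with both sd columns complete and `sd_imputed_flag`
#'   set on rows where either arm was imputed.
#' @export
impute_missing_sd <- function(db, multiplier = 1.5) {
  db <- .recover_sds(db)
  reported <- c(db$yield_t_sd, db$yield_c_sd)
  reported <- reported[!is.na(reported)]
  miss_t <- is.na(db$yield_t_sd); miss_c <- is.na(db$yield_c_sd)
  prior <- if (!is.null(db$sd_imputed_flag)) db$sd_imputed_flag %in% TRUE
           else rep(FALSE, nrow(db))
  if (!any(miss_t | miss_c)) {
    db$sd_imputed_flag <- prior
    return(db)
  }
  if (!length(reported))
    stop("no reported standard deviations anywhere in the dataset")
  fill <- multiplier * mean(reported)
  db$yield_t_sd[miss_t] <- fill
  db$yield_c_sd[miss_c] <- fill
  db$sd_imputed_flag <- prior | miss_t | miss_c
  db
}

#' Pairwise Pearson correlations on pairwise-complete observations
#'
#' @param db Trial table.
#' @param variables Character vector of numeric column names.
#' @param min_pairs Minimum complete pairs required for an entry
#'   (default 3); entries with fewer are `NA`.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlations <- function(db, variables, min_pairs = 3) {
  x <- as.matrix(db[, variables, drop = FALSE])
  p <- length(variables)
  r <- diag(1, p)
  dimnames(r) <- list(variables, variables)
  for (i in seq_len(p)) for (j in seq_len(p)) {
    if (j <= i) next
    ok <- stats::complete.cases(x[, c(i, j)])
    r[i, j] <- r[j, i] <-
      if (sum(ok) >= min_pairs &&
          stats::sd(x[ok, i]) > 0 && stats::sd(x[ok, j]) > 0)
        stats::cor(x[ok, i], x[ok, j])
      else NA_real_
  }
  r
}

#' Plan correlation-gated linear imputation
#'
#' Pairs of variables correlated above `threshold_r` are selected greedily
#' by descending correlation; in each pair the variable with more missing
#' values is dropped and an OLS line predicting the kept variable from the
#' dropped one (fit on complete pairs) is stored. A variable joins at most
#' one pair. Ties in missing counts are broken by dropping the variable
#' that comes later in `variables`.
#'
#' @param corr Correlation matrix from [pairwise_correlations()].
#' @param missing_counts Named integer vector of missing-value counts.
#' @param db Trial table (used to fit the OLS lines).
#' @param threshold_r Correlation gate (default 0.8). Applied to r itself;
#'   set `use_abs_r = TRUE` to gate on |r|.
#' @param use_abs_r Gate on the absolute correlation instead.
#' @return An object of class `"imputation_plan"`: list with `pairs`
#'   (data frame kept_var, dropped_var, slope, intercept, r) and
#'   `dropped_vars`.
#' @export
plan_linear_imputation <- function(corr, missing_counts, db,
                                   threshold_r = 0.8, use_abs_r = FALSE) {
  vars <- rownames(corr)
  stopifnot(all(vars %in% names(missing_counts)))
  cand <- which(upper.tri(corr), arr.ind = TRUE)
  score <- corr[cand]
  eligible <- !is.na(score) &
    (if (use_abs_r) abs(score) else score) > threshold_r
  cand <- cand[eligible, , drop = FALSE]
  score <- score[eligible]
  ord <- order(abs(score), decreasing = TRUE)
  used <- character(0)
  pairs <- list()
  for (idx in ord) {
    v1 <- vars[cand[idx, 1]]; v2 <- vars[cand[idx, 2]]
    if (v1 %in% used || v2 %in% used) next
    m1 <- missing_counts[[v1]]; m2 <- missing_counts[[v2]]
    if (m1 > m2) { dropped <- v1; kept <- v2 }
    else if (m2 > m1) { dropped <- v2; kept <- v1 }
    else { # tie: drop the later variable in the canonical ordering
      later <- vars[max(match(v1, vars), match(v2, vars))]
      dropped <- later; kept <- setdiff(c(v1, v2), later)
    }
    ok <- stats::complete.cases(db[, c(kept, dropped)])
    fit <- stats::lm(db[ok, kept] ~ db[ok, dropped])
    pairs[[length(pairs) + 1L]] <- data.frame(
      kept_var = kept, dropped_var = dropped,
      slope = unname(stats::coef(fit)[2]),
      intercept = unname(stats::coef(fit)[1]),
      r = score[idx])
    used <- c(used, v1, v2)
  }
  structure(list(
    pairs = if (length(pairs)) do.call(rbind, pairs)
            else data.frame(kept_var = character(), dropped_var = character(),
                            slope = numeric(), intercept = numeric(),
                            r = numeric()),
    dropped_vars = vapply(pairs, function(p) p$dropped_var, character(1)),
    threshold_r = threshold_r, use_abs_r = use_abs_r),
    class = "imputation_plan")
}

#' @export
print.imputation_plan <- function(x, ...) {
  cat("Linear imputation plan (gate r >", x$threshold_r, ")\n")
  if (nrow(x$pairs) == 0) cat("  no eligible pairs\n") else print(x$pairs)
  invisible(x)
}

#' Apply a linear imputation plan
#'
#' Fills gaps in each kept variable from its dropped partner through the
#' stored OLS line where the partner is observed; where both members of a
#' pair are missing the gap is left for predictive mean matching.
#'
#' @param db Trial table.
#' @param plan An [plan_linear_imputation()] result.
#' @return The table with `<kept_var>_imputed` provenance columns added.
#' @export
apply_linear_imputation <- function(db, plan) {
  stopifnot(inherits(plan, "imputation_plan"))
  for (i in seq_len(nrow(plan$pairs))) {
    p <- plan$pairs[i, ]
    fill <- is.na(db[[p$kept_var]]) & !is.na(db[[p$dropped_var]])
    db[[p$kept_var]][fill] <- p$slope * db[[p$dropped_var]][fill] + p$intercept
    flag_col <- paste0(p$kept_var, "_imputed")
    if (is.null(db[[flag_col]])) db[[flag_col]] <- FALSE
    db[[flag_col]] <- db[[flag_col]] | fill
  }
  db
}

#' Configuration for predictive mean matching
#'
#' @param variables Character vector of numeric columns to impute.
#' @param k Donor-pool size (default 5).
#' @param iterations Chained-equations sweeps (default 10).
#' @param seed Integer seed controlling all PMM randomness.
#' @return A list of class `"pmm_config"`.
#' @export
pmm_config <- function(variables, k = 5, iterations = 10, seed = 1) {
  stopifnot(k >= 1, iterations >= 1)
  structure(list(variables = variables, k = as.integer(k),
                 iterations = as.integer(iterations),
                 seed = as.integer(seed)),
            class = "pmm_config")
}

# Bayesian-flavoured PMM step for one target variable: fit OLS of the
# target on the other variables (complete cases), draw a coefficient
# vector from its estimated sampling distribution, and match each missing
# case to one of the k observed cases with nearest perturbed prediction.
.pmm_step <- function(y, X, miss, k) {
  obs <- !miss
  Xd <- cbind(1, X)
  fit <- stats::lm.fit(Xd[obs, , drop = FALSE], y[obs])
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  dfres <- max(1, sum(obs) - sum(!is.na(fit$coefficients)))
  sigma2 <- sum(fit$residuals^2) / dfres
  # draw beta* ~ N(beta_hat, sigma2 * (X'X)^-1); ridge guard for near-singularity
  xtx <- crossprod(Xd[obs, , drop = FALSE])
  V <- tryCatch(sigma2 * solve(xtx),
                error = function(e)
                  sigma2 * solve(xtx + diag(1e-8 * diag(xtx))))
  L <- tryCatch(chol(V), error = function(e) diag(sqrt(pmax(diag(V), 0))))
  beta_star <- beta + drop(t(L) %*% stats::rnorm(length(beta)))
  pred_obs <- drop(Xd[obs, , drop = FALSE] %*% beta)
  pred_mis <- drop(Xd[miss, , drop = FALSE] %*% beta_star)
  y_obs <- y[obs]
  out <- numeric(sum(miss))
  for (m in seq_along(pred_mis)) {
    d <- abs(pred_obs - pred_mis[m])
    donors <- order(d)[seq_len(min(k, length(d)))]
    out[m] <- y_obs[donors[sample.int(length(donors), 1)]]
  }
  out
}

#' Predictive mean matching imputation by chained equations
#'
#' Loops over the configured variables for the configured number of
#' sweeps. Each sweep regresses the target on the other configured
#' variables on complete data, perturbs the coefficients by a draw from
#' their estimated sampling distribution, and fills each missing case with
#' the observed value of a donor drawn uniformly from the `k` cases with
#' nearest predicted mean. Every imputed value is therefore an observed
#' value of the same variable. Deterministic under a fixed seed.
#'
#' @param db Trial table.
#' @param config A [pmm_config()].
#' @return The table with the configured variables complete and
#'   `<var>_imputed` provenance columns set.
#' @export
pmm_impute <- function(db, config) {
  stopifnot(inherits(config, "pmm_config"))
  vars <- config$variables
  for (v in vars) {
    if (!is.numeric(db[[v]])) stop("PMM variable '", v, "' is not numeric")
    if (sum(!is.na(db[[v]])) < config$k)
      stop("PMM variable '", v, "' has fewer than k = ", config$k,
           " observed values")
  }
  miss0 <- lapply(db[vars], is.na)
  if (!any(unlist(miss0))) {
    for (v in vars) {
      flag <- paste0(v, "_imputed")
      if (is.null(db[[flag]])) db[[flag]] <- FALSE
    }
    return(db)
  }
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  work <- db[vars]
  # initialize gaps with random observed draws of the same variable
  for (v in vars) {
    m <- miss0[[v]]
    if (any(m))
      work[[v]][m] <- sample(work[[v]][!m], sum(m), replace = TRUE)
  }
  for (it in seq_len(config$iterations)) {
    for (v in vars) {
      m <- miss0[[v]]
      if (!any(m)) next
      X <- as.matrix(work[setdiff(vars, v)])
      if (ncol(X) == 0) X <- matrix(numeric(0), nrow = nrow(work), ncol = 0)
      work[[v]][m] <- .pmm_step(db[[v]], X, m, config$k)
    }
  }
  for (v in vars) {
    db[[v]] <- work[[v]]
    flag <- paste0(v, "_imputed")
    if (is.null(db[[flag]])) db[[flag]] <- FALSE
    db[[flag]] <- db[[flag]] | miss0[[v]]
  }
  db
}

#' Run the full missing-data cascade
#'
#' Fixed order: sd recovery, the 1.5x pooled-mean sd rule, the
#' correlation-gated linear plan and its application, then predictive mean
#' matching on whatever soil gaps remain. Re-running the cascade on its
#' own output is a no-op.
#'
#' @param db Harmonized trial table.
#' @param soil_vars Numeric columns entering the correlation gate and PMM.
#' @param threshold_r Correlation gate (default 0.8).
#' @param use_abs_r Gate on |r| instead of r.
#' @param sd_multiplier Multiplier for the sd rule (default 1.5).
#' @param pmm A [pmm_config()]; its `variables` field is replaced by the
#'   still-incomplete soil variables.
#' @return List with `db` (completed table), `plan`, and `dropped_vars`
#'   (variables excluded from downstream analysis).
#' @export
impute_cascade <- function(db,
                           soil_vars = c("soil_ph", "total_c", "total_n",
                                         "p_olsen", "exch_k", "exch_ca",
                                         "exch_mg", "clay", "sand", "silt"),
                           threshold_r = 0.8, use_abs_r = FALSE,
                           sd_multiplier = 1.5,
                           pmm = pmm_config(character(0))) {
  soil_vars <- intersect(soil_vars, names(db))
  db <- impute_missing_sd(db, multiplier = sd_multiplier)
  corr <- pairwise_correlations(db, soil_vars)
  miss <- vapply(db[soil_vars], function(v) sum(is.na(v)), integer(1))
  plan <- plan_linear_imputation(corr, miss, db, threshold_r = threshold_r,
                                 use_abs_r = use_abs_r)
  db <- apply_linear_imputation(db, plan)
  keep <- setdiff(soil_vars, plan$dropped_vars)
  todo <- keep[vapply(db[keep], function(v) any(is.na(v)), logical(1))]
  if (length(todo)) {
    pmm$variables <- todo
    db <- pmm_impute(db, pmm)
  }
  list(db = db, plan = plan, dropped_vars = plan$dropped_vars)
}
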