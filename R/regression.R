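# Standardized general linear models for ln FR and N-AE, PLS-based
# variable importance, and the FR-vs-control-yield power law.

#' Default log-transform recipe for the GLM predictors
#'
#' Predictors that are right-skewed get a natural-log transform: total C,
#' P-Olsen, N rate, exchangeable K, silt, and rainfall. Soil pH and clay
#' stay on their original scale.
#'
#' @return Character vector of column names to log-transform.
#' @export
default_log_recipe <- function() {
  c("total_c", "p_olsen", "n_rate", "exch_k", "silt", "rainfall")
}

#' Log-transform skewed predictors
#'
#' Applies a natural-log transform to the recipe columns, renaming them
#' with a `log_` prefix. Non-positive values under the log are rejected
#' by default.
#'
#' @param table Data frame of predictors.
#' @param recipe Columns to transform (default [default_log_recipe()],
#'   intersected with the table's columns).
#' @param on_nonpositive `"error"` (default) or `"na"`.
#' @return The transformed table.
#' @export
transform_predictors <- function(table, recipe = default_log_recipe(),
                                 on_nonpositive = c("error", "na")) {
  on_nonpositive <- match.arg(on_nonpositive)
  for (col in intersect(recipe, names(table))) {
    v <- table[[col]]
    bad <- !is.na(v) & v <= 0
    if (any(bad)) {
      if (on_nonpositive == "error")
        stop("non-positive value(s) in '", col, "' under log transform")
      v[bad] <- NA
    }
    table[[col]] <- NULL
    table[[paste0("log_", col)]] <- log(v)
  }
  table
}

#' Scale columns to unit standard deviation
#'
#' Divides each column by its sample standard deviation (no centering),
#' so every predictor has equal representation in the regression. The
#' scale factors are recorded for back-transformation.
#'
#' @param table Data frame of numeric columns, each with sd > 0.
#' @return The scaled table, with attribute `"scales"` (named vector of
#'   the divisors).
#' @export
standardize <- function(table) {
  scales <- vapply(table, function(v) stats::sd(v, na.rm = TRUE), numeric(1))
  if (any(is.na(scales) | scales == 0))
    stop("constant column(s): ",
         paste(names(table)[is.na(scales) | scales == 0], collapse = ", "))
  out <- as.data.frame(mapply(function(v, s) v / s, table, scales,
                              SIMPLIFY = FALSE))
  attr(out, "scales") <- scales
  out
}

#' Ordinary least-squares GLM of an effect-size response on standardized
#' predictors
#'
#' Fits `y ~ X` with an intercept by OLS and reports the per-coefficient
#' table (estimate, standard error, t-based p), R-squared and adjusted
#' R-squared. When the response is N-AE the N application rate must not
#' be among the predictors (the rate enters the response's denominator);
#' this is enforced.
#'
#' @param y Response vector (ln FR or N-AE).
#' @param X Data frame of standardized predictors.
#' @param response `"ln_fr"` or `"n_ae"` (governs the N-rate exclusion).
#' @return Object of class `"fr_glm"`: list with `coefficients` (data
#'   frame), `r2`, `adjusted_r2`, `n`, `response`, and the underlying
#'   `lm` fit.
#' @export
fit_glm <- function(y, X, response = c("ln_fr", "n_ae")) {
  response <- match.arg(response)
  if (response == "n_ae" && any(grepl("n_rate", names(X))))
    stop("the N application rate must not predict N-AE")
  ok <- !is.na(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (length(y) <= ncol(X) + 1)
    stop("need n > number of predictors + 1")
  dat <- cbind(data.frame(.y = y), X)
  fit <- stats::lm(.y ~ ., data = dat)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient design")
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  names(co) <- c("estimate", "std_error", "t_value", "p_value")
  co <- cbind(predictor = rownames(co), co)
  rownames(co) <- NULL
  co$signif_code <- cut(co$p_value, c(0, 0.001, 0.01, 0.05, 0.1, 1),
                        labels = c("***", "**", "*", ".", ""),
                        include.lowest = TRUE)
  structure(list(coefficients = co, r2 = sm$r.squared,
                 adjusted_r2 = sm$adj.r.squared, n = length(y),
                 response = response, lm = fit),
            class = "fr_glm")
}

#' @export
print.fr_glm <- function(x, digits = 4, ...) {
  cat("GLM for", x$response, " (n =", x$n, ")\n")
  print(x$coefficients, digits = digits)
  cat(sprintf("R2 = %.*f, adjusted R2 = %.*f\n",
              digits, x$r2, digits, x$adjusted_r2))
  invisible(x)
}

# NIPALS PLS1 on centered data. Returns weights (p x a), x-scores
# (n x a), and per-component explained y-variance SS_a.
.pls_nipals <- function(X, y, ncomp) {
  X <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  y <- y - mean(y)
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); TT <- matrix(0, n, ncomp)
  ss <- numeric(ncomp)
  Xa <- X; ya <- y
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { ncomp <- a - 1L; break }
    w <- w / nw
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- drop(crossprod(Xa, t_a)) / tt
    q_a <- sum(ya * t_a) / tt
    ss[a] <- q_a^2 * tt           # y-variance captured by component a
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - q_a * t_a
    W[, a] <- w; TT[, a] <- t_a
  }
  list(weights = W[, seq_len(ncomp), drop = FALSE],
       scores = TT[, seq_len(ncomp), drop = FALSE],
       ss = ss[seq_len(ncomp)], ncomp = ncomp)
}

# Leave-one-out PRESS for a PLS1 fit with `a` components.
.pls_loo_press <- function(X, y, a) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    fit <- .pls_nipals(Xi, yi, a)
    if (fit$ncomp < 1) return(Inf)
    # regression prediction for the held-out row
    b <- .pls_coefficients(fit, Xi, yi)
    xh <- as.numeric(X[i, ]) - colMeans(Xi)
    press <- press + (y[i] - (mean(yi) + sum(xh * b)))^2
  }
  press
}

# Regression coefficients of a fitted PLS1 (on centered scale).
.pls_coefficients <- function(fit, X, y) {
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  W <- fit$weights
  TT <- fit$scores
  P <- crossprod(Xc, TT) %*% diag(1 / colSums(TT^2), fit$ncomp)
  q <- drop(crossprod(TT, yc)) / colSums(TT^2)
  R <- W %*% solve(crossprod(P, W))
  drop(R %*% q)
}

#' Variable importance in projection (VIP) scores
#'
#' Decomposes (X, y) by partial least squares (NIPALS) and scores each
#' predictor j as
#' VIP_j = sqrt(p * sum_a SS_a (w_aj / ||w_a||)^2 / sum_a SS_a),
#' where SS_a is the y-variance explained by component a and w_a its
#' weight vector. Predictors with VIP > 1 are conventionally deemed
#' important. sum_j VIP_j^2 = p by construction.
#'
#' @param y Response vector.
#' @param X Data frame or matrix of standardized predictors.
#' @param n_components Number of PLS components; `NULL` (default) selects
#'   by leave-one-out cross-validated prediction error, capped at
#'   min(p, 10).
#' @param threshold Importance cutoff (default 1).
#' @return Object of class `"vip_result"`: list with `scores` (named
#'   vector), `important` (names with score > threshold),
#'   `n_components`.
#' @export
vip_scores <- function(y, X, n_components = NULL, threshold = 1) {
  X <- as.data.frame(X)
  ok <- !is.na(y) & stats::complete.cases(X)
  y <- y[ok]; X <- X[ok, , drop = FALSE]
  if (stats::sd(y) == 0) stop("zero-variance response")
  p <- ncol(X)
  cap <- min(p, 10, length(y) - 2)
  if (is.null(n_components)) {
    press <- vapply(seq_len(cap), function(a)
      .pls_loo_press(as.matrix(X), y, a), numeric(1))
    n_components <- which.min(press)
  }
  stopifnot(n_components >= 1, n_components <= cap)
  fit <- .pls_nipals(X, y, n_components)
  W <- fit$weights; ss <- fit$ss
  wn2 <- sweep(W^2, 2, colSums(W^2), "/")   # (w_aj/||w_a||)^2
  vip <- sqrt(p * drop(wn2 %*% ss) / sum(ss))
  names(vip) <- colnames(X)
  structure(list(scores = vip,
                 important = names(vip)[vip > threshold],
                 n_components = fit$ncomp, threshold = threshold),
            class = "vip_result")
}

#' @export
print.vip_result <- function(x, digits = 3, ...) {
  cat("VIP scores (", x$n_components, "PLS component(s) )\n")
  print(round(sort(x$scores, decreasing = TRUE), digits))
  cat("important (>", x$threshold, "):",
      paste(x$important, collapse = ", "), "\n")
  invisible(x)
}

#' Fit the FR-vs-control-yield power law
#'
#' Fits FR = a * (control yield)^b by OLS on the log-log scale
#' (ln FR = ln a + b ln yield), a multiplicative-error model consistent
#' with the log-scale analysis. Reports a = exp(intercept), the exponent
#' b, R-squared, and the slope p-value.
#'
#' @param fr Back-transformed fertilizer responses (> 0).
#' @param control_yield Control mean yields, kg/ha (> 0).
#' @return Object of class `"power_law_fit"`: list with `a`, `b`, `r2`,
#'   `p`, `n`, and the underlying `lm`.
#' @export
fit_power_law <- function(fr, control_yield) {
  ok <- !is.na(fr) & !is.na(control_yield)
  fr <- fr[ok]; control_yield <- control_yield[ok]
  if (any(fr <= 0) || any(control_yield <= 0))
    stop("fr and control_yield must be > 0")
  if (length(fr) < 3) stop("need at least 3 points")
  if (stats::sd(control_yield) == 0)
    stop("degenerate: all control yields equal")
  fit <- stats::lm(log(fr) ~ log(control_yield))
  sm <- summary(fit)
  structure(list(a = exp(unname(stats::coef(fit)[1])),
                 b = unname(stats::coef(fit)[2]),
                 r2 = sm$r.squared,
                 p = sm$coefficients[2, 4],
                 n = length(fr), lm = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, digits = 3, ...) {
  cat(sprintf("FR = %.*g * (control yield)^%.*f   (R2 = %.*f, p = %.3g, n = %d)\n",
              digits + 2, x$a, digits, x$b, digits, x$r2, x$p, x$n))
  invisible(x)
}
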