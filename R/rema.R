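# Random-effects meta-analysis of log response ratios.
#
# Model: y_i ~ Normal(mu, v_i + tau2), with known sampling variances v_i
# and between-observation variance tau2 estimated by restricted maximum
# likelihood. Intercept-only (no moderators); each observation is treated
# as an independent record.

#' Cochran heterogeneity statistic
#'
#' Q_T = sum w_i (y_i - ybar_w)^2 with fixed-effect weights w_i = 1/v_i
#' and ybar_w the weighted mean. Under homogeneity Q_T follows a
#' chi-square distribution with k - 1 degrees of freedom.
#'
#' @param yi Effect sizes (ln FR).
#' @param vi Sampling variances (> 0).
#' @return List with `q_t`, `df`, `p`.
#' @export
q_statistic <- function(yi, vi) {
  stopifnot(length(yi) == length(vi), length(yi) >= 1)
  if (any(vi <= 0)) stop("all sampling variances must be > 0")
  k <- length(yi)
  if (k == 1) return(list(q_t = 0, df = 0L, p = NA_real_))
  w <- 1 / vi
  ybar <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - ybar)^2)
  list(q_t = q, df = k - 1L, p = stats::pchisq(q, k - 1, lower.tail = FALSE))
}

# Restricted log-likelihood of the intercept-only RE model at tau2.
.reml_ll <- function(tau2, yi, vi) {
  wi <- 1 / (vi + tau2)
  mu <- sum(wi * yi) / sum(wi)
  -0.5 * (sum(log(vi + tau2)) + log(sum(wi)) + sum(wi * (yi - mu)^2))
}

#' Fit a random-effects meta-analysis by REML
#'
#' Estimates the pooled log fertilizer response mu and the
#' between-observation variance tau2 of the model
#' y_i ~ Normal(mu, v_i + tau2). tau2 maximizes the restricted
#' log-likelihood over a bounded one-dimensional search on
#' \[0, 10 * var(y)\] (tolerance 1e-8, with an explicit boundary check at
#' tau2 = 0); mu and its standard error follow from inverse-variance
#' weights 1/(v_i + tau2). The Cochran Q_T test is attached.
#'
#' @param yi Effect sizes (ln FR), length >= 2.
#' @param vi Sampling variances (> 0), same length.
#' @param data Optional data frame from which `yi`/`vi` are taken (as
#'   column names `ln_fr` and `fr_var` when missing).
#' @return An object of class `"rema"`: list with `mu`, `tau2`, `se_mu`,
#'   `ci_low`, `ci_high` (95%, normal), `q_t`, `df`, `p_q`, `k`, `yi`,
#'   `vi`.
#' @seealso [egger_test()], [trim_and_fill()], [funnel_data()]
#' @export
#' @examples
#' fit <- rema(c(0.2, 0.5, 0.8, 0.4), c(0.02, 0.05, 0.03, 0.04))
#' summary(fit)
rema <- function(yi, vi, data = NULL) {
  if (!is.null(data)) {
    if (missing(yi)) yi <- data$ln_fr
    if (missing(vi)) vi <- data$fr_var
  }
  ok <- !is.na(yi) & !is.na(vi)
  yi <- yi[ok]; vi <- vi[ok]
  k <- length(yi)
  if (k < 2) stop("need at least 2 records")
  if (any(vi <= 0)) stop("all sampling variances must be > 0")
  vy <- stats::var(yi)
  upper <- max(10 * vy, 10 * max(vi), 1e-6)
  opt <- stats::optimize(.reml_ll, c(0, upper), yi = yi, vi = vi,
                         maximum = TRUE, tol = 1e-8)
  tau2 <- opt$maximum
  # optimize never returns an exact endpoint; snap to 0 when it wins
  if (.reml_ll(0, yi, vi) >= opt$objective) tau2 <- 0
  wi <- 1 / (vi + tau2)
  mu <- sum(wi * yi) / sum(wi)
  se <- sqrt(1 / sum(wi))
  z <- stats::qnorm(0.975)
  q <- q_statistic(yi, vi)
  structure(list(mu = mu, tau2 = tau2, se_mu = se,
                 ci_low = mu - z * se, ci_high = mu + z * se,
                 z = mu / se, p_mu = 2 * stats::pnorm(-abs(mu / se)),
                 q_t = q$q_t, df = q$df, p_q = q$p,
                 k = k, yi = yi, vi = vi),
            class = "rema")
}

#' @export
print.rema <- function(x, digits = 4, ...) {
  cat("Random-effects meta-analysis (REML), k =", x$k, "records\n")
  cat(sprintf("  pooled ln FR: %.*f (SE %.*f), FR = %.*f\n",
              digits, x$mu, digits, x$se_mu, digits, exp(x$mu)))
  cat(sprintf("  tau^2: %.*f\n", digits, x$tau2))
  cat(sprintf("  Q_T = %.*f, df = %d, p %s\n", digits, x$q_t, x$df,
              format.pval(x$p_q, digits = digits)))
  invisible(x)
}

#' @export
summary.rema <- function(object, ...) {
  out <- data.frame(
    estimate = c(object$mu, exp(object$mu), object$tau2),
    se = c(object$se_mu, NA, NA),
    ci_low = c(object$ci_low, exp(object$ci_low), NA),
    ci_high = c(object$ci_high, exp(object$ci_high), NA),
    row.names = c("ln FR (pooled)", "FR (back-transformed)", "tau^2"))
  structure(list(table = out, q_t = object$q_t, df = object$df,
                 p_q = object$p_q, k = object$k, fit = object),
            class = "summary.rema")
}

#' @export
print.summary.rema <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat("\n")
  print(round(x$table, digits))
  invisible(x)
}

#' @export
coef.rema <- function(object, ...) c(mu = object$mu, tau2 = object$tau2)

#' @export
confint.rema <- function(object, parm = "mu", level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  out <- matrix(c(object$mu - z * object$se_mu,
                  object$mu + z * object$se_mu), 1,
                dimnames = list("mu", c(sprintf("%.1f %%", 100 * (1 - level) / 2),
                                        sprintf("%.1f %%", 100 * (1 + level) / 2))))
  out
}

#' Funnel-plot coordinates
#'
#' Emits the (effect, standard error) pairs of a fit or effect table for
#' funnel plotting; no binning.
#'
#' @param x A `rema` fit, or a data frame with `ln_fr` and `fr_var`.
#' @return Data frame with columns `effect` and `se`.
#' @export
funnel_data <- function(x) {
  if (inherits(x, "rema")) data.frame(effect = x$yi, se = sqrt(x$vi))
  else data.frame(effect = x$ln_fr, se = sqrt(x$fr_var))
}

#' @describeIn rema Funnel plot of the fitted records (base graphics):
#'   effect against standard error, inverted se axis, pseudo-confidence
#'   funnel around the pooled estimate.
#' @param x,y,... Plot method arguments (`y` ignored).
#' @export
plot.rema <- function(x, y, ...) {
  fd <- funnel_data(x)
  ylim <- rev(range(c(0, fd$se)))
  plot(fd$effect, fd$se, ylim = ylim, xlab = "ln FR",
       ylab = "Standard error", pch = 19, cex = 0.6, ...)
  se_grid <- seq(0, max(fd$se), length.out = 50)
  z <- stats::qnorm(0.975)
  graphics::lines(x$mu - z * se_grid, se_grid, lty = 2)
  graphics::lines(x$mu + z * se_grid, se_grid, lty = 2)
  graphics::abline(v = x$mu, lty = 3)
  invisible(x)
}
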