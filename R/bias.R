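# Publication-bias diagnostics: Egger-type weighted regression test and
# the Duval-Tweedie trim-and-fill procedure (L0 estimator).

#' Egger-type regression test for funnel asymmetry
#'
#' Weighted least-squares regression of the effect y_i on its standard
#' error sqrt(v_i) with inverse-variance weights 1/v_i; the test statistic
#' is z = slope / se(slope) with a two-sided normal p-value. A nonzero
#' slope indicates that small (high-se) studies report systematically
#' different effects, the funnel-plot signature of publication bias.
#'
#' @param x A [rema()] fit, or effect sizes `yi` with variances `vi`.
#' @param yi,vi Used when `x` is missing.
#' @return List with `z`, `p`, `slope`, `slope_se`, `intercept`, `k`.
#' @export
egger_test <- function(x, yi, vi) {
  if (!missing(x) && inherits(x, "rema")) { yi <- x$yi; vi <- x$vi }
  else if (!missing(x) && is.data.frame(x)) { yi <- x$ln_fr; vi <- x$fr_var }
  stopifnot(length(yi) == length(vi))
  if (length(yi) < 3) stop("need at least 3 records")
  if (any(vi <= 0)) stop("all sampling variances must be > 0")
  se <- sqrt(vi)
  if (stats::sd(se) == 0) stop("degenerate design: all standard errors equal")
  fit <- stats::lm(yi ~ se, weights = 1 / vi)
  sm <- summary(fit)$coefficients
  z <- sm["se", "Estimate"] / sm["se", "Std. Error"]
  list(z = unname(z), p = 2 * stats::pnorm(-abs(z)),
       slope = unname(sm["se", "Estimate"]),
       slope_se = unname(sm["se", "Std. Error"]),
       intercept = unname(sm["(Intercept)", "Estimate"]),
       k = length(yi))
}

# Fixed-effect pooled mean.
.fe_mean <- function(yi, vi) sum(yi / vi) / sum(1 / vi)

# One L0 evaluation: number of suppressed studies implied by the rank sum
# of the positive deviations from `center`. `n` is the current
# (untrimmed) study count.
.l0_estimate <- function(yi, center, n) {
  d <- yi - center
  r <- rank(abs(d), ties.method = "first")
  t_n <- sum(r[d > 0])
  l0 <- (4 * t_n - n * (n + 1)) / (2 * n - 1)
  max(0L, as.integer(round(l0)))
}

#' Trim-and-fill estimate of suppressed studies
#'
#' Iterative Duval-Tweedie procedure with the L0 estimator. Effects are
#' (if needed) reflected so the asymmetry sits on the right; the rank-based
#' L0 count of suppressed studies is computed about the fixed-effect
#' center, the k0 most extreme right-side effects are trimmed, the center
#' re-estimated, and the loop repeated until k0 stabilizes. The filled
#' records are mirror images of the k0 most extreme effects about the
#' final center, and the adjusted estimate is the fixed-effect pooled
#' mean over observed plus filled records.
#'
#' @param x A [rema()] fit, or effect sizes `yi` with variances `vi`.
#' @param yi,vi Used when `x` is missing.
#' @param side Side on which missing studies are imputed: `"left"`,
#'   `"right"`, or `"auto"` (default; chosen opposite to the skew of the
#'   effects about the fixed-effect center).
#' @param max_iter Iteration cap (default 50).
#' @return List with `k0` (estimated number of suppressed studies),
#'   `side`, `adjusted_mu` (fixed-effect mean over observed + filled),
#'   `filled` (data frame of imputed effect/variance pairs), and
#'   `mu_observed`.
#' @export
trim_and_fill <- function(x, yi, vi, side = c("auto", "left", "right"),
                          max_iter = 50) {
  side <- match.arg(side)
  if (!missing(x) && inherits(x, "rema")) { yi <- x$yi; vi <- x$vi }
  else if (!missing(x) && is.data.frame(x)) { yi <- x$ln_fr; vi <- x$fr_var }
  stopifnot(length(yi) == length(vi))
  if (length(yi) < 3) stop("need at least 3 records")
  n <- length(yi)
  mu_obs <- .fe_mean(yi, vi)
  if (side == "auto") {
    d <- yi - mu_obs
    sk <- mean(d^3) / (mean(d^2)^1.5 + .Machine$double.eps)
    # right skew (extra large effects) implies suppression of small ones
    side <- if (sk >= 0) "left" else "right"
  }
  # work on the scale where suppression is on the LEFT, i.e. observed
  # extremes on the right get trimmed
  flip <- if (side == "right") -1 else 1
  y <- flip * yi
  ord <- order(y)
  y <- y[ord]; v <- vi[ord]
  k0 <- 0L
  center <- .fe_mean(y, v)
  for (it in seq_len(max_iter)) {
    keep <- if (k0 > 0) seq_len(n - k0) else seq_len(n)
    center <- .fe_mean(y[keep], v[keep])
    k0_new <- .l0_estimate(y, center, n)
    k0_new <- min(k0_new, n - 1L)
    if (k0_new == k0) break
    k0 <- k0_new
  }
  filled <- if (k0 > 0) {
    idx <- seq.int(n - k0 + 1L, n)  # the k0 most extreme effects
    data.frame(effect = flip * (2 * center - y[idx]), var = v[idx])
  } else data.frame(effect = numeric(), var = numeric())
  all_y <- c(yi, filled$effect)
  all_v <- c(vi, filled$var)
  list(k0 = k0, side = side,
       adjusted_mu = .fe_mean(all_y, all_v),
       mu_observed = mu_obs, filled = filled, iterations = it)
}
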