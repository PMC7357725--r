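# Weighted subgroup means of ln FR across levels of a categorical
# moderator, with fixed-effect (1/v) weights and normal 95% CIs.

#' Weighted mean fertilizer response per subgroup
#'
#' For each level of a categorical moderator, computes the weighted mean
#' log response ratio ln FR_w = sum(w_i y_i) / sum(w_i) with w_i = 1/v_i
#' (inverse sampling-variance weights), its standard error
#' (sum w_i)^(-1/2), and a 95% normal CI, back-transforming to the FR
#' scale alongside. Records with a missing level are excluded and
#' counted. Random-effects weights 1/(v_i + tau2) are available as an
#' option.
#'
#' @param effects Effect table from [compute_effects()] (needs `ln_fr`,
#'   `fr_var`, and the moderator column).
#' @param variable Name of the categorical moderator.
#' @param weights `"fixed"` (1/v, default) or `"random"`
#'   (1/(v + tau2) with tau2 from a pooled REML fit).
#' @param conf_level Confidence level (default 0.95).
#' @return Data frame of class `"subgroup_summary"`: one row per level
#'   with `variable`, `level`, `k`, `ln_fr_w`, `se_w`, `ci_low`,
#'   `ci_high` (ln scale), `fr_w`, `fr_ci_low`, `fr_ci_high`, and
#'   `differs_from_no_effect`. Attribute `"n_excluded"` counts records
#'   with a missing level.
#' @export
subgroup_weighted_means <- function(effects, variable,
                                    weights = c("fixed", "random"),
                                    conf_level = 0.95) {
  weights <- match.arg(weights)
  lev <- effects[[variable]]
  if (is.null(lev)) stop("no column '", variable, "' in effects")
  ok <- !is.na(lev) & !is.na(effects$ln_fr) & !is.na(effects$fr_var)
  n_excluded <- sum(!ok)
  eff <- effects[ok, ]
  lev <- as.character(lev[ok])
  tau2 <- if (weights == "random") rema(eff$ln_fr, eff$fr_var)$tau2 else 0
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(sort(unique(lev)), function(l) {
    sub <- eff[lev == l, ]
    if (nrow(sub) == 0) stop("level with 0 records: ", l)
    w <- 1 / (sub$fr_var + tau2)
    m <- sum(w * sub$ln_fr) / sum(w)
    se <- sqrt(1 / sum(w))
    data.frame(variable = variable, level = l, k = nrow(sub),
               ln_fr_w = m, se_w = se,
               ci_low = m - z * se, ci_high = m + z * se,
               fr_w = exp(m), fr_ci_low = exp(m - z * se),
               fr_ci_high = exp(m + z * se),
               differs_from_no_effect = (m - z * se) > 0 | (m + z * se) < 0)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_excluded") <- n_excluded
  class(out) <- c("subgroup_summary", "data.frame")
  out
}

#' Compare subgroup summaries
#'
#' A level differs from no effect iff its CI excludes ln FR = 0; two
#' levels differ iff their CIs are disjoint.
#'
#' @param summaries A [subgroup_weighted_means()] result (one variable).
#' @return List with `vs_no_effect` (level, differs flag) and `pairwise`
#'   (level_a, level_b, differ flag).
#' @export
compare_subgroups <- function(summaries) {
  stopifnot(length(unique(summaries$variable)) <= 1)
  vs0 <- data.frame(level = summaries$level,
                    differs = summaries$differs_from_no_effect)
  n <- nrow(summaries)
  pw <- if (n >= 2) {
    idx <- utils::combn(n, 2)
    data.frame(
      level_a = summaries$level[idx[1, ]],
      level_b = summaries$level[idx[2, ]],
      differ = summaries$ci_low[idx[1, ]] > summaries$ci_high[idx[2, ]] |
               summaries$ci_low[idx[2, ]] > summaries$ci_high[idx[1, ]])
  } else data.frame(level_a = character(), level_b = character(),
                    differ = logical())
  list(vs_no_effect = vs0, pairwise = pw)
}
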