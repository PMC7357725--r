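# Log response-ratio effect sizes, N use efficiency, and soil
# responsiveness classification.

#' Log fertilizer response
#'
#' The fertilizer response FR is the ratio of fertilized-plot to
#' control-plot mean yield; it is analyzed on the natural-log scale (the
#' log response ratio).
#'
#' @param yield_t_mean,yield_c_mean Treatment and control mean yields,
#'   kg/ha, both positive.
#' @return ln(yield_t_mean / yield_c_mean).
#' @export
ln_fr <- function(yield_t_mean, yield_c_mean) {
  if (any(yield_t_mean <= 0 | yield_c_mean <= 0, na.rm = TRUE))
    stop("yield means must be > 0")
  log(yield_t_mean / yield_c_mean)
}

#' Sampling variance of the log fertilizer response
#'
#' Delta-method variance of the log response ratio:
#' sd_t^2 / (n_t * xbar_t^2) + sd_c^2 / (n_c * xbar_c^2).
#'
#' @param sd_t,sd_c Arm standard deviations (>= 0).
#' @param n_t,n_c Replicate counts (>= 1).
#' @param yield_t_mean,yield_c_mean Arm means (> 0).
#' @return The sampling variance (unitless).
#' @export
fr_variance <- function(sd_t, n_t, yield_t_mean, sd_c, n_c, yield_c_mean) {
  if (any(yield_t_mean <= 0 | yield_c_mean <= 0, na.rm = TRUE))
    stop("yield means must be > 0")
  if (any(c(n_t, n_c) < 1, na.rm = TRUE)) stop("replicate counts must be >= 1")
  if (any(c(sd_t, sd_c) < 0, na.rm = TRUE)) stop("sds must be >= 0")
  sd_t^2 / (n_t * yield_t_mean^2) + sd_c^2 / (n_c * yield_c_mean^2)
}

#' Agronomic nitrogen use efficiency
#'
#' Yield gain over the control per kg of applied fertilizer N, in kg dry
#' weight per kg N. Negative values are legitimate (fertilization can
#' depress yield).
#'
#' @param yield_t_mean,yield_c_mean Arm mean yields, kg/ha.
#' @param n_rate Applied N, kg N/ha; must be positive (unfertilized
#'   controls are not efficiency-scored).
#' @return (yield_t_mean - yield_c_mean) / n_rate.
#' @export
n_ae <- function(yield_t_mean, yield_c_mean, n_rate) {
  if (any(n_rate <= 0, na.rm = TRUE)) stop("n_rate must be > 0")
  (yield_t_mean - yield_c_mean) / n_rate
}

#' Classify soil responsiveness
#'
#' Observations with FR > 1 are responsive. Non-responsive soils
#' (FR <= 1, boundary inclusive) are split by the control-plot yield:
#' above `fertile_threshold` they are fertile non-responsive, otherwise
#' poor non-responsive. The default threshold of 1125 kg/ha is the
#' smallholder-farm benchmark for Sub-Saharan Africa.
#'
#' @param fr Back-transformed fertilizer response (> 0).
#' @param yield_c_mean Control mean yield, kg/ha (> 0).
#' @param fertile_threshold Control-yield benchmark, kg/ha (default 1125).
#' @return Factor with levels `responsive`, `poor_nonresponsive`,
#'   `fertile_nonresponsive`.
#' @export
classify_responsiveness <- function(fr, yield_c_mean,
                                    fertile_threshold = 1125) {
  if (any(fr <= 0, na.rm = TRUE)) stop("fr must be > 0")
  if (any(yield_c_mean <= 0, na.rm = TRUE)) stop("yield_c_mean must be > 0")
  cls <- ifelse(fr > 1, "responsive",
                ifelse(yield_c_mean > fertile_threshold,
                       "fertile_nonresponsive", "poor_nonresponsive"))
  factor(cls, levels = c("responsive", "poor_nonresponsive",
                         "fertile_nonresponsive"))
}

#' Compute per-observation effect sizes and moderators
#'
#' Builds the effect table the meta-analysis consumes: ln FR, its
#' back-transform, its delta-method sampling variance, N-AE (missing where
#' no N was applied), and the responsiveness class, with all moderators
#' carried along.
#'
#' @param db Harmonized, variance-complete trial table.
#' @param fertile_threshold Passed to [classify_responsiveness()].
#' @return Data frame with one row per observation.
#' @export
compute_effects <- function(db, fertile_threshold = 1125) {
  lnfr <- ln_fr(db$yield_t_mean, db$yield_c_mean)
  v <- fr_variance(db$yield_t_sd, db$n_t, db$yield_t_mean,
                   db$yield_c_sd, db$n_c, db$yield_c_mean)
  nae <- ifelse(!is.na(db$n_rate) & db$n_rate > 0,
                (db$yield_t_mean - db$yield_c_mean) / db$n_rate, NA_real_)
  carry <- intersect(c("study_id", "site_id", "region", "soil_order",
                       "texture_class", "aez", "nutrient_type", "manager",
                       "n_rate", "soil_ph", "total_c", "total_n", "p_olsen",
                       "exch_k", "exch_ca", "exch_mg", "clay", "sand",
                       "silt", "rainfall", "altitude", "yield_c_mean",
                       "yield_t_mean", "sd_imputed_flag"),
                     names(db))
  cbind(data.frame(ln_fr = lnfr, fr = exp(lnfr), fr_var = v, n_ae = nae,
                   responsiveness = classify_responsiveness(
                     exp(lnfr), db$yield_c_mean, fertile_threshold)),
        db[, carry, drop = FALSE])
}
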