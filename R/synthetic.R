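# Seeded generator of synthetic on-farm trial databases with the
# statistical structure the analysis assumes: study-level heterogeneity,
# covariate-linked log response ratios, within-plot sampling error,
# mixed variance reporting, missingness and optional publication bias.

#' Configuration of the synthetic trial-database generator
#'
#' Defaults emulate the published database's conditions: about 70 studies
#' of ~6.5 observations each (~457 observations), a 0.44 Kenya fraction,
#' N rates uniform on 15-150 kg N/ha, soil pH around 5.2, control yields
#' log-normal around 1500 kg/ha, a pooled median FR near 1.8
#' (`true_mu = log(1.8)`), a control-yield power-law exponent of -0.5,
#' and within-plot CVs around 15%.
#'
#' @param n_studies Number of studies.
#' @param obs_per_study Integer vector to sample each study's
#'   observation count from.
#' @param kenya_fraction Probability a study is Kenyan.
#' @param true_mu Pooled mean ln FR.
#' @param tau2 Study-level heterogeneity variance of ln FR.
#' @param b_control_yield Effect of centered ln(control yield) on ln FR
#'   (the power-law exponent).
#' @param moderator_effects Named coefficients on centered covariates
#'   (names: `soil_ph`, `log_total_c`, `log_p_olsen`, `log_exch_k`,
#'   `log_silt`, `log_rainfall`).
#' @param npk_effect Additive ln FR shift for NPK vs N-only records.
#' @param npk_fraction,farmer_fraction Category probabilities.
#' @param control_yield_meanlog,control_yield_sdlog Log-normal control
#'   yield parameters (kg/ha scale).
#' @param cv_meanlog,cv_sdlog Log-normal within-plot CV parameters.
#' @param n_rate_range N application range, kg N/ha.
#' @param variance_reporting Probabilities that a record reports sd, se,
#'   cv, or nothing (in that order; must sum to 1).
#' @param missingness Named per-variable masking rates applied to the
#'   emitted table (empty vector for complete data).
#' @param missing_mechanism `"MCAR"` or `"MAR_on_region"`.
#' @param publication_bias `NULL` (off) or
#'   `list(strength =, center =, scale =)`: each record is suppressed
#'   with probability `strength * (1 - plogis((z - center)/scale))` where
#'   `z = ln FR / se` is its studentized effect, so weak
#'   (non-significant) results are preferentially lost; `center` is on
#'   the z scale (1.96 censors at nominal significance).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_studies = 70,
                             obs_per_study = 3:10,
                             kenya_fraction = 0.44,
                             true_mu = log(1.8),
                             tau2 = 0.15,
                             b_control_yield = -0.5,
                             moderator_effects = c(soil_ph = 0.10,
                                                   log_total_c = -0.08,
                                                   log_p_olsen = -0.05,
                                                   log_exch_k = 0.10,
                                                   log_silt = -0.05,
                                                   log_rainfall = 0.15),
                             npk_effect = 0.35,
                             npk_fraction = 0.16,
                             farmer_fraction = 0.86,
                             control_yield_meanlog = log(1500),
                             control_yield_sdlog = 0.55,
                             cv_meanlog = log(0.15),
                             cv_sdlog = 0.3,
                             n_rate_range = c(15, 150),
                             variance_reporting = c(sd = 0.5, se = 0.15,
                                                    cv = 0.15, none = 0.2),
                             missingness = c(soil_ph = 0.07, total_c = 0.10,
                                             total_n = 0.15, p_measured = 0.10,
                                             exch_k = 0.18, exch_ca = 0.28,
                                             exch_mg = 0.30, clay = 0.25,
                                             sand = 0.28, silt = 0.24,
                                             rainfall = 0.05, altitude = 0.30),
                             missing_mechanism = c("MCAR", "MAR_on_region"),
                             publication_bias = NULL,
                             seed = 1) {
  stopifnot(tau2 >= 0, kenya_fraction >= 0, kenya_fraction <= 1,
            abs(sum(variance_reporting) - 1) < 1e-8,
            all(missingness >= 0 & missingness <= 1),
            n_rate_range[1] < n_rate_range[2], n_rate_range[1] >= 0)
  if (exp(cv_meanlog + 3 * cv_sdlog) / sqrt(min(3)) > 1)
    stop("infeasible config: within-plot sd model risks negative yields")
  structure(as.list(environment())[c(
    "n_studies", "obs_per_study", "kenya_fraction", "true_mu", "tau2",
    "b_control_yield", "moderator_effects", "npk_effect", "npk_fraction",
    "farmer_fraction", "control_yield_meanlog", "control_yield_sdlog",
    "cv_meanlog", "cv_sdlog", "n_rate_range", "variance_reporting",
    "missingness", "publication_bias", "seed")] |>
      c(list(missing_mechanism = match.arg(missing_mechanism))),
    class = "synthetic_config")
}

.soil_orders <- c(Ferralsols = 0.30, Arcrisols = 0.13, Nitisols = 0.15,
                  Cambisols = 0.05, Luvisols = 0.02, Lixisols = 0.09,
                  Alfisols = 0.08, Vertisols = 0.02, Phaeozems = 0.02,
                  Alisols = 0.02, Andosols = 0.07, Arenosols = 0.05)

.aez_kenya <- c("lowlands", "lower_midlands", "upper_midlands",
                "lower_highlands")
.aez_ssa <- c("humid", "sub_humid", "semi_arid")

# coarse USDA texture label from the fractions
.usda_texture <- function(clay, sand) {
  ifelse(clay >= 40 & sand < 45, "Clay",
  ifelse(clay >= 35 & sand >= 45, "Sandy clay",
  ifelse(sand >= 85, "Sand",
  ifelse(sand >= 70, "Loamy sand",
  ifelse(clay >= 27 & sand < 45, "Clay loam",
  ifelse(clay >= 20 & sand >= 45, "Sandy clay loam",
  ifelse(sand >= 43, "Sandy loam", "Loam")))))))
}

#' Generate a synthetic trial database
#'
#' Control yields are log-normal; the true ln FR of each observation is
#' `true_mu` plus centered-covariate effects, an NPK shift, and a
#' study-level Normal(0, tau2) deviation; observed arm means perturb the
#' true means by within-plot error consistent with the drawn sds and
#' replicate counts; variance statistics are reported as sd, se, cv, or
#' not at all; missingness and optional publication bias are applied
#' last. The sidecar records every latent truth.
#'
#' @param config A [synthetic_config()].
#' @return List with `db` (trial table in the [trial_schema()] layout),
#'   `truth` (per-observation latent values plus the implied power-law
#'   `a` and `b` as attributes), and `deletion_log` (masked cells).
#' @export
generate_trials <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)
  cfg <- config
  n_obs_study <- sample(cfg$obs_per_study, cfg$n_studies, replace = TRUE)
  study <- rep(seq_len(cfg$n_studies), n_obs_study)
  n <- length(study)
  region_study <- ifelse(stats::runif(cfg$n_studies) < cfg$kenya_fraction,
                         "kenya", "ssa_other")
  region <- region_study[study]
  u_study <- stats::rnorm(cfg$n_studies, 0, sqrt(cfg$tau2))[study]

  # covariates (study-level mean + site noise for soil properties)
  ph_study <- stats::rnorm(cfg$n_studies, 5.2, 0.45)[study]
  soil_ph <- pmin(8.5, pmax(3.8, ph_study + stats::rnorm(n, 0, 0.25)))
  total_c <- stats::rlnorm(n, log(14), 0.6)
  total_n <- total_c / 11 * stats::rlnorm(n, 0, 0.15)
  p_true <- stats::rlnorm(n, log(6), 0.7)     # Olsen scale, mg/kg
  exch_k <- stats::rlnorm(n, log(0.5), 0.6)
  exch_ca <- stats::rlnorm(n, log(4), 0.5)
  exch_mg <- stats::rlnorm(n, log(1.2), 0.5)
  g <- cbind(stats::rgamma(n, 2.5), stats::rgamma(n, 4), stats::rgamma(n, 2.5))
  tex <- round(100 * g / rowSums(g), 1)
  clay <- tex[, 1]; sand <- tex[, 2]; silt <- pmax(0.1, 100 - tex[, 1] - tex[, 2])
  rain_study <- stats::rnorm(cfg$n_studies, 800, 180)[study]
  rainfall <- pmax(250, rain_study + stats::rnorm(n, 0, 60))
  altitude <- round(pmax(10, ifelse(region == "kenya",
                                    stats::rnorm(n, 1400, 350),
                                    stats::rnorm(n, 800, 300))))
  n_rate <- round(stats::runif(n, cfg$n_rate_range[1], cfg$n_rate_range[2]))
  nutrient_type <- ifelse(stats::runif(n) < cfg$npk_fraction, "NPK", "N_only")
  manager <- ifelse(stats::runif(n) < cfg$farmer_fraction,
                    "farmer", "researcher")
  soil_order <- sample(names(.soil_orders), n, TRUE, .soil_orders)
  aez <- ifelse(region == "kenya",
                sample(.aez_kenya, n, TRUE),
                sample(.aez_ssa, n, TRUE))

  # true effects
  yield_c_true <- stats::rlnorm(n, cfg$control_yield_meanlog,
                                cfg$control_yield_sdlog)
  covs <- cbind(soil_ph = soil_ph, log_total_c = log(total_c),
                log_p_olsen = log(p_true), log_exch_k = log(exch_k),
                log_silt = log(silt), log_rainfall = log(rainfall))
  eff <- cfg$moderator_effects[colnames(covs)]
  eff[is.na(eff)] <- 0
  lin <- drop(scale(covs, center = TRUE, scale = FALSE) %*% eff)
  npk <- cfg$npk_effect * ((nutrient_type == "NPK") - cfg$npk_fraction)
  lcy <- log(yield_c_true)
  true_ln_fr <- cfg$true_mu + cfg$b_control_yield * (lcy - mean(lcy)) +
    lin + npk + u_study
  yield_t_true <- yield_c_true * exp(true_ln_fr)

  # within-plot error and variance reporting
  n_t <- sample(3:4, n, TRUE); n_c <- n_t
  cv_t <- stats::rlnorm(n, cfg$cv_meanlog, cfg$cv_sdlog)
  cv_c <- stats::rlnorm(n, cfg$cv_meanlog, cfg$cv_sdlog)
  sd_t <- cv_t * yield_t_true; sd_c <- cv_c * yield_c_true
  yield_t_mean <- pmax(1, yield_t_true + stats::rnorm(n, 0, sd_t / sqrt(n_t)))
  yield_c_mean <- pmax(1, yield_c_true + stats::rnorm(n, 0, sd_c / sqrt(n_c)))
  vr <- sample(names(cfg$variance_reporting), n, TRUE,
               cfg$variance_reporting)
  db <- data.frame(
    study_id = sprintf("S%03d", study),
    site_id = sprintf("S%03d_O%02d", study, stats::ave(study, study,
                                                       FUN = seq_along)),
    region = region,
    yield_t_mean = round(yield_t_mean, 1),
    yield_c_mean = round(yield_c_mean, 1),
    yield_t_sd = ifelse(vr == "sd", round(sd_t, 1), NA),
    yield_c_sd = ifelse(vr == "sd", round(sd_c, 1), NA),
    yield_t_se = ifelse(vr == "se", round(sd_t / sqrt(n_t), 1), NA),
    yield_c_se = ifelse(vr == "se", round(sd_c / sqrt(n_c), 1), NA),
    yield_t_cv = ifelse(vr == "cv", round(100 * cv_t, 1), NA),
    yield_c_cv = ifelse(vr == "cv", round(100 * cv_c, 1), NA),
    n_t = n_t, n_c = n_c, n_rate = n_rate,
    soil_ph = round(soil_ph, 2), total_c = round(total_c, 2),
    total_n = round(total_n, 3),
    p_olsen = NA_real_, p_bray1 = NA_real_, p_bray2 = NA_real_,
    exch_k = round(exch_k, 3), exch_ca = round(exch_ca, 2),
    exch_mg = round(exch_mg, 2),
    clay = clay, sand = sand, silt = round(silt, 1),
    rainfall = round(rainfall), altitude = altitude,
    soil_order = soil_order,
    texture_class = .usda_texture(clay, sand), aez = aez,
    nutrient_type = nutrient_type, manager = manager)

  # one extractable-P method per study
  p_method <- sample(c("olsen", "bray1", "bray2"), cfg$n_studies, TRUE,
                     c(0.45, 0.15, 0.40))[study]
  db$p_olsen[p_method == "olsen"] <- round(p_true[p_method == "olsen"], 2)
  db$p_bray1[p_method == "bray1"] <- round(p_true[p_method == "bray1"] / 0.44, 2)
  db$p_bray2[p_method == "bray2"] <- round(p_true[p_method == "bray2"] / 0.79, 2)

  truth <- data.frame(
    study_id = db$study_id, site_id = db$site_id, region = region,
    true_ln_fr = true_ln_fr, u_study = u_study,
    yield_t_true = yield_t_true, yield_c_true = yield_c_true,
    sd_t_true = sd_t, sd_c_true = sd_c, p_method = p_method)
  attr(truth, "true_mu") <- cfg$true_mu
  attr(truth, "tau2") <- cfg$tau2
  attr(truth, "power_law_b") <- cfg$b_control_yield
  attr(truth, "power_law_a") <- exp(cfg$true_mu -
                                    cfg$b_control_yield * mean(lcy))

  # publication bias: preferentially suppress weak results. The censoring
  # acts on the studentized effect z_i = lnFR_i / se_i (the record's
  # apparent significance), the mechanism that produces the asymmetric
  # funnel the diagnostics look for; censoring the raw effect alone
  # barely distorts the funnel once true heterogeneity dominates the
  # sampling error.
  if (!is.null(cfg$publication_bias)) {
    pb <- cfg$publication_bias
    obs_lnfr <- log(db$yield_t_mean / db$yield_c_mean)
    obs_se <- sqrt(sd_t^2 / (n_t * yield_t_mean^2) +
                   sd_c^2 / (n_c * yield_c_mean^2))
    zstat <- obs_lnfr / obs_se
    p_drop <- pb$strength * (1 - stats::plogis((zstat - pb$center) / pb$scale))
    keep <- stats::runif(n) >= p_drop
    db <- db[keep, ]; truth <- truth[keep, ]
    rownames(db) <- rownames(truth) <- NULL
  }

  # missingness last
  dl <- data.frame(row = integer(), column = character(), value = numeric())
  if (length(cfg$missingness)) {
    rates <- cfg$missingness
    # p_measured masks whichever P column the study reported
    if ("p_measured" %in% names(rates)) {
      pm <- truth$p_method
      pcol <- c(olsen = "p_olsen", bray1 = "p_bray1", bray2 = "p_bray2")[pm]
      mask <- stats::runif(nrow(db)) < rates[["p_measured"]]
      for (i in which(mask)) {
        dl <- rbind(dl, data.frame(row = i, column = pcol[i],
                                   value = db[i, pcol[i]]))
        db[i, pcol[i]] <- NA
      }
      rates <- rates[names(rates) != "p_measured"]
    }
    im <- inject_missingness(db, rates, cfg$missing_mechanism)
    db <- im$db
    dl <- rbind(dl, im$deletion_log)
  }
  list(db = db, truth = truth, deletion_log = dl)
}

#' Mask values in a trial table
#'
#' Masks the requested fraction of each named variable, either completely
#' at random (MCAR) or at a region-dependent rate (MAR_on_region: the
#' non-Kenya stratum is masked at 1.5x and Kenya at the complementary
#' rate so the marginal rate is preserved). A deletion log records every
#' masked cell for imputation-accuracy scoring.
#'
#' @param db Trial table.
#' @param rates Named per-variable masking rates in \[0, 1\].
#' @param mechanism `"MCAR"` or `"MAR_on_region"`.
#' @return List with `db` and `deletion_log` (row, column, value).
#' @export
inject_missingness <- function(db, rates,
                               mechanism = c("MCAR", "MAR_on_region")) {
  mechanism <- match.arg(mechanism)
  stopifnot(all(rates >= 0 & rates <= 1))
  logs <- list()
  for (v in names(rates)) {
    if (is.null(db[[v]])) next
    r <- rates[[v]]
    p <- if (mechanism == "MCAR") rep(r, nrow(db)) else {
      f_ssa <- mean(db$region == "ssa_other")
      # 1.5x rate outside Kenya, rescaled to keep the marginal rate
      w <- ifelse(db$region == "ssa_other", 1.5, 1)
      pmin(1, r * w / (1.5 * f_ssa + (1 - f_ssa)))
    }
    mask <- stats::runif(nrow(db)) < p & !is.na(db[[v]])
    if (any(mask)) {
      logs[[v]] <- data.frame(row = which(mask), column = v,
                              value = db[[v]][mask])
      db[[v]][mask] <- NA
    }
  }
  list(db = db,
       deletion_log = if (length(logs)) do.call(rbind, c(logs,
                                                         make.row.names = FALSE))
                      else data.frame(row = integer(), column = character(),
                                      value = numeric()))
}
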