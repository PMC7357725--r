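# End-to-end orchestration: read/generate -> harmonize -> impute ->
# effects -> pooled RE fit -> bias diagnostics -> subgroups -> GLM/VIP ->
# power law, with a manifest and plot-ready CSV/JSON outputs.

#' Pipeline configuration
#'
#' @param input Path to a trial CSV, or `NULL` to generate a synthetic
#'   database from `synthetic`.
#' @param synthetic A [synthetic_config()] used when `input` is `NULL`.
#' @param outdir Output directory (created if absent).
#' @param seed Integer seed for imputation (and the generator, unless the
#'   synthetic config sets its own).
#' @param fertile_threshold Control-yield benchmark for the fertile
#'   non-responsive class, kg/ha.
#' @param subgroup_vars Categorical moderators to summarize; include
#'   `"n_rate_bin"` for binned N rates.
#' @param n_rate_bins Bin edges for the N-rate subgroup, kg N/ha
#'   (strictly increasing).
#' @param glm_predictors Predictor columns for the GLMs (before the log
#'   recipe is applied).
#' @param log_recipe Columns log-transformed before standardization.
#' @param threshold_r,use_abs_r,sd_multiplier,pmm_k,pmm_iterations
#'   Imputation settings (see [impute_cascade()] and [pmm_config()]).
#' @param subgroup_weights `"fixed"` or `"random"` subgroup weighting.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(input = NULL,
                            synthetic = synthetic_config(),
                            outdir = tempfile("frmeta_run_"),
                            seed = 1,
                            fertile_threshold = 1125,
                            subgroup_vars = c("soil_order", "texture_class",
                                              "aez", "nutrient_type",
                                              "manager", "n_rate_bin"),
                            n_rate_bins = c(0, 30, 60, 90, 120, 150),
                            glm_predictors = c("n_rate", "total_c", "soil_ph",
                                               "p_olsen", "exch_k", "clay",
                                               "silt", "rainfall"),
                            log_recipe = default_log_recipe(),
                            threshold_r = 0.8, use_abs_r = FALSE,
                            sd_multiplier = 1.5,
                            pmm_k = 5, pmm_iterations = 10,
                            subgroup_weights = "fixed") {
  stopifnot(all(diff(n_rate_bins) > 0))
  structure(list(input = input, synthetic = synthetic, outdir = outdir,
                 seed = as.integer(seed),
                 fertile_threshold = fertile_threshold,
                 subgroup_vars = subgroup_vars, n_rate_bins = n_rate_bins,
                 glm_predictors = glm_predictors, log_recipe = log_recipe,
                 threshold_r = threshold_r, use_abs_r = use_abs_r,
                 sd_multiplier = sd_multiplier, pmm_k = pmm_k,
                 pmm_iterations = pmm_iterations,
                 subgroup_weights = subgroup_weights),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the [pipeline_config()] arguments; a `synthetic`
#' mapping is passed to [synthetic_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$synthetic))
    y$synthetic <- do.call(synthetic_config, y$synthetic)
  if (!is.null(y$n_rate_bins)) y$n_rate_bins <- as.numeric(y$n_rate_bins)
  do.call(pipeline_config, y)
}

#' Descriptive N-AE statistics per categorical level
#'
#' Unweighted mean, standard error of the mean and n of the agronomic N
#' use efficiency for each level of each listed moderator; the se is
#' missing for single-record levels.
#'
#' @param effects Effect table from [compute_effects()].
#' @param variables Categorical moderator names.
#' @return Data frame with `variable`, `level`, `n`, `mean_n_ae`,
#'   `se_n_ae`.
#' @export
summarize_categories <- function(effects,
                                 variables = c("soil_order", "texture_class",
                                               "aez", "manager",
                                               "nutrient_type")) {
  rows <- list()
  for (v in intersect(variables, names(effects))) {
    lev <- as.character(effects[[v]])
    for (l in sort(unique(lev[!is.na(lev)]))) {
      x <- effects$n_ae[!is.na(lev) & lev == l]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = l, n = length(x),
        mean_n_ae = if (length(x)) mean(x) else NA_real_,
        se_n_ae = if (length(x) > 1) stats::sd(x) / sqrt(length(x))
                  else NA_real_)
    }
  }
  do.call(rbind, rows)
}

.bin_n_rate <- function(n_rate, edges) {
  lab <- paste0(utils::head(edges, -1), "-", utils::tail(edges, -1))
  cut(n_rate, edges, labels = lab, include.lowest = TRUE)
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
}

#' Run the full analysis pipeline
#'
#' Stages: read or generate the trial database, harmonize, run the
#' missing-data cascade, compute effect sizes and responsiveness classes,
#' fit the pooled random-effects model with the Q_T heterogeneity test,
#' run the publication-bias diagnostics, summarize subgroups per
#' configured moderator split by region, fit the standardized GLMs with
#' VIP scores per response and region, and fit the power law of FR
#' against control yield per region. All tables are written to
#' `config$outdir` together with a manifest of settings and seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every intermediate and final table.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  truth <- NULL
  db <- stage("input", {
    if (!is.null(config$input)) read_trials(config$input)
    else {
      gen <- generate_trials(config$synthetic)
      truth <- gen$truth
      gen$db
    }
  })
  db <- stage("harmonize", harmonize(db))
  imp <- stage("impute", impute_cascade(
    db, threshold_r = config$threshold_r, use_abs_r = config$use_abs_r,
    sd_multiplier = config$sd_multiplier,
    pmm = pmm_config(character(0), k = config$pmm_k,
                     iterations = config$pmm_iterations,
                     seed = config$seed)))
  db <- imp$db
  effects <- stage("effects", compute_effects(
    db, fertile_threshold = config$fertile_threshold))
  if ("n_rate_bin" %in% config$subgroup_vars)
    effects$n_rate_bin <- .bin_n_rate(effects$n_rate, config$n_rate_bins)

  regions <- list(all = effects)
  for (r in unique(effects$region)) regions[[r]] <- effects[effects$region == r, ]

  fits <- stage("random_effects", lapply(regions, function(e)
    rema(e$ln_fr, e$fr_var)))
  bias <- stage("bias", list(
    egger = egger_test(fits$all),
    trimfill = trim_and_fill(fits$all)))
  subgroups <- if (length(config$subgroup_vars)) {
    stage("subgroups", {
      out <- list()
      for (r in names(regions)) for (v in config$subgroup_vars) {
        e <- regions[[r]]
        if (is.null(e[[v]]) || all(is.na(e[[v]]))) next
        s <- subgroup_weighted_means(e, v, weights = config$subgroup_weights)
        s$region <- r
        out[[paste(r, v)]] <- s
      }
      do.call(rbind, c(out, make.row.names = FALSE))
    })
  } else {
    message("subgroup stage skipped: empty subgroup list")
    NULL
  }

  drop_glm <- intersect(imp$dropped_vars, config$glm_predictors)
  glms <- stage("glm_vip", {
    out <- list()
    for (r in setdiff(names(regions), "all")) {
      e <- regions[[r]]
      for (resp in c("ln_fr", "n_ae")) {
        preds <- setdiff(config$glm_predictors, drop_glm)
        if (resp == "n_ae") preds <- setdiff(preds, "n_rate")
        X <- transform_predictors(e[, preds, drop = FALSE],
                                  recipe = config$log_recipe)
        ok <- stats::complete.cases(X) & !is.na(e[[resp]])
        if (sum(ok) <= ncol(X) + 2) next
        Xs <- standardize(X[ok, , drop = FALSE])
        gfit <- fit_glm(e[[resp]][ok], Xs, response = resp)
        vip <- vip_scores(e[[resp]][ok], Xs)
        out[[paste(r, resp)]] <- list(region = r, response = resp,
                                      glm = gfit, vip = vip)
      }
    }
    out
  })
  power <- stage("power_law", lapply(regions, function(e)
    fit_power_law(e$fr, e$yield_c_mean)))
  nae_desc <- stage("nae_descriptives", summarize_categories(effects))

  # emit the bundle
  od <- config$outdir
  write_trials(db, file.path(od, "trials_harmonized.csv"))
  utils::write.csv(effects, file.path(od, "effects.csv"), row.names = FALSE,
                   na = "")
  .write_json(lapply(fits, function(f)
    f[c("mu", "tau2", "se_mu", "ci_low", "ci_high", "q_t", "df", "p_q", "k")]),
    file.path(od, "pooled_fit.json"))
  if (!is.null(subgroups))
    utils::write.csv(subgroups, file.path(od, "subgroups.csv"),
                     row.names = FALSE, na = "")
  .write_json(list(
    egger = bias$egger,
    trimfill = bias$trimfill[c("k0", "side", "adjusted_mu", "mu_observed")]),
    file.path(od, "bias.json"))
  utils::write.csv(funnel_data(fits$all), file.path(od, "funnel.csv"),
                   row.names = FALSE)
  if (length(glms)) {
    coefs <- do.call(rbind, lapply(glms, function(g)
      cbind(region = g$region, response = g$response, g$glm$coefficients,
            r2 = g$glm$r2, adjusted_r2 = g$glm$adjusted_r2, n = g$glm$n)))
    utils::write.csv(coefs, file.path(od, "glm_coefficients.csv"),
                     row.names = FALSE)
    vips <- do.call(rbind, lapply(glms, function(g)
      data.frame(region = g$region, response = g$response,
                 predictor = names(g$vip$scores), vip = g$vip$scores,
                 important = g$vip$scores > g$vip$threshold,
                 n_components = g$vip$n_components)))
    utils::write.csv(vips, file.path(od, "vip.csv"), row.names = FALSE)
  }
  .write_json(lapply(power, function(p) p[c("a", "b", "r2", "p", "n")]),
              file.path(od, "power_law.json"))
  utils::write.csv(nae_desc, file.path(od, "nae_descriptives.csv"),
                   row.names = FALSE, na = "")
  manifest <- list(
    seed = config$seed,
    input = if (is.null(config$input)) "synthetic" else config$input,
    synthetic_seed = if (is.null(config$input)) config$synthetic$seed,
    n_records = nrow(db),
    settings = config[c("fertile_threshold", "subgroup_vars", "n_rate_bins",
                        "glm_predictors", "log_recipe", "threshold_r",
                        "use_abs_r", "sd_multiplier", "pmm_k",
                        "pmm_iterations", "subgroup_weights")],
    dropped_vars = imp$dropped_vars,
    stage_counts = list(records_in = nrow(db), effects = nrow(effects)))
  .write_json(manifest, file.path(od, "manifest.json"))

  invisible(list(db = db, truth = truth, effects = effects, fits = fits,
                 bias = bias, subgroups = subgroups, glms = glms,
                 power = power, nae_descriptives = nae_desc,
                 plan = imp$plan, dropped_vars = imp$dropped_vars,
                 manifest = manifest, outdir = od))
}
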