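# Example frmeta pipeline configuration.
# Omit `input` to analyse a synthetic database generated from `synthetic`.
seed: 1
outdir: frmeta_out
fertile_threshold: 1125
threshold_r: 0.8
use_abs_r: false
sd_multiplier: 1.5
pmm_k: 5
pmm_iterations: 10
subgroup_weights: fixed
n_rate_bins: [0, 30, 60, 90, 120, 150]
subgroup_vars: [soil_order, texture_class, aez, nutrient_type, manager, n_rate_bin]
glm_predictors: [n_rate, total_c, soil_ph, p_olsen, exch_k, clay, silt, rainfall]
log_recipe: [total_c, p_olsen, n_rate, exch_k, silt, rainfall]
synthetic:
  n_studies: 70
  kenya_fraction: 0.44
  tau2: 0.15
  seed: 1
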