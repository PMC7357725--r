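"column","type","required","unit"
"study_id","character",TRUE,""
"site_id","character",FALSE,""
"region","character",TRUE,""
"soil_order","character",FALSE,""
"texture_class","character",FALSE,""
"aez","character",FALSE,""
"nutrient_type","character",FALSE,""
"manager","character",FALSE,""
"yield_t_mean","numeric",TRUE,"kg/ha"
"yield_c_mean","numeric",TRUE,"kg/ha"
"yield_t_sd","numeric",FALSE,"kg/ha"
"yield_c_sd","numeric",FALSE,"kg/ha"
"yield_t_se","numeric",FALSE,"kg/ha"
"yield_c_se","numeric",FALSE,"kg/ha"
"yield_t_cv","numeric",FALSE,"%"
"yield_c_cv","numeric",FALSE,"%"
"n_t","integer",TRUE,"count"
"n_c","integer",TRUE,"count"
"n_rate","numeric",TRUE,"kg N/ha"
"soil_ph","numeric",FALSE,""
"total_c","numeric",FALSE,"g/kg"
"total_n","numeric",FALSE,"g/kg"
"p_olsen","numeric",FALSE,"mg/kg"
"p_bray1","numeric",FALSE,"mg/kg"
"p_bray2","numeric",FALSE,"mg/kg"
"exch_k","numeric",FALSE,"cmol/kg"
"exch_ca","numeric",FALSE,"cmol/kg"
"exch_mg","numeric",FALSE,"cmol/kg"
"clay","numeric",FALSE,"%"
"sand","numeric",FALSE,"%"
"silt","numeric",FALSE,"%"
"rainfall","numeric",FALSE,"mm"
"altitude","numeric",FALSE,"m"
"sd_imputed_flag","logical",FALSE,""
"p_olsen_converted","logical",FALSE,""
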