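"study_id","site_id","region","soil_order","texture_class","aez","nutrient_type","manager","yield_t_mean","yield_c_mean","yield_t_sd","yield_c_sd","yield_t_se","yield_c_se","yield_t_cv","yield_c_cv","n_t","n_c","n_rate","soil_ph","total_c","total_n","p_olsen","p_bray1","p_bray2","exch_k","exch_ca","exch_mg","clay","sand","silt","rainfall","altitude"
"S001","S001_O01","kenya","Ferralsols","Sandy loam","lowlands","N_only","farmer",2698.8,953,,,,,,,4,4,77,4.79,17.3,1.38,,10.72,,0.455,2.34,0.7,8.7,65,26.3,1050,1298
"S001","S001_O02","kenya","Alfisols","Sandy loam","lower_midlands","N_only","farmer",4953.1,2014.5,911.4,186.9,,,,,4,4,37,5.12,14.63,1.43,,2.95,,,2.95,,,,30.4,965,1361
"S001","S001_O03","kenya","Ferralsols","Sandy clay loam","lowlands","N_only","researcher",3827.6,1341,399.1,167,,,,,3,3,26,4.89,14.06,1.243,,25.25,,1.221,5.83,,,54,17.8,999,1490
"S002","S002_O01","ssa_other","Ferralsols","Sandy loam","sub_humid","N_only","farmer",1340.3,1397.1,,,,,,,4,4,131,4.75,12.51,1.434,9.96,,,0.518,5.02,,14.9,45,,638,
"S002","S002_O02","ssa_other","Alfisols","Sandy clay loam","sub_humid","N_only","farmer",1416,1106.3,190.5,149.4,,,,,3,3,69,4.69,8.84,,7,,,0.3,3.76,,27.5,67.2,5.3,622,
"S002","S002_O03","ssa_other","Vertisols","Sandy loam","semi_arid","N_only","farmer",1340.9,830.4,201.6,67.3,,,,,3,3,126,4.97,12.26,1.058,10.43,,,2.035,2.73,0.76,17.4,61.7,20.9,507,715
"S003","S003_O01","kenya","Nitisols","Sandy loam","lower_midlands","N_only","researcher",2556.1,532.4,375.7,91.8,,,,,3,3,84,4.68,7.76,0.552,,,,0.465,,3.72,8.1,,27.6,758,
"S003","S003_O02","kenya","Nitisols","Sandy loam","lower_highlands","NPK","farmer",3474.1,976.8,502.7,80.5,,,,,4,4,30,4.66,7.22,0.658,,,4.28,0.155,7,0.89,,52.2,29.8,792,841
"S003","S003_O03","kenya","Nitisols","Sandy clay","upper_midlands","N_only","farmer",3177.5,953.6,364.5,141.9,,,,,3,3,81,4.66,7.97,0.829,,,10.78,0.691,4.33,0.63,,56.2,,682,
"S004","S004_O01","kenya","Nitisols","Sandy loam","lower_midlands","N_only","farmer",3768.9,2421,538.4,359.7,,,,,3,3,127,5.04,21.04,1.678,,,8.49,1.381,2.83,1.55,12.5,47.4,40.1,618,
"S004","S004_O02","kenya","Lixisols","Clay loam","lower_midlands","N_only","farmer",1773.1,921.7,,,,,15.1,22.7,4,4,109,4.93,5.43,,,,11.1,0.311,,0.78,32.3,,,493,1641
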