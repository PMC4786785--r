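product,catalyst,pH,mass_mg,mass_unit,substrate_mM,volume_ml,contaminant_w_fraction,printed_mmol,printed_mmol_unit,printed_percent,printed_percent_unit
6a,WT,7.3,8.2,0.1,2,60,0,0.042,0.001,36,1
6a,M45Y/F50A,7.3,6.9,0.1,2,60,0,0.036,0.001,30,1
6a,M45Y/F50A,5.5,15.2,0.1,2,60,0,0.079,0.001,65,1
6a,A33D,7.3,6.5,0.1,2,60,0,0.034,0.001,28,1
6a,WT,6.5,22,1,2,60,0,0.11,0.01,94,1
6a,A33D,6.5,22,1,2,60,0,0.11,0.01,94,1
7,WT,5.5,17.7,0.1,2,60,0,0.080,0.001,67,1
7,H6M/A33E/F50V,5.5,20.2,0.1,2,60,0,0.091,0.001,76,1
7,R39E,5.5,17.6,0.1,2,60,0,0.080,0.001,66,1
7,M45Y/F50A,5.5,22.7,0.1,2,60,0,0.102,0.001,86,1
6b,A33D,5.5,12,1,1.3,50,0,0.053,0.001,81,1
6b,M45Y/F50A,5.5,9,1,1.3,50,0,0.0393,0.0001,60,1
6c,A33D,5.5,16,1,2,60,0,0.076,0.001,63,1
6c,M45Y/F50A,5.5,12,1,2,60,0,0.058,0.001,47,1
6d,A33D,6.5,11,1,2,60,0,0.052,0.001,44,1
6d,M45Y/F50A,5.5,13,1,2,60,0.06,0.058,0.001,48,1
6e,A33D,6.5,27,1,2,60,0,0.112,0.001,94,1
6e,M45Y/F50A,5.5,21,1,2,60,0,0.088,0.001,73,1
6f,A33D,5.5,24,1,2,60,0,0.078,0.001,65,1
6f,M45Y/F50A,5.5,26,1,2,60,0,0.085,0.001,70,1
6g,A33D,5.5,4,1,3,12.8,0,0.023,0.001,60,1
6g,M45Y/F50A,5.5,4,1,3,12.8,0,0.023,0.001,60,1
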