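experiment,dose,n_mothers,n_offspring,n_male,n_males_tested,n_diploid_males_found,n_flies_emerged,n_flies_unemerged
control_water,0,1,12,0,0,0,8,1
control_ethanol,0,4,10,0,0,0,90,3
treatment_1,0.004,3,42,0,0,0,56,5
treatment_1,0.008,5,33,0,0,0,108,1
treatment_1,0.016,2,2,0,0,0,36,0
treatment_1,0.031,5,12,0,0,0,116,3
treatment_1,0.063,1,2,0,0,0,21,0
treatment_1,0.125,6,38,0,0,0,89,6
treatment_1,0.25,7,153,99,39,0,107,9
treatment_1,0.5,6,36,36,17,0,83,4
treatment_1,1,8,62,62,25,0,108,3
treatment_2,0.067,3,19,10,9,0,52,3
treatment_2,0.089,5,37,1,1,0,75,1
treatment_2,0.119,2,5,4,4,0,22,1
treatment_2,0.158,5,14,6,3,0,90,4
treatment_2,0.211,5,59,51,12,0,87,2
treatment_2,0.281,8,67,65,30,0,131,2
treatment_2,0.375,4,32,32,16,0,95,2
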