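characteristic,level,reference,benign,malignant,npv,ppv,sen,spe,auc
shape,apt_ge_1,FALSE,89,685,32.9,88.5,56.6,74.4,0.655
shape,apt_lt_1,TRUE,258,526,NA,NA,NA,NA,NA
margin,regular,TRUE,180,189,NA,NA,NA,NA,NA
margin,irregular,FALSE,167,1022,48.8,86.0,84.4,51.9,0.681
border,unclear,FALSE,137,820,34.9,85.7,67.7,60.5,0.641
border,clear,TRUE,210,391,NA,NA,NA,NA,NA
hackly_border,present,FALSE,91,745,35.5,89.1,61.5,73.8,0.676
hackly_border,absent,TRUE,256,466,NA,NA,NA,NA,NA
component,solid,FALSE,207,1158,72.5,84.8,95.6,40.3,0.680
component,mixed,TRUE,140,53,NA,NA,NA,NA,NA
calcification,macro,FALSE,46,137,21.9,74.9,11.3,86.7,0.490
calcification,micro,FALSE,139,712,29.4,83.7,58.8,59.9,0.594
calcification,none,TRUE,162,362,NA,NA,NA,NA,NA
halo,present,FALSE,303,1132,35.8,78.9,93.5,12.7,0.531
halo,absent,TRUE,44,79,NA,NA,NA,NA,NA
attenuation,present,FALSE,33,208,23.8,86.3,17.2,90.5,0.538
attenuation,absent,TRUE,314,1003,NA,NA,NA,NA,NA
lateral_shadow,present,FALSE,9,52,22.6,85.2,4.3,97.4,0.509
lateral_shadow,absent,TRUE,338,1159,NA,NA,NA,NA,NA
blood_flow,low,FALSE,80,417,25.2,83.9,34.4,76.9,0.557
blood_flow,medium,TRUE,152,402,NA,NA,NA,NA,NA
blood_flow,high,FALSE,115,392,22.1,77.3,32.4,66.9,0.496
vascularity,peripheral,TRUE,103,255,NA,NA,NA,NA,NA
vascularity,mixed,FALSE,88,231,20.9,72.4,19.1,74.6,0.469
vascularity,central,FALSE,156,725,28.2,82.3,59.9,55.0,0.575
echogenicity,hypoechoic,FALSE,198,925,34.3,82.4,76.4,42.9,0.597
echogenicity,hyperechoic,TRUE,149,286,NA,NA,NA,NA,NA
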