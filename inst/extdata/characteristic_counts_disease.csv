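characteristic,level,reference,benign,malignant,npv,ppv,sen,spe,auc
shape,apt_ge_1,FALSE,34,684,29.3,95.3,57.0,86.3,0.716
shape,apt_lt_1,TRUE,214,516,NA,NA,NA,NA,NA
margin,regular,TRUE,174,180,NA,NA,NA,NA,NA
margin,irregular,FALSE,74,1020,49.2,93.2,85.0,70.2,0.776
border,unclear,FALSE,55,819,33.6,93.7,68.2,77.8,0.730
border,clear,TRUE,193,381,NA,NA,NA,NA,NA
hackly_border,present,FALSE,22,744,33.1,97.1,62.0,91.1,0.766
hackly_border,absent,TRUE,226,456,NA,NA,NA,NA,NA
component,solid,FALSE,108,1157,76.5,91.5,96.4,56.5,0.764
component,mixed,TRUE,140,43,NA,NA,NA,NA,NA
calcification,macro,FALSE,30,137,17.0,82.0,11.4,87.9,0.497
calcification,micro,FALSE,78,711,25.8,90.1,59.2,68.5,0.639
calcification,none,TRUE,140,352,NA,NA,NA,NA,NA
halo,present,FALSE,209,1123,33.6,84.3,93.6,15.7,0.547
halo,absent,TRUE,39,77,NA,NA,NA,NA,NA
attenuation,present,FALSE,12,208,19.2,94.5,17.3,95.2,0.562
attenuation,absent,TRUE,236,992,NA,NA,NA,NA,NA
lateral_shadow,present,FALSE,5,52,17.5,91.2,4.3,98.0,0.512
lateral_shadow,absent,TRUE,243,1148,NA,NA,NA,NA,NA
blood_flow,low,FALSE,49,417,20.3,89.5,34.8,80.2,0.575
blood_flow,medium,TRUE,116,396,NA,NA,NA,NA,NA
blood_flow,high,FALSE,83,387,16.9,82.3,32.2,66.5,0.494
vascularity,peripheral,TRUE,78,250,NA,NA,NA,NA,NA
vascularity,mixed,FALSE,69,228,15.6,76.8,19.0,72.2,0.456
vascularity,central,FALSE,101,722,23.5,87.7,60.2,59.3,0.597
echogenicity,hypoechoic,FALSE,117,920,31.9,88.7,76.7,52.8,0.647
echogenicity,hyperechoic,TRUE,131,280,NA,NA,NA,NA,NA
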