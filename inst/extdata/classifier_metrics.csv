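classifier,split,auc,sen,f1,spe,ppv,npv
RF,validating,0.960,0.892,0.701,0.820,0.960,0.612
RF,testing,0.958,0.883,0.721,0.880,0.972,0.611
LR,validating,0.965,0.875,0.720,0.900,0.977,0.600
LR,testing,0.965,0.875,0.720,0.900,0.977,0.600
SVM,validating,0.952,0.862,0.713,0.920,0.981,0.582
SVM,testing,0.962,0.896,0.740,0.900,0.977,0.643
NET,validating,0.965,0.879,0.726,0.900,0.977,0.608
NET,testing,0.964,0.879,0.746,0.920,0.981,0.613
ELM,validating,0.952,0.833,0.657,0.880,0.971,0.524
ELM,testing,0.952,0.833,0.657,0.880,0.971,0.524
KNN,validating,0.926,0.825,0.657,0.900,0.975,0.517
KNN,testing,0.926,0.825,0.657,0.900,0.975,0.517
NB,validating,0.940,0.871,0.672,0.820,0.959,0.569
NB,testing,0.940,0.871,0.672,0.820,0.959,0.569
ADAB,validating,0.955,0.891,0.733,0.880,0.973,0.629
ADAB,testing,0.958,0.855,0.712,0.940,0.985,0.574
LOG,validating,0.964,0.846,0.711,0.960,0.970,0.565
LOG,testing,0.956,0.846,0.711,0.960,0.970,0.565
LDA,validating,0.954,0.850,0.687,0.900,0.976,0.556
LDA,testing,0.954,0.850,0.687,0.900,0.976,0.556
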