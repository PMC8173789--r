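oar,dsc,dsc_sd,cmd_cm,cmd_cm_sd,dv_pct,dv_pct_sd,mhd_cm,mhd_cm_sd,ahd_cm,ahd_cm_sd
R Lung,0.96,0.02,0.13,0.07,7,5,2.18,0.72,0.11,0.05
L Lung,0.94,0.03,0.28,0.28,10,8,3.45,2.19,0.17,0.12
Skin,0.93,0.06,2.06,2.38,11,10,8.85,4.21,0.58,0.54
Heart,0.90,0.07,0.40,0.40,7,10,1.85,1.11,0.24,0.17
SC,0.88,0.04,1.34,2.01,9,7,2.74,4.19,0.13,0.21
AOR,0.79,0.10,0.92,0.48,24,20,2.72,1.15,0.28,0.16
CW,0.77,0.05,1.29,0.66,39,26,6.51,1.97,0.46,0.19
Trachea,0.75,0.09,0.53,0.31,34,51,4.27,4.65,0.25,0.25
PA,0.73,0.09,0.71,0.44,16,10,2.12,1.14,0.28,0.17
SVC,0.62,0.09,1.17,0.52,29,17,1.87,0.79,0.33,0.13
ESO,0.57,0.11,0.89,0.60,33,33,2.10,0.74,0.29,0.13
IVC,0.56,0.16,0.91,0.62,30,25,2.17,1.07,0.43,0.24
PV,0.53,0.14,1.00,0.49,35,24,2.65,0.90,0.44,0.11
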