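oar,dsc_our,dsc_velker,dsc_ciardo,cmd_our,cmd_ciardo,dv_our,mhd_our,ahd_our,ahd_ciardo
R Lung,3,3,3,3,3,3,2,3,3
L Lung,3,3,3,3,2,3,1,3,2
Skin,3,3,3,1,1,2,1,1,1
Heart,3,3,3,3,2,3,2,2,2
SC,3,3,3,1,1,3,1,3,3
AOR,2,2,2,2,1,1,1,2,2
CW,2,2,2,1,1,1,1,1,1
Trachea,2,2,2,2,1,1,1,2,2
PA,2,2,2,2,1,2,2,2,2
SVC,1,2,2,1,1,1,2,2,2
ESO,1,1,1,2,1,1,2,2,2
IVC,1,1,1,2,1,1,2,1,1
PV,1,1,1,2,1,1,1,1,1
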