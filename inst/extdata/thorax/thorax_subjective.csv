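oar,total_slices,modified_slices,pct_modified,score
R Lung,71,5,6,3
L Lung,71,7,10,3
Skin,125,19,14,2
Heart,31,6,17,2
SC,124,11,8,3
AOR,62,27,41,1
CW,71,29,42,1
Trachea,47,15,31,1
PA,12,7,58,1
SVC,22,13,57,1
ESO,72,54,74,1
IVC,13,10,75,1
PV,9,7,NA,1
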