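feature,family,column,p_value
min,statistical,t11,0.009
min,statistical,t22,0.025
min,statistical,t44,0.024
range,statistical,t44,0.038
range,statistical,t55,0.019
energy,statistical,t11,0.025
energy,statistical,t22,0.002
energy,statistical,t33,0.009
energy,statistical,t44,0.006
energy,statistical,t55,0.028
surface,morphological,t44,0.003
surface,morphological,t55,0.019
volume,morphological,t11,0.049
volume,morphological,t22,0.003
volume,morphological,t44,0.006
volume,morphological,t55,0.028
areavolume,morphological,t22,0.003
areavolume,morphological,t33,0.013
areavolume,morphological,t44,0.006
L_major,morphological,t44,0.028
L_least,morphological,t11,0.037
L_least,morphological,t22,0.001
L_least,morphological,t33,0.006
L_least,morphological,t44,0.002
L_least,morphological,t55,0.013
compactness1,morphological,t0,0.038
compactness2,morphological,t0,0.038
sphdispr,morphological,t0,0.038
sphericity,morphological,t0,0.038
asphericity,morphological,t0,0.038
medianFD,fractal,t11,0.038
minFD,fractal,t22,0.013
glnu,textural,t0,0.027
glnu,textural,t11,0.038
glnu,textural,t22,0.001
glnu,textural,t33,0.013
glnu,textural,t44,0.003
glnu,textural,t55,0.038
sre,textural,t11,0.019
sre,textural,t22,0.019
sre,textural,t33,0.028
lre,textural,t11,0.019
lre,textural,t22,0.019
lre,textural,t33,0.038
hgre,textural,t22,0.038
hgre,textural,t44,0.013
hgre,textural,t55,0.009
srhge,textural,t22,0.038
srhge,textural,t44,0.013
srhge,textural,t55,0.009
lrhge,textural,t22,0.038
lrhge,textural,t44,0.013
lrhge,textural,t55,0.009
rlnu,textural,t22,0.028
rlnu,textural,t44,0.013
rlnu_norm,textural,t22,0.019
rlnu_norm,textural,t33,0.028
rperc,textural,t11,0.019
rperc,textural,t22,0.019
rperc,textural,t33,0.028
rlvar,textural,t22,0.019
rlvar,textural,t33,0.038
rlvar,textural,t44,0.018
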