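variable,group,pup,value
body_weight_g,FLT,1,54.1
body_weight_g,FLT,2,31.1
body_weight_g,FLT,3,24.5
body_weight_g,FLT,4,32.7
body_weight_g,FLT,5,43.7
body_weight_g,FLT,6,53.9
body_weight_g,AGC,1,83.0
body_weight_g,AGC,2,78.8
body_weight_g,AGC,3,71.2
body_weight_g,AGC,4,71.4
body_weight_g,AGC,5,78.7
body_weight_g,AGC,6,81.9
body_weight_g,VIV,1,87.4
body_weight_g,VIV,2,80.3
body_weight_g,VIV,3,81.4
body_weight_g,VIV,4,88.8
body_weight_g,VIV,5,80.9
body_weight_g,VIV,6,78.9
aorta_weight_per_cm2_mg,FLT,1,14.2
aorta_weight_per_cm2_mg,FLT,2,16.0
aorta_weight_per_cm2_mg,FLT,3,13.9
aorta_weight_per_cm2_mg,FLT,4,16.4
aorta_weight_per_cm2_mg,FLT,5,13.6
aorta_weight_per_cm2_mg,FLT,6,10.9
aorta_weight_per_cm2_mg,AGC,1,17.1
aorta_weight_per_cm2_mg,AGC,2,16.5
aorta_weight_per_cm2_mg,AGC,3,23.3
aorta_weight_per_cm2_mg,AGC,4,24.1
aorta_weight_per_cm2_mg,AGC,5,22.4
aorta_weight_per_cm2_mg,AGC,6,16.4
aorta_weight_per_cm2_mg,VIV,1,19.5
aorta_weight_per_cm2_mg,VIV,2,14.0
aorta_weight_per_cm2_mg,VIV,3,14.3
aorta_weight_per_cm2_mg,VIV,4,26.4
aorta_weight_per_cm2_mg,VIV,5,24.9
aorta_weight_per_cm2_mg,VIV,6,20.0
cross_section_mm2,FLT,1,0.51
cross_section_mm2,FLT,2,0.46
cross_section_mm2,FLT,3,0.40
cross_section_mm2,FLT,4,0.51
cross_section_mm2,FLT,5,0.46
cross_section_mm2,FLT,6,0.37
cross_section_mm2,AGC,1,0.69
cross_section_mm2,AGC,2,0.65
cross_section_mm2,AGC,3,0.84
cross_section_mm2,AGC,4,0.93
cross_section_mm2,AGC,5,0.88
cross_section_mm2,AGC,6,0.68
cross_section_mm2,VIV,1,0.69
cross_section_mm2,VIV,2,0.58
cross_section_mm2,VIV,3,0.57
cross_section_mm2,VIV,4,1.12
cross_section_mm2,VIV,5,0.91
cross_section_mm2,VIV,6,0.74
internal_diameter_mm,FLT,1,1.20
internal_diameter_mm,FLT,2,0.97
internal_diameter_mm,FLT,3,0.97
internal_diameter_mm,FLT,4,1.05
internal_diameter_mm,FLT,5,1.13
internal_diameter_mm,FLT,6,1.17
internal_diameter_mm,AGC,1,1.37
internal_diameter_mm,AGC,2,1.33
internal_diameter_mm,AGC,3,1.22
internal_diameter_mm,AGC,4,1.30
internal_diameter_mm,AGC,5,1.32
internal_diameter_mm,AGC,6,1.38
internal_diameter_mm,VIV,1,1.19
internal_diameter_mm,VIV,2,1.39
internal_diameter_mm,VIV,3,1.35
internal_diameter_mm,VIV,4,1.43
internal_diameter_mm,VIV,5,1.24
internal_diameter_mm,VIV,6,1.26
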