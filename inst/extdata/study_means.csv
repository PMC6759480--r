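treatment_id,replicate,time_h,acetic_mM,propionic_mM,butyric_mM,valeric_mM,isobutyric_mM,methylbutyric2_mM,isovaleric_mM,lactic_mM,total_bcvfa_mM,total_vfa_mM,nh3_mM,gas_mL,bacteria_copies_per_mL
Control,1,4,17.0,5.88,1.90,0.16,,,,5.16,0.34,25.3,,,
SBM_low,1,4,17.2,5.89,1.90,0.18,,,,5.23,0.35,25.5,,,
WHEY_low,1,4,17.2,5.94,1.92,0.15,,,,5.15,0.36,25.6,,,
YMP_low,1,4,17.2,5.94,1.93,0.16,,,,5.33,0.35,25.6,,,
SBM_med,1,4,18.1,6.06,1.93,0.15,,,,6.55,0.36,26.6,,,
WHEY_med,1,4,17.3,5.92,1.91,0.16,,,,5.37,0.41,25.7,,,
YMP_med,1,4,17.5,5.94,1.98,0.16,,,,6.29,0.37,26.0,,,
SBM_high,1,4,19.2,6.06,1.93,0.17,,,,9.46,0.43,27.8,,,
WHEY_high,1,4,17.6,6.03,1.94,0.16,,,,5.57,0.41,26.1,,,
YMP_high,1,4,18.9,5.97,2.18,0.17,,,,9.98,0.41,27.6,,,
Control,1,10,35.8,21.6,6.35,0.61,,,,0.14,0.35,64.8,,,
SBM_low,1,10,36.6,22.2,6.54,0.69,,,,0.15,0.39,66.4,,,
WHEY_low,1,10,35.7,21.5,6.39,0.63,,,,0.13,0.46,64.7,,,
YMP_low,1,10,36.7,22.3,6.54,0.67,,,,0.14,0.36,66.5,,,
SBM_med,1,10,38.9,24.3,6.67,0.68,,,,0.14,0.39,70.9,,,
WHEY_med,1,10,37.4,23.3,6.80,0.74,,,,0.17,0.68,68.9,,,
YMP_med,1,10,38.0,23.6,7.10,0.76,,,,0.16,0.37,69.9,,,
SBM_high,1,10,44.8,31.0,7.53,0.85,,,,0.18,0.34,84.5,,,
WHEY_high,1,10,37.2,24.1,7.14,0.80,,,,0.16,1.01,70.2,,,
YMP_high,1,10,42.9,30.8,8.76,1.28,,,,0.31,0.35,84.1,,,
Control,1,24,56.3,26.7,8.81,3.13,,,,0.08,1.25,96.2,,,
SBM_low,1,24,55.8,27.1,8.89,3.15,,,,0.06,1.34,96.3,,,
WHEY_low,1,24,56.2,27.2,8.86,3.28,,,,0.08,1.49,97.0,,,
YMP_low,1,24,56.2,26.8,9.02,3.22,,,,0.06,1.31,96.6,,,
SBM_med,1,24,59.7,30.3,9.59,3.58,,,,0.08,1.89,105,,,
WHEY_med,1,24,58.0,29.2,9.66,3.86,,,,0.06,2.70,103,,,
YMP_med,1,24,59.3,30.3,10.1,3.72,,,,0.06,1.61,105,,,
SBM_high,1,24,69.6,39.9,12.1,4.84,,,,0.11,3.76,130,,,
WHEY_high,1,24,61.6,32.4,11.5,5.46,,,,0.05,6.05,117,,,
YMP_high,1,24,67.5,40.4,12.8,4.90,,,,0.07,1.86,127,,,
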