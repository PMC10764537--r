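plot,mfac_km,pred_minus_obs_2019_m,pred_minus_obs_2020_m
GA,3.47,-0.02,-0.02
GB,6.71,0.00,0.01
GC,1.17,-0.03,-0.03
GD,5.09,0.02,0.02
GE,3.79,-0.05,-0.01
GF,1.07,-0.02,-0.06
GG,3.92,NA,-0.05
LA,4.96,0.05,0.04
LC,0.4,-0.04,-0.08
LD,3.38,-0.03,-0.02
LF,1.21,-0.01,0.01
LG,4.6,NA,0.00
CA,0.63,0.04,NA
CB,1.61,-0.04,NA
CC,1.71,-0.06,NA
CD,2.51,0.00,NA
F1,10.08,0.03,0.08
F2,0.36,0.17,0.14
F3,0.84,-0.09,-0.10
F4,0.46,-0.02,0.06
F5,6.23,-0.02,-0.02
F6,4.54,0.03,0.00
F7,4.85,0.05,0.05
F8,0.23,0.13,0.10
F9,0.8,-0.04,-0.03
F10,2.11,0.01,-0.01
F11,1.55,-0.07,-0.07
F12,3.08,0.08,0.05
F13,0.96,-0.04,-0.05
F14,4.85,0.08,0.07
F15,4.43,-0.02,-0.07
F16,8.63,0.07,0.05
F17,0.88,-0.01,0.06
F18,4.56,0.04,0.02
F19,8.25,-0.02,-0.02
F20,1.24,-0.06,-0.03
F21,2.57,-0.07,-0.08
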