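well_id,site,mfac_km,median_2019_m,median_2020_m,d90_2019_m,d90_2020_m,fluct_2019_m,fluct_2020_m,hgrad_min,hgrad_max,vgrad_min,vgrad_max
GA,Garron,3.47,-0.08,-0.09,-0.13,-0.2,0.15,0.26,0.028,0.054,0.310,0.438
GB,Garron,6.71,-0.06,-0.07,-0.1,-0.18,0.12,0.21,0.027,0.029,0.002,0.774
GC,Garron,1.17,-0.11,-0.14,-0.2,-0.28,0.17,0.25,0.158,0.176,NA,NA
GD,Garron,5.09,-0.05,-0.1,-0.15,-0.21,0.2,0.26,0.015,0.018,0.066,0.171
GE,Garron,3.79,-0.03,-0.04,-0.1,-0.2,0.17,0.24,0.012,0.026,0.019,0.368
GF,Garron,1.07,-0.1,-0.15,-0.22,-0.25,0.21,0.26,0.126,0.142,NA,NA
GG,Garron,3.92,NA,-0.09,NA,-0.16,NA,0.16,0.022,0.060,-0.010,0.313
LA,Letterunshin,4.96,-0.06,-0.08,-0.17,-0.23,0.22,0.3,0.008,0.016,-0.010,0.263
LC,Letterunshin,0.4,-0.08,-0.11,-0.27,-0.31,0.34,0.36,0.095,0.096,NA,NA
LD,Letterunshin,3.38,-0.02,-0.05,-0.12,-0.2,0.21,0.26,0.012,0.019,0.050,0.153
LF,Letterunshin,1.21,-0.13,-0.17,-0.22,-0.31,0.18,0.32,0.039,0.042,0.048,0.153
LG,Letterunshin,4.6,NA,-0.07,NA,-0.2,NA,0.21,0.018,0.020,-0.005,0.044
CA,Cuilcagh,0.63,-0.15,NA,-0.32,NA,0.35,NA,0.089,0.132,NA,NA
CB,Cuilcagh,1.61,-0.07,NA,-0.17,NA,0.23,NA,0.029,0.058,NA,NA
CC,Cuilcagh,1.71,-0.07,NA,-0.14,NA,0.2,NA,0.045,0.061,NA,NA
CD,Cuilcagh,2.51,-0.08,NA,-0.18,NA,0.2,NA,0.022,0.028,NA,NA
F1,Fiddandarry,10.08,-0.05,-0.06,-0.1,-0.21,0.21,0.35,NA,NA,0.273,0.427
F2,Fiddandarry,0.36,-0.2,-0.21,-0.49,-0.54,0.57,0.61,NA,NA,NA,NA
F3,Fiddandarry,0.84,-0.08,-0.08,-0.17,-0.23,0.17,0.27,NA,NA,NA,NA
F4,Fiddandarry,0.46,-0.09,-0.17,-0.29,-0.44,0.32,0.48,NA,NA,NA,NA
F5,Fiddandarry,6.23,-0.02,-0.07,-0.09,-0.15,0.15,0.19,NA,NA,0.000,0.047
F6,Fiddandarry,4.54,-0.05,-0.05,-0.16,-0.2,0.21,0.26,NA,NA,NA,NA
F7,Fiddandarry,4.85,-0.05,-0.1,-0.18,-0.24,0.23,0.31,NA,NA,0.000,0.186
F8,Fiddandarry,0.23,-0.36,-0.28,-0.49,-0.53,0.51,0.57,NA,NA,NA,NA
F9,Fiddandarry,0.8,-0.07,-0.11,-0.22,-0.3,0.29,0.38,NA,NA,NA,NA
F10,Fiddandarry,2.11,-0.11,-0.14,-0.2,-0.25,0.2,0.27,NA,NA,0.006,0.043
F11,Fiddandarry,1.55,-0.05,-0.08,-0.14,-0.21,0.17,0.29,NA,NA,NA,NA
F12,Fiddandarry,3.08,-0.13,-0.16,-0.24,-0.28,0.3,0.33,NA,NA,0.033,0.187
F13,Fiddandarry,0.96,-0.12,-0.14,-0.21,-0.27,0.22,0.32,NA,NA,NA,NA
F14,Fiddandarry,4.85,-0.09,-0.1,-0.21,-0.26,0.22,0.31,NA,NA,0.000,0.067
F15,Fiddandarry,4.43,-0.06,-0.05,-0.12,-0.13,0.2,0.23,NA,NA,0.016,0.105
F16,Fiddandarry,8.63,-0.08,-0.11,-0.16,-0.2,0.2,0.23,NA,NA,NA,NA
F17,Fiddandarry,0.88,-0.12,-0.17,-0.25,-0.39,0.29,0.43,NA,NA,NA,NA
F18,Fiddandarry,4.56,-0.07,-0.11,-0.17,-0.22,0.2,0.28,NA,NA,0.000,0.074
F19,Fiddandarry,8.25,-0.01,-0.04,-0.07,-0.13,0.11,0.16,NA,NA,-0.010,0.195
F20,Fiddandarry,1.24,-0.07,-0.11,-0.17,-0.27,0.22,0.33,NA,NA,NA,NA
F21,Fiddandarry,2.57,0,-0.12,-0.11,-0.16,0.16,0.23,NA,NA,-0.012,0.047
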