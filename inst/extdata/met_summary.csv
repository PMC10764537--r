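site,year,variable,summer,winter,annual,prop_summer_pct,prop_winter_pct
Garron,2019,precip_mm,564.6,703.5,1268.1,45,55
Garron,2019,pe_mm,393.8,108.6,502.4,78,22
Garron,2019,rain_days,93,103,196,47,53
Garron,2019,wet_days,51,48,99,52,48
Garron,2020,precip_mm,545.0,757.6,1302.6,42,58
Garron,2020,pe_mm,405.0,98.6,503.6,80,20
Garron,2020,rain_days,80,116,196,41,59
Garron,2020,wet_days,39,60,99,39,61
Letterunshin,2019,precip_mm,718.9,808.0,1526.9,47,53
Letterunshin,2019,pe_mm,471.8,127.3,599.1,79,21
Letterunshin,2019,rain_days,107,117,224,48,52
Letterunshin,2019,wet_days,54,64,118,46,54
Letterunshin,2020,precip_mm,511.3,1159.5,1670.8,31,69
Letterunshin,2020,pe_mm,520.4,153.3,673.7,77,23
Letterunshin,2020,rain_days,89,136,225,40,60
Letterunshin,2020,wet_days,35,83,118,30,70
Fiddandarry,2019,precip_mm,718.9,783.6,1502.5,48,52
Fiddandarry,2019,rain_days,102,111,213,48,52
Fiddandarry,2019,wet_days,51,63,114,45,55
Fiddandarry,2020,precip_mm,523.4,1111.8,1635.2,32,68
Fiddandarry,2020,rain_days,86,131,217,40,60
Fiddandarry,2020,wet_days,33,76,109,30,70
Cuilcagh,2019,precip_mm,875.2,1359.8,2235,39,61
Cuilcagh,2019,rain_days,92,124,216,43,57
Cuilcagh,2019,wet_days,55,80,135,41,59
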