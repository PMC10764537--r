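class_km,lower_km,upper_km,predicted_d90_cm_band
0-0.5,0,0.5,>=30
0.5-1,0.5,1,25-30
1-2,1,2,20-25
2-5,2,5,13-20
>5,5,Inf,<13
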