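site,effective_rainfall_mm_yr,k_factor,stream_threshold_ha
Garron,1194,1.32,2.0
Cuilcagh,1586,1.75,1.5
Letterunshin,907,1,5.0
Fiddandarry,900,0.99,5.0
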