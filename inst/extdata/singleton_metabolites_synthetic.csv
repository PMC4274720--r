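metabolite,delta_h_ppm,delta_c_ppm,amplitude,lw_h_ppm,lw_c_ppm,long_range,selected
Glycine,3.56,42,1,0.03,0.5,0,1
Methanol,3.36,65.6,1,0.03,0.5,0,1
1-Methyluric acid,3.28,30.3,1,0.03,0.5,0,1
TMAO,3.26,62,1,0.03,0.5,0,1
Dimethylamine,2.72,35,1,0.03,0.5,0,1
Succinic acid,2.4,36.7,1,0.03,0.5,0,1
Acetic acid,1.92,20.5,1,0.03,0.5,0,1
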