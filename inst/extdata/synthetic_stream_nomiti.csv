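date,rflx_mg_m2_d,runf_L_m2_d,infl_L_m2_d,precip_mm
1984-05-07,2.1e-2,2.8,1.3,31.5
1984-05-08,0,0,1.3,2.1
1984-05-12,6.0e-3,0.9,1.3,12.4
1984-05-20,1.3e-2,1.6,1.3,19.9
1984-05-27,1.5e-3,0.4,1.3,6.2
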