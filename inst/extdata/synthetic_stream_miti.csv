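date,rflx_mg_m2_d,runf_L_m2_d,infl_L_m2_d,precip_mm
1984-05-07,9.0e-5,0.5,1.3,31.5
1984-05-08,0,0,1.3,2.1
1984-05-12,2.2e-5,0.1,1.3,12.4
1984-05-20,4.6e-5,0.2,1.3,19.9
1984-05-27,1.0e-6,0.03,1.3,6.2
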