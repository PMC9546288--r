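trial,area_ha,slope_pct,k,ls,p
2018,0.0072,9,0.12,1.05,1
2019,0.0054,9,0.12,0.90,1
2013-16,0.0072,16,0.12,2.25,1
2013-9,0.0072,9,0.12,1.05,1
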