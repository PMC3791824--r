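component,max_points,rule,age_lo,age_hi,lo,hi,source_field
added_sugar,10,cap,2,18,NA,10,added_sugar_pct
fat,2.5,range,2,3,30,40,total_fat_pct
fat,2.5,range,4,18,25,35,total_fat_pct
linoleic,2.5,range,2,18,5,10,linoleic_pct
linolenic,2.5,range,2,18,0.6,1.2,linolenic_pct
dha_epa,2.5,cap,2,18,NA,10,dha_epa_pct_of_ala
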