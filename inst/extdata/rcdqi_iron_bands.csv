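variant,age_lo,age_hi,ear_max,rda_min
table_b,2,3,3.0,7
table_b,4,8,4.1,10
table_b,9,13,5.7,8
table_b,14,18,7.9,15
table_c,2,3,3.0,7
table_c,4,8,4.1,10
table_c,9,13,5.9,8
table_c,14,18,7.7,11
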