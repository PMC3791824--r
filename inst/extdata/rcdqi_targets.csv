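variant,component,age_lo,age_hi,value,units
table_b,total_grains,2,3,3,oz equiv per day
table_b,total_grains,4,8,4,oz equiv per day
table_b,total_grains,9,13,6,oz equiv per day
table_b,total_grains,14,18,7,oz equiv per day
table_b,whole_grains,2,3,1.5,oz equiv per day
table_b,whole_grains,4,8,2,oz equiv per day
table_b,whole_grains,9,13,3,oz equiv per day
table_b,whole_grains,14,18,3.5,oz equiv per day
table_b,fruit,2,8,1.5,cup equiv per day
table_b,fruit,9,18,2,cup equiv per day
table_b,vegetable,2,3,1,cup equiv per day
table_b,vegetable,4,8,2,cup equiv per day
table_b,vegetable,9,13,3,cup equiv per day
table_b,vegetable,14,18,4,cup equiv per day
table_b,excess_juice,2,6,6,fl oz per day
table_b,excess_juice,7,18,12,fl oz per day
table_b,dairy,2,8,2,cup equiv per day
table_b,dairy,9,18,3,cup equiv per day
table_b,eer,2,2,1072,kcal per day
table_b,eer,3,3,1080,kcal per day
table_b,eer,4,4,1133,kcal per day
table_b,eer,5,5,1189,kcal per day
table_b,eer,6,6,1247,kcal per day
table_b,eer,7,7,1298,kcal per day
table_b,eer,8,8,1360,kcal per day
table_b,eer,9,9,1415,kcal per day
table_b,eer,10,10,1470,kcal per day
table_b,eer,11,11,1538,kcal per day
table_b,eer,12,12,1617,kcal per day
table_b,eer,13,13,1684,kcal per day
table_b,eer,14,14,1718,kcal per day
table_b,eer,15,15,1731,kcal per day
table_b,eer,16,16,1729,kcal per day
table_b,eer,17,17,1710,kcal per day
table_b,eer,18,18,1690,kcal per day
table_c,total_grains,2,3,3,oz equiv per day
table_c,total_grains,4,8,5,oz equiv per day
table_c,total_grains,9,13,7,oz equiv per day
table_c,total_grains,14,18,9,oz equiv per day
table_c,whole_grains,2,3,1.5,oz equiv per day
table_c,whole_grains,4,8,2.5,oz equiv per day
table_c,whole_grains,9,13,3.5,oz equiv per day
table_c,whole_grains,14,18,4.5,oz equiv per day
table_c,fruit,2,3,1.5,cup equiv per day
table_c,fruit,4,13,2,cup equiv per day
table_c,fruit,14,18,3,cup equiv per day
table_c,vegetable,2,3,1,cup equiv per day
table_c,vegetable,4,8,2,cup equiv per day
table_c,vegetable,9,18,4,cup equiv per day
table_c,excess_juice,2,6,6,fl oz per day
table_c,excess_juice,7,18,12,fl oz per day
table_c,dairy,2,8,2,cup equiv per day
table_c,dairy,9,18,3,cup equiv per day
table_c,eer,2,2,1120,kcal per day
table_c,eer,3,3,1162,kcal per day
table_c,eer,4,4,1215,kcal per day
table_c,eer,5,5,1275,kcal per day
table_c,eer,6,6,1328,kcal per day
table_c,eer,7,7,1393,kcal per day
table_c,eer,8,8,1453,kcal per day
table_c,eer,9,9,1530,kcal per day
table_c,eer,10,10,1601,kcal per day
table_c,eer,11,11,1691,kcal per day
table_c,eer,12,12,1798,kcal per day
table_c,eer,13,13,1935,kcal per day
table_c,eer,14,14,2090,kcal per day
table_c,eer,15,15,2223,kcal per day
table_c,eer,16,16,2320,kcal per day
table_c,eer,17,17,2366,kcal per day
table_c,eer,18,18,2383,kcal per day
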