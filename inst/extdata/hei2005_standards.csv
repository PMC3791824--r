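component,max_points,direction,basis,max_standard,min_standard,units,source_field
total_fruit,5,adequacy,density,0.8,0,cup equiv per 1000 kcal,total_fruit
whole_fruit,5,adequacy,density,0.4,0,cup equiv per 1000 kcal,whole_fruit
total_veg,5,adequacy,density,1.1,0,cup equiv per 1000 kcal,total_veg
dgo_veg_legumes,5,adequacy,density,0.4,0,cup equiv per 1000 kcal,dgo_veg_legumes
total_grains,5,adequacy,density,3.0,0,oz equiv per 1000 kcal,total_grains
whole_grains,5,adequacy,density,1.5,0,oz equiv per 1000 kcal,whole_grains
milk,10,adequacy,density,1.3,0,cup equiv per 1000 kcal,dairy
meat_beans,10,adequacy,density,2.5,0,oz equiv per 1000 kcal,meat_beans
oils,10,adequacy,density,12,0,grams per 1000 kcal,oils
sat_fat,10,moderation,pct_energy,7,15,% of energy,sat_fat_pct
sodium,10,moderation,density,0.7,2.0,grams per 1000 kcal,sodium
sofaas,20,moderation,pct_energy,20,50,% of energy,sofaas_pct
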