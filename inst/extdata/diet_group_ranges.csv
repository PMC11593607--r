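group,min_g_day,max_g_day
whole_grains,200,600
tubers,0,100
vegetables,200,600
fruits,100,300
dairy,0,500
animal_protein,0,211
other_protein,25,250
added_fats,20,91.8
added_sugars,0,31
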