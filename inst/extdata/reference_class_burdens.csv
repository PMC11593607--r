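diet,percentile,chem_class,burden_ug_day
omnivorous,p25,heavy_metal,230.9
omnivorous,p25,HAA,20.1
omnivorous,p25,mycotoxin,196.9
omnivorous,p25,pesticide,43.2
omnivorous,p25,PAH,4.11
omnivorous,p50,heavy_metal,389.7
omnivorous,p50,HAA,20.2
omnivorous,p50,mycotoxin,1122
omnivorous,p50,pesticide,61
omnivorous,p50,PAH,9.29
omnivorous,p75,heavy_metal,567.9
omnivorous,p75,HAA,23.6
omnivorous,p75,mycotoxin,5389
omnivorous,p75,pesticide,135.8
omnivorous,p75,PAH,34.76
vegetarian,p25,heavy_metal,243.1
vegetarian,p25,HAA,0.01
vegetarian,p25,mycotoxin,165.9
vegetarian,p25,pesticide,39.7
vegetarian,p25,PAH,2.6
vegetarian,p50,heavy_metal,393.6
vegetarian,p50,HAA,0.01
vegetarian,p50,mycotoxin,947
vegetarian,p50,pesticide,54.7
vegetarian,p50,PAH,3
vegetarian,p75,heavy_metal,544.4
vegetarian,p75,HAA,0.01
vegetarian,p75,mycotoxin,4447
vegetarian,p75,pesticide,120.5
vegetarian,p75,PAH,4.33
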