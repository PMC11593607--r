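food,origin,food_group,cereal
beef,animal,animal_protein,FALSE
egg,animal,animal_protein,FALSE
salmon,animal,animal_protein,FALSE
cheese,animal,dairy,FALSE
bread,plant,whole_grains,FALSE
pasta,plant,whole_grains,FALSE
rice,plant,whole_grains,TRUE
wheat,plant,whole_grains,TRUE
maize,plant,whole_grains,TRUE
potato,plant,tubers,FALSE
cabbage,plant,vegetables,FALSE
carrot,plant,vegetables,FALSE
apple,plant,fruits,FALSE
peanuts,plant,other_protein,FALSE
beans,plant,other_protein,FALSE
olive oil,plant,added_fats,FALSE
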