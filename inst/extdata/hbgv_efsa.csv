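contaminant,gtype,value,units,period,endpoint,moe_threshold
cadmium,TWI,2.5,ug,week,kidney toxicity,
mercury,TWI,4,ug,week,neurodevelopmental toxicity,
arsenic,BMDL05,0.06,ug,day,skin cancer,
lead,BMDL01,0.5,ug,day,developmental neurotoxicity,
lead,BMDL01,1.5,ug,day,systolic blood pressure,
lead,BMDL10,0.63,ug,day,nephrotoxicity,
acetamiprid,ADI,0.025,mg,day,chronic dietary,
cypermethrin,ADI,0.005,mg,day,chronic dietary,
deltamethrin,ADI,0.01,mg,day,chronic dietary,
chlorpyrifos,ADI,0.001,mg,day,chronic dietary,
methomyl,ADI,0.02,mg,day,chronic dietary,
propiconazole,ADI,0.07,mg,day,chronic dietary,
pyraclostrobin,ADI,0.03,mg,day,chronic dietary,
tebuconazole,ADI,0.03,mg,day,chronic dietary,
lambda-cyhalothrin,ADI,0.005,mg,day,chronic dietary,
deoxynivalenol,TDI,1,ug,day,chronic dietary,
fumonisin B1,TDI,0.1,ug,day,chronic dietary,
nivalenol,TDI,1.2,ug,day,chronic dietary,
T-2 toxin,TDI,0.1,ug,day,chronic dietary,
zearalenone,TDI,0.25,ug,day,chronic dietary,
ochratoxin A,BMDL10,4.73,ug,day,non-neoplastic kidney effects,200
ochratoxin A,BMDL10,14.5,ug,day,neoplastic kidney effects,10000
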