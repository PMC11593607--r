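contaminant,chem_class,abbrev
arsenic,heavy_metal,As
cadmium,heavy_metal,Cd
lead,heavy_metal,Pb
mercury,heavy_metal,Hg
naphthalene,PAH,Nap
acenaphthylene,PAH,Acy
acenaphthene,PAH,Ace
fluorene,PAH,F
phenanthrene,PAH,Phe
anthracene,PAH,Ant
fluoranthene,PAH,Fla
pyrene,PAH,P
benz[a]anthracene,PAH,B[a]A
chrysene,PAH,Chr
benzo[b]fluoranthene,PAH,B[b]F
benzo[k]fluoranthene,PAH,B[k]F
benzo[j]fluoranthene,PAH,B[j]F
benzo[a]pyrene,PAH,B[a]P
5-methylchrysene,PAH,5MC
"dibenz[a,h]anthracene",PAH,D[ah]A
"benzo[g,h,i]perylene",PAH,B[ghi]P
"indeno[1,2,3-cd]pyrene",PAH,IP
acetamiprid,pesticide,ACET
chlorpyrifos,pesticide,CPF
chlorpyrifos-methyl,pesticide,CPFm
cypermethrin,pesticide,CYP
deltamethrin,pesticide,DEL
lambda-cyhalothrin,pesticide,CYH
methomyl,pesticide,MTM
propiconazole,pesticide,PCZ
pyraclostrobin,pesticide,PYR
tebuconazole,pesticide,TEB
aflatoxin B1,mycotoxin,AFB1
alternariol,mycotoxin,AOH
alternariol methyl ether,mycotoxin,AME
beauvericin,mycotoxin,BEA
citrinin,mycotoxin,CIT
deoxynivalenol,mycotoxin,DON
enniatin A,mycotoxin,ENN A
enniatin A1,mycotoxin,ENN A1
enniatin B,mycotoxin,ENN B
enniatin B1,mycotoxin,ENN B1
ergotamine,mycotoxin,ETam
ergotaminine,mycotoxin,ETamn
ergokryptine,mycotoxin,EKry
ergokryptinine,mycotoxin,EKryn
ergonisine,mycotoxin,ENis
ergosine,mycotoxin,ESin
ergometrine,mycotoxin,EMet
ergocornine,mycotoxin,ECor
ergocristine,mycotoxin,ECri
fumonisin B1,mycotoxin,FB1
fusaric acid,mycotoxin,FA
HT-2 toxin,mycotoxin,HT2
moniliformin,mycotoxin,MON
nivalenol,mycotoxin,NIV
ochratoxin A,mycotoxin,OTA
sterigmatocystin,mycotoxin,STER
T-2 toxin,mycotoxin,T2
tenuazonic acid,mycotoxin,TeA
zearalenone,mycotoxin,ZEN
harman,HAA,H
norharman,HAA,NH
PhIP,HAA,PhIP
IQ,HAA,IQ
IQx,HAA,IQx
MeIQ,HAA,MeIQ
MeIQx,HAA,MeIQx
"4,8-DiMeIQx",HAA,"4,8dMQx"
"7,8-DiMeIQx",HAA,"7,8dMQx"
A-alpha-C,HAA,AaC
Trp-P-1,HAA,TrpP1
Trp-P-2,HAA,TrpP2
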