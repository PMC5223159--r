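gene_symbol,division,category
Col11a1,core_matrisome,collagen
Col11a2,core_matrisome,collagen
Col12a1,core_matrisome,collagen
Col14a1,core_matrisome,collagen
Col16a1,core_matrisome,collagen
Col18a1,core_matrisome,collagen
Col1a1,core_matrisome,collagen
Col1a2,core_matrisome,collagen
Col27a1,core_matrisome,collagen
Col28a1,core_matrisome,collagen
Col2a1,core_matrisome,collagen
Col3a1,core_matrisome,collagen
Col4a1,core_matrisome,collagen
Col4a2,core_matrisome,collagen
Col4a5,core_matrisome,collagen
Col5a1,core_matrisome,collagen
Col5a2,core_matrisome,collagen
Col5a3,core_matrisome,collagen
Col6a1,core_matrisome,collagen
Col6a2,core_matrisome,collagen
Col6a3,core_matrisome,collagen
Col6a5,core_matrisome,collagen
Col6a6,core_matrisome,collagen
Col7a1,core_matrisome,collagen
Col8a1,core_matrisome,collagen
Creld2,core_matrisome,ecm_glycoprotein
Dmbt1,core_matrisome,ecm_glycoprotein
Dpt,core_matrisome,ecm_glycoprotein
Ecm1,core_matrisome,ecm_glycoprotein
Efemp1,core_matrisome,ecm_glycoprotein
Eln,core_matrisome,ecm_glycoprotein
Emilin1,core_matrisome,ecm_glycoprotein
Fbln5,core_matrisome,ecm_glycoprotein
Fbn1,core_matrisome,ecm_glycoprotein
Fbn2,core_matrisome,ecm_glycoprotein
Fga,core_matrisome,ecm_glycoprotein
Fgb,core_matrisome,ecm_glycoprotein
Fgg,core_matrisome,ecm_glycoprotein
Fn1,core_matrisome,ecm_glycoprotein
Hmcn1,core_matrisome,ecm_glycoprotein
Lama1,core_matrisome,ecm_glycoprotein
Lama2,core_matrisome,ecm_glycoprotein
Lama3,core_matrisome,ecm_glycoprotein
Lama4,core_matrisome,ecm_glycoprotein
Lama5,core_matrisome,ecm_glycoprotein
Lamb1,core_matrisome,ecm_glycoprotein
Lamb2,core_matrisome,ecm_glycoprotein
Lamc1,core_matrisome,ecm_glycoprotein
Nid1,core_matrisome,ecm_glycoprotein
Nid2,core_matrisome,ecm_glycoprotein
Postn,core_matrisome,ecm_glycoprotein
Slit2,core_matrisome,ecm_glycoprotein
Sspo,core_matrisome,ecm_glycoprotein
Tgfbi,core_matrisome,ecm_glycoprotein
Thbs1,core_matrisome,ecm_glycoprotein
Tinagl1,core_matrisome,ecm_glycoprotein
Tnc,core_matrisome,ecm_glycoprotein
Vtn,core_matrisome,ecm_glycoprotein
Vwa1,core_matrisome,ecm_glycoprotein
Vwa5a,core_matrisome,ecm_glycoprotein
Vwf,core_matrisome,ecm_glycoprotein
Aspn,core_matrisome,proteoglycan
Bgn,core_matrisome,proteoglycan
Dcn,core_matrisome,proteoglycan
Hspg2,core_matrisome,proteoglycan
Lum,core_matrisome,proteoglycan
Ogn,core_matrisome,proteoglycan
Prelp,core_matrisome,proteoglycan
Prg2,core_matrisome,proteoglycan
Spock2,core_matrisome,proteoglycan
Anxa1,matrisome_associated,ecm_affiliated
Anxa11,matrisome_associated,ecm_affiliated
Anxa2,matrisome_associated,ecm_affiliated
Anxa3,matrisome_associated,ecm_affiliated
Anxa4,matrisome_associated,ecm_affiliated
Anxa5,matrisome_associated,ecm_affiliated
Anxa6,matrisome_associated,ecm_affiliated
Anxa7,matrisome_associated,ecm_affiliated
Lgals1,matrisome_associated,ecm_affiliated
Lman1,matrisome_associated,ecm_affiliated
Reg1,matrisome_associated,ecm_affiliated
Reg2,matrisome_associated,ecm_affiliated
Reg3b,matrisome_associated,ecm_affiliated
Reg3g,matrisome_associated,ecm_affiliated
Cela1,matrisome_associated,ecm_regulator
Cela2a,matrisome_associated,ecm_regulator
Cela3b,matrisome_associated,ecm_regulator
Cst3,matrisome_associated,ecm_regulator
Cstb,matrisome_associated,ecm_regulator
Ctsb,matrisome_associated,ecm_regulator
Ctsd,matrisome_associated,ecm_regulator
Ctsl,matrisome_associated,ecm_regulator
F13a1,matrisome_associated,ecm_regulator
F2,matrisome_associated,ecm_regulator
Gm5771,matrisome_associated,ecm_regulator
Itih4,matrisome_associated,ecm_regulator
Kng1,matrisome_associated,ecm_regulator
Kng2,matrisome_associated,ecm_regulator
Ngly1,matrisome_associated,ecm_regulator
Plg,matrisome_associated,ecm_regulator
Prss1,matrisome_associated,ecm_regulator
Prss2,matrisome_associated,ecm_regulator
Prss3,matrisome_associated,ecm_regulator
Pzp,matrisome_associated,ecm_regulator
Serpina3k,matrisome_associated,ecm_regulator
Serpinb1a,matrisome_associated,ecm_regulator
Serpinf2,matrisome_associated,ecm_regulator
Serpinh1,matrisome_associated,ecm_regulator
Serpini2,matrisome_associated,ecm_regulator
Tgm2,matrisome_associated,ecm_regulator
Try10,matrisome_associated,ecm_regulator
Try4,matrisome_associated,ecm_regulator
Hcfc1,matrisome_associated,secreted_factor
Ins1,matrisome_associated,secreted_factor
Ins2,matrisome_associated,secreted_factor
S100a10,matrisome_associated,secreted_factor
S100a11,matrisome_associated,secreted_factor
S100a6,matrisome_associated,secreted_factor
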