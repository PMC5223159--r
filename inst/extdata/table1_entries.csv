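entry_id,gene_symbol,category
T1_001,Dmbt1,ecm_glycoprotein
T1_002,Dpt,ecm_glycoprotein
T1_003,Ecm1,ecm_glycoprotein
T1_004,Efemp1,ecm_glycoprotein
T1_005,Eln,ecm_glycoprotein
T1_006,Emilin1,ecm_glycoprotein
T1_007,Fbln5,ecm_glycoprotein
T1_008,Fbn1,ecm_glycoprotein
T1_009,Fbn1,ecm_glycoprotein
T1_010,Fbn2,ecm_glycoprotein
T1_011,Fga,ecm_glycoprotein
T1_012,Fgb,ecm_glycoprotein
T1_013,Fgg,ecm_glycoprotein
T1_014,Fn1,ecm_glycoprotein
T1_015,Hmcn1,ecm_glycoprotein
T1_016,Lama1,ecm_glycoprotein
T1_017,Lama2,ecm_glycoprotein
T1_018,Lama3,ecm_glycoprotein
T1_019,Lama4,ecm_glycoprotein
T1_020,Lama5,ecm_glycoprotein
T1_021,Lamb1,ecm_glycoprotein
T1_022,Lamb2,ecm_glycoprotein
T1_023,Lamc1,ecm_glycoprotein
T1_024,Lamc1,ecm_glycoprotein
T1_025,Nid1,ecm_glycoprotein
T1_026,Nid2,ecm_glycoprotein
T1_027,Postn,ecm_glycoprotein
T1_028,Tgfbi,ecm_glycoprotein
T1_029,Thbs1,ecm_glycoprotein
T1_030,Tinagl1,ecm_glycoprotein
T1_031,Tnc,ecm_glycoprotein
T1_032,Vtn,ecm_glycoprotein
T1_033,Vwa1,ecm_glycoprotein
T1_034,Vwa5a,ecm_glycoprotein
T1_035,Vwf,ecm_glycoprotein
T1_036,Col1a1,collagen
T1_037,Col1a1,collagen
T1_038,Col1a2,collagen
T1_039,Col2a1,collagen
T1_040,Col3a1,collagen
T1_041,Col4a1,collagen
T1_042,Col4a2,collagen
T1_043,Col4a5,collagen
T1_044,Col5a1,collagen
T1_045,Col5a2,collagen
T1_046,Col5a3,collagen
T1_047,Col6a1,collagen
T1_048,Col6a2,collagen
T1_049,Col6a3,collagen
T1_050,Col6a3,collagen
T1_051,Col6a5,collagen
T1_052,Col6a6,collagen
T1_053,Col7a1,collagen
T1_054,Col8a1,collagen
T1_055,Col11a1,collagen
T1_056,Col11a2,collagen
T1_057,Col12a1,collagen
T1_058,Col12a1,collagen
T1_059,Col14a1,collagen
T1_060,Col16a1,collagen
T1_061,Col18a1,collagen
T1_062,Col27a1,collagen
T1_063,Col28a1,collagen
T1_064,Aspn,proteoglycan
T1_065,Bgn,proteoglycan
T1_066,Dcn,proteoglycan
T1_067,Hspg2,proteoglycan
T1_068,Lum,proteoglycan
T1_069,Ogn,proteoglycan
T1_070,Prelp,proteoglycan
T1_071,Prg2,proteoglycan
T1_072,Cela1,ecm_regulator
T1_073,Cela2a,ecm_regulator
T1_074,Cela3b,ecm_regulator
T1_075,Cst3,ecm_regulator
T1_076,Cstb,ecm_regulator
T1_077,Ctsb,ecm_regulator
T1_078,Ctsd,ecm_regulator
T1_079,Ctsl,ecm_regulator
T1_080,F13a1,ecm_regulator
T1_081,F2,ecm_regulator
T1_082,Gm5771,ecm_regulator
T1_083,Itih4,ecm_regulator
T1_084,Kng1,ecm_regulator
T1_085,Kng2,ecm_regulator
T1_086,Ngly1,ecm_regulator
T1_087,Plg,ecm_regulator
T1_088,Prss1,ecm_regulator
T1_089,Prss2,ecm_regulator
T1_090,Prss3,ecm_regulator
T1_091,Pzp,ecm_regulator
T1_092,Serpina3k,ecm_regulator
T1_093,Serpinb1a,ecm_regulator
T1_094,Serpinf2,ecm_regulator
T1_095,Serpinh1,ecm_regulator
T1_096,Serpini2,ecm_regulator
T1_097,Tgm2,ecm_regulator
T1_098,Try10,ecm_regulator
T1_099,Try4,ecm_regulator
T1_100,Anxa1,ecm_affiliated
T1_101,Anxa2,ecm_affiliated
T1_102,Anxa3,ecm_affiliated
T1_103,Anxa4,ecm_affiliated
T1_104,Anxa5,ecm_affiliated
T1_105,Anxa6,ecm_affiliated
T1_106,Anxa6,ecm_affiliated
T1_107,Anxa7,ecm_affiliated
T1_108,Anxa11,ecm_affiliated
T1_109,Lgals1,ecm_affiliated
T1_110,Lman1,ecm_affiliated
T1_111,Reg1,ecm_affiliated
T1_112,Reg2,ecm_affiliated
T1_113,Reg3b,ecm_affiliated
T1_114,Reg3g,ecm_affiliated
T1_115,Hcfc1,secreted_factor
T1_116,Ins1,secreted_factor
T1_117,Ins2,secreted_factor
T1_118,S100a10,secreted_factor
T1_119,S100a11,secreted_factor
T1_120,S100a6,secreted_factor
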