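factor_name	compartment	baits	literature_flag
Srp9	ER	scer|Y_SRP9;atha|AT_SRP9	confirmed
Srp14	ER	scer|Y_SRP14;atha|AT_SRP14	confirmed
Srp21	ER	scer|Y_SRP21;atha|AT_SRP21	confirmed
Srp54	ER	scer|Y_SRP54;atha|AT_SRP54	confirmed
Srp68	ER	scer|Y_SRP68;atha|AT_SRP68	confirmed
Srp72	ER	scer|Y_SRP72;atha|AT_SRP72	confirmed
Sec65	ER	scer|Y_SEC65;atha|AT_SEC65	confirmed
Srp101	ER	scer|Y_SRP101;atha|AT_SRP101	confirmed
Srp102	ER	scer|Y_SRP102;atha|AT_SRP102	confirmed
Sec61	ER	scer|Y_SEC61;atha|AT_SEC61	confirmed
Sbh1	ER	scer|Y_SBH1;atha|AT_SBH1	confirmed
Sbh2	ER	scer|Y_SBH2;atha|AT_SBH2	confirmed
Sss1	ER	scer|Y_SSS1;atha|AT_SSS1	confirmed
Ssh1	ER	scer|Y_SSH1;atha|AT_SSH1	confirmed
Sec62	ER	scer|Y_SEC62;atha|AT_SEC62	confirmed
Sec63	ER	scer|Y_SEC63;atha|AT_SEC63	confirmed
Sec71	ER	scer|Y_SEC71;atha|AT_SEC71	confirmed
Sec72	ER	scer|Y_SEC72;atha|AT_SEC72	confirmed
Kar2	ER	scer|Y_KAR2;atha|AT_KAR2	confirmed
TPR7	ER	atha|AT_TPR7	confirmed
Sgt2	ER	scer|Y_SGT2;atha|AT_SGT2	confirmed
Get1	ER	scer|Y_GET1;atha|AT_GET1	confirmed
Get2	ER	scer|Y_GET2;atha|AT_GET2	confirmed
Get3	ER	scer|Y_GET3;atha|AT_GET3	confirmed
Get4	ER	scer|Y_GET4;atha|AT_GET4	confirmed
Get5	ER	scer|Y_GET5;atha|AT_GET5	confirmed
Doa10	ERAD	scer|Y_DOA10;atha|AT_DOA10	confirmed
Ubc6	ERAD	scer|Y_UBC6;atha|AT_UBC6	confirmed
Ubc7	ERAD	scer|Y_UBC7;atha|AT_UBC7	confirmed
Cue1	ERAD	scer|Y_CUE1;atha|AT_CUE1	confirmed
Hrd1	ERAD	scer|Y_HRD1;atha|AT_HRD1	confirmed
Hrd3	ERAD	scer|Y_HRD3;atha|AT_HRD3	confirmed
Der1	ERAD	scer|Y_DER1;atha|AT_DER1	confirmed
Dfm1	ERAD	scer|Y_DFM1;atha|AT_DFM1	confirmed
Usa1	ERAD	scer|Y_USA1;atha|AT_USA1	confirmed
Cdc48	ERAD	scer|Y_CDC48;atha|AT_CDC48	confirmed
Npl4	ERAD	scer|Y_NPL4;atha|AT_NPL4	confirmed
Ufd1	ERAD	scer|Y_UFD1;atha|AT_UFD1	confirmed
Ubx2	ERAD	scer|Y_UBX2;atha|AT_UBX2	confirmed
Pex1	Peroxisome	scer|Y_PEX1;atha|AT_PEX1	confirmed
Pex2	Peroxisome	scer|Y_PEX2;atha|AT_PEX2	confirmed
Pex3	Peroxisome	scer|Y_PEX3;atha|AT_PEX3	confirmed
Pex4	Peroxisome	scer|Y_PEX4;atha|AT_PEX4	confirmed
Pex5	Peroxisome	scer|Y_PEX5;atha|AT_PEX5	confirmed
Pex6	Peroxisome	scer|Y_PEX6;atha|AT_PEX6	confirmed
Pex7	Peroxisome	scer|Y_PEX7;atha|AT_PEX7	confirmed
Pex10	Peroxisome	scer|Y_PEX10;atha|AT_PEX10	confirmed
Pex12	Peroxisome	scer|Y_PEX12;atha|AT_PEX12	confirmed
Pex13	Peroxisome	scer|Y_PEX13;atha|AT_PEX13	confirmed
Pex14	Peroxisome	scer|Y_PEX14;atha|AT_PEX14	confirmed
Pex15	Peroxisome	scer|Y_PEX15;atha|AT_PEX15	confirmed
Pex17	Peroxisome	scer|Y_PEX17;atha|AT_PEX17	confirmed
Pex18	Peroxisome	scer|Y_PEX18;atha|AT_PEX18	confirmed
Pex19	Peroxisome	scer|Y_PEX19;atha|AT_PEX19	confirmed
Pex21	Peroxisome	scer|Y_PEX21;atha|AT_PEX21	confirmed
Pex22	Peroxisome	scer|Y_PEX22;atha|AT_PEX22	confirmed
Ubc4	Peroxisome	scer|Y_UBC4;atha|AT_UBC4	confirmed
Ubc5	Peroxisome	scer|Y_UBC5;atha|AT_UBC5	confirmed
PMP22	Peroxisome	atha|AT_PMP22	confirmed
Tom20	Mitochondrion	scer|Y_TOM20;atha|AT_TOM20	confirmed
Tom22	Mitochondrion	scer|Y_TOM22;atha|AT_TOM22	confirmed
Tom40	Mitochondrion	scer|Y_TOM40;atha|AT_TOM40	confirmed
Tom5	Mitochondrion	scer|Y_TOM5;atha|AT_TOM5	confirmed
Tom6	Mitochondrion	scer|Y_TOM6;atha|AT_TOM6	confirmed
Tom7	Mitochondrion	scer|Y_TOM7;atha|AT_TOM7	confirmed
Tom70	Mitochondrion	scer|Y_TOM70;atha|AT_TOM70	confirmed
OM64	Mitochondrion	atha|AT_OM64	confirmed
Tim50	Mitochondrion	scer|Y_TIM50;atha|AT_TIM50	confirmed
Tim23	Mitochondrion	scer|Y_TIM23;atha|AT_TIM23	confirmed
Tim21	Mitochondrion	scer|Y_TIM21;atha|AT_TIM21	confirmed
Tim17	Mitochondrion	scer|Y_TIM17;atha|AT_TIM17	confirmed
Tim44	Mitochondrion	scer|Y_TIM44;atha|AT_TIM44	confirmed
Pam16	Mitochondrion	scer|Y_PAM16;atha|AT_PAM16	confirmed
Pam17	Mitochondrion	scer|Y_PAM17;atha|AT_PAM17	confirmed
Pam18	Mitochondrion	scer|Y_PAM18;atha|AT_PAM18	confirmed
Mdj2	Mitochondrion	scer|Y_MDJ2;atha|AT_MDJ2	confirmed
mtHsp70	Mitochondrion	scer|Y_MTHSP70;atha|AT_MTHSP70	confirmed
Tim54	Mitochondrion	scer|Y_TIM54;atha|AT_TIM54	confirmed
Tim22	Mitochondrion	scer|Y_TIM22;atha|AT_TIM22	confirmed
Tim18	Mitochondrion	scer|Y_TIM18;atha|AT_TIM18	confirmed
Tim12	Mitochondrion	scer|Y_TIM12;atha|AT_TIM12	confirmed
Tim9	Mitochondrion	scer|Y_TIM9;atha|AT_TIM9	confirmed
Tim10	Mitochondrion	scer|Y_TIM10;atha|AT_TIM10	confirmed
Tim8	Mitochondrion	scer|Y_TIM8;atha|AT_TIM8	confirmed
Tim13	Mitochondrion	scer|Y_TIM13;atha|AT_TIM13	confirmed
Oxa1	Mitochondrion	scer|Y_OXA1;atha|AT_OXA1	confirmed
Mia40	Mitochondrion	scer|Y_MIA40;atha|AT_MIA40	confirmed
Erv1	Mitochondrion	scer|Y_ERV1;atha|AT_ERV1	confirmed
Hot13	Mitochondrion	scer|Y_HOT13;atha|AT_HOT13	confirmed
Sam50	Mitochondrion	scer|Y_SAM50;atha|AT_SAM50	confirmed
Sam35	Mitochondrion	scer|Y_SAM35;atha|AT_SAM35	confirmed
Sam37	Mitochondrion	scer|Y_SAM37;atha|AT_SAM37	confirmed
Metaxin	Mitochondrion	atha|AT_METAXIN	confirmed
Mdm10	Mitochondrion	scer|Y_MDM10;atha|AT_MDM10	confirmed
Mim1	Mitochondrion	scer|Y_MIM1;atha|AT_MIM1	confirmed
Toc159	Chloroplast	atha|AT_TOC159	confirmed
Toc132	Chloroplast	atha|AT_TOC132	confirmed
Toc120	Chloroplast	atha|AT_TOC120	confirmed
Toc90	Chloroplast	atha|AT_TOC90	confirmed
Toc33	Chloroplast	atha|AT_TOC33	confirmed
Toc34	Chloroplast	atha|AT_TOC34	confirmed
Toc64	Chloroplast	atha|AT_TOC64	confirmed
Toc75-III	Chloroplast	atha|AT_TOC75III	confirmed
Toc75-IV	Chloroplast	atha|AT_TOC75IV	confirmed
Toc12	Chloroplast	atha|AT_TOC12	confirmed
imsHsp70	Chloroplast	atha|AT_IMSHSP70	confirmed
Tic22	Chloroplast	atha|AT_TIC22	confirmed
Tic110	Chloroplast	atha|AT_TIC110	confirmed
Tic62	Chloroplast	atha|AT_TIC62	confirmed
Tic55	Chloroplast	atha|AT_TIC55	confirmed
Tic40	Chloroplast	atha|AT_TIC40	confirmed
Tic32	Chloroplast	atha|AT_TIC32	confirmed
Tic21	Chloroplast	atha|AT_TIC21	confirmed
Tic20-I	Chloroplast	atha|AT_TIC20I	confirmed
Tic20-IV	Chloroplast	atha|AT_TIC20IV	confirmed
Tic20-V	Chloroplast	atha|AT_TIC20V	confirmed
stHsp70	Chloroplast	atha|AT_STHSP70	confirmed
Hsp93	Chloroplast	atha|AT_HSP93	confirmed
cpSecA	Chloroplast	atha|AT_CPSECA	confirmed
cpSecA2	Chloroplast	atha|AT_CPSECA2	confirmed
cpSecY	Chloroplast	atha|AT_CPSECY	confirmed
cpSecY2	Chloroplast	atha|AT_CPSECY2	confirmed
cpSecE	Chloroplast	atha|AT_CPSECE	confirmed
cpSRP54	Chloroplast	atha|AT_CPSRP54	confirmed
cpSRP43	Chloroplast	atha|AT_CPSRP43	confirmed
cpFtsY	Chloroplast	atha|AT_CPFTSY	confirmed
Alb3	Chloroplast	atha|AT_ALB3	confirmed
Hcf106	Chloroplast	atha|AT_HCF106	confirmed
cpTatC	Chloroplast	atha|AT_CPTATC	confirmed
Tha4	Chloroplast	atha|AT_THA4	confirmed
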