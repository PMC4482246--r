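study_id	author	year	cancer_type	country	ethnicity	control_source	genotyping_method	case_ref_hom	case_het	case_var_hom	ctrl_ref_hom	ctrl_het	ctrl_var_hom	variant
sakamoto2008_japan_gastric	Sakamoto	2008	gastric	Japan	Asian	HB	GWAS	97	691	737	211	650	536	rs2976392
sakamoto2008_korea_gastric	Sakamoto	2008	gastric	Korea	Asian	HB	Taqman	134	453	278	122	175	93	rs2976392
matsuo2009_japan_gastric	Matsuo	2009	gastric	Japan	Asian	HB	Taqman	331	328	48	274	337	96	rs2976392
wu2009_china_gastric	Wu	2009	gastric	China	Asian	PB	PCR-RFLP	789	793	142	492	429	81	rs2976392
lu2010_china_gastric	Lu	2010	gastric	China	Asian	PB	PCR-RFLP	500	464	79	602	402	78	rs2976392
ou2010_china_gastric	Ou	2010	gastric	China	Asian	HB	PCR/LDR	99	85	12	130	102	14	rs2976392
joung2011_korea_prostate	Joung	2011	prostate	Korea	Asian	HB	MassARRAY	45	100	49	46	85	37	rs2976392
shen2011_china_gastric	Shen	2011	gastric	China	Asian	PB	DHPLC	24	31	5	29	26	5	rs2976392
kim2012_korea_breast	Kim	2012	breast	Korea	Asian	HB	MassARRAY	121	217	115	115	239	106	rs2976392
ono2013_japan_gallbladder	Ono	2013	gallbladder	Japan	Asian	HB	Taqman	9	23	12	29	76	68	rs2976392
ju2013_china_gastric	Ju	2013	gastric	China	Asian	HB	sequencing	67	65	23	107	87	16	rs2976392
wang2014_china_gastric	Wang	2014	gastric	China	Asian	HB	Taqman	131	134	18	149	108	18	rs2976392
kupcinskas2014_lithuania_gastric	Kupcinskas	2014	gastric	Lithuania	Caucasian	HB	Taqman	34	113	102	62	116	54	rs2976392
sun2015_china_gastric	Sun	2015	gastric	China	Asian	HB	Taqman	319	308	65	403	299	72	rs2976392
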