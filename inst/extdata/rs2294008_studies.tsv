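study_id	author	year	cancer_type	country	ethnicity	control_source	genotyping_method	case_ref_hom	case_het	case_var_hom	ctrl_ref_hom	ctrl_het	ctrl_var_hom	variant
sakamoto2008_japan_gastric	Sakamoto	2008	gastric	Japan	Asian	HB	GWAS	96	700	728	210	650	536	rs2294008
sakamoto2008_korea_gastric	Sakamoto	2008	gastric	Korea	Asian	HB	Taqman	133	461	277	122	176	92	rs2294008
matsuo2009_japan_gastric	Matsuo	2009	gastric	Japan	Asian	HB	Taqman	330	329	49	273	338	97	rs2294008
wu2009_china_gastric	Wu	2009	gastric	China	Asian	PB	PCR-RFLP	759	819	132	506	412	77	rs2294008
wu2009_usa-european_bladder	Wu	2009	bladder	USA&European	Caucasian	HB	GWAS	1288	2613	1137	2842	4668	1853	rs2294008
lu2010_china_gastric	Lu	2010	gastric	China	Asian	PB	PCR-RFLP	547	404	72	605	387	77	rs2294008
ou2010_china_gastric	Ou	2010	gastric	China	Asian	HB	PCR/LDR	85	93	18	132	96	18	rs2294008
wang2010_china_bladder	Wang	2010	bladder	China	Asian	HB	PCR-RFLP	272	259	50	316	220	44	rs2294008
joung2011_korea_prostate	Joung	2011	prostate	Korea	Asian	HB	MassARRAY	45	98	49	47	84	37	rs2294008
lochhead2011_poland_gastric	Lochhead	2011	gastric	Poland	Caucasian	PB	Taqman	47	143	102	101	166	115	rs2294008
lochhead2011_usa_gastric	Lochhead	2011	gastric	USA	Caucasian	PB	Taqman	85	129	94	49	110	49	rs2294008
lochhead2011_usa_esophageal	Lochhead	2011	esophageal	USA	Caucasian	PB	Taqman	61	63	34	49	110	49	rs2294008
song2011_korea_gastric	Song	2011	gastric	Korea	Asian	HB	PCR-RFLP	576	1620	1049	414	818	468	rs2294008
zeng2011_china_gastric	Zeng	2011	gastric	China	Asian	HB	PCR-RFLP	202	216	42	289	223	37	rs2294008
fu2012_european-usa_bladder	Fu	2012	bladder	European&USA	Caucasian	PB	GWAS	1363	2804	1226	2107	3645	1572	rs2294008
kim2012_korea_breast	Kim	2012	breast	Korea	Asian	HB	MassARRAY	119	216	116	113	240	106	rs2294008
li2012_china_gastric	Li	2012	gastric	China	Asian	PB	MassARRAY	124	141	35	168	111	21	rs2294008
sala2012_european_gastric	Sala	2012	gastric	European	Caucasian	PB	Taqman	93	198	118	491	714	310	rs2294008
smith2012_uk_colorectal	Smith	2012	colorectal	UK	Caucasian	HB	Taqman	25	39	13	287	387	130	rs2294008
ma2013_china_bladder	Ma	2013	bladder	China	Asian	PB	MassARRAY	84	80	11	543	355	64	rs2294008
ono2013_japan_gallbladder	Ono	2013	gallbladder	Japan	Asian	HB	Taqman	9	23	12	30	75	68	rs2294008
rai2013_india_gallbladder	Rai	2013	gallbladder	India	Asian	HB	Taqman	104	233	68	79	126	42	rs2294008
rizzato2013_germany_gastric	Rizzato	2013	gastric	Germany	Caucasian	PB	Taqman	23	86	69	231	507	319	rs2294008
zhao2013_china_gastric	Zhao	2013	gastric	China	Asian	PB	DHPLC	275	342	100	465	401	85	rs2294008
dai2014_china_esophageal	Dai	2014	esophageal	China	Asian	PB	Taqman	1232	724	127	1222	851	147	rs2294008
sun2014_usa_gastric	Sun	2014	gastric	USA	African	HB	Taqman	17	64	49	30	63	32	rs2294008
wang2014_china_bladder	Wang	2014	bladder	China	Asian	PB	Taqman	604	509	97	566	376	66	rs2294008
lee2014_korea_bladder	Lee	2014	bladder	Korea	Asian	HB	HRM	70	222	119	414	818	468	rs2294008
kupcinskas2014_lithuania_gastric	Kupcinskas	2014	gastric	Lithuania	Caucasian	HB	Taqman	33	116	102	64	123	56	rs2294008
sun2015_china_gastric	Sun	2015	gastric	China	Asian	HB	Taqman	322	309	61	405	297	72	rs2294008
ichikawa2015_japan_gastric	Ichikawa	2015	gastric	Japan	Asian	HB	PCR-RFLP	24	104	65	52	119	95	rs2294008
garcia-gonzalez2015_spain_gastric	Garcia-Gonzalez	2015	gastric	Spain	Caucasian	HB	Taqman	154	302	147	199	346	130	rs2294008
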