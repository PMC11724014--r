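gene	group	chrom_type	a_cases	a_gnomad	a_mgrb	a_lifepool
PALB2	proposed	autosome	3	86	4	3
ATM	proposed	autosome	4	195	13	3
MRE11A	proposed	autosome	2	57	1	2
ERCC3	proposed	autosome	3	125	2	2
BLM	proposed	autosome	3	131	5	3
FANCM	proposed	autosome	2	344	11	7
MAP6D1	candidate	autosome	3	9	3	1
SLC12A4	candidate	autosome	5	54	6	0
SORD	candidate	autosome	6	89	26	0
CPT1B	candidate	autosome	4	36	2	0
ZBTB45	candidate	autosome	4	37	3	0
LOXL2	candidate	autosome	4	39	3	2
SSX3	candidate	X	3	11	1	0
ZCCHC4	candidate	autosome	12	444	20	8
RPA3	candidate	autosome	3	18	2	1
IMPDH2	candidate	autosome	3	19	1	0
GPALPP1	candidate	autosome	3	19	2	0
WRAP53	candidate	autosome	4	49	2	1
STARD6	candidate	autosome	3	22	0	2
LLGL2	candidate	autosome	4	55	0	3
CCDC88B	candidate	autosome	4	57	2	4
FBLIM1	candidate	autosome	3	26	2	0
IFIT2	candidate	autosome	4	58	3	1
MIPOL1	candidate	autosome	4	60	6	3
CCDC14	candidate	autosome	6	150	9	1
TTC24	candidate	autosome	3	32	0	1
SLC38A8	candidate	autosome	3	34	2	2
ANKAR	candidate	autosome	6	174	8	11
CARMIL2	candidate	autosome	3	36	3	1
SCYL3	candidate	autosome	3	37	6	1
MMAA	candidate	autosome	4	78	4	3
ZNF418	candidate	autosome	5	127	3	3
RAD1	candidate	autosome	5	129	6	2
USP50	candidate	autosome	4	80	2	3
RASSF7	candidate	autosome	3	41	3	1
LRRC56	candidate	autosome	3	44	1	7
HARS2	candidate	autosome	3	45	2	0
PRKACG	candidate	autosome	3	46	0	6
CDKL3	candidate	autosome	4	90	7	0
ZNF616	candidate	autosome	4	91	4	2
VSIG1	candidate	X	3	33	2	0
ANKRD18A	candidate	autosome	3	47	0	3
FAM216A	candidate	autosome	3	60	7	3
TBXAS1	candidate	autosome	3	61	3	1
CDH23	candidate	autosome	2	26	4	1
LTBP1	candidate	autosome	2	28	3	0
ADGRD1	candidate	autosome	2	46	0	2
PLEKHA4	candidate	autosome	2	82	4	3
DLGAP5	candidate	autosome	1	33	1	0
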