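gene_id	nloglik	aic	gene_symbol	selected
ILMN_2323338	644.17	1290.35	NR1I2	1
ILMN_1673843	632.73	1269.46	CST2	1
ILMN_1713561	627.89	1261.77	LAMP5	1
ILMN_2192072	626.6	1261.2	MMP7	1
ILMN_1673548	621.82	1253.65	LGALSL	1
ILMN_2150095	617.24	1246.49	CES1P1	1
ILMN_2402392	615.38	1244.76	COL8A1	1
ILMN_1811790	614.94	1245.88	FOXS1	1
ILMN_1657683	613	1244.01	C1ORF198	1
ILMN_1735996	612.83	1245.65		0
ILMN_1767665	611.84	1245.69		0
ILMN_1732158	611.01	1246.02		0
ILMN_1736078	610.86	1247.71		0
ILMN_1685433	610.82	1249.63		0
ILMN_2387995	610.75	1251.49		0
ILMN_1748283	608.79	1249.59		0
ILMN_2382705	608.48	1250.97		0
ILMN_2118129	607.4	1250.8		0
ILMN_1749846	606.15	1250.3		0
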