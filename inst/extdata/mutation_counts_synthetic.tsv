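locus	mutations	meioses
DYS19	120	52000
DYS389I	115	46000
DYS389II	162	45000
DYS390	110	50000
DYS391	127	49000
DYS392	24	47000
DYS393	55	46000
DYS385	78	60000
DYS437	40	40000
DYS438	12	40000
DYS439	223	42000
DYS448	61	38000
DYS456	158	36000
DYS458	248	37000
DYS635	122	33000
YGATAH4	95	34000
DYS481	74	16000
DYS533	62	15000
DYS549	60	14000
DYS570	214	17000
DYS576	247	17500
DYS643	13	14000
DYS449	113	9000
DYS460	67	12000
DYS518	146	8000
DYS627	102	8000
DYF387S1	79	10000
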