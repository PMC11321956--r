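drug	section	category	count
aprepitant	age	<18	103
aprepitant	age	18-45	452
aprepitant	age	45-65	1197
aprepitant	age	65-75	608
aprepitant	age	>=75	203
aprepitant	age	Unknown	1341
aprepitant	sex	Female	2087
aprepitant	sex	Male	1276
aprepitant	sex	Unknown	541
aprepitant	reporter	physician	1146
aprepitant	reporter	consumer	1072
aprepitant	reporter	other-health-professional	816
aprepitant	reporter	pharmacist	794
aprepitant	reporter	lawyer	1
aprepitant	reporter	registered-nurse	1
aprepitant	reporter	unknown	74
aprepitant	country	US	1778
aprepitant	country	FR	399
aprepitant	country	KR	347
aprepitant	country	JP	246
aprepitant	country	Other	1134
aprepitant	outcomes	HO	1095
aprepitant	outcomes	DE	366
aprepitant	outcomes	LT	299
aprepitant	outcomes	DS	120
aprepitant	outcomes	RI	22
aprepitant	outcomes	CA	1
aprepitant	outcomes	OT	1546
fosaprepitant	age	<18	21
fosaprepitant	age	18-45	152
fosaprepitant	age	45-65	426
fosaprepitant	age	65-75	201
fosaprepitant	age	>=75	70
fosaprepitant	age	Unknown	253
fosaprepitant	sex	Female	578
fosaprepitant	sex	Male	413
fosaprepitant	sex	Unknown	132
fosaprepitant	reporter	physician	451
fosaprepitant	reporter	consumer	203
fosaprepitant	reporter	other-health-professional	170
fosaprepitant	reporter	pharmacist	280
fosaprepitant	reporter	unknown	19
fosaprepitant	country	US	409
fosaprepitant	country	KR	338
fosaprepitant	country	JP	113
fosaprepitant	country	Other	263
fosaprepitant	outcomes	HO	290
fosaprepitant	outcomes	DE	73
fosaprepitant	outcomes	LT	100
fosaprepitant	outcomes	DS	32
fosaprepitant	outcomes	RI	17
fosaprepitant	outcomes	OT	655
netupitant	age	<18	1
netupitant	age	18-45	28
netupitant	age	45-65	102
netupitant	age	65-75	54
netupitant	age	>=75	14
netupitant	age	Unknown	44
netupitant	sex	Female	141
netupitant	sex	Male	94
netupitant	sex	Unknown	8
netupitant	reporter	physician	95
netupitant	reporter	consumer	29
netupitant	reporter	other-health-professional	43
netupitant	reporter	pharmacist	55
netupitant	reporter	lawyer	1
netupitant	reporter	unknown	20
netupitant	country	US	122
netupitant	country	Other	121
netupitant	outcomes	HO	76
netupitant	outcomes	DE	72
netupitant	outcomes	LT	5
netupitant	outcomes	DS	6
netupitant	outcomes	CA	1
netupitant	outcomes	OT	72
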