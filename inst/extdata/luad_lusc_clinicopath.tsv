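cohort	factor	level	n_low	n_high
LUAD	age	<60	29	45
LUAD	age	>=60	65	129
LUAD	sex	Female	36	75
LUAD	sex	Male	58	99
LUAD	smoking	Non-smoker	31	59
LUAD	smoking	Smoker	42	81
LUAD	pT	pT1/pT2	89	148
LUAD	pT	pT3/pT4	5	26
LUAD	pN	pN0	77	120
LUAD	pN	pN1-pN3	15	51
LUAD	stage	I/II	85	134
LUAD	stage	III/IV	9	40
LUSC	age	<60	9	7
LUSC	age	>=60	39	43
LUSC	sex	Female	3	3
LUSC	sex	Male	45	47
LUSC	smoking	Non-smoker	1	3
LUSC	smoking	Smoker	35	39
LUSC	pT	pT1/pT2	42	30
LUSC	pT	pT3/pT4	6	20
LUSC	pN	pN0	32	30
LUSC	pN	pN1-pN3	16	18
LUSC	stage	I/II	39	27
LUSC	stage	III/IV	9	23
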