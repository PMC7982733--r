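panel	TNM	NMM	NDL_turionifera	NDL_minor_SCI	NDL_minor_SCII	NDL_gibba
PC47	177	4	73	66	92	50
PC48	145	3	46	46	70	44
PC49	101	5	37	42	54	31
PC50	206	1	71	73	99	69
PC51	186	2	61	58	85	58
PC52	176	0	62	57	82	58
PC53	88	6	29	34	39	51
PC54	154	3	47	60	71	57
PC55	161	10	72	83	83	64
PC56	225	6	101	86	119	85
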