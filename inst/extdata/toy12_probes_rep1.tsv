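probe_id	target	site	treated_signal	treated_error	control_signal	control_error
P01	AKT1	S473	2000	50	1000	40
P02	MTOR	S2448	999	10	1500	10
P03	GSK3B	S9	1500	10	999	5
P04	TP53	S37	1000	0	1000	0
P05	JUN	S73	1200	300	1000	0
P06	SRC	Y419	1200	0	1000	0
P07	MAPK1	T185	1100	50	1000	50
P08	EZR	T567	1000	50	1000	50
P09	BAD	S75	1800	40	1200	30
P10	CDK1	Y15	800	10	1600	10
P11	RPS6KB1	T252	3000	100	2000	80
P12	CHEK1	S280	1500	60	1250	50
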