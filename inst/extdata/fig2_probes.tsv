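probe_id	target	site	treated_signal	treated_error	control_signal	control_error
F01	AKT	S473	2500	40	2000	40
F02	AKT	Y326	2360	40	2000	40
F03	BAD	S75	2600	40	2000	40
F04	EZR	T567	2440	40	2000	40
F05	RPS6KB1	T252	1700	40	2000	40
F06	RPS6KB1	S447	1760	40	2000	40
F07	IRS1	S636	1820	40	2000	40
F08	CDK1	T161	1600	40	2000	40
F09	CDK1	Y15	1500	40	2000	40
F10	JUN	S73	1640	40	2000	40
F11	TP53	S37	1800	40	2000	40
F12	ESR1	S118	1720	40	2000	40
F13	ESR1	Y537	1780	40	2000	40
F14	AKT	pan	2300	40	2000	40
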