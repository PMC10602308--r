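kinase	substrate	site	effect
PDK1	AKT	S473	activation
MAPK14	AKT	S473	activation
SRC	AKT	Y326	activation
AKT	BAD	S75	inhibition
AKT	EZR	T567	activation
PDK1	RPS6KB1	T252	activation
PIK3CA	RPS6KB1	T252	activation
CDK1	RPS6KB1	S447	activation
RPS6KB1	IRS1	S636	inhibition
CDK7	CDK1	T161	activation
SRC	CDK1	Y15	inhibition
CHEK1	CDK1	Y15	inhibition
CDK1	JUN	S73	activation
CHEK1	TP53	S37	inhibition
CDK1	ESR1	S118	activation
SRC	ESR1	Y537	activation
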