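enzyme_code	enzyme_name	side	targets	blocked_when
TR	Trypsin	C	KR	P1'=P
CTR	Chymotrypsin (low specificity)	C	FLMWY	P1'=P
PEP	Pepsin (pH 1.3)	C	FL	P1'=P
TLN	Thermolysin	N	AFILMV	P1=P
LysC	Lysyl endopeptidase (LysC)	C	K
PROK	Proteinase K	C	AEFILTVWY
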