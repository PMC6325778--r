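gene	role
EGFR	ONCOGENE
KRAS	ONCOGENE
BRAF	ONCOGENE
PIK3CA	ONCOGENE
MET	ONCOGENE
ERBB2	ONCOGENE
ALK	ONCOGENE
RET	ONCOGENE
ROS1	ONCOGENE
NRAS	ONCOGENE
MYC	ONCOGENE
CCND1	ONCOGENE
FGFR1	ONCOGENE
AKT1	ONCOGENE
HRAS	ONCOGENE
TP53	TSG
RB1	TSG
PTEN	TSG
STK11	TSG
KEAP1	TSG
CDKN2A	TSG
NF1	TSG
SMAD4	TSG
ARID1A	TSG
BRCA2	TSG
ATM	TSG
APC	TSG
SETD2	TSG
SMARCA4	TSG
NOTCH1	TSG
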