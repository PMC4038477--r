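alias	symbol
ARNTL	BMAL1
ARNTL2	BMAL2
MOP3	BMAL1
NR1D1	REV-ERBA
NR1D2	REV-ERBB
RORG	RORC
RZRB	RORB
BHLHE40	DEC1
BHLHE41	DEC2
NFIL3	E4BP4
EP300	P300
CREBBP	CBP
TNF	TNFA
PRKCA	PRKC-A
CTNNB1	B-CATENIN
ATF2	ATF-2
COP1	RFWD2
GNB2L1	RACK1
VEGFA	VEGF
PPARB	PPARD
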