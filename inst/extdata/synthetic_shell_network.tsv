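src	dst	type	source	pubmed_ids	confidence
BMAL1	PER1	activation	textmine		0.9
BMAL1	PER2	activation	textmine		0.9
BMAL1	PER3	activation	textmine		0.9
BMAL1	CRY1	activation	textmine		0.9
BMAL1	CRY2	activation	textmine		0.9
CLOCK	PER1	activation	textmine		0.9
CLOCK	PER2	activation	textmine		0.9
CLOCK	CRY1	activation	textmine		0.9
NPAS2	PER1	activation	textmine		0.9
NPAS2	CRY1	activation	textmine		0.9
REV-ERBA	BMAL1	inhibition	textmine		0.9
REV-ERBB	BMAL1	inhibition	textmine		0.9
RORA	BMAL1	activation	textmine		0.9
RORB	BMAL1	activation	textmine		0.9
RORC	BMAL1	activation	textmine		0.9
BMAL2	PER2	activation	textmine		0.9
AHR	PER1	other	textmine		0.9
ALAS1	PER2	other	textmine		0.9
AMPK	PER3	other	textmine		0.9
BTRCP	CRY1	other	textmine		0.9
CAR	CRY2	other	textmine		0.9
CBP	BMAL1	other	textmine		0.9
CK2	BMAL2	other	textmine		0.9
CREB	REV-ERBA	other	textmine		0.9
CSNK1D	REV-ERBB	other	textmine		0.9
CSNK1E	RORA	other	textmine		0.9
CSNK2A	RORB	other	textmine		0.9
DBP	RORC	other	textmine		0.9
DEC1	CLOCK	other	textmine		0.9
DEC2	NPAS2	other	textmine		0.9
E4BP4	PER1	other	textmine		0.9
FBXL3	PER2	other	textmine		0.9
GSK3B	CRY2	other	textmine		0.9
HLF	BMAL1	other	textmine		0.9
IFNA	BMAL2	other	textmine		0.9
NONO	REV-ERBA	other	textmine		0.9
P300	REV-ERBB	other	textmine		0.9
PARP1	RORA	other	textmine		0.9
PPARA	RORB	other	textmine		0.9
PPARG	RORC	other	textmine		0.9
PRKC-A	CLOCK	other	textmine		0.9
RACK1	NPAS2	other	textmine		0.9
SIRT1	PER1	other	textmine		0.9
TEF	PER2	other	textmine		0.9
TNFA	PER3	other	textmine		0.9
WDR5	CRY1	other	textmine		0.9
ERK	CRY2	other	textmine		0.9
MEK	BMAL1	other	textmine		0.9
RAF	BMAL2	other	textmine		0.9
P300	PARP1	other	textmine		0.9
ALAS1	CK2	other	textmine		0.9
PER3	CREB	activation	textmine		0.9
RORB	CREB	other	textmine		0.9
CSNK1E	AHR	inhibition	textmine		0.9
DEC1	AMPK	other	textmine		0.9
MEK	GSK3B	inhibition	textmine		0.9
BMAL2	PPARA	activation	textmine		0.9
PER3	HLF	other	textmine		0.9
PPARA	GSK3B	other	textmine		0.9
E4BP4	TNFA	inhibition	textmine		0.9
PER1	WDR5	other	textmine		0.9
PPARG	TEF	other	textmine		0.9
GSK3B	HLF	activation	textmine		0.9
PER3	CRY2	inhibition	textmine		0.9
CLOCK	REV-ERBA	activation	textmine		0.9
REV-ERBA	FBXL3	other	textmine		0.9
REV-ERBB	CRY2	other	textmine		0.9
PARP1	WDR5	other	textmine		0.9
TEF	RORC	inhibition	textmine		0.9
AMPK	TNFA	other	textmine		0.9
HLF	ERK	inhibition	textmine		0.9
REV-ERBA	WDR5	other	textmine		0.9
CAR	CSNK1E	inhibition	textmine		0.9
CSNK2A	CRY1	other	textmine		0.9
DBP	DEC2	other	textmine		0.9
BMAL2	BMAL1	other	textmine		0.9
GSK3B	CSNK2A	inhibition	textmine		0.9
BTRCP	PER3	other	textmine		0.9
BMAL2	REV-ERBB	activation	textmine		0.9
WDR5	RAF	other	textmine		0.9
E4BP4	RACK1	other	textmine		0.9
REV-ERBB	BTRCP	activation	textmine		0.9
BTRCP	FBXL3	other	textmine		0.9
CSNK1D	GSK3B	other	textmine		0.9
CSNK1D	TNFA	other	textmine		0.9
PER3	RORC	inhibition	textmine		0.9
HLF	CK2	activation	textmine		0.9
AHR	PRKC-A	activation	textmine		0.9
CSNK1D	DEC2	inhibition	textmine		0.9
PARP1	E4BP4	activation	textmine		0.9
HLF	CAR	inhibition	textmine		0.9
P300	IFNA	inhibition	textmine		0.9
PARP1	TEF	activation	textmine		0.9
CBP	P300	activation	textmine		0.9
TEF	SIRT1	activation	textmine		0.9
FBXL3	CRY2	other	textmine		0.9
PER3	CSNK2A	activation	textmine		0.9
CSNK1E	ERK	other	textmine		0.9
BMAL2	ERK	activation	textmine		0.9
IFNA	NONO	other	textmine		0.9
E4BP4	RORB	other	textmine		0.9
DBP	PER2	other	textmine		0.9
TNFA	PPARG	activation	textmine		0.9
SIRT1	AHR	activation	textmine		0.9
HLF	REV-ERBA	inhibition	textmine		0.9
CRY2	RACK1	activation	textmine		0.9
CLOCK	WDR5	activation	textmine		0.9
HLF	DEC1	inhibition	textmine		0.9
BMAL1	PARP1	other	textmine		0.9
GSK3B	TNFA	activation	textmine		0.9
DBP	CBP	other	textmine		0.9
FBXL3	CSNK2A	inhibition	textmine		0.9
RORB	DEC1	other	textmine		0.9
PPARG	DBP	other	textmine		0.9
RAF	NONO	other	textmine		0.9
BMAL1	TNFA	activation	textmine		0.9
NPAS2	MEK	other	textmine		0.9
PRKC-A	BTRCP	inhibition	textmine		0.9
PRKC-A	RORC	activation	textmine		0.9
BTRCP	CAR	activation	textmine		0.9
CK2	CBP	inhibition	textmine		0.9
WDR5	AHR	other	textmine		0.9
RORB	BMAL2	activation	textmine		0.9
PPARG	CRY2	other	textmine		0.9
HLF	CSNK2A	other	textmine		0.9
SIRT1	PER3	other	textmine		0.9
CAR	SIRT1	inhibition	textmine		0.9
CBP	CSNK1E	other	textmine		0.9
CAR	CK2	inhibition	textmine		0.9
NPAS2	ERK	other	textmine		0.9
REV-ERBB	PER2	activation	textmine		0.9
PARP1	BTRCP	other	textmine		0.9
RACK1	GSK3B	inhibition	textmine		0.9
BMAL2	CSNK1D	other	textmine		0.9
RORA	RAF	activation	textmine		0.9
CAR	RORC	activation	textmine		0.9
CK2	FBXL3	other	textmine		0.9
CLOCK	RORA	inhibition	textmine		0.9
PPARG	FBXL3	other	textmine		0.9
WDR5	PPARA	activation	textmine		0.9
CSNK2A	REV-ERBA	other	textmine		0.9
DEC2	CRY2	other	textmine		0.9
PER1	MEK	other	textmine		0.9
E4BP4	CREB	inhibition	textmine		0.9
IFNA	CLOCK	activation	textmine		0.9
HLF	PPARG	inhibition	textmine		0.9
CREB	PER1	other	textmine		0.9
CLOCK	RORC	activation	textmine		0.9
PER1	CSNK2A	inhibition	textmine		0.9
BTRCP	RORB	other	textmine		0.9
PPARA	RORA	inhibition	textmine		0.9
HLF	CRY1	inhibition	textmine		0.9
CREB	BMAL1	inhibition	textmine		0.9
ALAS1	BTRCP	inhibition	textmine		0.9
REV-ERBB	DBP	other	textmine		0.9
PPARA	HLF	other	textmine		0.9
MEK	TEF	inhibition	textmine		0.9
RAF	CLOCK	activation	textmine		0.9
PER1	RORC	other	textmine		0.9
REV-ERBB	CAR	activation	textmine		0.9
TEF	BTRCP	inhibition	textmine		0.9
PPARA	RAF	other	textmine		0.9
BMAL1	CSNK1E	other	textmine		0.9
ERK	AMPK	inhibition	textmine		0.9
E4BP4	CLOCK	activation	textmine		0.9
NPAS2	HLF	inhibition	textmine		0.9
CRY2	IFNA	activation	textmine		0.9
HLF	RORC	other	textmine		0.9
RORC	WDR5	other	textmine		0.9
HLF	MEK	activation	textmine		0.9
RORA	REV-ERBB	activation	textmine		0.9
FBXL3	CLOCK	other	textmine		0.9
P300	PRKC-A	other	textmine		0.9
AMPK	PER2	inhibition	textmine		0.9
RACK1	BMAL1	inhibition	textmine		0.9
TEF	CSNK2A	other	textmine		0.9
PPARA	PRKC-A	activation	textmine		0.9
NONO	BTRCP	other	textmine		0.9
E4BP4	CRY2	activation	textmine		0.9
TNFA	PARP1	other	textmine		0.9
DBP	PER1	activation	textmine		0.9
E4BP4	SIRT1	activation	textmine		0.9
REV-ERBA	CAR	activation	textmine		0.9
GSK3B	CLOCK	inhibition	textmine		0.9
NONO	RORA	inhibition	textmine		0.9
CRY2	MEK	other	textmine		0.9
GSK3B	NPAS2	activation	textmine		0.9
DEC2	BTRCP	other	textmine		0.9
NONO	CK2	other	textmine		0.9
ALAS1	DEC1	other	textmine		0.9
CSNK1D	PER1	other	textmine		0.9
CLOCK	ERK	inhibition	textmine		0.9
ALAS1	REV-ERBA	activation	textmine		0.9
AHR	P300	activation	textmine		0.9
DBP	PPARA	activation	textmine		0.9
RAF	CBP	other	textmine		0.9
TEF	AMPK	inhibition	textmine		0.9
DEC1	RACK1	other	textmine		0.9
ALAS1	PRKC-A	inhibition	textmine		0.9
CREB	CSNK1D	activation	textmine		0.9
CSNK2A	ALAS1	other	textmine		0.9
NPAS2	PPARA	inhibition	textmine		0.9
CBP	CRY1	inhibition	textmine		0.9
TNFA	CK2	inhibition	textmine		0.9
CRY2	PRKC-A	inhibition	textmine		0.9
PPARG	AHR	inhibition	textmine		0.9
SIRT1	P300	inhibition	textmine		0.9
AMPK	BMAL2	other	textmine		0.9
CSNK1D	MEK	other	textmine		0.9
GSK3B	DEC1	other	textmine		0.9
CREB	HLF	other	textmine		0.9
REV-ERBB	CRY1	inhibition	textmine		0.9
CK2	DEC2	other	textmine		0.9
RORB	PARP1	other	textmine		0.9
NPAS2	AHR	other	textmine		0.9
IFNA	PARP1	other	textmine		0.9
REV-ERBA	E4BP4	inhibition	textmine		0.9
CSNK1E	IFNA	activation	textmine		0.9
DEC1	CREB	activation	textmine		0.9
CK2	CSNK1D	activation	textmine		0.9
P300	RACK1	inhibition	textmine		0.9
DBP	FBXL3	other	textmine		0.9
SIRT1	CSNK1D	inhibition	textmine		0.9
CK2	REV-ERBB	other	textmine		0.9
ALAS1	HLF	inhibition	textmine		0.9
RAF	P300	activation	textmine		0.9
AMPK	CSNK2A	inhibition	textmine		0.9
AMPK	SIRT1	activation	textmine		0.9
BTRCP	IFNA	inhibition	textmine		0.9
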