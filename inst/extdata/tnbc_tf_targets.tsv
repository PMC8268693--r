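tf	gene	frequency	group
AR	ST3GAL6	1	TNBC
AR	HPSE	1	TNBC
AR	IDUA	1	TNBC
AR	MAN1C1	1	TNBC
AR	B3GNT5	1	TNBC
AR	GNPTG	1	TNBC
AR	B4GALT4	1	TNBC
TCF7L2	HPSE	1	TNBC
TCF7L2	LFNG	1	TNBC
TCF7L2	CHST6	1	TNBC
TCF7L2	PIGG	1	TNBC
TCF7L2	PIGV	1	TNBC
TCF7L2	MAN1C1	1	TNBC
NFIB	MGAT4B	1	TNBC
NFIB	IDUA	1	TNBC
NFIB	LFNG	1	TNBC
NFIB	CHST6	1	TNBC
NFIB	PLOD3	1	TNBC
TAF7	DDOST	1	TNBC
TAF7	MAN2B2	1	TNBC
TAF7	MAN2B1	1	TNBC
TAF7	UGT8	1	TNBC
TAF7	MOGS	1	TNBC
ZNF622	ST3GAL6	1	TNBC
ZNF622	FUT3	1	TNBC
ZNF622	CHPF2	1	TNBC
ZNF622	C1GALT1	1	TNBC
ZNF622	ST3GAL4	1	TNBC
E2F6	CHST4	1	TNBC
E2F6	DDOST	1	TNBC
E2F6	MAN2B2	1	TNBC
E2F6	FUT3	1	TNBC
E2F6	PLOD3	1	TNBC
GATA3	EXT1	1	TNBC
GATA3	GCNT2	1	TNBC
GATA3	UGT8	1	TNBC
GATA3	B4GALT4	1	TNBC
RUNX1T1	ARSB	1	TNBC
RUNX1T1	CHPF2	1	TNBC
RUNX1T1	GALNT10	1	TNBC
RUNX1T1	MAN1C1	1	TNBC
ETV5	GCNT2	1	TNBC
ETV5	PIGG	1	TNBC
ETV5	B4GALT4	1	TNBC
ETV5	PLOD3	1	TNBC
CBFB	ST3GAL6	1	TNBC
CBFB	IDUA	1	TNBC
CBFB	CHST6	1	TNBC
CBFB	UGT8	1	TNBC
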