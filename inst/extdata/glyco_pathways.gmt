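GSL_biosynthesis_lacto_neolacto_series	lacto-/neolacto-series glycosphingolipid biosynthesis candidate glycogenes	ST3GAL6	FUT3	ST3GAL4	GCNT2	UGT8	B4GALT4	B3GNT5
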