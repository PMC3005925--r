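name	recognition	cut_offset_top
EcoRI	GAATTC	1
XbaI	TCTAGA	1
SalI	GTCGAC	1
BamHI	GGATCC	1
BglII	AGATCT	1
MluI	ACGCGT	1
SpeI	ACTAGT	1
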