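symbol	somatic_mutation_frequency
PRKACA	0.7
EWSR1	1.2
NDRG1	0.8
FGFR1	1.4
IDH1	5.1
PABPC1	0.9
LMNA	0.8
MYH9	3.2
SUZ12	1.0
TP53	35.3
HRAS	1.2
IKBKB	1.4
CYLD	1.3
ERBB2	2.9
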