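symbol	class
PRKAA1	protein_kinase
PPP2CA	protein_phosphatase
CTSL	protease
RNF145	ubiquitin_ligase
AMFR	ubiquitin_ligase
USP20	deubiquitinase
MAP2K5	protein_kinase
GSK3B	protein_kinase
MARCH6	ubiquitin_ligase
MYLIP	ubiquitin_ligase
PRKCA	protein_kinase
ITCH	ubiquitin_ligase
PRKACA	protein_kinase
SYVN1	ubiquitin_ligase
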