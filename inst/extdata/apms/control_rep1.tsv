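protein_id	unique_peptides
UHRF1	2
DNMT1	2
EZH2	1
SUZ12	0
EED	2
TRIM28	12
HELLS	1
USP7	10
DECOY1	8
DECOY2	8
BGA	177
BGB	177
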