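protein_id	unique_peptides
UHRF1	4
DNMT1	4
EZH2	2
SUZ12	2
EED	3
TRIM28	16
HELLS	2
USP7	12
DECOY1	10
DECOY2	10
BGA	217
BGB	218
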