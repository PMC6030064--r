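protein_id	unique_peptides
UHRF1	50
DNMT1	4
EZH2	2
SUZ12	1
EED	6
TRIM28	8
HELLS	3
USP7	6
DECOY1	5
DECOY2	5
BGA	80
BGB	80
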