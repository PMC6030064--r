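protein_id	unique_peptides
UHRF1	40
DNMT1	8
EZH2	6
SUZ12	4
EED	2
TRIM28	6
HELLS	1
USP7	5
DECOY1	4
DECOY2	4
BGA	60
BGB	60
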