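Synthetic AP-MS unique-peptide toy fixture (12 proteins, 2 bait and 2
control pull-down replicates) with hand-computed calling truth; protein
ids are illustrative, the counts are constructed, not measured.
Totals: bait 200/250, control 400/500.
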