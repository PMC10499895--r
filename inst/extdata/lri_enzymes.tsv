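# Restriction enzymes used for long range-inverse PCR breakpoint capture.
# cut_offset_top/bottom: cut position within the recognition site, counted in
# bases from its 5' end on the respective strand (0..site length).
# BamHI was printed in the source protocol as "G|GACC"; that is not a BamHI
# site and is treated as a typo for the canonical G|GATCC.
name	recognition	cut_offset_top	cut_offset_bottom
SphI	GCATGC	5	1
BamHI	GGATCC	1	5
TaqI	TCGA	1	3
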