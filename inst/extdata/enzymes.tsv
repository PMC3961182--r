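# Restriction enzymes used for iPCR genotyping. cut_top/cut_bottom are the cut
# offsets (bases from the start of the recognition site) on the top and bottom
# strand; equal offsets give blunt ends.
name	site	cut_top	cut_bottom	end_type
EcoRI	GAATTC	1	5	staggered
HindIII	AAGCTT	1	5	staggered
SacI	GAGCTC	5	1	staggered
BamHI	GGATCC	1	5	staggered
NsiI	ATGCAT	5	1	staggered
BglII	AGATCT	1	5	staggered
SwaI	ATTTAAAT	4	4	blunt
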