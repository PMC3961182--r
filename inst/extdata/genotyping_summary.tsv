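# CEU genotyping summary and primate iPCR calls for the 17 validated inversions.
# n_chrom: chromosomes from unrelated individuals used for the inversion frequency;
# n_chrom_het: chromosomes (females only on chrX) used for observed heterozygosity.
# chimp / gorilla: iPCR orientation call in that species (ND = not determined).
inversion	chrom	n_chrom	n_chrom_het	inv_freq	obs_het	families_valid	families_total	chimp	gorilla	ancestral
HsInv0114	chr9	92	92	0.64	0.50	12	12	Inv	Inv	Inv
HsInv0124	chr11	92	92	0.39	0.43	12	12	Std	Std	Std
HsInv0209	chr11	90	90	0.02	0.04	12	12	Std	Std	Std
HsInv0241	chr2	92	92	0.16	0.28	12	12	Std	Std/Inv	Std
HsInv0278	chr5	92	92	0.10	0.20	12	12	Inv	Inv	Inv
HsInv0286	chr7	72	72	0.47	0.50	3	3	Std	Std	Std
HsInv0340	chr13	90	90	0.01	0.02	11	11	Std/Inv	Inv	Inv
HsInv0341	chr13	92	92	0.03	0.07	12	12	Std/Inv	Std	Std
HsInv0344	chr14	92	92	0.59	0.48	12	12	Std/Inv	ND	Unknown
HsInv0347	chr14	92	92	0.10	0.15	12	12	Std	Std/Inv	Std
HsInv0389	chrX	69	46	0.17	0.17	14	14	Inv	Inv	Inv
HsInv0393	chrX	66	44	0.36	0.55	13	13	Std/Inv	Inv	Inv
HsInv0396	chrX	69	46	0.16	0.22	14	14	Std/Inv	Std	Std
HsInv0397	chrX	68	46	0.18	0.35	13	13	Std/Inv	Inv	Inv
HsInv0403	chrX	69	46	0.26	0.30	14	14	Std/Inv	Std/Inv	Unknown
HsInv0832	chrY	25	NA	0	0	7	7	Inv	Std	Unknown
HsInv1051	chr17	86	86	0	0	9	9	ND	ND	Std
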