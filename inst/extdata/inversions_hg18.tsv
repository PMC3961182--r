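# 22 inversion predictions analysed by iPCR: NCBI36/HG18 breakpoint intervals,
# inverted-repeat class and printed sizes, iPCR self-ligation fragment range,
# validation status and iPCR/PEM consistency tally.
inversion	chrom	bp1_start	bp1_end	bp2_start	bp2_end	repeat_type	ir_class	ir1_kb	ir2_kb	size_kb	frag_min_kb	frag_max_kb	status	pem_consistent	pem_n	pem_total
HsInv0114	chr9	125778473	125781206	125793139	125795872	TEs/SDs	mixed	2.7	2.7	14.7	13.8	17.8	Inversion	Yes	9	9
HsInv0124	chr11	300225	301836	307945	309555	SDs	SD	4.5	8.9	7.7	2.3	14.8	Inversion	Yes	9	9
HsInv0209	chr11	70953485	70960513	70965419	70972446	SDs	SD	7.0	7.0	11.9	9.2	11.7	Inversion	Yes	9	9
HsInv0241	chr2	241264234	241270541	241280391	241286847	SDs	SD	13.3	12.8	16.2	17	20.1	Inversion	Yes	7	7
HsInv0272	chr5	178802777	178811616	178857371	178867555	SDs	SD	8.8	10.2	55.3	8.8	17.6	Not validated	Yes	9	9
HsInv0278	chr5	180455356	180458186	180460457	180463248	SDs	SD	2.8	2.8	5.1	3.3	13.8	Inversion	Yes	8	8
HsInv0286	chr7	54258468	54259261	54353522	54354315	TEs/SDs	mixed	15.9	15.9	95.1	23.3	41.5	Inversion	Yes	9	9
HsInv0306	chr8	2272127	2276815	2311945	2316621	L1PA7,AluSc	TE	4.7	4.7	39.8	9.7	25.6	Complex region	NA	NA	NA
HsInv0340	chr13	63188985	63193242	63237334	63241591	SDs	SD	10.6	10.6	48.4	31.6	39.9	Inversion	Yes	9	9
HsInv0341	chr13	79291903	79294413	79312733	79315243	L1PA3	TE	6.2	6.2	20.8	7.2	17.1	Inversion	Yes	9	9
HsInv0344	chr14	34079802	34086813	34094204	34101227	SDs	SD	7.2	7.2	14.4	9.8	28.7	Inversion	Yes	9	9
HsInv0347	chr14	60141001	60142582	60148138	60149719	THE1C	TE	1.6	1.6	7.1	4.3	9.2	Inversion	Yes	8	8
HsInv0389	chrX	153219602	153228808	153266422	153275629	SDs	SD	11.3	11.3	46.8	12	30.8	Inversion	Yes	9	9
HsInv0393	chrX	100739178	100743833	100753236	100757891	SDs	SD	4.7	4.7	14.1	7.3	8.5	Inversion	Yes	9	9
HsInv0396	chrX	72132652	72141803	72214354	72223499	SDs	SD	9.5	9.5	81.7	12.3	17.9	Inversion	Yes	9	9
HsInv0397	chrX	105396369	105408238	105417867	105429736	SDs	SD	32.2	15.1	21.5	18.4	20.7	Inversion	Yes	8	8
HsInv0403	chrX	75278106	75282269	75285318	75289479	TEs/SDs	mixed	4.3	4.3	7.2	8.2	10.1	Inversion	Yes	5	5
HsInv0414	chrX	151985038	151993457	151994653	152003088	SDs	SD	8.4	8.4	9.6	NA	NA	Complex region	NA	NA	NA
HsInv0526	chr11	116509421	116514763	116581672	116587255	SDs	SD	5.3	5.6	72.4	9.1	27.6	Not validated	Yes	9	9
HsInv0710	chr8	2167585	2182892	2316618	2331389	SDs	SD	15.3	14.8	148.8	25.6	33.2	Complex region	NA	NA	NA
HsInv0832	chrY	16496132	16504854	16517493	16526218	SDs	SD	8.7	8.7	21.4	15.5	37.4	Inversion	Yes	1	1
HsInv1051	chr17	18442024	18466271	18667812	18692134	SDs	SD	24.2	24.3	225.8	46.4	72.7	Inversion	Yes	9	9
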