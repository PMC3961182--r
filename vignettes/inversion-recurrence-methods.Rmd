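---
title: "Models and methods: inversion genotyping and recurrence inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: inversion genotyping and recurrence inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invrec)
```

# The locus model

An IR-mediated inversion locus is modeled as six ordered, non-overlapping
intervals on one chromosome: unique segments A and B flanking the first
inverted repeat (IR1), and C and D flanking the second (IR2), with the
invertible interior between the repeats. Coordinates are 1-based and fully
closed at every file boundary, matching how breakpoint intervals are
published; internal arithmetic converts where needed.

Two conventions are fixed by the requirement that the packaged 22-locus
survey table reproduce its printed values exactly:

* **Inversion size** is the distance between the midpoints of the two
  breakpoint intervals, counted *inclusively* in base pairs
  (`|mid2 − mid1| + 1`), reported in kb to one decimal, rounding half away
  from zero. The inclusive count is the only reading under which every one of
  the 22 printed sizes reproduces (one locus falls on the 48.35 boundary and
  discriminates the conventions); midpoints may be half-integral and are
  never rounded before the final kb rounding.
* **IR span** is `end − start` (not `end − start + 1`), again the convention
  under which the printed IR sizes (e.g. 7.0 and 1.6 kb) reproduce.

Breakpoint refinement uses paralogous sequence variants (PSVs): columns where
the two aligned IR copies differ. In an inverted allele, PSVs distal to the
exchange point show swapped copy-of-origin. The refined breakpoint interval
is bounded by the transition between runs of at least `min_run = 3`
contiguous exchanged PSVs and the adjacent non-exchanged PSVs; when several
transitions exist the widest interval consistent with all exchanged runs is
reported, a deliberately conservative uncertainty. With no qualifying run the
full IR extent is returned flagged `unrefined`; with every PSV exchanged the
breakpoint lies outside the aligned portion and is flagged.

# In-silico iPCR

Virtual digestion finds recognition sites on both strands (IUPAC codes in
the site expand; `N` in the sequence never matches) and cuts the top strand
at `site_start + cut_top` for forward sites and the mirrored offset for
reverse-orientation sites. Fragment lengths always tile the input, linear or
circular.

Enzyme screening keeps enzymes that cut at least once in each of A, B, C, D,
never inside either IR, and whose breakpoint-spanning fragments on *both*
alleles fall in the 2.3–73 kb window, with fragments at or under 70 kb marked
efficiently recircularizable. Staggered-end enzymes rank above blunt ones,
which self-ligate poorly and are annotated low-efficiency rather than
excluded.

**Amplicon size convention.** Published product sizes cannot adjudicate
whether primers are counted without their exact genomic coordinates, so the
convention is fixed by decision: the product is measured on the self-ligated
circle from the 5' end of the forward primer, across the ligated junction, to
the 5' end of the reverse primer — inclusive of both primers. Converging
primer pairs on the same fragment (which would amplify without any junction)
are not iPCR products and are excluded. AD is computed only in concatamer
mode, on the head-to-tail ligation of the A- and D-containing fragments; it
is a contamination control, never a genotype signal.

The predictor does this with coordinate arithmetic on cut and primer
positions. A second, independent route — literal string digestion, rotation
of each fragment to simulate self-ligation, and string search for the primer
sites — serves as the oracle; the two must agree base-for-base, and the test
suite checks this on 200 generated regions across all seven packaged enzymes.

Band-pattern genotyping is presence/absence only (heterozygote band-intensity
imbalance carries no information here): per breakpoint, the standard
diagnostic (AB or CD) and inverted diagnostic (AC or BD) map the four
presence combinations to Std/Std, Inv/Inv, Std/Inv or missing, with
hemizygous calls in haploid mode and all calls voided when digestion or
ligation control lanes fail. When the two breakpoints disagree, the
`trust_informative` policy adopts the call whose allele set contains the
other's — the breakpoint showing both arrangements wins, because a
restriction-site polymorphism or unknown variant dropping one allele from one
assay explains the discordance; `strict` instead reports missing.

# Fosmid paired-end classification

Per read, mappings are filtered to identity strictly above 90%, score
strictly above 300, within 5% of the best *retained* score (the published
wording does not distinguish overall-best from best-retained; best-retained
is implemented and noted here), capped at the top 10 by score with ties
broken by leftmost coordinate. Pairs classify as:

* **concordant** — unique best placements `+/−` with span inside the insert
  window, default 32–48 kb around the ~40 kb fosmid insert;
* **discordant_orientation** — `+/+` or `−/−`;
* **ambiguous** — a read inside a highly identical IR copy (≥1 kb, ≥97%
  identity) whose alternative placements produce both orientations, or exact
  score ties across orientations;
* **uninformative** — fewer than two mapped reads, split chromosomes,
  outward-facing `−/+` pairs, or an out-of-window span. The three published
  categories say nothing about span or outward pairs, so these map to
  uninformative rather than to a new discordant class.

Only breakpoint-spanning pairs (footprint bracketing an IR copy entirely)
count as orientation support; with at least two supporting pairs per
arrangement an individual reads Std/Inv, one-sided support is
homozygous-consistent, anything else insufficient. A support set is
consistent with an iPCR genotype when every supported orientation appears in
the genotype's allele set.

# Population genetics

Frequency and heterozygosity count unrelated individuals only (children are
dropped; parents kept). Males contribute one chromosome on chrX/chrY;
observed heterozygosity — the fraction of heterozygous diploid genotypes, not
expected heterozygosity — uses females only on chrX and is undefined on chrY.

The Hardy–Weinberg test is the conditional exact (Levene/Haldane) test:
conditioning on allele counts, the two-sided p-value sums the probabilities
of heterozygote counts no more probable than the observed one. The choice of
an exact test over chi-squared follows from the small cohort (46 unrelated
individuals) and low-frequency inversions; the suite verifies agreement with
a full allele-pairing enumeration at small n and empirical size at n = 46.

Genotype-likelihood filtering keeps a call when the best genotype is at
least 10 times as likely as the runner-up (the boundary ratio of exactly 10
is kept); phred-scaled input is converted first.

LD uses `r² = D²/(p(1−p)q(1−q))` from the 2×2 haplotype table when phase is
available, otherwise from EM-estimated two-locus haplotype frequencies.
Tag SNPs are those at r² = 1; r² ≥ 0.9 is high-LD. Raw r² values are
reported with no multiple-testing adjustment, matching how such scans are
read.

**Shared/fixed SNP classification** is deliberately phase-free and
conservative. Per-arrangement allele sets are built only from unambiguous
chromosome assignments: inversion homozygotes contribute both SNP alleles to
their arrangement, hemizygotes their single allele, and Std/Inv heterozygotes
contribute only when homozygous at the SNP (that allele then provably sits on
one chromosome of each arrangement). Shared means both alleles in both sets;
fixed means non-empty disjoint sets; both alleles confined to one set is
polymorphic-in-one-arrangement; anything else is uninformative. Doubly
heterozygous individuals are dropped (and counted per SNP), making shared and
fixed counts minimum estimates. The published rule's final clause admits two
readings; the allele-set semantics above is implemented, and the per-SNP
count of dropped double-heterozygotes flags where the other reading could
matter. An enumeration oracle over all phase-consistent assignments confirms
the sound directions: a SNP is reported shared exactly when it is shared in
*every* consistent assignment, and a reported fixed SNP always admits a
consistent assignment with disjoint sets. (Requiring disjointness in every
assignment would contradict the rule's own canonical fixed case — a
heterozygote's phase can always be flipped — so existence is the correct
oracle for fixed.)

Nucleotide diversity is mean pairwise differences divided by the surveyed
length in bp (not the segregating-site count); per-arrangement values need at
least two haplotypes, otherwise they are reported absent. Fst between
arrangements is the Hudson estimator `1 − mean(π_Std, π_Inv)/π_between`,
chosen over the AMOVA-based estimator the original analysis used because it
is closed-form and oracle-testable; values can differ in low-information
cases, and zero between-group diversity is reported as Fst 0. Raw estimates
are retained alongside the [0, 1]-clamped value. Significance comes from
label permutations with add-one correction, `p = (1 + #{Fst* ≥ Fst})/(B+1)`,
reported raw with the conventional 0.05 flag.

# Recurrence inference

Trio phasing is deterministic: a child's allele is assigned to a parent
whenever only one assignment is transmission-consistent; triple-heterozygous
sites stay unphased; chrX sons phase trivially; inconsistencies error naming
the site. Statistical phasing is intentionally out of scope — externally
phased data are accepted as a haplotype matrix or phased VCF.

Trees are neighbor-joining (delegated to `ape`, exact on additive matrices —
and infinite-sites Hamming distances are additive on the true genealogy).
The haplotype network collapses duplicate haplotypes into frequency-weighted
nodes and keeps, at each distance class in increasing order, every edge
joining previously disconnected components: a minimum-spanning network
retaining all co-minimal connections (reduced, ε = 0 behavior; no latent
median nodes are inserted, so the network is descriptive rather than the
basis of the event count).

The headline statistic is the Fitch small-parsimony count of Std/Inv state
changes on the NJ tree: 1 is compatible with a unique origin, ≥2 means
recurrence. Parsimony is counted on the tree rather than the network because
network loops preclude a unique count. A recurrent call is annotated with the
longest haplotype block shared between arrangements; blocks of ≤1 kb are
flagged as potentially explained by a gene-conversion tract instead, 1 kb
being the scale above which mammalian conversion tracts are rare.

Ancestral orientation is a vote over the chimpanzee and gorilla calls:
polymorphic (Std/Inv) and undetermined species abstain; two agreeing fixed
states decide; a conflict or no voters gives Unknown; a single voter decides
with a low-confidence annotation.

# What the generator emulates — and what it does not

`simulate_haplotypes` builds a Kingman genealogy, drops Poisson(θ/2 × tree
length) mutations under infinite sites (so fixed and shared classes have
unambiguous ground truth — no back mutation), and places inversion events on
branches. Defaults are the study conditions used throughout: 40 haplotypes,
20 kb regions, θ = 20 per region, inversion frequency 0.3, cohorts of 46
unrelated individuals plus 12 trios, gene-conversion tracts geometric with
mean 518 bp (the high-resolution *Drosophila* estimate; mammalian tracts are
of the same few-hundred-bp order).

Event branches are restricted to branches carrying at least one mutation.
An event on a mutation-free branch leaves no fixed background difference
between arrangements and is unidentifiable from SNP data by *any* method;
the recovery properties quantify how well the pipeline reads identifiable
histories, not how often nature produces unidentifiable ones. For recurrent
histories, k events are placed on branches with pairwise disjoint tip sets
and backgrounds at least `min_background_divergence = 10` mutations apart,
and the combined inverted tip set may not form a clade (nor its complement),
since such a set is explainable by a single event.

The cohort generator pairs haplotypes per Hardy–Weinberg at the configured
frequency, transmits alleles through trios Mendelianly (chrX sons receive a
single maternal X; chrY passes father to son), and can spike a requested
number of child genotypes with transmission-violating values, chosen only at
(trio, marker) slots where a violation is constructible — so every spiked
error is detectable and detection can be required to be 100%.

The region-sequence generator plants exactly one restriction site per unique
segment (scrubbing accidental occurrences), outward-facing 22-mer primers at
fixed distances from the cuts, and identical IR copies in opposite
orientation; the emitted truth product sizes *are* the string-ligation
oracle's output. The fosmid generator is purely geometric: mapping records
are computed from coordinates (reads inside the inverted span map back
reverse-complemented; reads inside an IR copy emit the paralogous placement
at 98% identity), with no sequencing-error or alignment-noise model.

Passing tests on these simulations therefore demonstrate correctness of the
algorithms under idealized mapping and genotyping, identifiability-conditioned
histories, no recombination (other than explicit gene-conversion tracts), no
demography and no genotyping error — not performance on real cohorts, where
phasing error, low coverage and reference artifacts add noise the original
study handled with repeated genotyping and likelihood filters.

# Numerical choices and problem sizes

* Rounding: half away from zero at the final kb step only.
* HWE enumeration in log-space with an `(1 + 1e-9)` tolerance when comparing
  point probabilities, so ties at the observed probability are included.
* EM for two-locus haplotype frequencies: only double heterozygotes are
  ambiguous; 100 iterations, 1e-10 convergence tolerance.
* NJ ties and zero-length branches follow `ape`'s deterministic behavior;
  the two-taxon case returns a single split of the input distance.
* Network edge order: weight, then lower node index — deterministic output.
* Seeds: every generator derives an offset stream from the config seed, so
  toggling one stage does not shift another's draws; the pipeline writes
  byte-identical output for identical seed and configuration.
* Suite sizes: 200 regions for the amplicon oracle, 500 tables for the
  classifier oracle, 200 replicates per recurrence scenario, 2000 null
  cohorts for HWE size, 1000 replicates × 199 permutations for Fst size.
  These sizes give the property checks two-digit resolution while keeping
  the default suite fast.

# Interface notes and limitations

The exported functions and `invrec_pipeline()` are the interface; no shell
entry point is shipped, since users drive the analysis from R. VCF is the
genotype interchange format, with the inversion as a symbolic `<INV>`
pseudo-marker record; PED carries pedigree and sex; haplotypes travel as a
plain TSV matrix. Known limitations: no statistical phasing; no thermodynamic
primer design (placement and uniqueness only); the Fst estimator differs from
AMOVA-based values in low-information cases; median (latent) network nodes
are not inserted; and recurrence counts are lower bounds by construction of
parsimony.
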