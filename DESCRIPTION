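Package: invrec
Title: Genotyping and Recurrence Analysis of Human Polymorphic Inversions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for validating and genotyping polymorphic inversions mediated
    by inverted repeats, and for inferring how often they recur. Implements
    in-silico inverse-PCR (iPCR) assay design (virtual restriction digestion,
    self-ligation circle formation, amplicon prediction for standard and
    inverted alleles) and band-pattern genotype calling; fosmid paired-end
    mapping filtering and orientation-discordance classification; arrangement
    aware population genetics of inversion plus SNP genotypes (allele
    frequency, exact Hardy-Weinberg test, Mendelian trio checks, genotype
    likelihood filtering, linkage disequilibrium and tag SNPs, a conservative
    shared/fixed SNP classifier, nucleotide diversity and Hudson Fst with
    permutation significance); haplotype-based recurrence inference (trio
    phasing, neighbor-joining trees, minimum-spanning haplotype networks,
    Fitch parsimony event counts, ancestral orientation calls); and a
    synthetic-data generator that produces every input with known ground truth
    so the whole pipeline runs without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    phangorn,
    vcfR,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
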