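make_table <- function(calls, sex = NULL, chrom = "autosome", snp = NULL,
                       pos = NULL) {
  n <- length(calls)
  if (is.null(sex)) sex <- rep("female", n)
  samples <- data.frame(sample_id = sprintf("s%d", 1:n), sex = sex,
                        stringsAsFactors = FALSE)
  genotype_table(samples, calls, snp_pos = if (is.null(pos)) numeric(0) else pos,
                 snp_geno = snp, chrom_type = chrom)
}

test_that("inversion frequency and observed heterozygosity, autosomal", {
  tab <- make_table(c(rep("Std/Std", 37), rep("Std/Inv", 9)))
  fh <- allele_freq_het(tab)
  expect_equal(round(fh$inv_freq, 2), 0.10)   # 9 / 92
  expect_equal(round(fh$obs_het, 2), 0.20)    # 9 / 46
  expect_equal(fh$n_chromosomes, 92)
  mono <- allele_freq_het(make_table(rep("Std/Std", 10)))
  expect_equal(mono$inv_freq, 0)
  expect_equal(mono$obs_het, 0)
})

test_that("chrX counting: males contribute one chromosome, heterozygosity from females", {
  calls <- c(rep("Std/Inv", 3), rep("Std/Std", 7), "Inv", rep("Std", 4))
  sex <- c(rep("female", 10), rep("male", 5))
  fh <- allele_freq_het(make_table(calls, sex, chrom = "chrX"))
  expect_equal(fh$inv_freq, 4 / 25)
  expect_equal(fh$obs_het, 0.30)
  expect_equal(fh$n_chromosomes, 25)
})

test_that("unrelated-only counting drops children but keeps parents", {
  samples <- data.frame(sample_id = c("f", "m", "c"),
                        sex = c("male", "female", "female"),
                        father_id = c(NA, NA, "f"), mother_id = c(NA, NA, "m"),
                        stringsAsFactors = FALSE)
  tab <- genotype_table(samples, c("Std/Inv", "Std/Std", "Std/Inv"))
  expect_equal(unrelated_samples(tab), 1:2)
  expect_equal(allele_freq_het(tab)$n_chromosomes, 4)
})

test_that("exact HWE test agrees with full allele-pairing enumeration", {
  expect_equal(hwe_exact_test(1, 2, 1), 1)
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  expect_lt(hwe_exact_test(25, 0, 25), 1e-10)
  # independent oracle: enumerate all pairings of the 2n alleles (n = 4)
  for (cnt in list(c(1, 2, 1), c(2, 2, 0), c(0, 4, 0), c(3, 0, 1))) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_enum_oracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-10,
                 label = paste("counts", paste(cnt, collapse = "/")))
  }
})

test_that("HWE exact test holds its size under null sampling", {
  set.seed(1234)
  rej <- 0; B <- 400
  for (b in seq_len(B)) {
    g <- sample(0:2, 46, replace = TRUE, prob = c(0.81, 0.18, 0.01))
    if (hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2)) <= 0.05)
      rej <- rej + 1
  }
  expect_lte(rej / B, 0.06)
})

test_that("Mendelian transmission checks, including hemizygosity", {
  expect_equal(mendelian_check("Inv/Inv", "Std/Std", "Std/Inv"), "fail")
  for (g in c("Std/Std", "Std/Inv", "Inv/Inv"))
    expect_equal(mendelian_check(g, "Std/Inv", "Std/Inv"), "pass")
  # chrX son draws from the mother only
  expect_equal(mendelian_check("Inv", "Std/Std", "Std/Inv",
                               chrom_type = "chrX", child_sex = "male"),
               "pass")
  expect_equal(mendelian_check("Inv", "Inv/Inv", "Std/Std",
                               chrom_type = "chrX", child_sex = "male"),
               "fail")
  expect_equal(mendelian_check("Std/Inv", NA, NA), "not_evaluable")
  # a single typed parent constrains one allele only
  expect_equal(mendelian_check("Inv/Inv", "Std/Std", NA), "fail")
  expect_equal(mendelian_check("Std/Inv", "Std/Std", NA), "pass")
})

test_that("error-free simulated trios all pass the Mendelian check", {
  cfg <- sim_config(seed = 31)
  hs <- simulate_haplotypes(cfg)
  co <- simulate_cohort(hs$haps, cfg)
  tab <- co$table
  kids <- which(!is.na(tab$samples$father_id))
  expect_equal(length(kids), 12)
  res <- vapply(kids, function(ci) {
    fi <- match(tab$samples$father_id[ci], tab$samples$sample_id)
    mi <- match(tab$samples$mother_id[ci], tab$samples$sample_id)
    mendelian_check(tab$inv_call[ci], tab$inv_call[fi], tab$inv_call[mi])
  }, "")
  expect_equal(sum(res == "pass"), 12)
})

test_that("genotype-likelihood filter keeps the 10x boundary, in both scales", {
  expect_true(gl_filter(c(1, 0.1, 0.001)))            # ratio exactly 10
  expect_false(gl_filter(c(1, 1 / 9.9, 0.001)))       # ratio 9.9
  expect_true(gl_filter(c(0, 10, 100), phred = TRUE)) # 10^(10/10) = 10
  expect_false(gl_filter(c(0, 0, 0)))
})

test_that("r2 from phased haplotypes equals the 2x2 haplotype-count computation", {
  lab <- rep(c("Inv", "Std"), each = 20)
  snp <- c(rep(1, 18), rep(0, 2), rep(1, 2), rep(0, 18))
  haps <- haplotype_set(matrix(snp, ncol = 1), lab, positions = 500)
  ld <- ld_r2_tags(haps)
  expect_equal(ld$r2, 0.64)
  # a perfectly coupled SNP is a tag
  tag <- haplotype_set(cbind(as.integer(lab == "Inv")), lab, positions = 7)
  expect_true(ld_r2_tags(tag)$tag)
  # monomorphic SNP excluded
  mono <- haplotype_set(cbind(rep(0L, 40)), lab)
  expect_equal(nrow(ld_r2_tags(mono)), 0)
})

test_that("EM haplotype frequencies from unphased genotypes match phased r2", {
  set.seed(77)
  for (rep in 1:5) {
    lab <- sample(c("Std", "Inv"), 60, replace = TRUE, prob = c(.6, .4))
    snp <- ifelse(lab == "Inv", rbinom(60, 1, 0.9), rbinom(60, 1, 0.1))
    haps <- haplotype_set(cbind(snp), lab, positions = 1)
    phased_r2 <- ld_r2_tags(haps)$r2
    # pair haplotypes randomly into diploids
    idx <- matrix(sample(60), ncol = 2)
    calls <- apply(idx, 1, function(p)
      invrec:::geno_string(lab[p[1]], lab[p[2]]))
    dos <- snp[idx[, 1]] + snp[idx[, 2]]
    tab <- make_table(calls, snp = cbind(as.integer(dos)), pos = 1)
    em_r2 <- ld_r2_tags(tab)$r2
    expect_equal(em_r2, phased_r2, tolerance = 0.12)
  }
})

test_that("shared/fixed classifier follows the conservative allele-set rule", {
  # Std/Std {AA, aa} and Inv/Inv {AA, aa} -> shared
  tab <- make_table(c("Std/Std", "Std/Std", "Inv/Inv", "Inv/Inv"),
                    snp = cbind(c(0L, 2L, 0L, 2L)), pos = 1)
  expect_equal(classify_snps_fixed_shared(tab)$classes$class, "shared")
  # Std/Std all AA, Inv/Inv all aa, Std/Inv all Aa -> fixed
  tab2 <- make_table(c("Std/Std", "Std/Std", "Inv/Inv", "Std/Inv"),
                     snp = cbind(c(0L, 0L, 2L, 1L)), pos = 1)
  expect_equal(classify_snps_fixed_shared(tab2)$classes$class, "fixed")
  expect_equal(classify_snps_fixed_shared(tab2)$classes$ambiguous_dropped, 1L)
  # heterozygote homozygous at the SNP places the allele on both arrangements
  tab3 <- make_table(c("Std/Std", "Std/Std", "Inv/Inv", "Std/Inv"),
                     snp = cbind(c(0L, 2L, 0L, 2L)), pos = 1)
  expect_equal(classify_snps_fixed_shared(tab3)$classes$class, "shared")
  expect_error(classify_snps_fixed_shared(
    make_table(c(NA, NA), snp = cbind(c(0L, 1L)), pos = 1)), "no inversion")
})

test_that("classifier agrees with phase-assignment enumeration on random tables", {
  for (seed in 1:60) {
    tab <- random_small_table(seed)
    got <- classify_snps_fixed_shared(tab)$classes
    oracle <- phase_enum_oracle(tab)
    expect_equal(got$class == "shared", oracle$shared_always,
                 label = paste("shared, seed", seed))
    fixed <- which(got$class == "fixed")
    expect_true(all(oracle$exists_disjoint[fixed]),
                label = paste("fixed, seed", seed))
  }
})

test_that("nucleotide diversity from pairwise differences", {
  H <- rbind(c(0, 0), c(0, 0))
  same <- haplotype_set(H, c("Std", "Std"))
  expect_equal(nucleotide_diversity(same, 100)$pi_all, 0)
  two <- haplotype_set(rbind(c(0, 0), c(1, 1)), c("Std", "Inv"))
  expect_equal(nucleotide_diversity(two, 100)$pi_all, 0.02)
  # four haplotypes over 10 sites with pairwise diffs {0,1,1,1,1,0}
  H4 <- rbind(c(0, 0), c(0, 0), c(1, 0), c(1, 0))
  d4 <- nucleotide_diversity(haplotype_set(H4, c("Std", "Std", "Inv", "Inv")),
                             10)
  expect_equal(d4$pi_all, (4 / 6) / 10)
  # an arrangement with < 2 haplotypes reports NA
  one <- haplotype_set(rbind(c(0, 0), c(1, 1), c(1, 0)),
                       c("Std", "Std", "Inv"))
  expect_true(is.na(nucleotide_diversity(one, 10)$pi_inv))
  expect_error(nucleotide_diversity(two, 0), "positive")
})

test_that("Hudson Fst estimator and its limits", {
  # within-diversity 2 on both sides, between-diversity 4 -> Fst 0.5
  D <- rbind(c(0, 2, 4, 4), c(2, 0, 4, 4), c(4, 4, 0, 2), c(4, 4, 2, 0))
  expect_equal(invrec:::hudson_fst_from_D(D, 1:2, 3:4), 0.5)
  # distinct fixed haplotypes: Fst = 1
  Hf <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  hps <- haplotype_set(Hf, c("Std", "Std", "Inv", "Inv"))
  f <- fst_arrangements(hps, n_permutations = 99, seed = 1)
  expect_equal(f$fst, 1)
  expect_error(fst_arrangements(haplotype_set(Hf, c("Std", "Std", "Std",
                                                    "Inv")), 10),
               "two haplotypes")
})

test_that("Fst permutation p-value holds its level under label exchange", {
  set.seed(99)
  rej <- 0; B <- 300
  for (b in seq_len(B)) {
    H <- matrix(rbinom(20 * 25, 1, 0.3), 20, 25)
    hp <- haplotype_set(H, rep(c("Std", "Inv"), each = 10))
    if (fst_arrangements(hp, n_permutations = 99, seed = b)$p_value <= 0.05)
      rej <- rej + 1
  }
  expect_lte(rej / B, 0.08)
})
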