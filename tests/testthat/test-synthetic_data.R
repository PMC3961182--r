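test_that("generators are seed-deterministic", {
  cfg <- sim_config(seed = 17)
  a <- simulate_haplotypes(cfg)
  b <- simulate_haplotypes(cfg)
  expect_identical(a$haps$haplotypes, b$haps$haplotypes)
  expect_identical(a$truth$labels, b$truth$labels)
  ca <- simulate_cohort(a$haps, cfg)
  cb <- simulate_cohort(b$haps, cfg)
  expect_identical(ca$table$snp_geno, cb$table$snp_geno)
  ra <- simulate_region_sequence(17)
  rb <- simulate_region_sequence(17)
  expect_identical(ra$std_seq, rb$std_seq)
  fa <- simulate_fosmid_pairs(fosmid_region_template(), "Std/Inv", seed = 17)
  fb <- simulate_fosmid_pairs(fosmid_region_template(), "Std/Inv", seed = 17)
  expect_identical(fa$mappings, fb$mappings)
})

test_that("theta = 0 gives identical haplotypes and no SNPs", {
  cfg <- sim_config(seed = 3, theta = 0)
  hs <- simulate_haplotypes(cfg)
  expect_equal(ncol(hs$haps$haplotypes), 0)
  expect_equal(hs$truth$event_count, 1)
})

test_that("single-origin histories never produce shared SNPs", {
  for (seed in 1:25) {
    cfg <- sim_config(seed = seed)
    hs <- simulate_haplotypes(cfg)
    co <- simulate_cohort(hs$haps, cfg)
    s <- classify_snps_fixed_shared(co$table)$summary
    expect_equal(s[["shared"]], 0L, label = paste("seed", seed))
  }
})

test_that("recurrent histories carry their configured event count in the truth", {
  cfg <- sim_config(seed = 9,
                    inversion_scenario = list(type = "recurrent", k_events = 2,
                                              min_background_divergence = 10))
  hs <- simulate_haplotypes(cfg)
  expect_equal(hs$truth$event_count, 2)
  expect_equal(length(hs$truth$event_branches), 2)
  # impossible requests error with advice
  expect_error(simulate_haplotypes(
    sim_config(seed = 9, theta = 0,
               inversion_scenario = list(type = "recurrent", k_events = 2,
                                         min_background_divergence = 10))),
    "theta")
})

test_that("gene conversion copies tracts between arrangements", {
  cfg <- sim_config(seed = 13, gene_conversion = list(rate = 1,
                                                      tract_mean_bp = 518))
  hs <- simulate_haplotypes(cfg)
  expect_gt(nrow(hs$truth$conversion_tracts), 0)
  # converted regions can create shared SNPs, so sharing is no longer barred
  expect_true(is.matrix(hs$haps$haplotypes))
})

test_that("cohort pairing respects the configured inversion frequency (HWE)", {
  cfg <- sim_config(seed = 23, inversion_frequency = 0.3, n_individuals = 500,
                    n_trios = 0)
  hs <- simulate_haplotypes(cfg)
  co <- simulate_cohort(hs$haps, cfg)
  het <- mean(co$table$inv_call == "Std/Inv")
  p <- 2 * 0.3 * 0.7
  expect_lt(abs(het - p), 3 * sqrt(p * (1 - p) / 500))
  fh <- allele_freq_het(co$table)
  expect_lt(abs(fh$inv_freq - 0.3), 3 * sqrt(0.3 * 0.7 / 1000))
  # frequency zero: everyone Std/Std
  cfg0 <- sim_config(seed = 23, inversion_frequency = 0, n_individuals = 20,
                     n_trios = 0)
  co0 <- simulate_cohort(hs$haps, cfg0)
  expect_true(all(co0$table$inv_call == "Std/Std"))
})

test_that("chrX cohorts give males a single haplotype", {
  cfg <- sim_config(seed = 29, chrom_type = "chrX", n_individuals = 30,
                    n_trios = 4)
  hs <- simulate_haplotypes(cfg)
  co <- simulate_cohort(hs$haps, cfg)
  tab <- co$table
  males <- tab$samples$sex == "male"
  expect_true(all(tab$ploidy[males] == 1))
  expect_true(all(tab$inv_call[males] %in% c("Std", "Inv")))
  expect_true(all(tab$snp_geno[males, ] <= 1, na.rm = TRUE))
  # chrX transmission is Mendelian-consistent
  kids <- which(!is.na(tab$samples$father_id))
  for (ci in kids) {
    fi <- match(tab$samples$father_id[ci], tab$samples$sample_id)
    mi <- match(tab$samples$mother_id[ci], tab$samples$sample_id)
    expect_equal(mendelian_check(tab$inv_call[ci], tab$inv_call[fi],
                                 tab$inv_call[mi], chrom_type = "chrX",
                                 child_sex = tab$samples$sex[ci]), "pass")
  }
})

test_that("spiked Mendelian errors are always detectable and all detected", {
  cfg <- sim_config(seed = 37)
  hs <- simulate_haplotypes(cfg)
  co <- simulate_cohort(hs$haps, cfg, n_mendel_errors = 8)
  tab <- co$table
  spiked <- co$truth$spiked
  expect_equal(nrow(spiked), 8)
  code <- c("0" = "A/A", "1" = "A/B", "2" = "B/B")
  flagged <- vapply(seq_len(nrow(spiked)), function(k) {
    ci <- match(spiked$sample[k], tab$samples$sample_id)
    fi <- match(tab$samples$father_id[ci], tab$samples$sample_id)
    mi <- match(tab$samples$mother_id[ci], tab$samples$sample_id)
    m <- spiked$marker[k]
    mendelian_check(code[[as.character(tab$snp_geno[ci, m])]],
                    code[[as.character(tab$snp_geno[fi, m])]],
                    code[[as.character(tab$snp_geno[mi, m])]])
  }, "")
  expect_true(all(flagged == "fail"))
})

test_that("planted-assay regions genotype correctly end to end", {
  rs <- simulate_region_sequence(41)
  a <- predict_amplicons(rs$assay, rs$std_seq, rs$inv_seq)
  # the emitted truth is the string-ligation oracle
  expect_identical(a$predicted_products$std, rs$truth_products$std)
  expect_identical(a$predicted_products$inv, rs$truth_products$inv)
  expect_false(any(c("AC", "BD") %in% names(rs$truth_products$std)))
  expect_false(any(c("AB", "CD") %in% names(rs$truth_products$inv)))
})

test_that("planted PSV exchange is recovered by breakpoint refinement", {
  sim <- simulate_psv_alignment(19, n_cols = 300,
                                psv_cols = seq(15, 285, by = 15),
                                exchange_after = 150)
  ref <- refine_breakpoints_psv(sim$std, sim$inv)
  expect_equal(ref$flag, "refined")
  expect_equal(ref$start, max(setdiff(seq(15, 285, 15),
                                      sim$truth$exchanged_cols)))
  expect_equal(ref$end, min(sim$truth$exchanged_cols))
})

test_that("fosmid geometry: inserts longer than the region are rejected", {
  r <- toy_region()
  expect_error(simulate_fosmid_pairs(r, "Std/Std", insert_mean = 40000),
               "insert")
  expect_error(simulate_fosmid_pairs(fosmid_region_template(), "missing"),
               "uncalled")
})
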