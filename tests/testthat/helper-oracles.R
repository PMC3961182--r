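# Independent oracles and small fixture builders used across the suite.

toy_region <- function(chrom = "chr1") {
  gi <- function(s, e) genomic_interval(chrom, s, e)
  inversion_region("ToyInv",
                   a = gi(1, 1000), ir1 = gi(1001, 1200), b = gi(1201, 2000),
                   c = gi(2001, 2800), ir2 = gi(2801, 3000),
                   d = gi(3001, 4000))
}

# Brute-force allele-pairing enumeration of the conditional heterozygote-count
# distribution: all orderings of the 2n alleles, paired consecutively.
hwe_enum_oracle <- function(n_aa, n_ab, n_bb) {
  alleles <- c(rep(0L, 2 * n_aa + n_ab), rep(1L, 2 * n_bb + n_ab))
  n2 <- length(alleles)
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    out <- NULL
    for (i in seq_along(v))
      out <- rbind(out, cbind(v[i], perms(v[-i])))
    out
  }
  P <- perms(seq_len(n2))
  hets <- apply(P, 1, function(idx) {
    a <- alleles[idx]
    sum(a[seq(1, n2, 2)] != a[seq(2, n2, 2)])
  })
  tab <- table(hets) / length(hets)
  obs_p <- tab[[as.character(n_ab)]]
  sum(tab[tab <= obs_p + 1e-12])
}

# Enumeration over all phase-consistent haplotype assignments of a genotype
# table: for each SNP, whether it is shared in EVERY assignment and whether
# some assignment yields non-empty disjoint arrangement allele sets.
phase_enum_oracle <- function(tab) {
  n <- nrow(tab$samples)
  res <- data.frame(shared_always = logical(length(tab$snp_pos)),
                    exists_disjoint = logical(length(tab$snp_pos)))
  for (j in seq_along(tab$snp_pos)) {
    fixed_std <- integer(0); fixed_inv <- integer(0)
    amb <- list()   # each: the two alleles of a Std/Inv double heterozygote
    for (i in seq_len(n)) {
      g <- tab$inv_call[i]
      if (is.na(g) || g == "missing") next
      d <- tab$snp_geno[i, j]
      if (is.na(d)) next
      al <- if (tab$ploidy[i] == 1) d else
        switch(as.character(d), "0" = c(0L, 0L), "1" = c(0L, 1L),
               "2" = c(1L, 1L))
      if (g %in% c("Std/Std", "Std")) fixed_std <- c(fixed_std, al)
      else if (g %in% c("Inv/Inv", "Inv")) fixed_inv <- c(fixed_inv, al)
      else if (g == "Std/Inv") {
        if (length(unique(al)) == 1L) {
          fixed_std <- c(fixed_std, al[1]); fixed_inv <- c(fixed_inv, al[1])
        } else amb[[length(amb) + 1L]] <- al
      }
    }
    k <- length(amb)
    shared_always <- TRUE; exists_disjoint <- FALSE
    for (mask in seq_len(2^k) - 1L) {
      s <- fixed_std; v <- fixed_inv
      for (b in seq_len(k)) {
        if (bitwAnd(mask, bitwShiftL(1L, b - 1L)) > 0) {
          s <- c(s, amb[[b]][1]); v <- c(v, amb[[b]][2])
        } else {
          s <- c(s, amb[[b]][2]); v <- c(v, amb[[b]][1])
        }
      }
      su <- unique(s); vu <- unique(v)
      if (!(all(0:1 %in% su) && all(0:1 %in% vu))) shared_always <- FALSE
      if (length(su) && length(vu) && length(intersect(su, vu)) == 0)
        exists_disjoint <- TRUE
    }
    res$shared_always[j] <- shared_always
    res$exists_disjoint[j] <- exists_disjoint
  }
  res
}

random_small_table <- function(seed) {
  set.seed(seed)
  n <- sample(3:8, 1)
  m <- sample(2:6, 1)
  samples <- data.frame(sample_id = sprintf("s%d", 1:n),
                        sex = sample(c("male", "female"), n, replace = TRUE),
                        stringsAsFactors = FALSE)
  inv <- sample(c("Std/Std", "Std/Inv", "Inv/Inv"), n, replace = TRUE)
  geno <- matrix(sample(c(0:2, NA), n * m, replace = TRUE,
                        prob = c(.3, .3, .3, .1)), n, m)
  genotype_table(samples, inv, snp_pos = seq_len(m) * 100, snp_geno = geno)
}

# mapping-record row builder
hit <- function(chrom = "chr1", start, end, strand, identity = 99,
                score = 1000, read_id = "f1", mate = 1) {
  data.frame(read_id = read_id, mate = mate, chrom = chrom, start = start,
             end = end, strand = strand, identity = identity, score = score,
             stringsAsFactors = FALSE)
}

hap_distance_matrix <- function(haps) {
  H <- haps$haplotypes
  D <- as.matrix(stats::dist(H, method = "manhattan"))
  rownames(D) <- colnames(D) <- sprintf("h%02d", seq_len(nrow(H)))
  D
}
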