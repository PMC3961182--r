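#' Genotype table: inversion + SNP genotypes for a cohort
#'
#' Samples by markers container used by the population-genetic operations.
#' SNP genotypes are stored as counts of the alternate allele (0/1/2 for
#' diploids, 0/1 for hemizygous chrX males and chrY), with NA for missing.
#'
#' @param samples data.frame with sample_id, sex ("male"/"female"/"unknown"),
#'   and optional population, father_id, mother_id columns (NA when absent).
#' @param inv_call Character vector, one inversion genotype per sample
#'   ("Std/Std", "Std/Inv", "Inv/Inv", hemizygous "Std"/"Inv", or NA).
#' @param snp_pos Numeric positions of the SNPs (bp).
#' @param snp_geno Integer matrix samples x SNPs of alt-allele dosages.
#' @param gl Optional samples x SNPs x 3 array of genotype likelihoods
#'   (ref-hom, het, alt-hom).
#' @param chrom_type "autosome", "chrX" or "chrY".
#' @return An object of class \code{genotype_table}.
#' @export
genotype_table <- function(samples, inv_call, snp_pos = numeric(0),
                           snp_geno = NULL, gl = NULL,
                           chrom_type = c("autosome", "chrX", "chrY")) {
  chrom_type <- match.arg(chrom_type)
  n <- nrow(samples)
  stopifnot(length(inv_call) == n)
  for (col in c("population", "father_id", "mother_id"))
    if (is.null(samples[[col]])) samples[[col]] <- NA_character_
  bad <- setdiff(stats::na.omit(c(samples$father_id, samples$mother_id)),
                 samples$sample_id)
  if (length(bad)) stop("pedigree links to unknown samples: ",
                        paste(bad, collapse = ", "))
  if (is.null(snp_geno)) snp_geno <- matrix(NA_integer_, n, 0)
  stopifnot(nrow(snp_geno) == n, ncol(snp_geno) == length(snp_pos))
  ploidy <- rep(2L, n)
  if (chrom_type == "chrX") ploidy[samples$sex == "male"] <- 1L
  if (chrom_type == "chrY") ploidy <- ifelse(samples$sex == "male", 1L, 0L)
  rownames(snp_geno) <- samples$sample_id
  structure(list(samples = samples, inv_call = inv_call, snp_pos = snp_pos,
                 snp_geno = snp_geno, gl = gl, chrom_type = chrom_type,
                 ploidy = ploidy),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d samples (%s), %d SNPs, inversion calls: %s\n",
              nrow(x$samples), x$chrom_type, length(x$snp_pos),
              paste(names(table(x$inv_call)), table(x$inv_call),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' Indices of unrelated samples
#'
#' Children (samples with a recorded parent in the table) are excluded, so one
#' member of each parent-child pair and both parents of each trio remain.
#'
#' @param table A \code{\link{genotype_table}}.
#' @return Integer indices of the unrelated samples.
#' @export
unrelated_samples <- function(table) {
  s <- table$samples
  which(!(s$father_id %in% s$sample_id | s$mother_id %in% s$sample_id))
}

#' Inversion allele frequency and observed heterozygosity
#'
#' Frequency of the inverted allele over all counted chromosomes: males
#' contribute one chromosome on chrX/chrY, everyone else two. Observed
#' heterozygosity is the fraction of heterozygous diploid genotypes (females
#' only on chrX; undefined on chrY). By default only unrelated individuals are
#' counted.
#'
#' @param table A \code{\link{genotype_table}}.
#' @param unrelated_only Drop children first (default TRUE).
#' @return list(inv_freq, obs_het, n_chromosomes, n_het_individuals).
#' @export
allele_freq_het <- function(table, unrelated_only = TRUE) {
  idx <- if (unrelated_only) unrelated_samples(table) else
    seq_len(nrow(table$samples))
  calls <- table$inv_call[idx]
  ploidy <- table$ploidy[idx]
  ok <- !is.na(calls) & calls != "missing" & ploidy > 0
  calls <- calls[ok]; ploidy <- ploidy[ok]
  n_chrom <- sum(ploidy)
  if (n_chrom == 0) stop("no callable chromosomes")
  n_inv <- sum(vapply(calls, function(g) sum(geno_alleles(g) == "Inv"), 0))
  dip <- ploidy == 2
  obs_het <- if (any(dip)) mean(calls[dip] == "Std/Inv") else NA_real_
  list(inv_freq = n_inv / n_chrom, obs_het = obs_het,
       n_chromosomes = n_chrom, n_het_individuals = sum(calls == "Std/Inv"))
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Two-sided conditional exact test (Levene/Haldane): conditioning on the
#' observed allele counts, the p-value is the sum of the probabilities of all
#' heterozygote counts whose conditional probability does not exceed that of
#' the observed count. Monomorphic samples return 1.
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major-hom, het, minor-hom).
#' @return p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  if (n < 1) stop("need at least one individual")
  na <- 2 * n_aa + n_ab
  nb <- 2 * n_bb + n_ab
  if (na == 0 || nb == 0) return(1)
  hets <- seq(na %% 2, min(na, nb), by = 2)
  logp <- vapply(hets, function(h) {
    aa <- (na - h) / 2; bb <- (nb - h) / 2
    lgamma(n + 1) - lgamma(aa + 1) - lgamma(h + 1) - lgamma(bb + 1) +
      h * log(2) + lgamma(na + 1) + lgamma(nb + 1) - lgamma(2 * n + 1)
  }, 0)
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-9)]))
}

#' Mendelian transmission check for one marker in a trio
#'
#' Passes when the child's alleles can be drawn one from each parent.
#' Hemizygosity aware: chrX sons draw their single allele from the mother
#' only; chrX daughters draw one allele from the father's single X and one
#' from the mother; chrY sons draw from the father. A missing child genotype
#' (or both parents missing) is not evaluable; a single missing parent is
#' treated as unconstrained.
#'
#' @param child,father,mother Genotype strings over the Std/Inv alphabet (or
#'   any two-allele coding accepted by the same format, e.g. "A/B").
#' @param chrom_type "autosome", "chrX" or "chrY".
#' @param child_sex Required for sex chromosomes.
#' @return "pass", "fail" or "not_evaluable".
#' @export
mendelian_check <- function(child, father = NA, mother = NA,
                            chrom_type = "autosome", child_sex = NULL) {
  alle <- function(g) {
    if (is.na(g) || identical(g, "missing")) return(NULL)
    strsplit(g, "/", fixed = TRUE)[[1]]
  }
  ch <- alle(child); fa <- alle(father); mo <- alle(mother)
  if (is.null(ch) || (is.null(fa) && is.null(mo))) return("not_evaluable")
  if (chrom_type == "chrX" && identical(child_sex, "male")) {
    if (length(ch) != 1) return("not_evaluable")
    if (is.null(mo)) return("not_evaluable")
    return(if (ch %in% mo) "pass" else "fail")
  }
  if (chrom_type == "chrY") {
    if (length(ch) != 1 || is.null(fa)) return("not_evaluable")
    return(if (ch %in% fa) "pass" else "fail")
  }
  if (length(ch) != 2) return("not_evaluable")
  ok_from <- function(a, par) is.null(par) || a %in% par
  if ((ok_from(ch[1], fa) && ok_from(ch[2], mo)) ||
      (ok_from(ch[2], fa) && ok_from(ch[1], mo))) "pass" else "fail"
}

#' Genotype-likelihood confidence filter
#'
#' Keeps a genotype call when the likelihood of the called (most likely)
#' genotype is at least \code{min_ratio} times that of the second most likely
#' one. Input may be raw likelihoods or phred-scaled likelihoods (PL field
#' convention: -10 log10 L, minimum 0).
#'
#' @param gl Numeric vector of three genotype likelihoods.
#' @param min_ratio Minimum best/second ratio (default 10; the boundary
#'   ratio of exactly 10 is kept).
#' @param phred Is \code{gl} phred-scaled?
#' @return TRUE (keep) or FALSE (discard).
#' @export
gl_filter <- function(gl, min_ratio = 10, phred = FALSE) {
  stopifnot(length(gl) == 3)
  if (phred) gl <- 10^(-gl / 10)
  if (any(gl < 0)) stop("likelihoods must be non-negative")
  s <- sort(gl, decreasing = TRUE)
  if (s[1] == 0) return(FALSE)
  if (s[2] == 0) return(TRUE)
  s[1] / s[2] >= min_ratio * (1 - 1e-12)
}

## EM for two-locus haplotype frequencies from unphased diploid dosages.
## gA, gB: 0/1/2 vectors; returns 2x2 haplotype frequency matrix
## [allele at A (0/1), allele at B (0/1)].
em_haplotype_freqs <- function(gA, gB, max_iter = 100, tol = 1e-10) {
  ok <- !is.na(gA) & !is.na(gB)
  gA <- gA[ok]; gB <- gB[ok]
  n <- length(gA)
  pA <- mean(gA) / 2; pB <- mean(gB) / 2
  h <- c(p00 = (1 - pA) * (1 - pB), p01 = (1 - pA) * pB,
         p10 = pA * (1 - pB), p11 = pA * pB)
  dh <- gA == 1 & gB == 1          # double heterozygotes: phase unknown
  n_dh <- sum(dh)
  ## haplotype counts from individuals het at no more than one locus, whose
  ## two haplotypes are fully determined
  cnt <- c(0, 0, 0, 0)             # order 00, 01, 10, 11
  for (i in which(!dh)) {
    ha <- switch(as.character(gA[i]), "0" = c(0, 0), "1" = c(0, 1),
                 "2" = c(1, 1))
    hb <- switch(as.character(gB[i]), "0" = c(0, 0), "1" = c(0, 1),
                 "2" = c(1, 1))
    for (k in 1:2) {
      idx <- ha[k] * 2 + hb[k] + 1
      cnt[idx] <- cnt[idx] + 1
    }
  }
  if (n_dh == 0) {
    h <- cnt / sum(cnt)
    names(h) <- c("p00", "p01", "p10", "p11")
    return(matrix(h, 2, 2, byrow = TRUE))
  }
  for (it in seq_len(max_iter)) {
    ## E step: split double hets between cis (00/11) and trans (01/10)
    cis <- h["p00"] * h["p11"]; trans <- h["p01"] * h["p10"]
    w <- if (cis + trans == 0) 0.5 else cis / (cis + trans)
    e <- cnt
    e[1] <- e[1] + n_dh * w; e[4] <- e[4] + n_dh * w
    e[2] <- e[2] + n_dh * (1 - w); e[3] <- e[3] + n_dh * (1 - w)
    hn <- e / sum(e)
    names(hn) <- names(h)
    if (max(abs(hn - h)) < tol) { h <- hn; break }
    h <- hn
  }
  matrix(h, 2, 2, byrow = TRUE)
}

r2_from_hapfreq <- function(H) {
  pA <- H[2, 1] + H[2, 2]; pB <- H[1, 2] + H[2, 2]
  den <- pA * (1 - pA) * pB * (1 - pB)
  if (den == 0) return(NA_real_)
  D <- H[2, 2] - pA * pB
  D^2 / den
}

#' Linkage disequilibrium between an inversion and SNPs; tag SNP detection
#'
#' Computes r-squared between the inversion and each SNP. With phased data
#' (a \code{\link{haplotype_set}} whose labels give the arrangement), r-squared
#' comes directly from the 2x2 haplotype count table; with an unphased
#' \code{\link{genotype_table}}, two-locus haplotype frequencies are estimated
#' by EM first. SNPs in perfect LD (r-squared equal to \code{tag_threshold})
#' are reported as tag SNPs; those at or above \code{high_threshold} as
#' high-LD. Monomorphic markers are excluded.
#'
#' @param x A \code{\link{haplotype_set}} or \code{\link{genotype_table}}.
#' @param tag_threshold r-squared defining a tag SNP (default 1).
#' @param high_threshold r-squared defining high LD (default 0.9).
#' @return data.frame with pos, r2, tag, high_ld (excluded SNPs dropped).
#' @export
ld_r2_tags <- function(x, tag_threshold = 1, high_threshold = 0.9) {
  if (inherits(x, "haplotype_set")) {
    inv <- as.integer(x$labels == "Inv")
    keep <- x$labels %in% c("Std", "Inv")
    inv <- inv[keep]
    H <- x$haplotypes[keep, , drop = FALSE]
    pos <- x$positions
    r2 <- vapply(seq_len(ncol(H)), function(j) {
      s <- H[, j]
      tab <- matrix(0, 2, 2)
      for (k in seq_along(s)) tab[inv[k] + 1, s[k] + 1] <-
          tab[inv[k] + 1, s[k] + 1] + 1
      r2_from_hapfreq(tab / sum(tab))
    }, 0)
  } else if (inherits(x, "genotype_table")) {
    g_inv <- vapply(x$inv_call, function(g) {
      a <- geno_alleles(g)
      if (length(a) == 0) NA_integer_ else sum(a == "Inv") * (2L / length(a))
    }, 0)
    dip <- x$ploidy == 2
    pos <- x$snp_pos
    r2 <- vapply(seq_len(ncol(x$snp_geno)), function(j) {
      H <- em_haplotype_freqs(g_inv[dip], x$snp_geno[dip, j])
      r2_from_hapfreq(H)
    }, 0)
  } else stop("unsupported input")
  out <- data.frame(pos = pos, r2 = r2)
  out <- out[!is.na(out$r2), , drop = FALSE]
  out$tag <- out$r2 >= tag_threshold - 1e-9
  out$high_ld <- out$r2 >= high_threshold - 1e-9
  rownames(out) <- NULL
  out
}

snp_alleles_of <- function(dosage, ploidy) {
  ## alleles (0 = ref, 1 = alt) carried by one genotype
  if (is.na(dosage)) return(integer(0))
  if (ploidy == 1) return(as.integer(dosage))
  switch(as.character(dosage), "0" = c(0L, 0L), "1" = c(0L, 1L),
         "2" = c(1L, 1L), integer(0))
}

#' Conservative shared/fixed classification of SNPs between arrangements
#'
#' Classifies each SNP without phasing, using only unambiguous chromosome
#' assignments: inversion homozygotes contribute both SNP alleles to their
#' arrangement, hemizygotes their single allele, and inversion heterozygotes
#' contribute only when homozygous at the SNP (then the allele is known to sit
#' on one Std and one Inv chromosome). A SNP is \emph{shared} when both its
#' alleles occur in both arrangement sets, \emph{fixed} when the two sets are
#' non-empty and disjoint, \emph{polymorphic_one_arrangement} when both
#' alleles occur in exactly one set, and uninformative otherwise. Because
#' doubly heterozygous individuals are ignored, shared/fixed counts are
#' minimum estimates; SNPs where such individuals exist are flagged.
#'
#' @param table A \code{\link{genotype_table}} with inversion and SNP calls.
#' @return list with \code{classes} (data.frame pos, class, evidence,
#'   ambiguous_dropped) and \code{summary} (counts per class).
#' @export
classify_snps_fixed_shared <- function(table) {
  calls <- table$inv_call
  if (all(is.na(calls) | calls == "missing"))
    stop("no inversion-genotyped samples")
  n_snp <- ncol(table$snp_geno)
  cls <- character(n_snp); ev <- character(n_snp); amb <- integer(n_snp)
  for (j in seq_len(n_snp)) {
    std <- integer(0); inv <- integer(0); dropped <- 0L
    for (i in seq_len(nrow(table$samples))) {
      g <- calls[i]
      if (is.na(g) || g == "missing") next
      al <- snp_alleles_of(table$snp_geno[i, j], table$ploidy[i])
      if (length(al) == 0) next
      if (g == "Std/Std") std <- c(std, al)
      else if (g == "Inv/Inv") inv <- c(inv, al)
      else if (g == "Std") std <- c(std, al)
      else if (g == "Inv") inv <- c(inv, al)
      else if (g == "Std/Inv") {
        if (length(unique(al)) == 1L) {     # SNP-homozygous het: both sides
          std <- c(std, al[1]); inv <- c(inv, al[1])
        } else dropped <- dropped + 1L      # doubly heterozygous: no phase
      }
    }
    s <- sort(unique(std)); v <- sort(unique(inv))
    both <- c(0L, 1L)
    cls[j] <- if (length(s) && length(v) && all(both %in% s) &&
                  all(both %in% v)) "shared"
    else if (length(s) && length(v) && length(intersect(s, v)) == 0L) "fixed"
    else if (xor(all(both %in% s), all(both %in% v)))
      "polymorphic_one_arrangement"
    else "uninformative"
    ev[j] <- sprintf("Std={%s} Inv={%s}", paste(s, collapse = ","),
                     paste(v, collapse = ","))
    amb[j] <- dropped
  }
  classes <- data.frame(pos = table$snp_pos, class = cls, evidence = ev,
                        ambiguous_dropped = amb)
  summary <- c(fixed = sum(cls == "fixed"), shared = sum(cls == "shared"),
               polymorphic_one_arrangement =
                 sum(cls == "polymorphic_one_arrangement"),
               uninformative = sum(cls == "uninformative"))
  list(classes = classes, summary = summary)
}
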