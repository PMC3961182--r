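#' Phased haplotypes labeled by arrangement
#'
#' Binary haplotype matrix (rows = chromosomes, columns = biallelic sites,
#' entries 0 = ancestral/reference, 1 = derived/alternate) with one
#' arrangement label per haplotype: "Std", "Inv" or "outgroup".
#'
#' @param haplotypes 0/1 matrix, haplotypes in rows.
#' @param labels Character vector of arrangement labels, one per row.
#' @param positions Optional site positions in bp.
#' @param sample_origin Optional vector naming the sample each haplotype came
#'   from.
#' @return An object of class \code{haplotype_set}.
#' @export
haplotype_set <- function(haplotypes, labels,
                          positions = seq_len(ncol(haplotypes)),
                          sample_origin = NULL) {
  haplotypes <- as.matrix(haplotypes)
  stopifnot(nrow(haplotypes) == length(labels),
            ncol(haplotypes) == length(positions),
            all(labels %in% c("Std", "Inv", "outgroup")))
  structure(list(haplotypes = haplotypes, labels = labels,
                 positions = positions, sample_origin = sample_origin),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat(sprintf("<haplotype_set> %d haplotypes (%s) x %d sites\n",
              nrow(x$haplotypes),
              paste(names(table(x$labels)), table(x$labels), sep = "=",
                    collapse = ", "),
              ncol(x$haplotypes)))
  invisible(x)
}

## pairwise difference-count matrix of a 0/1 haplotype matrix
hamming_matrix <- function(H) {
  H <- as.matrix(H)
  k <- rowSums(H)
  cross <- tcrossprod(H)
  outer(k, k, "+") - 2 * cross
}

#' Nucleotide diversity per arrangement
#'
#' Average number of pairwise differences between haplotypes, divided by the
#' number of surveyed sites, overall and within each arrangement. An
#' arrangement with fewer than two haplotypes gets NA (reported as a dash in
#' the source tables).
#'
#' @param haps A \code{\link{haplotype_set}}.
#' @param n_sites Length of the surveyed region in bp (the denominator; not
#'   the number of segregating sites).
#' @return list(pi_all, pi_std, pi_inv).
#' @export
nucleotide_diversity <- function(haps, n_sites) {
  if (n_sites <= 0) stop("n_sites must be positive")
  keep <- haps$labels %in% c("Std", "Inv")
  H <- haps$haplotypes[keep, , drop = FALSE]
  lab <- haps$labels[keep]
  if (nrow(H) < 2) stop("need at least two haplotypes")
  D <- hamming_matrix(H)
  pi_of <- function(idx) {
    if (length(idx) < 2) return(NA_real_)
    mean(D[idx, idx][upper.tri(D[idx, idx])]) / n_sites
  }
  list(pi_all = pi_of(seq_len(nrow(H))),
       pi_std = pi_of(which(lab == "Std")),
       pi_inv = pi_of(which(lab == "Inv")))
}

hudson_fst_from_D <- function(D, g1, g2) {
  w1 <- if (length(g1) > 1) mean(D[g1, g1][upper.tri(D[g1, g1])]) else NA
  w2 <- if (length(g2) > 1) mean(D[g2, g2][upper.tri(D[g2, g2])]) else NA
  b <- mean(D[g1, g2])
  if (b == 0) return(0)
  1 - mean(c(w1, w2)) / b
}

#' Fst between arrangements with permutation significance
#'
#' Treats the Std and Inv haplotypes as two sub-populations and computes the
#' Hudson estimator Fst = 1 - (mean within-arrangement diversity) / (between
#' arrangement diversity), with a permutation p-value obtained by shuffling
#' the arrangement labels (add-one corrected: p = (1 + #{perm >= obs}) /
#' (n_permutations + 1)).
#'
#' @param haps A \code{\link{haplotype_set}} with >= 2 haplotypes per
#'   arrangement.
#' @param n_permutations Number of label permutations (default 1000).
#' @param seed Optional RNG seed for the permutations.
#' @return list(fst = value clamped to [0, 1], fst_raw, p_value).
#' @export
fst_arrangements <- function(haps, n_permutations = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  keep <- haps$labels %in% c("Std", "Inv")
  H <- haps$haplotypes[keep, , drop = FALSE]
  lab <- haps$labels[keep]
  g1 <- which(lab == "Std"); g2 <- which(lab == "Inv")
  if (length(g1) < 2 || length(g2) < 2)
    stop("need at least two haplotypes per arrangement")
  D <- hamming_matrix(H)
  obs <- hudson_fst_from_D(D, g1, g2)
  n <- nrow(H)
  ge <- 0L
  for (b in seq_len(n_permutations)) {
    p1 <- sample.int(n, length(g1))
    if (hudson_fst_from_D(D, p1, setdiff(seq_len(n), p1)) >= obs - 1e-12)
      ge <- ge + 1L
  }
  list(fst = min(max(obs, 0), 1), fst_raw = obs,
       p_value = (1 + ge) / (n_permutations + 1))
}

#' Read / write a haplotype matrix as TSV
#'
#' Plain text interchange: first column \code{label}, optional column
#' \code{sample}, remaining columns one site each (named by position),
#' entries 0/1.
#'
#' @param path File path.
#' @param haps A \code{\link{haplotype_set}} (for writing).
#' @return \code{read_haplotypes} returns a \code{\link{haplotype_set}}.
#' @export
read_haplotypes <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  lab <- df$label
  samp <- df$sample
  df <- df[, setdiff(names(df), c("label", "sample")), drop = FALSE]
  haplotype_set(as.matrix(df), lab, positions = as.numeric(names(df)),
                sample_origin = samp)
}

#' @rdname read_haplotypes
#' @export
write_haplotypes <- function(haps, path) {
  df <- as.data.frame(haps$haplotypes)
  names(df) <- haps$positions
  df <- cbind(label = haps$labels, df)
  if (!is.null(haps$sample_origin))
    df <- cbind(df[1], sample = haps$sample_origin, df[-1])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
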