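#' Filter the mapping hits of one read
#'
#' Keeps at most \code{max_hits} mappings with identity strictly above
#' \code{min_identity}, Smith-Waterman score strictly above \code{min_score},
#' and score within \code{score_window} (fractional) of the best retained hit.
#' Ties at the last retained slot are broken by leftmost coordinate so the
#' result is deterministic.
#'
#' @param hits data.frame with columns read_id, mate, chrom, start, end,
#'   strand, identity, score (one read's hits).
#' @param max_hits Maximum mappings kept (default 10).
#' @param min_identity Minimum percent identity, exclusive (default 90).
#' @param min_score Minimum score, exclusive (default 300).
#' @param score_window Fraction below the best retained score that is still
#'   kept (default 0.05).
#' @return The retained subset of \code{hits} (possibly empty), best first.
#' @export
filter_mappings <- function(hits, max_hits = 10, min_identity = 90,
                            min_score = 300, score_window = 0.05) {
  keep <- hits[hits$identity > min_identity & hits$score > min_score, ,
               drop = FALSE]
  if (nrow(keep) == 0L) return(keep)
  keep <- keep[keep$score >= (1 - score_window) * max(keep$score), ,
               drop = FALSE]
  keep <- keep[order(-keep$score, keep$chrom, keep$start), , drop = FALSE]
  utils::head(keep, max_hits)
}

#' Inverted-repeat annotation for ambiguity detection
#'
#' Intervals of highly identical inverted-repeat copies (the default
#' definition: spans of at least \code{min_len_kb} kb at \code{>=
#' min_identity_pct}\% identity). Reads landing in such copies can map to
#' either copy, so their pairs are candidates for the ambiguous class.
#'
#' @param intervals data.frame with chrom, start, end (one row per IR copy).
#' @param min_len_kb,min_identity_pct Definition thresholds (annotation only).
#' @export
ir_annotation <- function(intervals, min_len_kb = 1, min_identity_pct = 97) {
  intervals <- intervals[order(intervals$chrom, intervals$start), ,
                         drop = FALSE]
  structure(list(intervals = intervals, min_len_kb = min_len_kb,
                 min_identity_pct = min_identity_pct),
            class = "ir_annotation")
}

in_ir <- function(ir, chrom, start, end) {
  iv <- ir$intervals
  any(iv$chrom == chrom & iv$start <= end & start <= iv$end)
}

pair_orientation <- function(h1, h2) {
  if (h1$chrom != h2$chrom) return("split")
  left <- if (h1$start <= h2$start) h1 else h2
  right <- if (h1$start <= h2$start) h2 else h1
  if (left$strand == "+" && right$strand == "-") "proper"
  else if (left$strand == right$strand) "inverted"
  else "outward"
}

#' Classify a fosmid end pair
#'
#' A pair whose unique best placements map in the expected +/- orientation with
#' an insert span inside \code{insert_range} is concordant; a pair mapping +/+
#' or -/- is discordant in orientation (an inversion-breakpoint signature).
#' When a read lies in a highly identical inverted-repeat copy and its
#' alternative placements produce both concordant-type and discordant-type
#' orientations, the pair is ambiguous. Pairs with fewer than two mapped reads,
#' on different chromosomes, outward-facing, or with an out-of-range span are
#' uninformative. Classification is symmetric in the two mates.
#'
#' @param mappings_r1,mappings_r2 Filtered mapping data.frames
#'   (\code{\link{filter_mappings}} output) for the two reads.
#' @param ir An \code{\link{ir_annotation}}.
#' @param insert_range Insert-size concordance window in bp
#'   (default \code{c(32000, 48000)}, fosmid inserts of about 40 kb).
#' @return One of "concordant", "discordant_orientation", "ambiguous",
#'   "uninformative".
#' @export
classify_pair <- function(mappings_r1, mappings_r2, ir = NULL,
                          insert_range = c(32000, 48000)) {
  if (is.null(mappings_r1) || is.null(mappings_r2) ||
      nrow(mappings_r1) == 0L || nrow(mappings_r2) == 0L)
    return("uninformative")
  best1 <- mappings_r1[1, ]; best2 <- mappings_r2[1, ]
  tie1 <- sum(mappings_r1$score == best1$score) > 1L
  tie2 <- sum(mappings_r2$score == best2$score) > 1L
  ir_read <- !is.null(ir) &&
    (any(mapply(function(c, s, e) in_ir(ir, c, s, e),
                mappings_r1$chrom, mappings_r1$start, mappings_r1$end)) ||
     any(mapply(function(c, s, e) in_ir(ir, c, s, e),
                mappings_r2$chrom, mappings_r2$start, mappings_r2$end)))
  ## alternative-placement orientations across all retained hit combinations
  if (ir_read || tie1 || tie2) {
    oris <- character(0)
    for (i in seq_len(nrow(mappings_r1)))
      for (j in seq_len(nrow(mappings_r2)))
        oris <- c(oris, pair_orientation(mappings_r1[i, ], mappings_r2[j, ]))
    if (all(c("proper", "inverted") %in% oris)) return("ambiguous")
  }
  ori <- pair_orientation(best1, best2)
  if (ori == "inverted") return("discordant_orientation")
  if (ori != "proper") return("uninformative")
  span <- max(best1$end, best2$end) - min(best1$start, best2$start) + 1
  if (span >= insert_range[1] && span <= insert_range[2]) "concordant"
  else "uninformative"
}

#' Classify all fosmid pairs in a mapping table
#'
#' Applies \code{\link{filter_mappings}} per read and
#' \code{\link{classify_pair}} per fosmid.
#'
#' @param mappings data.frame with read_id, mate, chrom, start, end, strand,
#'   identity, score; \code{read_id} identifies the fosmid.
#' @param ir Optional \code{\link{ir_annotation}}.
#' @param insert_range Concordance window in bp.
#' @param ... Passed to \code{\link{filter_mappings}}.
#' @return data.frame fosmid_id, classification, spans_breakpoint (whether the
#'   pair's best-placement footprint brackets an annotated IR copy entirely;
#'   only such pairs inform the arrangement).
#' @export
classify_fosmids <- function(mappings, ir = NULL,
                             insert_range = c(32000, 48000), ...) {
  out <- lapply(split(mappings, mappings$read_id), function(fm) {
    r1 <- filter_mappings(fm[fm$mate == 1, , drop = FALSE], ...)
    r2 <- filter_mappings(fm[fm$mate == 2, , drop = FALSE], ...)
    cls <- classify_pair(r1, r2, ir, insert_range)
    spans <- FALSE
    if (!is.null(ir) && nrow(r1) > 0 && nrow(r2) > 0 &&
        r1$chrom[1] == r2$chrom[1]) {
      lo <- min(r1$start[1], r2$start[1]); hi <- max(r1$end[1], r2$end[1])
      iv <- ir$intervals
      spans <- any(iv$chrom == r1$chrom[1] & iv$start > lo & iv$end < hi)
    }
    list(cls = cls, spans = spans)
  })
  data.frame(fosmid_id = names(out),
             classification = vapply(out, `[[`, "", "cls"),
             spans_breakpoint = vapply(out, `[[`, TRUE, "spans"),
             row.names = NULL)
}

#' Aggregate per-individual inversion support from classified pairs
#'
#' Counts informative pairs only: concordant pairs support the standard
#' arrangement, orientation-discordant pairs the inverted one. With at least
#' \code{min_support} pairs for each arrangement the predicted genotype is
#' Std/Inv; with support for only one arrangement (and none for the other) the
#' data are consistent with homozygosity; anything else is insufficient.
#'
#' @param classifications Character vector (or data.frame from
#'   \code{\link{classify_fosmids}}) of pair classifications.
#' @param sample_id,region_id Identifiers carried through.
#' @param min_support Minimum pairs per supported orientation (default 2).
#' @return An object of class \code{pem_support}: counts plus
#'   \code{predicted_genotype} in Std/Inv, Std-consistent, Inv-consistent,
#'   insufficient.
#' @export
genotype_support <- function(classifications, sample_id = NA,
                             region_id = NA, min_support = 2) {
  spans <- TRUE
  if (is.data.frame(classifications)) {
    if (!is.null(classifications$spans_breakpoint))
      spans <- classifications$spans_breakpoint
    classifications <- classifications$classification
  }
  n_std <- sum(classifications == "concordant" & spans)
  n_inv <- sum(classifications == "discordant_orientation" & spans)
  n_amb <- sum(classifications == "ambiguous")
  pred <- if (n_std >= min_support && n_inv >= min_support) "Std/Inv"
  else if (n_std >= min_support && n_inv == 0) "Std-consistent"
  else if (n_inv >= min_support && n_std == 0) "Inv-consistent"
  else "insufficient"
  structure(list(sample_id = sample_id, region_id = region_id,
                 n_std = n_std, n_inv = n_inv, n_ambiguous = n_amb,
                 predicted_genotype = pred),
            class = "pem_support")
}

#' @export
print.pem_support <- function(x, ...) {
  cat(sprintf("<pem_support> %s/%s: %d Std, %d Inv, %d ambiguous -> %s\n",
              x$sample_id, x$region_id, x$n_std, x$n_inv, x$n_ambiguous,
              x$predicted_genotype))
  invisible(x)
}

#' Check consistency between fosmid support and an iPCR genotype
#'
#' Consistent when every arrangement supported by informative fosmids appears
#' in the iPCR genotype's allele set; with no informative fosmids the
#' comparison is not evaluable.
#'
#' @param support A \code{\link{genotype_support}} result.
#' @param ipcr_call iPCR genotype string ("Std/Std", "Std/Inv", "Inv/Inv",
#'   "Std", "Inv") for the same sample and region.
#' @return "consistent", "inconsistent" or "not_evaluable".
#' @export
ipcr_consistency <- function(support, ipcr_call) {
  supported <- c(if (support$n_std > 0) "Std", if (support$n_inv > 0) "Inv")
  if (length(supported) == 0L) return("not_evaluable")
  if (is.na(ipcr_call) || ipcr_call == "missing") return("not_evaluable")
  if (all(supported %in% geno_alleles(ipcr_call))) "consistent"
  else "inconsistent"
}

#' Read a fosmid mapping table
#'
#' Tab-separated columns read_id, mate, chrom, start, end, strand, identity,
#' score; '#' comments allowed.
#'
#' @param path File path.
#' @export
read_mappings <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("read_id", "mate", "chrom", "start", "end", "strand",
            "identity", "score")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("mapping file missing columns: ",
                         paste(miss, collapse = ", "))
  df
}
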