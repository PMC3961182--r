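#' Genomic interval
#'
#' A 1-based, fully closed interval on a named chromosome. This is the external
#' coordinate convention used throughout the package (matching how inversion
#' breakpoints are published); arithmetic that needs half-open coordinates
#' converts internally.
#'
#' @param chrom Chromosome name (non-empty string).
#' @param start,end 1-based inclusive positions, \code{start <= end}.
#' @return An object of class \code{genomic_interval}.
#' @export
genomic_interval <- function(chrom, start, end) {
  stopifnot(is.character(chrom), nzchar(chrom), length(chrom) == 1L)
  start <- as.numeric(start); end <- as.numeric(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end))
    stop("start and end must be single non-missing positions")
  if (start > end) stop("interval start must not exceed end")
  structure(list(chrom = chrom, start = start, end = end),
            class = "genomic_interval")
}

#' @export
print.genomic_interval <- function(x, ...) {
  cat(sprintf("%s:%s-%s\n", x$chrom, format(x$start, scientific = FALSE),
              format(x$end, scientific = FALSE)))
  invisible(x)
}

iv_width <- function(x) x$end - x$start + 1
iv_mid <- function(x) (x$start + x$end) / 2
iv_overlaps <- function(a, b) a$chrom == b$chrom && a$start <= b$end && b$start <= a$end
iv_contains_pos <- function(x, pos) pos >= x$start & pos <= x$end

## round half away from zero to `digits` decimals (base round() is half-to-even)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Inversion locus model
#'
#' Describes one inversion locus mediated by a pair of inverted repeats (IRs):
#' unique segments A and B flank IR1 at breakpoint 1, and C and D flank IR2 at
#' breakpoint 2, in the order A < IR1 < B <= C < IR2 < D along the chromosome.
#' \code{bp1}/\code{bp2} are the breakpoint uncertainty intervals; they default
#' to the full IR extents when no refined location is known.
#'
#' @param id Locus name (e.g. \code{"HsInv0114"}).
#' @param a,b,c,d \code{\link{genomic_interval}}s for the unique segments.
#' @param ir1,ir2 \code{\link{genomic_interval}}s for the inverted repeats.
#' @param bp1,bp2 Breakpoint intervals (default: the IR extents).
#' @param ir_class One of \code{"SD"}, \code{"TE"}, \code{"mixed"}.
#' @return An object of class \code{inversion_region}.
#' @export
inversion_region <- function(id, a, ir1, b, c, ir2, d,
                             bp1 = ir1, bp2 = ir2, ir_class = "SD") {
  segs <- list(a = a, ir1 = ir1, b = b, c = c, ir2 = ir2, d = d)
  for (s in segs) stopifnot(inherits(s, "genomic_interval"))
  chroms <- unique(vapply(segs, `[[`, "", "chrom"))
  if (length(chroms) != 1L) stop("all segments must lie on one chromosome")
  ir_class <- match.arg(ir_class, c("SD", "TE", "mixed"))
  reg <- structure(list(id = id, a = a, ir1 = ir1, b = b, c = c, ir2 = ir2,
                        d = d, bp1 = bp1, bp2 = bp2, ir_class = ir_class),
                   class = "inversion_region")
  ord <- c(a$end < ir1$start, ir1$end < b$start, b$end <= c$start,
           c$end < ir2$start, ir2$end < d$start)
  if (!all(ord)) stop("segments out of order: need A < IR1 < B <= C < IR2 < D")
  if (!(bp1$start >= ir1$start && bp1$end <= ir1$end))
    stop("bp1 must lie within IR1")
  if (!(bp2$start >= ir2$start && bp2$end <= ir2$end))
    stop("bp2 must lie within IR2")
  reg
}

#' @export
print.inversion_region <- function(x, ...) {
  cat(sprintf("<inversion_region> %s (%s, IRs: %s)\n", x$id, x$a$chrom, x$ir_class))
  cat(sprintf("  A %d-%d | IR1 %d-%d | B %d-%d | C %d-%d | IR2 %d-%d | D %d-%d\n",
              x$a$start, x$a$end, x$ir1$start, x$ir1$end, x$b$start, x$b$end,
              x$c$start, x$c$end, x$ir2$start, x$ir2$end, x$d$start, x$d$end))
  cat(sprintf("  size %.1f kb, IR spans %.1f/%.1f kb\n",
              inversion_size(x), ir_span(x, 1), ir_span(x, 2)))
  invisible(x)
}

#' Inversion size in kb
#'
#' The inversion size is the distance between the middle positions of the two
#' breakpoint intervals, counted inclusively in base pairs, reported in kb to
#' one decimal (half away from zero). Works on an \code{inversion_region} or on
#' two explicit breakpoint intervals.
#'
#' @param region An \code{\link{inversion_region}}, or a
#'   \code{\link{genomic_interval}} for breakpoint 1 when \code{bp2} is given.
#' @param bp2 Optional second breakpoint interval.
#' @return Size in kb, one decimal.
#' @export
inversion_size <- function(region, bp2 = NULL) {
  if (is.null(bp2)) {
    bp1 <- region$bp1; bp2 <- region$bp2
  } else bp1 <- region
  if (iv_overlaps(bp1, bp2) && !identical(unclass(bp1), unclass(bp2)))
    stop("breakpoint intervals overlap")
  d <- abs(iv_mid(bp2) - iv_mid(bp1))
  if (d == 0) return(0)
  round_half_up((d + 1) / 1000, 1)
}

#' Inverted-repeat span in kb
#'
#' Span (end minus start, the convention under which published IR sizes were
#' printed) of the chosen breakpoint interval, in kb to one decimal.
#'
#' @param region An \code{\link{inversion_region}}.
#' @param which Breakpoint 1 or 2.
#' @export
ir_span <- function(region, which = 1) {
  bp <- if (which == 1) region$bp1 else region$bp2
  round_half_up((bp$end - bp$start) / 1000, 1)
}

#' Locus selection criteria
#'
#' Thresholds used to decide whether an inversion locus is assayable:
#' at least \code{min_fosmids_each_orientation} fosmid pairs supporting each
#' orientation, IRs below \code{max_ir_kb}, and self-ligation fragments below
#' \code{max_fragment_kb}.
#'
#' @param min_fosmids_each_orientation Minimum informative fosmids per orientation.
#' @param max_ir_kb Maximum IR span in kb.
#' @param max_fragment_kb Maximum circularizable fragment in kb.
#' @export
selection_criteria <- function(min_fosmids_each_orientation = 2,
                               max_ir_kb = 40, max_fragment_kb = 70) {
  stopifnot(min_fosmids_each_orientation > 0, max_ir_kb > 0, max_fragment_kb > 0)
  structure(list(min_fosmids_each_orientation = min_fosmids_each_orientation,
                 max_ir_kb = max_ir_kb, max_fragment_kb = max_fragment_kb),
            class = "selection_criteria")
}

#' Validate an inversion region against selection criteria
#'
#' Report-style check: never errors, returns one row per criterion with a
#' pass/fail flag and a note. Checks IR spans against \code{max_ir_kb},
#' segment ordering, and pairwise segment overlaps.
#'
#' @param region An \code{\link{inversion_region}} (or an unchecked list with
#'   the same fields, so broken regions can be reported rather than rejected).
#' @param criteria A \code{\link{selection_criteria}}.
#' @return data.frame with columns criterion, pass, note.
#' @export
validate_region <- function(region, criteria = selection_criteria()) {
  segs <- list(A = region$a, IR1 = region$ir1, B = region$b,
               C = region$c, IR2 = region$ir2, D = region$d)
  out <- list()
  for (w in 1:2) {
    bp <- if (w == 1) region$bp1 else region$bp2
    span <- (bp$end - bp$start) / 1000
    out[[length(out) + 1L]] <- data.frame(
      criterion = sprintf("max_ir_kb_bp%d", w),
      pass = span < criteria$max_ir_kb,
      note = sprintf("IR%d span %.1f kb (limit %g)", w, span, criteria$max_ir_kb))
  }
  bounds <- unlist(lapply(segs, function(s) c(s$start, s$end)))
  ordered <- all(diff(bounds) >= 0) &&
    segs$A$end < segs$IR1$start && segs$IR1$end < segs$B$start &&
    segs$B$end <= segs$C$start && segs$C$end < segs$IR2$start &&
    segs$IR2$end < segs$D$start
  out[[length(out) + 1L]] <- data.frame(
    criterion = "segment_order", pass = ordered,
    note = if (ordered) "A < IR1 < B <= C < IR2 < D" else "segments out of order")
  ov <- FALSE
  nm <- names(segs)
  for (i in seq_along(segs)) for (j in seq_len(i - 1L)) {
    if (!(nm[i] == "C" && nm[j] == "B") && iv_overlaps(segs[[i]], segs[[j]]))
      ov <- TRUE
  }
  out[[length(out) + 1L]] <- data.frame(
    criterion = "no_overlap", pass = !ov,
    note = if (ov) "segments overlap" else "no segment overlaps")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Refine a breakpoint interval from exchanged paralogous sequence variants
#'
#' The two IR copies differ at paralogous sequence variants (PSVs). In an
#' individual carrying the inversion, the IR portion distal to the exchange
#' point carries the other copy's PSV states. Given the column-aligned IR
#' copies from the reference (standard allele) and from an inverted-allele
#' sequence, this finds runs of at least \code{min_run} contiguous PSVs whose
#' copy of origin is swapped, and returns the interval spanning the
#' transition(s) between swapped and non-swapped territory. When several
#' transitions exist the widest interval consistent with all exchanged runs is
#' reported (conservative uncertainty).
#'
#' @param std_ir_alignment 2-row character matrix (or 2 equal-length strings):
#'   the aligned IR copies in the reference.
#' @param inv_ir_alignment Same shape: the aligned IR copies in the inverted
#'   allele, on the same column coordinate system.
#' @param min_run Minimum number of contiguous exchanged PSVs (default 3).
#' @return list with \code{start}, \code{end} (alignment columns) and
#'   \code{flag} in \code{"refined"}, \code{"unrefined"},
#'   \code{"all_exchanged"}.
#' @export
refine_breakpoints_psv <- function(std_ir_alignment, inv_ir_alignment,
                                   min_run = 3) {
  as_mat <- function(x) {
    if (!is.matrix(x) && is.character(x))
      x <- do.call(rbind, strsplit(toupper(x), ""))
    stopifnot(is.matrix(x), nrow(x) == 2L)
    x
  }
  std <- as_mat(std_ir_alignment); inv <- as_mat(inv_ir_alignment)
  if (ncol(std) != ncol(inv)) stop("alignments must have equal length")
  n <- ncol(std)
  psv <- which(std[1, ] != std[2, ])
  full <- list(start = 1L, end = n, flag = "unrefined")
  if (length(psv) == 0L) return(full)
  ## exchanged: the inverted allele shows the swapped copy assignment
  ex <- inv[1, psv] == std[2, psv] & inv[2, psv] == std[1, psv]
  same <- inv[1, psv] == std[1, psv] & inv[2, psv] == std[2, psv]
  status <- ifelse(ex, "ex", ifelse(same, "same", "other"))
  r <- rle(status)
  run_id <- rep(seq_along(r$lengths), r$lengths)
  good_run <- r$values == "ex" & r$lengths >= min_run
  if (!any(good_run)) return(full)
  if (all(status == "ex"))
    return(list(start = 1L, end = n, flag = "all_exchanged"))
  ## transitions between a qualifying exchanged run and adjacent non-exchanged PSVs
  bounds <- c()
  for (i in which(good_run)) {
    idx <- which(run_id == i)             # indices into psv vector
    if (idx[1] > 1L) bounds <- c(bounds, psv[idx[1] - 1L], psv[idx[1]])
    if (idx[length(idx)] < length(psv))
      bounds <- c(bounds, psv[idx[length(idx)]], psv[idx[length(idx)] + 1L])
  }
  if (length(bounds) == 0L)  # exchanged run covers all PSVs but not all columns
    return(list(start = min(psv), end = max(psv), flag = "refined"))
  list(start = min(bounds), end = max(bounds), flag = "refined")
}

#' Read an inversion region file
#'
#' Tab-separated file with one row per inversion: \code{id}, \code{chrom}, then
#' start-end pairs for A, IR1, B, C, IR2, D, bp1, bp2 (columns
#' \code{a_start,a_end,...,bp2_end}), optional \code{ir_class}. Lines starting
#' with \code{#} are comments.
#'
#' @param path File path.
#' @return A list of \code{\link{inversion_region}} objects, named by id.
#' @export
read_regions <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "chrom", paste0(rep(c("a", "ir1", "b", "c", "ir2", "d",
                                        "bp1", "bp2"), each = 2),
                                  c("_start", "_end")))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("region file missing columns: ", paste(miss, collapse = ", "))
  out <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    gi <- function(p) genomic_interval(r$chrom, r[[paste0(p, "_start")]],
                                       r[[paste0(p, "_end")]])
    inversion_region(r$id, gi("a"), gi("ir1"), gi("b"), gi("c"), gi("ir2"),
                     gi("d"), gi("bp1"), gi("bp2"),
                     ir_class = if ("ir_class" %in% names(df)) r$ir_class else "SD")
  })
  names(out) <- df$id
  out
}

#' Packaged inversion survey table
#'
#' The 22 analysed inversion predictions with HG18 breakpoint intervals,
#' IR classes and printed sizes, the iPCR self-ligation fragment range, the
#' validation status, and the iPCR/PEM consistency tally.
#'
#' @return data.frame with one row per inversion.
#' @export
inversion_table <- function() {
  utils::read.delim(system.file("extdata", "inversions_hg18.tsv",
                                package = "invrec"),
                    comment.char = "#", stringsAsFactors = FALSE)
}

#' Packaged genotyping and primate summary table
#'
#' CEU genotyping summary (chromosome counts, inversion frequency, observed
#' heterozygosity, valid trio transmissions) and primate iPCR orientation calls
#' for the 17 validated inversions.
#'
#' @return data.frame with one row per validated inversion.
#' @export
genotyping_table <- function() {
  utils::read.delim(system.file("extdata", "genotyping_summary.tsv",
                                package = "invrec"),
                    comment.char = "#", stringsAsFactors = FALSE)
}
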