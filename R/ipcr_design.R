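#' Restriction enzyme
#'
#' @param name Enzyme name.
#' @param site Recognition site (IUPAC allowed).
#' @param cut_top,cut_bottom Cut offsets in bases from the start of the site on
#'   the top and bottom strand; equal offsets mean a blunt cutter.
#' @param end_type \code{"staggered"} or \code{"blunt"}; inferred from the
#'   offsets when missing.
#' @return An object of class \code{restriction_enzyme}.
#' @export
restriction_enzyme <- function(name, site, cut_top, cut_bottom,
                               end_type = NULL) {
  site <- toupper(site)
  len <- nchar(site)
  stopifnot(cut_top >= 0, cut_top <= len, cut_bottom >= 0, cut_bottom <= len)
  blunt <- cut_top == cut_bottom
  if (is.null(end_type)) end_type <- if (blunt) "blunt" else "staggered"
  end_type <- match.arg(end_type, c("staggered", "blunt"))
  if ((end_type == "blunt") != blunt)
    stop("end_type inconsistent with cut offsets")
  structure(list(name = name, site = site, cut_top = cut_top,
                 cut_bottom = cut_bottom, end_type = end_type),
            class = "restriction_enzyme")
}

#' @export
print.restriction_enzyme <- function(x, ...) {
  cat(sprintf("%s: %s^%s (%s ends)\n", x$name,
              substr(x$site, 1, x$cut_top),
              substr(x$site, x$cut_top + 1, nchar(x$site)), x$end_type))
  invisible(x)
}

#' Read a restriction-enzyme catalog
#'
#' Tab-separated columns: name, site, cut_top, cut_bottom, end_type. With no
#' path, returns the packaged catalog of the seven enzymes used for iPCR
#' genotyping (EcoRI, HindIII, SacI, BamHI, NsiI, BglII, SwaI).
#'
#' @param path Optional catalog path.
#' @return Named list of \code{\link{restriction_enzyme}} objects.
#' @export
read_enzyme_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "enzymes.tsv", package = "invrec")
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty enzyme catalog")
  out <- lapply(seq_len(nrow(df)), function(i)
    restriction_enzyme(df$name[i], df$site[i], df$cut_top[i], df$cut_bottom[i],
                       df$end_type[i]))
  names(out) <- df$name
  out
}

revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

## 1-based start positions of enzyme sites on the top strand of `seq`,
## for both orientations of the recognition site; IUPAC codes in the site
## are expanded, N in the sequence never matches a non-N site base.
match_sites <- function(seq, site) {
  subj <- Biostrings::DNAString(seq)
  fwd <- Biostrings::start(Biostrings::matchPattern(
    site, subj, fixed = c(pattern = FALSE, subject = TRUE)))
  rc <- revcomp(site)
  if (rc == site) return(list(fwd = fwd, rev = integer(0)))
  rev <- Biostrings::start(Biostrings::matchPattern(
    rc, subj, fixed = c(pattern = FALSE, subject = TRUE)))
  list(fwd = fwd, rev = setdiff(rev, fwd))
}

#' Virtually digest a sequence with a restriction enzyme
#'
#' Finds recognition sites on both strands and cuts the top strand at
#' \code{site_start + cut_top} (forward sites) or at the mirrored offset
#' (reverse-orientation sites). Returns the cut positions (number of bases to
#' the left of each cut) and the resulting fragments, which tile the input.
#' On a circular molecule, sites spanning the origin are found and a single cut
#' linearizes the whole molecule into one fragment.
#'
#' @param sequence Uppercase ACGTN string.
#' @param enzyme A \code{\link{restriction_enzyme}}.
#' @param topology \code{"linear"} or \code{"circular"}.
#' @return list with \code{cuts} (integer vector) and \code{fragments}
#'   (data.frame start, end, length; for circular molecules a fragment may wrap
#'   past the origin, in which case end < start).
#' @export
virtual_digest <- function(sequence, enzyme, topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  n <- nchar(sequence)
  if (n == 0L) stop("empty sequence")
  L <- nchar(enzyme$site)
  scan_seq <- if (topology == "circular" && n > L)
    paste0(sequence, substr(sequence, 1, L - 1)) else sequence
  m <- match_sites(scan_seq, enzyme$site)
  cuts <- sort(unique(c(m$fwd - 1L + enzyme$cut_top,
                        m$rev - 1L + (L - enzyme$cut_bottom))))
  if (topology == "linear") {
    cuts <- cuts[cuts > 0 & cuts < n]
    b <- c(0L, cuts, n)
    frags <- data.frame(start = utils::head(b, -1) + 1L, end = b[-1])
    frags$length <- frags$end - frags$start + 1L
  } else {
    cuts <- sort(unique(cuts %% n))
    cuts[cuts == 0L] <- n
    if (length(cuts) == 0L) {
      frags <- data.frame(start = 1L, end = n, length = n)
    } else if (length(cuts) == 1L) {
      s <- (cuts %% n) + 1L
      frags <- data.frame(start = s, end = cuts, length = n)
    } else {
      s <- (cuts %% n) + 1L
      e <- c(cuts[-1], cuts[1])
      frags <- data.frame(start = s, end = e)
      frags$length <- ifelse(frags$end >= frags$start,
                             frags$end - frags$start + 1L,
                             n - frags$start + 1L + frags$end)
    }
  }
  list(cuts = cuts, fragments = frags)
}

#' Construct the inverted allele of a region
#'
#' Reverse-complements the segment between two exchange points (one inside each
#' inverted repeat) of a reference sequence, modelling the non-allelic
#' homologous recombination product. Length is preserved and applying the
#' operation twice with the same points restores the input.
#'
#' @param reference Reference (standard-allele) sequence; region coordinates
#'   are positions in this string.
#' @param region An \code{\link{inversion_region}} with coordinates local to
#'   \code{reference}.
#' @param exchange_points Length-2 numeric: positions inside IR1 and IR2 after
#'   which the orientation flips. Defaults to the breakpoint-interval midpoints
#'   (rounded down).
#' @return The inverted-allele sequence (same length).
#' @export
build_inverted_allele <- function(reference, region,
                                  exchange_points = NULL) {
  n <- nchar(reference)
  if (is.null(exchange_points))
    exchange_points <- floor(c(iv_mid(region$bp1), iv_mid(region$bp2)))
  e1 <- exchange_points[1]; e2 <- exchange_points[2]
  if (e1 == e2) return(reference)     # zero-length interior: nothing to flip
  if (!(e1 >= region$ir1$start && e1 <= region$ir1$end))
    stop("exchange point 1 outside IR1")
  if (!(e2 >= region$ir2$start && e2 <= region$ir2$end))
    stop("exchange point 2 outside IR2")
  if (e2 > n) stop("exchange point beyond reference end")
  if (e1 >= e2) return(reference)
  paste0(substr(reference, 1, e1),
         revcomp(substr(reference, e1 + 1, e2)),
         substr(reference, e2 + 1, n))
}

#' Screen restriction enzymes for an iPCR assay
#'
#' Keeps enzymes that cut at least once in each unique segment A, B, C and D,
#' never inside either inverted repeat, and whose breakpoint-spanning fragments
#' (the fragment covering IR1 and the one covering IR2, on both the standard
#' and the inverted allele) fall within the circularizable size window.
#' Staggered-end enzymes are ranked above blunt-end ones, which self-ligate
#' poorly and are annotated low-efficiency.
#'
#' @param region \code{\link{inversion_region}} with coordinates local to
#'   \code{reference}.
#' @param reference Standard-allele sequence of the region.
#' @param catalog List of \code{\link{restriction_enzyme}} objects.
#' @param limits list(min_kb, max_kb, circ_max_kb): fragment-size window in kb
#'   and the efficient-recircularization bound.
#' @param exchange_points Passed to \code{\link{build_inverted_allele}}.
#' @return data.frame of candidate enzymes, ranked; zero rows when none pass.
#' @export
select_enzymes <- function(region, reference, catalog,
                           limits = list(min_kb = 2.3, max_kb = 73,
                                         circ_max_kb = 70),
                           exchange_points = NULL) {
  if (length(catalog) == 0L) stop("empty enzyme catalog")
  inv_allele <- build_inverted_allele(reference, region, exchange_points)
  if (is.null(exchange_points))
    exchange_points <- floor(c(iv_mid(region$bp1), iv_mid(region$bp2)))
  rows <- list()
  for (enz in catalog) {
    cuts <- virtual_digest(reference, enz)$cuts
    in_seg <- function(iv) any(cuts >= iv$start & cuts <= iv$end)
    if (in_seg(region$ir1) || in_seg(region$ir2)) next
    if (!all(vapply(list(region$a, region$b, region$c, region$d), in_seg,
                    logical(1)))) next
    bp_frag <- function(cutpos, pos) {
      lo <- max(cutpos[cutpos < pos], 0)
      hi <- min(cutpos[cutpos >= pos], nchar(reference))
      hi - lo
    }
    std1 <- bp_frag(cuts, region$ir1$start)
    std2 <- bp_frag(cuts, region$ir2$start)
    icuts <- virtual_digest(inv_allele, enz)$cuts
    inv1 <- bp_frag(icuts, exchange_points[1])
    inv2 <- bp_frag(icuts, exchange_points[2])
    sizes <- c(std1, std2, inv1, inv2) / 1000
    if (any(sizes < limits$min_kb) || any(sizes > limits$max_kb)) next
    rows[[length(rows) + 1L]] <- data.frame(
      name = enz$name, end_type = enz$end_type,
      std_bp1_kb = std1 / 1000, std_bp2_kb = std2 / 1000,
      inv_bp1_kb = inv1 / 1000, inv_bp2_kb = inv2 / 1000,
      circ_efficient = max(sizes) <= limits$circ_max_kb,
      note = if (enz$end_type == "blunt") "low-efficiency" else "")
  }
  if (length(rows) == 0L)
    return(data.frame(name = character(0), end_type = character(0),
                      std_bp1_kb = numeric(0), std_bp2_kb = numeric(0),
                      inv_bp1_kb = numeric(0), inv_bp2_kb = numeric(0),
                      circ_efficient = logical(0), note = character(0)))
  out <- do.call(rbind, rows)
  out <- out[order(out$end_type == "blunt",
                   out$std_bp1_kb + out$std_bp2_kb), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' iPCR primer
#'
#' A primer is stored as its 5'-to-3' oligo sequence plus the unique segment it
#' was designed in; its strand and position in an allele are recovered by exact
#' matching when products are predicted.
#'
#' @param name Primer name.
#' @param seq Oligo sequence, 5' to 3'.
#' @param segment Segment label: "A", "B", "C" or "D".
#' @export
primer <- function(name, seq, segment) {
  segment <- match.arg(segment, c("A", "B", "C", "D"))
  structure(list(name = name, seq = toupper(seq), segment = segment),
            class = "ipcr_primer")
}

#' iPCR assay definition
#'
#' Bundles the enzyme and the outward-facing primers for one inversion locus.
#' Product labels pair the primers' segment labels: AB and CD are diagnostic
#' for the standard arrangement, AC and BD for the inverted one, and AD can
#' only arise from a two-fragment concatamer, so it serves as a ligation
#' artifact control rather than a genotype signal.
#'
#' @param region_id Locus name.
#' @param enzyme A \code{\link{restriction_enzyme}}.
#' @param primers List of \code{\link{primer}} objects (one per segment used).
#' @param breakpoint 1, 2 or "both".
#' @export
ipcr_assay <- function(region_id, enzyme, primers, breakpoint = "both") {
  stopifnot(inherits(enzyme, "restriction_enzyme"))
  for (p in primers) stopifnot(inherits(p, "ipcr_primer"))
  names(primers) <- vapply(primers, `[[`, "", "segment")
  structure(list(region_id = region_id, breakpoint = breakpoint,
                 enzyme = enzyme, primers = primers,
                 predicted_products = NULL, circle_sizes = NULL),
            class = "ipcr_assay")
}

#' @export
print.ipcr_assay <- function(x, ...) {
  cat(sprintf("<ipcr_assay> %s, enzyme %s, primers %s\n", x$region_id,
              x$enzyme$name, paste(names(x$primers), collapse = "")))
  if (!is.null(x$predicted_products)) {
    for (al in c("std", "inv")) {
      pp <- x$predicted_products[[al]]
      cat(sprintf("  %s allele: %s\n", al,
                  if (length(pp)) paste(sprintf("%s=%d bp", names(pp), pp),
                                        collapse = ", ") else "no products"))
    }
  }
  invisible(x)
}

## All (start, end) placements of a primer on the + strand of `sequence`, with
## role "fwd" (oligo matches + strand, extends rightward) or "rev" (oligo's
## reverse complement matches + strand, extends leftward).
primer_placements <- function(p, sequence) {
  subj <- Biostrings::DNAString(sequence)
  f <- Biostrings::matchPattern(p$seq, subj)
  r <- Biostrings::matchPattern(revcomp(p$seq), subj)
  data.frame(
    start = c(Biostrings::start(f), Biostrings::start(r)),
    end = c(Biostrings::end(f), Biostrings::end(r)),
    role = c(rep("fwd", length(f)), rep("rev", length(r))))
}

## iPCR product size on one self-ligated circle: forward primer starting at
## relative position a, reverse primer site ending at relative position d on a
## circle of length L; the product runs rightward from a across the ligated
## junction to d and includes both primers.
circle_amplicon <- function(a, d, L) ((d - a) %% L) + 1

#' Predict iPCR amplicons for both alleles
#'
#' For each allele the sequence is digested, each restriction fragment is
#' self-ligated into a circle, and every outward-facing primer pair landing on
#' the same fragment yields a product whose length is measured across the
#' ligated junction (inclusive of both primers). The AD product is computed in
#' concatamer mode only: the A- and D-containing fragments ligated head to
#' tail. Primers absent from an allele simply yield no product there.
#'
#' @param assay An \code{\link{ipcr_assay}}.
#' @param std_allele,inv_allele Sequences of the two alleles.
#' @return The assay with \code{predicted_products} filled: a list with
#'   elements \code{std} and \code{inv}, each a named integer vector of product
#'   sizes in bp (names among AB, CD, AC, BD, AD).
#' @export
predict_amplicons <- function(assay, std_allele, inv_allele) {
  stopifnot(inherits(assay, "ipcr_assay"))
  assay$predicted_products <- list(
    std = allele_products(assay, std_allele),
    inv = allele_products(assay, inv_allele))
  assay$circle_sizes <- list(
    std = virtual_digest(std_allele, assay$enzyme)$fragments$length / 1000,
    inv = virtual_digest(inv_allele, assay$enzyme)$fragments$length / 1000)
  assay
}

allele_products <- function(assay, allele) {
  frags <- virtual_digest(allele, assay$enzyme)$fragments
  plc <- lapply(assay$primers, function(p) {
    pl <- primer_placements(p, allele)
    if (nrow(pl) > 1L)
      stop(sprintf("primer %s does not map uniquely", p$name))
    pl
  })
  segs <- names(assay$primers)
  prods <- integer(0)
  for (i in seq_along(segs)) for (j in seq_along(segs)) {
    if (i == j) next
    p1 <- plc[[i]]; p2 <- plc[[j]]
    if (nrow(p1) == 0L || nrow(p2) == 0L) next
    if (p1$role != "fwd" || p2$role != "rev") next
    lab <- paste0(sort(c(segs[i], segs[j])), collapse = "")
    if (lab == "AD") next          # only via concatamers, handled below
    fi <- which(frags$start <= p1$start & frags$end >= p1$end)
    fj <- which(frags$start <= p2$start & frags$end >= p2$end)
    if (length(fi) != 1L || length(fj) != 1L || fi != fj) next
    if (p1$start <= p2$end) next    # converging pair: not a junction product
    L <- frags$length[fi]
    a <- p1$start - frags$start[fi] + 1
    d <- p2$end - frags$start[fj] + 1
    prods[lab] <- as.integer(circle_amplicon(a, d, L))
  }
  ## AD concatamer: head-to-tail ligation of the A- and D-containing fragments
  if (all(c("A", "D") %in% segs)) {
    pa <- plc[[match("A", segs)]]; pd <- plc[[match("D", segs)]]
    if (nrow(pa) == 1L && nrow(pd) == 1L) {
      fa <- which(frags$start <= pa$start & frags$end >= pa$end)
      fd <- which(frags$start <= pd$start & frags$end >= pd$end)
      if (length(fa) == 1L && length(fd) == 1L && fa != fd) {
        ## combined circle: A-fragment laid first, D-fragment second
        L1 <- frags$length[fa]; L2 <- frags$length[fd]
        if (pa$role == "rev" && pd$role == "fwd") {
          d <- pa$end - frags$start[fa] + 1
          a <- L1 + (pd$start - frags$start[fd] + 1)
          prods["AD"] <- as.integer(circle_amplicon(a, d, L1 + L2))
        } else if (pa$role == "fwd" && pd$role == "rev") {
          a <- pa$start - frags$start[fa] + 1
          d <- L1 + (pd$end - frags$start[fd] + 1)
          prods["AD"] <- as.integer(circle_amplicon(a, d, L1 + L2))
        }
      }
    }
  }
  prods
}

#' Call a per-breakpoint genotype from observed iPCR bands
#'
#' Presence/absence logic on the diagnostic products of one breakpoint:
#' AB (standard) vs AC (inverted) at breakpoint 1, CD vs BD at breakpoint 2.
#' Both products present means heterozygous; in haploid mode (chrY, male chrX)
#' single-product patterns map to hemizygous calls and a two-product pattern is
#' invalid. An observed AD band flags concatamer contamination and failed
#' digestion/ligation control lanes void all calls.
#'
#' @param pattern list(sample_id, observed = character vector of product
#'   labels, controls_ok = TRUE).
#' @param breakpoint 1 or 2.
#' @param haploid Logical: hemizygous sample.
#' @return list(call, ad_flag, control_flag).
#' @export
call_genotype_from_bands <- function(pattern, breakpoint = 1, haploid = FALSE) {
  obs <- pattern$observed
  ad <- "AD" %in% obs
  if (!is.null(pattern$controls_ok) && !pattern$controls_ok)
    return(list(call = "missing", ad_flag = ad, control_flag = TRUE))
  std_prod <- if (breakpoint == 1) "AB" else "CD"
  inv_prod <- if (breakpoint == 1) "AC" else "BD"
  s <- std_prod %in% obs
  v <- inv_prod %in% obs
  call <- if (haploid) {
    if (s && v) "missing" else if (s) "Std" else if (v) "Inv" else "missing"
  } else {
    if (s && v) "Std/Inv" else if (s) "Std/Std" else if (v) "Inv/Inv"
    else "missing"
  }
  list(call = call, ad_flag = ad, control_flag = FALSE)
}

geno_alleles <- function(call) {
  switch(call,
         "Std/Std" = c("Std", "Std"), "Inv/Inv" = c("Inv", "Inv"),
         "Std/Inv" = c("Std", "Inv"), "Std" = "Std", "Inv" = "Inv",
         character(0))
}

#' Consolidate the two breakpoint genotypes of one sample
#'
#' Equal calls are concordant. Under the \code{trust_informative} policy a
#' disagreement is resolved in favor of the breakpoint whose call contains the
#' other's alleles as a subset (e.g. Std/Inv at one breakpoint vs Inv/Inv at
#' the other is resolved to Std/Inv: an allele dropping out of one assay, by a
#' restriction-site polymorphism or an unknown variant, explains the
#' difference). Under \code{strict}, any disagreement gives a missing call.
#'
#' @param bp1_call,bp2_call Per-breakpoint call strings.
#' @param policy \code{"trust_informative"} or \code{"strict"}.
#' @return list(call, per_breakpoint, consistency) with consistency in
#'   concordant / discordant / resolved / single_breakpoint.
#' @export
combine_breakpoint_genotypes <- function(bp1_call, bp2_call,
                                         policy = c("trust_informative",
                                                    "strict")) {
  policy <- match.arg(policy)
  per <- c(bp1 = bp1_call, bp2 = bp2_call)
  m1 <- is.na(bp1_call) || bp1_call == "missing"
  m2 <- is.na(bp2_call) || bp2_call == "missing"
  if (m1 && m2)
    return(list(call = "missing", per_breakpoint = per,
                consistency = "concordant"))
  if (m1 || m2)
    return(list(call = if (m1) bp2_call else bp1_call, per_breakpoint = per,
                consistency = "single_breakpoint"))
  if (bp1_call == bp2_call)
    return(list(call = bp1_call, per_breakpoint = per,
                consistency = "concordant"))
  if (policy == "strict")
    return(list(call = "missing", per_breakpoint = per,
                consistency = "discordant"))
  a1 <- unique(geno_alleles(bp1_call)); a2 <- unique(geno_alleles(bp2_call))
  if (all(a2 %in% a1))
    return(list(call = bp1_call, per_breakpoint = per,
                consistency = "resolved"))
  if (all(a1 %in% a2))
    return(list(call = bp2_call, per_breakpoint = per,
                consistency = "resolved"))
  list(call = "missing", per_breakpoint = per, consistency = "discordant")
}

#' Pfaffl relative expression ratio
#'
#' Relative quantification of a qPCR target against a reference amplicon:
#' \code{e_target^dct_target / e_ref^dct_ref}, where each efficiency is the
#' per-cycle amplification factor from the standard curve (2 = perfect
#' doubling) and each delta-Ct is control Ct minus sample Ct.
#'
#' @param e_target,e_ref Amplification efficiencies (must be positive).
#' @param dct_target,dct_ref Delta-Ct values.
#' @return The relative ratio.
#' @export
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  if (e_target <= 0 || e_ref <= 0) stop("efficiencies must be positive")
  e_target^dct_target / e_ref^dct_ref
}
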