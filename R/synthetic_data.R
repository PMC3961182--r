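#' Simulation configuration
#'
#' Bundles the parameters of the synthetic-data generators. The defaults are
#' the study conditions the rest of the package is exercised under: cohorts of
#' 46 unrelated individuals plus 12 trios, a scaled mutation rate of theta = 20
#' per region over 40 haplotypes, 20 kb regions, and gene-conversion tracts
#' with a 518 bp mean length (the high-resolution Drosophila estimate, the
#' scale at which conversion competes with recurrence as an explanation for
#' shared variants).
#'
#' @param seed Integer seed; each generator derives its own stream from it.
#' @param n_haplotypes Haplotypes in the coalescent sample.
#' @param region_length_bp Surveyed region length.
#' @param theta Per-region scaled mutation rate (4 N mu).
#' @param inversion_scenario list(type = "single_origin") or
#'   list(type = "recurrent", k_events, min_background_divergence).
#' @param gene_conversion list(rate = tracts per haplotype, tract_mean_bp).
#' @param inversion_frequency Target inverted-allele frequency.
#' @param n_individuals Unrelated individuals in the cohort.
#' @param n_trios Complete trios (parents drawn from the unrelated set).
#' @param chrom_type "autosome", "chrX" or "chrY".
#' @export
sim_config <- function(seed = 1, n_haplotypes = 40, region_length_bp = 20000,
                       theta = 20,
                       inversion_scenario = list(type = "single_origin"),
                       gene_conversion = list(rate = 0, tract_mean_bp = 518),
                       inversion_frequency = 0.3, n_individuals = 46,
                       n_trios = 12,
                       chrom_type = c("autosome", "chrX", "chrY")) {
  chrom_type <- match.arg(chrom_type)
  stopifnot(theta >= 0, gene_conversion$rate >= 0,
            inversion_frequency >= 0, inversion_frequency <= 1,
            n_haplotypes >= 2)
  structure(list(seed = seed, n_haplotypes = n_haplotypes,
                 region_length_bp = region_length_bp, theta = theta,
                 inversion_scenario = inversion_scenario,
                 gene_conversion = gene_conversion,
                 inversion_frequency = inversion_frequency,
                 n_individuals = n_individuals, n_trios = n_trios,
                 chrom_type = chrom_type),
            class = "sim_config")
}

## random genealogy of n tips (Kingman pairwise coalescence);
## returns parent pointers, branch lengths (coalescent units) and the tip set
## below each node
random_genealogy <- function(n) {
  n_nodes <- 2L * n - 1L
  parent <- rep(NA_integer_, n_nodes)
  time <- numeric(n_nodes)
  below <- vector("list", n_nodes)
  for (i in seq_len(n)) below[[i]] <- i
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  while (length(active) > 1L) {
    k <- length(active)
    t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
    pick <- sample(seq_along(active), 2L)
    a <- active[pick[1]]; b <- active[pick[2]]
    parent[c(a, b)] <- nxt
    time[nxt] <- t
    below[[nxt]] <- c(below[[a]], below[[b]])
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  blen <- ifelse(is.na(parent), 0, time[parent] - time)
  list(parent = parent, time = time, branch_length = blen, below = below,
       n_tips = n, root = n_nodes)
}

## mutations on the path between two nodes (each mutation sits on one branch)
path_mutations <- function(gen, mut_branch, u, v) {
  anc <- function(x) {
    out <- x
    while (!is.na(gen$parent[x])) { x <- gen$parent[x]; out <- c(out, x) }
    out
  }
  au <- anc(u); av <- anc(v)
  lca <- au[min(which(au %in% av))]
  path <- c(au[seq_len(which(au == lca) - 1L)],
            av[seq_len(which(av == lca) - 1L)])
  sum(mut_branch %in% path)
}

#' Simulate arrangement-labeled haplotypes with a known inversion history
#'
#' Builds a random genealogy, drops Poisson(theta/2 x tree length) mutations
#' on its branches under the infinite-sites model, and places the inversion
#' event(s): one branch for a single-origin history, or k branches with
#' pairwise disjoint tip sets whose backgrounds differ by at least
#' \code{min_background_divergence} mutations for a recurrent history (an
#' error suggests raising theta when no such branches exist). Optional gene
#' conversion copies geometric-length tracts between arrangement backgrounds.
#' The single-origin branch is chosen so the inverted fraction is as close as
#' possible to the configured inversion frequency.
#'
#' @param config A \code{\link{sim_config}}.
#' @return list(haps = \code{\link{haplotype_set}}, truth = list with the true
#'   event count, event branches, arrangement labels and conversion tracts).
#' @export
simulate_haplotypes <- function(config) {
  set.seed(config$seed)
  n <- config$n_haplotypes
  gen <- random_genealogy(n)
  total_len <- sum(gen$branch_length)
  n_mut <- stats::rpois(1, config$theta / 2 * total_len)
  branches <- which(!is.na(gen$parent))
  mut_branch <- if (n_mut > 0)
    sample(branches, n_mut, replace = TRUE,
           prob = gen$branch_length[branches]) else integer(0)
  pos <- sort(sample.int(config$region_length_bp,
                         min(n_mut, config$region_length_bp)))
  n_mut <- length(pos)                 # infinite sites via distinct positions
  mut_branch <- mut_branch[seq_len(n_mut)]
  H <- matrix(0L, n, n_mut)
  for (m in seq_len(n_mut)) H[gen$below[[mut_branch[m]]], m] <- 1L
  ## candidate event branches: both arrangements must stay represented
  clade <- vapply(branches, function(b) length(gen$below[[b]]), 0L)
  cand <- branches[clade >= 1 & clade <= n - 1]
  sc <- config$inversion_scenario
  if (identical(sc$type, "single_origin")) {
    ## prefer branches carrying at least one mutation: those are the events
    ## whose haplotype background is marked by fixed SNPs, the identifiable
    ## situation the classifier and the trees are meant to recover
    marked <- cand[cand %in% mut_branch]
    if (length(marked)) cand <- marked
    frac <- vapply(cand, function(b) length(gen$below[[b]]), 0L) / n
    ev <- cand[which.min(abs(frac - config$inversion_frequency))]
    events <- ev
  } else if (identical(sc$type, "recurrent")) {
    k <- sc$k_events
    min_div <- sc$min_background_divergence
    clade_keys <- vapply(seq_along(gen$below), function(i)
      paste(sort(gen$below[[i]]), collapse = ","), "")
    valid_union <- function(ev) {
      tips <- sort(unique(unlist(gen$below[ev])))
      if (length(tips) >= n) return(FALSE)
      key <- paste(tips, collapse = ",")
      comp <- paste(setdiff(seq_len(n), tips), collapse = ",")
      ## the combined inverted set must not be explainable by one event:
      ## neither it nor its complement may form a clade
      !(key %in% clade_keys) && !(comp %in% clade_keys)
    }
    ## restrict to mutation-marked branches: an event on an unmarked branch
    ## leaves no fixed background difference and is unidentifiable from SNPs
    marked <- cand[cand %in% mut_branch]
    if (length(marked) >= k) cand <- marked
    ord <- cand[order(-clade[match(cand, branches)])]
    ord <- ord[vapply(ord, function(b) length(gen$below[[b]]), 0L) <= n / 2]
    pick <- function(events, pool) {
      if (length(events) == k)
        return(if (valid_union(events)) events else NULL)
      for (b in pool) {
        if (any(vapply(events, function(e)
          length(intersect(gen$below[[e]], gen$below[[b]])) > 0, TRUE))) next
        if (!all(vapply(events, function(e)
          path_mutations(gen, mut_branch, e, b) >= min_div, TRUE))) next
        res <- pick(c(events, b), pool[pool != b])
        if (!is.null(res)) return(res)
      }
      NULL
    }
    events <- pick(integer(0), ord)
    if (is.null(events))
      stop("not enough divergent lineages for ", k,
           " recurrent events; increase theta or n_haplotypes")
  } else stop("unknown inversion scenario")
  inv_tips <- unique(unlist(gen$below[events]))
  labels <- ifelse(seq_len(n) %in% inv_tips, "Inv", "Std")
  ## gene conversion between arrangements
  tracts <- data.frame(recipient = integer(0), donor = integer(0),
                       start = numeric(0), end = numeric(0))
  gc <- config$gene_conversion
  if (gc$rate > 0 && n_mut > 0) {
    for (i in seq_len(n)) {
      for (e in seq_len(stats::rpois(1, gc$rate))) {
        donors <- which(labels != labels[i])
        if (length(donors) == 0) next
        d <- donors[sample.int(length(donors), 1)]
        len <- stats::rgeom(1, 1 / gc$tract_mean_bp) + 1
        s <- sample.int(config$region_length_bp, 1)
        sel <- pos >= s & pos <= s + len - 1
        if (any(sel)) H[i, sel] <- H[d, sel]
        tracts <- rbind(tracts, data.frame(recipient = i, donor = d,
                                           start = s, end = s + len - 1))
      }
    }
  }
  haps <- haplotype_set(H, labels, positions = pos)
  list(haps = haps,
       truth = list(event_count = length(events), event_branches = events,
                    labels = labels, conversion_tracts = tracts,
                    genealogy = gen, mut_branch = mut_branch))
}

geno_string <- function(a1, a2 = NULL) {
  if (is.null(a2)) return(a1)
  paste(sort(c(a1, a2), decreasing = TRUE), collapse = "/")  # Std before Inv
}

#' Simulate a genotyped cohort from labeled haplotypes
#'
#' Unrelated founders draw two haplotypes independently (each inverted with
#' the configured frequency, then a uniform haplotype from that arrangement
#' pool: Hardy-Weinberg by construction); trio children receive one randomly
#' chosen haplotype from each parent, with chrX sons getting a single maternal
#' X and chrY passing father to son. \code{n_mendel_errors} child genotypes
#' can be spiked with a transmission-violating value (slots are chosen among
#' those where a violation is constructible, so every spiked error is
#' detectable by a Mendelian check).
#'
#' @param haps A \code{\link{haplotype_set}} (from
#'   \code{\link{simulate_haplotypes}}).
#' @param config A \code{\link{sim_config}}.
#' @param n_mendel_errors Number of spiked non-Mendelian child genotypes.
#' @return list(table = \code{\link{genotype_table}}, ped = data.frame,
#'   truth = list(hap_index matrix, spiked errors)).
#' @export
simulate_cohort <- function(haps, config, n_mendel_errors = 0) {
  set.seed(config$seed + 1000003L)
  lab <- haps$labels
  pool <- list(Std = which(lab == "Std"), Inv = which(lab == "Inv"))
  if (length(pool$Std) == 0 && config$inversion_frequency < 1)
    stop("no standard haplotypes available")
  if (length(pool$Inv) == 0 && config$inversion_frequency > 0)
    stop("no inverted haplotypes available")
  draw_hap <- function() {
    arr <- if (stats::runif(1) < config$inversion_frequency) "Inv" else "Std"
    pool[[arr]][sample.int(length(pool[[arr]]), 1)]
  }
  n_f <- config$n_individuals
  n_t <- config$n_trios
  if (2 * n_t > n_f) stop("need at least two founders per trio")
  chrom <- config$chrom_type
  founders <- sprintf("F%03d", seq_len(n_f))
  children <- if (n_t > 0) sprintf("C%03d", seq_len(n_t)) else character(0)
  ids <- c(founders, children)
  n_all <- length(ids)
  sex <- rep(NA_character_, n_all)
  sex[seq_len(n_f)] <- ifelse(seq_len(n_f) %% 2 == 1, "male", "female")
  father <- mother <- rep(NA_character_, n_all)
  hap1 <- hap2 <- rep(NA_integer_, n_all)
  for (i in seq_len(n_f)) {
    if (chrom == "autosome" || (chrom == "chrX" && sex[i] == "female")) {
      hap1[i] <- draw_hap(); hap2[i] <- draw_hap()
    } else if (chrom == "chrY" && sex[i] == "female") {
      ## no Y chromosome
    } else hap1[i] <- draw_hap()
  }
  for (t in seq_len(n_t)) {
    ci <- n_f + t
    fi <- 2 * t - 1; mi <- 2 * t
    father[ci] <- founders[fi]; mother[ci] <- founders[mi]
    sex[ci] <- if (stats::runif(1) < 0.5) "male" else "female"
    from <- function(p) {
      hs <- c(hap1[p], hap2[p]); hs <- hs[!is.na(hs)]
      hs[sample.int(length(hs), 1)]
    }
    if (chrom == "autosome") { hap1[ci] <- from(fi); hap2[ci] <- from(mi) }
    else if (chrom == "chrX") {
      if (sex[ci] == "male") hap1[ci] <- from(mi)
      else { hap1[ci] <- hap1[fi]; hap2[ci] <- from(mi) }
    } else if (sex[ci] == "male") hap1[ci] <- hap1[fi]
  }
  H <- haps$haplotypes
  arr_of <- function(h) if (is.na(h)) NA_character_ else lab[h]
  inv_call <- vapply(seq_len(n_all), function(i) {
    a1 <- arr_of(hap1[i]); a2 <- arr_of(hap2[i])
    if (is.na(a1)) NA_character_
    else if (is.na(a2)) a1
    else geno_string(a1, a2)
  }, "")
  n_snp <- ncol(H)
  snp <- matrix(NA_integer_, n_all, n_snp)
  for (i in seq_len(n_all)) {
    if (is.na(hap1[i])) next
    snp[i, ] <- H[hap1[i], ] + if (!is.na(hap2[i])) H[hap2[i], ] else 0L
  }
  samples <- data.frame(sample_id = ids, sex = sex,
                        population = "SIM", father_id = father,
                        mother_id = mother, stringsAsFactors = FALSE)
  spiked <- data.frame(sample = character(0), marker = integer(0))
  if (n_mendel_errors > 0 && n_t > 0) {
    slots <- list()
    for (t in seq_len(n_t)) {
      ci <- n_f + t; fi <- 2 * t - 1; mi <- 2 * t
      for (m in seq_len(n_snp)) {
        viol <- violating_dosages(snp[fi, m], snp[mi, m], chrom, sex[ci])
        if (length(viol))
          slots[[length(slots) + 1L]] <- list(ci = ci, m = m, viol = viol)
      }
    }
    if (length(slots) < n_mendel_errors)
      stop("cannot place ", n_mendel_errors, " detectable Mendelian errors")
    take <- sample.int(length(slots), n_mendel_errors)
    for (s in slots[take]) {
      snp[s$ci, s$m] <- s$viol[sample.int(length(s$viol), 1)]
      spiked <- rbind(spiked, data.frame(sample = ids[s$ci], marker = s$m))
    }
  }
  tab <- genotype_table(samples, inv_call, snp_pos = haps$positions,
                        snp_geno = snp, chrom_type = chrom)
  ped <- data.frame(family = c(rep("U", n_f),
                               if (n_t) sprintf("T%02d", seq_len(n_t))),
                    sample_id = ids, father_id = ifelse(is.na(father), "0",
                                                        father),
                    mother_id = ifelse(is.na(mother), "0", mother),
                    sex = ifelse(sex == "male", 1L, 2L),
                    phenotype = 0L, stringsAsFactors = FALSE)
  ## trio parents share the family id of their child
  if (n_t > 0) for (t in seq_len(n_t))
    ped$family[c(2 * t - 1, 2 * t)] <- sprintf("T%02d", t)
  list(table = tab, ped = ped,
       truth = list(hap1 = hap1, hap2 = hap2, spiked = spiked))
}

## child dosages that violate Mendelian transmission for given parent dosages
violating_dosages <- function(f, m, chrom_type = "autosome",
                              child_sex = "female") {
  dos <- function(g) if (is.na(g)) NULL else g
  codes <- c("0" = "A/A", "1" = "A/B", "2" = "B/B")
  hemi <- c("0" = "A", "1" = "B")
  if (chrom_type == "chrX" && child_sex == "male") {
    cand <- 0:1
    ok <- vapply(cand, function(d) mendelian_check(
      hemi[[as.character(d)]], NA, codes[[as.character(m)]],
      chrom_type = "chrX", child_sex = "male") == "pass", TRUE)
    return(cand[!ok])
  }
  if (chrom_type == "chrY") return(integer(0))
  if (is.na(f) || is.na(m)) return(integer(0))
  cand <- 0:2
  ok <- vapply(cand, function(d) mendelian_check(
    codes[[as.character(d)]], codes[[as.character(f)]],
    codes[[as.character(m)]]) == "pass", TRUE)
  cand[!ok]
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

## mutate away every occurrence of `word` (both orientations) in `seq`
scrub_word <- function(seq, word) {
  for (w in unique(c(word, revcomp(word)))) {
    repeat {
      hit <- regexpr(w, seq, fixed = TRUE)
      if (hit < 0) break
      p <- hit + floor(nchar(w) / 2)
      old <- substr(seq, p, p)
      repl <- setdiff(c("A", "C", "G", "T"), old)[1]
      substr(seq, p, p) <- repl
    }
  }
  seq
}

#' Simulate a region sequence with a planted iPCR assay
#'
#' Generates a random standard-allele sequence with the A-IR1-B-C-IR2-D
#' layout (IR2 the reverse complement of IR1), exactly one restriction site
#' planted in each unique segment and none elsewhere, and outward-facing
#' primers flanking the sites; builds the corresponding inverted allele; and
#' emits the expected product sizes computed by explicit string digestion and
#' self-ligation (\code{\link{amplicons_by_ligation}}), which serves as the
#' ground truth for the coordinate-arithmetic predictor.
#'
#' @param seed RNG seed.
#' @param enzyme A \code{\link{restriction_enzyme}} (default BamHI from the
#'   packaged catalog).
#' @param seg_len Segment lengths in bp:
#'   list(a, ir, b, c, d).
#' @param primer_len Primer length in bp.
#' @param site_margin Distance of each planted site from the segment edge.
#' @param primer_gap Distance between cut site and the near primer end.
#' @return list(region, std_seq, inv_seq, assay, truth_products,
#'   exchange_points).
#' @export
simulate_region_sequence <- function(seed, enzyme = NULL,
                                     seg_len = list(a = 1500, ir = 400,
                                                    b = 1000, c = 1000,
                                                    d = 1500),
                                     primer_len = 22, site_margin = 200,
                                     primer_gap = 40) {
  set.seed(seed + 2000003L)
  if (is.null(enzyme)) enzyme <- read_enzyme_catalog()[["BamHI"]]
  if (2 * (site_margin + primer_gap + primer_len) >
      min(unlist(seg_len[c("b", "c")])))
    stop("segments too short for the requested site/primer layout")
  ir1 <- scrub_word(rand_dna(seg_len$ir), enzyme$site)
  segs <- list(a = rand_dna(seg_len$a), ir1 = ir1, b = rand_dna(seg_len$b),
               c = rand_dna(seg_len$c), ir2 = revcomp(ir1),
               d = rand_dna(seg_len$d))
  for (s in c("a", "b", "c", "d"))
    segs[[s]] <- scrub_word(segs[[s]], enzyme$site)
  ## local coordinates of each segment
  lens <- vapply(segs, nchar, 0L)
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  names(starts) <- names(ends) <- names(segs)
  plant <- function(seq, at, word) {
    substr(seq, at, at + nchar(word) - 1L) <- word
    seq
  }
  ## one site per unique segment: near the IR-proximal side, leaving room for
  ## the outward primers between site and IR
  site_at <- c(a = ends[["a"]] - site_margin,
               b = starts[["b"]] + site_margin,
               c = ends[["c"]] - site_margin,
               d = starts[["d"]] + site_margin)
  seq <- paste(unlist(segs), collapse = "")
  site <- enzyme$site   # catalog sites are literal ACGT
  for (s in names(site_at)) seq <- plant(seq, site_at[[s]], site)
  cuts <- site_at - 1L + enzyme$cut_top
  names(cuts) <- names(site_at)
  sub <- function(s, e) substr(seq, s, e)
  primers <- list(
    ## reverse primers sit just right of the left cut, oligo = revcomp(+)
    primer("pA", revcomp(sub(cuts[["a"]] + primer_gap + 1,
                             cuts[["a"]] + primer_gap + primer_len)), "A"),
    primer("pB", sub(cuts[["b"]] - primer_gap - primer_len + 1,
                     cuts[["b"]] - primer_gap), "B"),
    primer("pC", revcomp(sub(cuts[["c"]] + primer_gap + 1,
                             cuts[["c"]] + primer_gap + primer_len)), "C"),
    primer("pD", sub(cuts[["d"]] - primer_gap - primer_len + 1,
                     cuts[["d"]] - primer_gap), "D"))
  chrom <- "chrSim"
  gi <- function(nm) genomic_interval(chrom, starts[[nm]], ends[[nm]])
  region <- inversion_region(sprintf("SimInv%05d", seed %% 100000),
                             gi("a"), gi("ir1"), gi("b"), gi("c"), gi("ir2"),
                             gi("d"))
  ex <- floor(c(iv_mid(region$ir1), iv_mid(region$ir2)))
  inv_seq <- build_inverted_allele(seq, region, ex)
  assay <- ipcr_assay(region$id, enzyme, primers)
  truth <- list(std = amplicons_by_ligation(assay, seq),
                inv = amplicons_by_ligation(assay, inv_seq))
  list(region = region, std_seq = seq, inv_seq = inv_seq, assay = assay,
       truth_products = truth, exchange_points = ex)
}

#' iPCR product sizes by explicit string digestion and self-ligation
#'
#' Independent route to the amplicon sizes: the allele is cut by literal
#' string search for the recognition site (both orientations), each fragment
#' is self-ligated by rotating it so it starts at the forward primer, and the
#' product length is read off as the end position of the reverse-primer site
#' in the rotated string. The AD concatamer is measured on the head-to-tail
#' concatenation of the A- and D-containing fragments. Used as the oracle the
#' coordinate-arithmetic \code{\link{predict_amplicons}} must reproduce.
#'
#' @param assay An \code{\link{ipcr_assay}} with literal (non-IUPAC) site.
#' @param allele Allele sequence.
#' @return Named integer vector of product sizes in bp.
#' @export
amplicons_by_ligation <- function(assay, allele) {
  enz <- assay$enzyme
  find_all <- function(word, s) {
    out <- c(); from <- 1L
    repeat {
      h <- regexpr(word, substr(s, from, nchar(s)), fixed = TRUE)
      if (h < 0) break
      out <- c(out, from + h - 1L); from <- from + h
    }
    out
  }
  sites_f <- find_all(enz$site, allele)
  rc <- revcomp(enz$site)
  sites_r <- if (rc == enz$site) integer(0) else
    setdiff(find_all(rc, allele), sites_f)
  cuts <- sort(unique(c(sites_f - 1L + enz$cut_top,
                        sites_r - 1L + nchar(enz$site) - enz$cut_bottom)))
  cuts <- cuts[cuts > 0 & cuts < nchar(allele)]
  b <- c(0L, cuts, nchar(allele))
  frag_str <- vapply(seq_len(length(b) - 1L), function(i)
    substr(allele, b[i] + 1L, b[i + 1L]), "")
  locate_frag <- function(word) {
    hits <- which(vapply(frag_str, function(f)
      grepl(word, f, fixed = TRUE) | grepl(revcomp(word), f, fixed = TRUE),
      TRUE))
    hits
  }
  measure <- function(circle, fwd_oligo, rev_oligo) {
    s <- regexpr(fwd_oligo, circle, fixed = TRUE)
    if (s < 0) return(NA_integer_)
    rot <- paste0(substr(circle, s, nchar(circle)), substr(circle, 1, s - 1))
    t <- regexpr(revcomp(rev_oligo), rot, fixed = TRUE)
    if (t < 0) return(NA_integer_)
    as.integer(t + nchar(rev_oligo) - 1L)
  }
  prim <- assay$primers
  segs <- names(prim)
  prods <- integer(0)
  for (i in seq_along(prim)) for (j in seq_along(prim)) {
    if (i == j) next
    lab <- paste0(sort(c(segs[i], segs[j])), collapse = "")
    if (lab == "AD" || lab %in% names(prods)) next
    fi <- locate_frag(prim[[i]]$seq); fj <- locate_frag(prim[[j]]$seq)
    common <- intersect(fi, fj)
    if (length(common) != 1L) next
    f <- frag_str[common]
    ## assign roles by where the oligos sit on the fragment: the junction
    ## product needs the forward primer to the right of the reverse-primer
    ## site (outward-facing pair); a converging pair amplifies without the
    ## junction and is not an iPCR product
    keep <- c()
    for (v in list(c(i, j), c(j, i))) {
      s <- regexpr(prim[[v[1]]]$seq, f, fixed = TRUE)
      rvs <- regexpr(revcomp(prim[[v[2]]]$seq), f, fixed = TRUE)
      if (s < 0 || rvs < 0 || s <= rvs + nchar(prim[[v[2]]]$seq) - 1L) next
      keep <- c(keep, measure(f, prim[[v[1]]]$seq, prim[[v[2]]]$seq))
    }
    keep <- keep[!is.na(keep)]
    if (length(keep) == 1L) prods[lab] <- keep
  }
  if (all(c("A", "D") %in% segs)) {
    fa <- locate_frag(prim[["A"]]$seq); fd <- locate_frag(prim[["D"]]$seq)
    if (length(fa) == 1L && length(fd) == 1L && fa != fd) {
      circle <- paste0(frag_str[fa], frag_str[fd])
      v1 <- measure(circle, prim[["D"]]$seq, prim[["A"]]$seq)
      v2 <- measure(circle, prim[["A"]]$seq, prim[["D"]]$seq)
      v <- c(v1, v2); v <- v[!is.na(v)]
      if (length(v)) prods["AD"] <- min(v)
    }
  }
  prods
}

#' Simulate fosmid paired-end mapping records for one individual
#'
#' Draws insert positions uniformly along the individual's two alleles
#' (genotype-weighted), computes where each 500 bp end read maps on the
#' standard reference (reads inside the inverted span of an inverted allele
#' map back reverse-complemented), and emits mapping records. Reads falling
#' inside an inverted-repeat copy also emit the paralogous placement in the
#' other copy (opposite orientation, slightly lower identity/score),
#' reproducing the multi-mapping ambiguity of real repeat-spanning reads.
#' Reads straddling an exchange point produce no contiguous mapping.
#'
#' @param region \code{\link{inversion_region}} (reference coordinates; the
#'   simulation is purely geometric, no sequence needed).
#' @param genotype "Std/Std", "Std/Inv" or "Inv/Inv".
#' @param n_pairs Number of fosmid pairs.
#' @param insert_mean,insert_sd Insert size distribution (bp).
#' @param read_len End-read length (bp).
#' @param ir_identity Percent identity of the paralogous IR placement.
#' @param seed RNG seed.
#' @return list(mappings = data.frame(read_id, mate, chrom, start, end,
#'   strand, identity, score), truth = data.frame(fosmid allele arrangement)).
#' @export
simulate_fosmid_pairs <- function(region, genotype, n_pairs = 20,
                                  insert_mean = 40000, insert_sd = 2000,
                                  read_len = 500, ir_identity = 98,
                                  seed = 1) {
  set.seed(seed + 3000003L)
  chrom <- region$a$chrom
  L <- region$d$end
  if (insert_mean + 4 * insert_sd >= L) stop("insert longer than region")
  e1 <- floor(iv_mid(region$bp1)); e2 <- floor(iv_mid(region$bp2))
  alleles <- geno_alleles(genotype)
  if (length(alleles) == 0) stop("uncalled genotype")
  map_read <- function(s, e, strand, arrangement) {
    ## returns NULL (no contiguous mapping) or rows of mapping records
    if (arrangement == "Inv") {
      if (s <= e1 && e > e1) return(NULL)
      if (s <= e2 && e > e2) return(NULL)
      if (s > e1 && e <= e2) {
        ns <- e1 + e2 + 1 - e; ne <- e1 + e2 + 1 - s
        s <- ns; e <- ne; strand <- if (strand == "+") "-" else "+"
      }
    }
    rows <- data.frame(chrom = chrom, start = s, end = e, strand = strand,
                       identity = 99.5, score = read_len * 2)
    ## paralogous placement for reads inside an IR copy
    ir1 <- region$ir1; ir2 <- region$ir2
    if (s >= ir1$start && e <= ir1$end) {
      ps <- ir2$end - (e - ir1$start); pe <- ir2$end - (s - ir1$start)
      rows <- rbind(rows, data.frame(chrom = chrom, start = ps, end = pe,
                                     strand = if (strand == "+") "-" else "+",
                                     identity = ir_identity,
                                     score = floor(read_len * 2 * 0.98)))
    } else if (s >= ir2$start && e <= ir2$end) {
      ps <- ir1$start + (ir2$end - e); pe <- ir1$start + (ir2$end - s)
      rows <- rbind(rows, data.frame(chrom = chrom, start = ps, end = pe,
                                     strand = if (strand == "+") "-" else "+",
                                     identity = ir_identity,
                                     score = floor(read_len * 2 * 0.98)))
    }
    rows
  }
  recs <- list(); truth <- list()
  for (p in seq_len(n_pairs)) {
    arr <- alleles[sample.int(length(alleles), 1)]
    ins <- round(stats::rnorm(1, insert_mean, insert_sd))
    ins <- max(ins, 2 * read_len + 1)
    s <- sample.int(L - ins, 1)
    r1 <- map_read(s, s + read_len - 1, "+", arr)
    r2 <- map_read(s + ins - read_len, s + ins - 1, "-", arr)
    fid <- sprintf("fosmid%04d", p)
    truth[[p]] <- data.frame(fosmid_id = fid, arrangement = arr)
    if (!is.null(r1)) recs[[length(recs) + 1L]] <-
        cbind(read_id = fid, mate = 1L, r1)
    if (!is.null(r2)) recs[[length(recs) + 1L]] <-
        cbind(read_id = fid, mate = 2L, r2)
  }
  mappings <- if (length(recs)) do.call(rbind, recs) else
    data.frame(read_id = character(0), mate = integer(0), chrom = character(0),
               start = numeric(0), end = numeric(0), strand = character(0),
               identity = numeric(0), score = numeric(0))
  rownames(mappings) <- NULL
  list(mappings = mappings, truth = do.call(rbind, truth))
}

#' Template inversion region at fosmid scale
#'
#' A geometry-only locus big enough for 40 kb inserts: 60 kb unique flanks,
#' 5 kb IRs and a 70 kb invertible interior.
#'
#' @param chrom Chromosome label.
#' @export
fosmid_region_template <- function(chrom = "chrSim") {
  gi <- function(s, e) genomic_interval(chrom, s, e)
  inversion_region("SimFosmid",
                   a = gi(1, 60000), ir1 = gi(60001, 65000),
                   b = gi(65001, 100000), c = gi(100001, 135000),
                   ir2 = gi(135001, 140000), d = gi(140001, 200000))
}

#' Simulate aligned IR copies with a planted exchange point
#'
#' Emits the standard-allele and inverted-allele alignments of the two IR
#' copies over the same columns, with paralogous sequence variants (PSVs) at
#' the requested columns; in the inverted allele the PSV states beyond the
#' exchange column are swapped between copies, as non-allelic homologous
#' recombination leaves them.
#'
#' @param seed RNG seed.
#' @param n_cols Alignment length.
#' @param psv_cols Columns carrying PSVs.
#' @param exchange_after PSVs at columns <= this value keep their copy of
#'   origin; later ones are exchanged... set 0 to exchange all.
#' @return list(std, inv, truth = list(exchanged_cols, boundary)).
#' @export
simulate_psv_alignment <- function(seed, n_cols = 200,
                                   psv_cols = seq(20, 180, by = 20),
                                   exchange_after = 100) {
  set.seed(seed + 4000003L)
  base <- strsplit(rand_dna(n_cols), "")[[1]]
  copy1 <- copy2 <- base
  for (p in psv_cols)
    copy2[p] <- setdiff(c("A", "C", "G", "T"), base[p])[sample.int(3, 1)]
  inv1 <- copy1; inv2 <- copy2
  swap <- psv_cols[psv_cols > exchange_after]
  inv1[swap] <- copy2[swap]; inv2[swap] <- copy1[swap]
  list(std = rbind(copy1, copy2), inv = rbind(inv1, inv2),
       truth = list(exchanged_cols = swap,
                    boundary = if (length(swap) && length(setdiff(psv_cols,
                                                                  swap)))
                      c(max(setdiff(psv_cols, swap)[setdiff(psv_cols, swap) <
                                                    min(swap)]), min(swap))
                    else NULL))
}
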