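#' Deterministic trio phasing of a child's genotypes
#'
#' Assigns each of the child's alleles to a parental origin whenever transmission
#' logic determines it uniquely: homozygous child sites are trivially phased,
#' heterozygous sites are phased when only one of the two (paternal, maternal)
#' assignments is compatible with the parents' genotypes, and sites where all
#' three members are heterozygous stay unphased. For chrX sons the single
#' maternal haplotype is the child's alleles verbatim. Inconsistent transmission
#' raises an error naming the site.
#'
#' @param child,father,mother Alt-allele dosage vectors (0/1/2; NA allowed in
#'   parents, treated as unconstrained).
#' @param positions Site positions used in error messages.
#' @param chrom_type,child_sex Sex-chromosome handling as in
#'   \code{\link{mendelian_check}}.
#' @return list(paternal, maternal, unphased): two 0/1 haplotype vectors with
#'   NA at unphased sites and the logical unphased mask.
#' @export
trio_phase <- function(child, father = NULL, mother = NULL,
                       positions = seq_along(child),
                       chrom_type = "autosome", child_sex = NULL) {
  n <- length(child)
  if (is.null(father)) father <- rep(NA_integer_, n)
  if (is.null(mother)) mother <- rep(NA_integer_, n)
  stopifnot(length(father) == n, length(mother) == n)
  if (chrom_type == "chrX" && identical(child_sex, "male")) {
    bad <- which(!is.na(mother) & ((child == 1 & mother == 0) |
                                   (child == 0 & mother == 2)))
    if (length(bad)) stop("Mendelian inconsistency at site ", positions[bad[1]])
    return(list(paternal = rep(NA_integer_, n), maternal = as.integer(child),
                unphased = rep(FALSE, n)))
  }
  transmissible <- function(g) {
    if (is.na(g)) c(0L, 1L)
    else switch(as.character(g), "0" = 0L, "1" = c(0L, 1L), "2" = 1L)
  }
  pat <- mat <- rep(NA_integer_, n)
  unphased <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (is.na(child[i])) { unphased[i] <- TRUE; next }
    tf <- transmissible(father[i]); tm <- transmissible(mother[i])
    if (child[i] != 1) {
      a <- child[i] / 2
      if (!(a %in% tf) || !(a %in% tm))
        stop("Mendelian inconsistency at site ", positions[i])
      pat[i] <- mat[i] <- as.integer(a)
    } else {
      opt1 <- 0L %in% tf && 1L %in% tm    # paternal 0, maternal 1
      opt2 <- 1L %in% tf && 0L %in% tm
      if (opt1 && opt2) unphased[i] <- TRUE
      else if (opt1) { pat[i] <- 0L; mat[i] <- 1L }
      else if (opt2) { pat[i] <- 1L; mat[i] <- 0L }
      else stop("Mendelian inconsistency at site ", positions[i])
    }
  }
  list(paternal = pat, maternal = mat, unphased = unphased)
}

#' Neighbor-joining tree from a haplotype distance matrix
#'
#' Saitou-Nei agglomeration over a symmetric distance matrix (delegated to the
#' standard implementation in \pkg{ape}); exact on additive matrices. The
#' degenerate two-taxon case returns a single split whose path length equals
#' the input distance.
#'
#' @param D Symmetric distance matrix (or \code{dist}) with zero diagonal.
#' @return An \pkg{ape} \code{phylo} tree with branch lengths.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (n < 2) stop("need at least two taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <- paste0("h", seq_len(n))
  if (n == 2) {
    tr <- list(edge = matrix(c(3L, 3L, 1L, 2L), 2, 2),
               edge.length = c(D[1, 2] / 2, D[1, 2] / 2),
               tip.label = rownames(D), Nnode = 1L)
    class(tr) <- "phylo"
    return(tr)
  }
  ape::nj(stats::as.dist(D))
}

## Fitch small parsimony for a binary character on a phylo tree.
## States coded as bitmasks (Std = 1, Inv = 2); returns the minimum number of
## state changes.
fitch_count <- function(tree, tip_states) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  sets <- integer(n_tip + tree$Nnode)
  sets[seq_len(n_tip)] <- tip_states
  changes <- 0L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  ## in postorder edge ordering every internal node first appears as a parent
  ## only after all its descendant internal nodes have been closed
  post_nodes <- unique(tree$edge[, 1])
  for (node in post_nodes) {
    s <- 0L; first <- TRUE
    for (ch in kids[[as.character(node)]]) {
      cs <- sets[ch]
      if (first) { s <- cs; first <- FALSE }
      else {
        inter <- bitwAnd(s, cs)
        if (inter == 0L) { s <- bitwOr(s, cs); changes <- changes + 1L }
        else s <- inter
      }
    }
    sets[node] <- s
  }
  changes
}

#' Minimum number of inversion events on a tree
#'
#' Fitch parsimony count of Std/Inv state changes over a haplotype tree: the
#' smallest number of inversion (or re-inversion) events that can explain the
#' arrangement labels given the genealogy. One event means the inversion is
#' compatible with a unique origin; two or more means it must have arisen
#' recurrently. Outgroup-labeled tips are dropped before counting. When the
#' haplotypes themselves are supplied, a recurrent call is annotated with the
#' longest haplotype block shared between arrangements; blocks of at most
#' \code{conversion_limit_bp} could instead be explained by a gene-conversion
#' tract and are flagged.
#'
#' @param tree \code{phylo} tree whose tip labels index \code{labels}.
#' @param labels Named character vector ("Std"/"Inv"/"outgroup") or vector in
#'   tip order.
#' @param haps Optional \code{\link{haplotype_set}} for the shared-block
#'   annotation.
#' @param conversion_limit_bp Tract length under which a shared block is
#'   flagged as potentially gene conversion (default 1000).
#' @return An object of class \code{event_count}: list(min_events,
#'   classification, shared_block_bp, conversion_flag).
#' @export
min_inversion_events <- function(tree, labels, haps = NULL,
                                 conversion_limit_bp = 1000) {
  tips <- tree$tip.label
  lab <- if (!is.null(names(labels))) labels[tips] else labels
  if (length(lab) != length(tips) || anyNA(lab))
    stop("every tip must be labeled")
  drop <- tips[lab == "outgroup"]
  if (length(drop)) {
    tree <- ape::drop.tip(tree, drop)
    tips <- tree$tip.label
    lab <- if (!is.null(names(labels))) labels[tips] else lab[lab != "outgroup"]
  }
  if (!all(lab %in% c("Std", "Inv"))) stop("labels must be Std or Inv")
  ev <- if (length(unique(lab)) == 1L) 0L
  else fitch_count(tree, ifelse(lab == "Std", 1L, 2L))
  classification <- if (ev == 0L) "indeterminate"
  else if (ev == 1L) "unique_origin" else "recurrent"
  block <- NA_real_; flag <- FALSE
  if (!is.null(haps) && ev >= 2L) {
    block <- shared_block_length(haps)
    flag <- is.finite(block) && block <= conversion_limit_bp
  }
  structure(list(min_events = ev, classification = classification,
                 shared_block_bp = block, conversion_flag = flag),
            class = "event_count")
}

#' @export
print.event_count <- function(x, ...) {
  cat(sprintf("<event_count> %d event(s): %s%s\n", x$min_events,
              x$classification,
              if (isTRUE(x$conversion_flag))
                sprintf(" (shared block %.0f bp: gene conversion possible)",
                        x$shared_block_bp) else ""))
  invisible(x)
}

#' Longest haplotype block shared between arrangements
#'
#' For every Std-Inv haplotype pair, the longest run of consecutive surveyed
#' sites with identical alleles, measured as the bp span of the run's
#' positions; the maximum over pairs is returned. Long shared blocks argue
#' for recurrence (or a long conversion tract) rather than independent
#' mutation.
#'
#' @param haps A \code{\link{haplotype_set}}.
#' @return Span in bp (0 when no two consecutive sites are ever shared).
#' @export
shared_block_length <- function(haps) {
  H <- haps$haplotypes
  pos <- haps$positions
  std <- which(haps$labels == "Std"); inv <- which(haps$labels == "Inv")
  best <- 0
  for (i in std) for (j in inv) {
    eq <- H[i, ] == H[j, ]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in which(r$values & r$lengths >= 2))
      best <- max(best, pos[ends[k]] - pos[starts[k]])
  }
  best
}

#' Haplotype network (minimum-spanning network over Hamming distances)
#'
#' Duplicate haplotypes are collapsed into nodes carrying their frequency and
#' arrangement composition. Edges form the minimum-spanning network: distances
#' are processed in increasing order and every edge of the current weight
#' class joining two previously disconnected components is kept, so all
#' co-minimal connections are retained (the epsilon = 0 reduced network).
#'
#' @param haps A \code{\link{haplotype_set}}.
#' @return An object of class \code{haplo_network}: list(nodes, edges,
#'   mst_weight) where nodes has frequency and per-arrangement counts and
#'   edges has from, to, weight (site differences).
#' @export
haplo_network <- function(haps) {
  H <- haps$haplotypes
  if (nrow(H) == 0L) stop("need at least one haplotype")
  key <- apply(H, 1, paste, collapse = "")
  uk <- unique(key)
  idx <- match(key, uk)
  nodes <- data.frame(node = seq_along(uk), frequency = tabulate(idx),
                      n_std = vapply(seq_along(uk), function(i)
                        sum(haps$labels[idx == i] == "Std"), 0L),
                      n_inv = vapply(seq_along(uk), function(i)
                        sum(haps$labels[idx == i] == "Inv"), 0L))
  Hu <- H[match(uk, key), , drop = FALSE]
  m <- nrow(Hu)
  edges <- data.frame(from = integer(0), to = integer(0), weight = numeric(0))
  mst_weight <- 0
  if (m > 1) {
    D <- hamming_matrix(Hu)
    cand <- which(upper.tri(D), arr.ind = TRUE)
    ew <- D[cand]
    ord <- order(ew, cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]; ew <- ew[ord]
    comp <- seq_len(m)
    keep <- logical(length(ew))
    for (w in unique(ew)) {
      sel <- which(ew == w)
      joined <- comp[cand[sel, 1]] != comp[cand[sel, 2]]
      keep[sel][joined] <- TRUE
      for (k in sel[joined]) {         # merge after collecting the class
        c1 <- comp[cand[k, 1]]; c2 <- comp[cand[k, 2]]
        if (c1 != c2) mst_weight <- mst_weight + w
        comp[comp == c2] <- c1
      }
    }
    edges <- data.frame(from = cand[keep, 1], to = cand[keep, 2],
                        weight = ew[keep])
  }
  structure(list(nodes = nodes, edges = edges, haplotypes = Hu,
                 mst_weight = mst_weight),
            class = "haplo_network")
}

#' @export
print.haplo_network <- function(x, ...) {
  cat(sprintf("<haplo_network> %d nodes, %d edges (spanning weight %g)\n",
              nrow(x$nodes), nrow(x$edges), x$mst_weight))
  invisible(x)
}

#' Write a haplotype network as an edge list / DOT file
#'
#' @param net A \code{\link{haplo_network}}.
#' @param path Output path; a \code{.dot} extension writes Graphviz DOT,
#'   anything else a TSV edge list.
#' @export
write_network <- function(net, path) {
  if (grepl("\\.dot$", path)) {
    lines <- c("graph haplotypes {",
               sprintf("  n%d [label=\"%d (Std %d/Inv %d)\"];",
                       net$nodes$node, net$nodes$frequency, net$nodes$n_std,
                       net$nodes$n_inv),
               sprintf("  n%d -- n%d [label=\"%g\"];",
                       net$edges$from, net$edges$to, net$edges$weight),
               "}")
    writeLines(lines, path)
  } else {
    utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Ancestral orientation call from outgroup states
#'
#' Votes over the chimpanzee and gorilla iPCR orientation calls: a species
#' that is polymorphic (Std/Inv) or undetermined (ND) abstains. Two agreeing
#' fixed states give that state; conflicting fixed states give Unknown; a
#' single voter gives its state with a low-confidence annotation; no voters
#' give Unknown.
#'
#' @param chimp_state,gorilla_state "Std", "Inv", "Std/Inv" or "ND".
#' @return list(chimp_state, gorilla_state, call, confidence).
#' @export
ancestral_orientation <- function(chimp_state, gorilla_state) {
  states <- c(chimp_state, gorilla_state)
  votes <- states[states %in% c("Std", "Inv")]
  out <- if (length(votes) == 2) {
    if (votes[1] == votes[2]) list(call = votes[1], confidence = "high")
    else list(call = "Unknown", confidence = "conflict")
  } else if (length(votes) == 1) {
    list(call = votes, confidence = "low")
  } else list(call = "Unknown", confidence = "none")
  c(list(chimp_state = chimp_state, gorilla_state = gorilla_state), out)
}

#' Summary of inversion orientation across primate species
#'
#' Counts, over the assayable inversions (at least one species with a call),
#' how many are polymorphic within at least one non-human species
#' (a Std/Inv call) and how many show both orientations either within a
#' species or between species (adding those whose two species are fixed for
#' opposite orientations).
#'
#' @param calls data.frame with columns \code{chimp} and \code{gorilla}
#'   ("Std", "Inv", "Std/Inv" or "ND"); e.g. \code{\link{genotyping_table}()}.
#' @return list(n_assayable, n_polymorphic_within, n_both_orientations).
#' @export
primate_polymorphism_summary <- function(calls) {
  ch <- calls$chimp; go <- calls$gorilla
  assayable <- ch != "ND" | go != "ND"
  poly <- (ch == "Std/Inv" | go == "Std/Inv") & assayable
  opposite <- ch %in% c("Std", "Inv") & go %in% c("Std", "Inv") & ch != go
  list(n_assayable = sum(assayable),
       n_polymorphic_within = sum(poly),
       n_both_orientations = sum(poly | opposite))
}
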