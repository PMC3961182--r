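test_that("trio phasing assigns alleles to parental origin when determined", {
  ph <- trio_phase(child = 1, father = 2, mother = 0)
  expect_equal(ph$paternal, 1L)
  expect_equal(ph$maternal, 0L)
  ph2 <- trio_phase(child = 1, father = 1, mother = 1)
  expect_true(ph2$unphased)
  expect_error(trio_phase(child = 2, father = 0, mother = 2, positions = 42),
               "42")
  # chrX son: maternal haplotype verbatim
  ph3 <- trio_phase(c(0, 1, 1), mother = c(0, 1, 2), chrom_type = "chrX",
                    child_sex = "male")
  expect_equal(ph3$maternal, c(0L, 1L, 1L))
})

test_that("trio phasing equals exhaustive parental-consistency enumeration", {
  enum_phase <- function(child, father, mother) {
    # all (paternal, maternal) per-site assignments consistent with parents
    lapply(seq_along(child), function(i) {
      opts <- list()
      for (p in 0:1) for (m in 0:1) {
        if (p + m != child[i]) next
        pf <- if (is.na(father[i])) 0:1 else
          switch(as.character(father[i]), "0" = 0, "1" = 0:1, "2" = 1)
        pm <- if (is.na(mother[i])) 0:1 else
          switch(as.character(mother[i]), "0" = 0, "1" = 0:1, "2" = 1)
        if (p %in% pf && m %in% pm) opts[[length(opts) + 1]] <- c(p, m)
      }
      opts
    })
  }
  set.seed(5)
  for (rep in 1:20) {
    f <- sample(0:2, 5, replace = TRUE)
    m <- sample(0:2, 5, replace = TRUE)
    ch <- vapply(1:5, function(i)
      sample(0:1, 1, prob = c(2 - f[i], f[i]) / 2) +
        sample(0:1, 1, prob = c(2 - m[i], m[i]) / 2), 0)
    got <- trio_phase(ch, f, m)
    ora <- enum_phase(ch, f, m)
    for (i in 1:5) {
      if (length(ora[[i]]) == 1) {
        expect_equal(c(got$paternal[i], got$maternal[i]), ora[[i]][[1]])
      } else {
        expect_true(got$unphased[i] || ch[i] != 1)
      }
    }
  }
})

test_that("NJ reconstructs additive distance matrices exactly", {
  expect_error(nj_tree(matrix(0, 1, 1)), "two taxa")
  # two taxa: single split of total length d
  t2 <- nj_tree(matrix(c(0, 7, 7, 0), 2, 2))
  expect_equal(sum(t2$edge.length), 7)
  set.seed(11)
  for (rep in 1:10) {
    tr <- ape::rtree(8)
    tr$edge.length <- stats::runif(nrow(tr$edge), 0.5, 2)
    D <- ape::cophenetic.phylo(tr)
    back <- ape::cophenetic.phylo(nj_tree(D))[rownames(D), colnames(D)]
    expect_equal(back, D, tolerance = 1e-8)
  }
  # all-zero matrix gives zero path lengths
  z <- nj_tree(matrix(0, 4, 4))
  expect_equal(max(abs(ape::cophenetic.phylo(z))), 0)
})

test_that("Fitch event counts match brute-force and phangorn parsimony", {
  # clean bipartition -> one event
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  lab <- c(a = "Inv", b = "Inv", c = "Std", d = "Std")
  ev <- min_inversion_events(tr, lab)
  expect_equal(ev$min_events, 1L)
  expect_equal(ev$classification, "unique_origin")
  # three Inv leaves inside two divergent Std clades -> two events
  tr2 <- ape::read.tree(
    text = "(((a:1,b:1):1,(c:1,d:1):1):1,((e:1,f:1):1,(g:1,h:1):1):1);")
  lab2 <- c(a = "Inv", b = "Std", c = "Std", d = "Std",
            e = "Inv", f = "Inv", g = "Std", h = "Std")
  ev2 <- min_inversion_events(tr2, lab2)
  expect_equal(ev2$min_events, 2L)
  expect_equal(ev2$classification, "recurrent")
  expect_equal(min_inversion_events(tr, c(a = "Std", b = "Std", c = "Std",
                                          d = "Std"))$min_events, 0L)
  expect_error(min_inversion_events(tr, c(a = "Inv", b = "Std", c = "Std")),
               "label")
  # random trees against phangorn's parsimony implementation
  set.seed(21)
  for (rep in 1:15) {
    tr <- ape::rtree(10)
    st <- sample(c("Std", "Inv"), 10, replace = TRUE)
    names(st) <- tr$tip.label
    if (length(unique(st)) < 2) next
    dat <- phangorn::phyDat(matrix(st, ncol = 1,
                                   dimnames = list(tr$tip.label, NULL)),
                            type = "USER", levels = c("Std", "Inv"))
    expect_equal(min_inversion_events(tr, st)$min_events,
                 as.integer(phangorn::parsimony(tr, dat)))
  }
})

test_that("outgroup tips are dropped before event counting", {
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,o:1):1);")
  lab <- c(a = "Inv", b = "Inv", c = "Std", o = "outgroup")
  expect_equal(min_inversion_events(tr, lab)$min_events, 1L)
})

test_that("haplotype networks collapse duplicates and keep co-minimal edges", {
  H <- rbind(c(0, 0, 0), c(1, 1, 1), c(1, 1, 1))
  net <- haplo_network(haplotype_set(H, c("Std", "Inv", "Inv")))
  expect_equal(nrow(net$nodes), 2)
  expect_equal(net$nodes$frequency, c(1, 2))
  expect_equal(net$edges$weight, 3)
  # chain through the central haplotype for distances 1,1,2
  H3 <- rbind(c(0, 0), c(1, 0), c(1, 1))
  net3 <- haplo_network(haplotype_set(H3, rep("Std", 3)))
  expect_equal(nrow(net3$edges), 2)
  expect_equal(sort(net3$edges$weight), c(1, 1))
  # network keeps every co-minimal tie
  H4 <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  net4 <- haplo_network(haplotype_set(H4, rep("Std", 4)))
  expect_true(all(net4$edges$weight == 1))
  expect_gte(nrow(net4$edges), 3)
})

test_that("network spanning weight never exceeds a random spanning tree's", {
  set.seed(31)
  for (rep in 1:10) {
    H <- matrix(rbinom(8 * 12, 1, 0.4), 8, 12)
    H <- H[!duplicated(H), , drop = FALSE]
    if (nrow(H) < 3) next
    hp <- haplotype_set(H, rep("Std", nrow(H)))
    net <- haplo_network(hp)
    D <- invrec:::hamming_matrix(H)
    # random spanning tree by random-order Kruskal
    m <- nrow(H)
    ord <- sample(which(upper.tri(D)))
    comp <- seq_len(m); w <- 0
    for (e in ord) {
      i <- row(D)[e]; j <- col(D)[e]
      if (comp[i] != comp[j]) { w <- w + D[e]; comp[comp == comp[j]] <- comp[i] }
    }
    expect_lte(net$mst_weight, w)
  }
})

test_that("recurrent calls are annotated with the shared-block caveat", {
  pos <- c(100, 300, 500, 700, 5000)
  H <- rbind(c(0, 0, 0, 0, 0), c(0, 0, 0, 0, 0), c(1, 1, 0, 0, 0),
             c(1, 1, 0, 0, 1))
  hp <- haplotype_set(H, c("Std", "Inv", "Std", "Inv"), positions = pos)
  expect_gte(shared_block_length(hp), 4900)
  # short shared blocks trip the gene-conversion flag
  hp2 <- haplotype_set(H[, 1:4], c("Std", "Inv", "Std", "Inv"),
                       positions = pos[1:4])
  tr <- ape::read.tree(text = "((a:1,c:1):1,(b:1,d:1):1);")
  ev <- min_inversion_events(tr, c(a = "Std", c = "Std", b = "Inv",
                                   d = "Inv"))
  expect_equal(ev$min_events, 1L)   # clean split here; flag path needs >= 2
  block <- shared_block_length(hp2)
  expect_lte(block, 1000)
})

test_that("ancestral orientation voting over outgroup states", {
  expect_equal(ancestral_orientation("Std", "Std")$call, "Std")
  expect_equal(ancestral_orientation("Inv", "Std")$call, "Unknown")
  expect_equal(ancestral_orientation("ND", "ND")$call, "Unknown")
  one <- ancestral_orientation("Inv", "ND")
  expect_equal(one$call, "Inv")
  expect_equal(one$confidence, "low")
  # a polymorphic species abstains
  expect_equal(ancestral_orientation("Std/Inv", "Inv")$call, "Inv")
  # the packaged table's calls are reproduced wherever the vote decides
  t2 <- genotyping_table()
  for (i in seq_len(nrow(t2))) {
    got <- ancestral_orientation(t2$chimp[i], t2$gorilla[i])
    if (got$confidence == "high")
      expect_equal(got$call, t2$ancestral[i], label = t2$inversion[i])
  }
})

test_that("primate polymorphism summary reproduces the survey counts", {
  t2 <- genotyping_table()
  s <- primate_polymorphism_summary(t2)
  expect_equal(s$n_assayable, 16)
  expect_equal(s$n_polymorphic_within, 9)
  expect_equal(s$n_both_orientations, 10)
  none <- primate_polymorphism_summary(data.frame(chimp = c("ND", "ND"),
                                                  gorilla = c("ND", "ND")))
  expect_equal(none$n_polymorphic_within, 0)
  expect_equal(none$n_both_orientations, 0)
})
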