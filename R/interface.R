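#' Write a genotype table as VCF (inversion as a pseudo-marker)
#'
#' Emits a minimal VCF 4.2: the inversion genotype as a symbolic record
#' (ID \code{INV}, ALT \code{<INV>}) at the given position, then one biallelic
#' record per SNP. Hemizygous samples carry single-allele GT fields.
#'
#' @param table A \code{\link{genotype_table}}.
#' @param path Output path.
#' @param chrom Chromosome label.
#' @param inv_pos Position given to the inversion pseudo-marker.
#' @export
write_genotypes_vcf <- function(table, path, chrom = "chrSim", inv_pos = 1) {
  ids <- table$samples$sample_id
  gt_inv <- vapply(seq_along(ids), function(i) {
    g <- table$inv_call[i]
    if (is.na(g) || g == "missing")
      return(if (table$ploidy[i] == 2) "./." else ".")
    a <- geno_alleles(g)
    paste(ifelse(a == "Inv", "1", "0"), collapse = "/")
  }, "")
  lines <- c("##fileformat=VCFv4.2",
             "##ALT=<ID=INV,Description=\"Inversion\">",
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"),
             paste(c(chrom, inv_pos, "INV", "N", "<INV>", ".", ".",
                     "SVTYPE=INV", "GT", gt_inv), collapse = "\t"))
  if (ncol(table$snp_geno) > 0) {
    for (j in seq_len(ncol(table$snp_geno))) {
      gt <- vapply(seq_along(ids), function(i) {
        d <- table$snp_geno[i, j]
        if (table$ploidy[i] < 2) {
          if (table$ploidy[i] == 0 || is.na(d)) "." else as.character(d)
        } else if (is.na(d)) "./."
        else c("0/0", "0/1", "1/1")[d + 1]
      }, "")
      lines <- c(lines, paste(c(chrom, table$snp_pos[j],
                                sprintf("snp%d", j), "A", "G", ".", ".", ".",
                                "GT", gt), collapse = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from VCF plus a PED pedigree
#'
#' Parses GT fields of a VCF written by \code{\link{write_genotypes_vcf}} (or
#' any VCF whose first record with ID \code{INV} encodes the inversion and
#' whose other records are biallelic SNPs) together with a 6-column PED file.
#'
#' @param vcf_path,ped_path File paths.
#' @param chrom_type Chromosome type of the region.
#' @return A \code{\link{genotype_table}}.
#' @export
read_genotypes_vcf <- function(vcf_path, ped_path,
                               chrom_type = c("autosome", "chrX", "chrY")) {
  chrom_type <- match.arg(chrom_type)
  lines <- readLines(vcf_path)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1)
    stop("malformed VCF: no #CHROM header in ", vcf_path)
  cols <- strsplit(lines[hdr], "\t")[[1]]
  ids <- cols[-(1:9)]
  body <- lines[-seq_len(hdr)]
  body <- body[nzchar(body)]
  recs <- strsplit(body, "\t")
  bad <- which(lengths(recs) != length(cols))
  if (length(bad))
    stop("malformed VCF record at line ", hdr + bad[1], " of ", vcf_path)
  ped <- read_ped(ped_path)
  m <- match(ids, ped$sample_id)
  if (anyNA(m)) stop("samples missing from PED: ",
                     paste(ids[is.na(m)], collapse = ", "))
  samples <- data.frame(sample_id = ids,
                        sex = c("male", "female")[ped$sex[m]],
                        population = "NA",
                        father_id = ifelse(ped$father_id[m] == "0", NA,
                                           ped$father_id[m]),
                        mother_id = ifelse(ped$mother_id[m] == "0", NA,
                                           ped$mother_id[m]),
                        stringsAsFactors = FALSE)
  parse_gt <- function(x) {
    gt <- sub(":.*", "", x)
    al <- strsplit(gt, "[/|]")
    al
  }
  inv_call <- rep(NA_character_, length(ids))
  snp_pos <- c(); snp_cols <- list()
  for (r in recs) {
    al <- parse_gt(r[-(1:9)])
    if (r[3] == "INV" || r[5] == "<INV>") {
      inv_call <- vapply(al, function(a) {
        a <- a[a != "."]
        if (length(a) == 0) NA_character_
        else geno_string_multi(ifelse(a == "1", "Inv", "Std"))
      }, "")
    } else {
      snp_pos <- c(snp_pos, as.numeric(r[2]))
      snp_cols[[length(snp_cols) + 1L]] <- vapply(al, function(a) {
        a <- a[a != "."]
        if (length(a) == 0) NA_integer_ else sum(as.integer(a))
      }, 0L)
    }
  }
  geno <- if (length(snp_cols)) do.call(cbind, snp_cols) else NULL
  genotype_table(samples, inv_call, snp_pos = as.numeric(snp_pos),
                 snp_geno = geno, chrom_type = chrom_type)
}

geno_string_multi <- function(a) {
  if (length(a) == 1) a else paste(sort(a, decreasing = TRUE), collapse = "/")
}

#' Read / write a 6-column PED pedigree file
#'
#' Columns: family, sample_id, father_id, mother_id, sex (1 = male,
#' 2 = female), phenotype; "0" marks an absent parent.
#'
#' @param path File path.
#' @param ped data.frame in the same column layout (for writing).
#' @export
read_ped <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("family", "sample_id", "father_id",
                                        "mother_id", "sex", "phenotype"))
  df$sample_id <- as.character(df$sample_id)
  df$father_id <- as.character(df$father_id)
  df$mother_id <- as.character(df$mother_id)
  df
}

#' @rdname read_ped
#' @export
write_ped <- function(ped, path) {
  utils::write.table(ped, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an inversion-region file
#'
#' Inverse of \code{\link{read_regions}}.
#'
#' @param regions List of \code{\link{inversion_region}} objects.
#' @param path Output path.
#' @export
write_regions <- function(regions, path) {
  rows <- lapply(regions, function(r) {
    out <- data.frame(id = r$id, chrom = r$a$chrom)
    for (p in c("a", "ir1", "b", "c", "ir2", "d", "bp1", "bp2")) {
      out[[paste0(p, "_start")]] <- r[[p]]$start
      out[[paste0(p, "_end")]] <- r[[p]]$end
    }
    out$ir_class <- r$ir_class
    out
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load and validate pipeline inputs
#'
#' Reads whichever of the standard inputs are given (region file, SNP VCF +
#' PED, fosmid mapping table, enzyme catalog), validates their schemas, and
#' returns the in-memory objects. Malformed files raise errors naming the
#' offending file (and line, where determinable).
#'
#' @param regions,vcf,ped,mappings,enzymes Optional file paths.
#' @param chrom_type Passed to \code{\link{read_genotypes_vcf}}.
#' @return list with the loaded components (absent ones NULL) and row counts.
#' @export
load_inputs <- function(regions = NULL, vcf = NULL, ped = NULL,
                        mappings = NULL, enzymes = NULL,
                        chrom_type = "autosome") {
  out <- list()
  if (!is.null(regions)) {
    if (!file.exists(regions)) stop("region file not found: ", regions)
    out$regions <- read_regions(regions)
    if (length(out$regions) == 0) stop("empty region file: ", regions)
  }
  if (!is.null(vcf)) {
    if (is.null(ped)) stop("a PED file is required with a VCF")
    out$genotypes <- read_genotypes_vcf(vcf, ped, chrom_type)
  }
  if (!is.null(mappings)) out$mappings <- read_mappings(mappings)
  out$enzymes <- read_enzyme_catalog(enzymes)
  out$counts <- list(regions = length(out$regions),
                     samples = if (!is.null(out$genotypes))
                       nrow(out$genotypes$samples) else 0L,
                     mappings = if (!is.null(out$mappings))
                       nrow(out$mappings) else 0L)
  out
}

band_pattern_from_truth <- function(assay, genotype) {
  present <- character(0)
  if (any(geno_alleles(genotype) == "Std"))
    present <- c(present, intersect(c("AB", "CD"),
                                    names(assay$predicted_products$std)))
  if (any(geno_alleles(genotype) == "Inv"))
    present <- c(present, intersect(c("AC", "BD"),
                                    names(assay$predicted_products$inv)))
  list(observed = unique(present), controls_ok = TRUE)
}

#' Run the full synthetic pipeline
#'
#' Chains every stage on generated data with known truth: region sequence and
#' assay design, amplicon prediction and band-pattern genotyping of a
#' simulated cohort, fosmid pair classification and iPCR/PEM consistency,
#' population genetics of the cohort (frequency, heterozygosity, exact HWE,
#' Mendelian trio checks, shared/fixed SNP classes, diversity, Fst), and
#' recurrence inference on the haplotypes (NJ tree + Fitch event count,
#' haplotype network). With \code{out_dir} set, all inputs and summary tables
#' are written as plain text plus a JSON manifest; outputs are byte-identical
#' for identical seed and configuration.
#'
#' @param seed Integer seed driving every stage.
#' @param config A \code{\link{sim_config}} (defaults to
#'   \code{sim_config(seed)}).
#' @param out_dir Optional output directory.
#' @param n_permutations Fst permutation count.
#' @return list of per-stage results (invisibly when writing).
#' @export
invrec_pipeline <- function(seed = 1, config = NULL, out_dir = NULL,
                            n_permutations = 199) {
  if (is.null(config)) config <- sim_config(seed = seed)
  ## stage 1: assay design on a generated region
  regsim <- simulate_region_sequence(seed)
  assay <- predict_amplicons(regsim$assay, regsim$std_seq, regsim$inv_seq)
  ## stage 2: haplotypes and cohort
  hs <- simulate_haplotypes(config)
  cohort <- simulate_cohort(hs$haps, config)
  tab <- cohort$table
  ## stage 3: band-pattern genotyping against truth
  calls <- vapply(seq_len(nrow(tab$samples)), function(i) {
    g <- tab$inv_call[i]
    if (is.na(g)) return(NA_character_)
    pat <- band_pattern_from_truth(assay, g)
    hap <- tab$ploidy[i] == 1
    b1 <- call_genotype_from_bands(pat, 1, haploid = hap)$call
    b2 <- call_genotype_from_bands(pat, 2, haploid = hap)$call
    combine_breakpoint_genotypes(b1, b2)$call
  }, "")
  genotyping_errors <- sum(calls != tab$inv_call, na.rm = TRUE)
  ## stage 4: fosmid support for the first nine samples
  fr <- fosmid_region_template()
  pem <- lapply(seq_len(min(9, nrow(tab$samples))), function(i) {
    g <- tab$inv_call[i]
    if (is.na(g)) return(NULL)
    fs <- simulate_fosmid_pairs(fr, g, n_pairs = 30, seed = seed + i)
    cls <- classify_fosmids(fs$mappings,
                            ir_annotation(data.frame(
                              chrom = fr$a$chrom,
                              start = c(fr$ir1$start, fr$ir2$start),
                              end = c(fr$ir1$end, fr$ir2$end))))
    sup <- genotype_support(cls, sample_id = tab$samples$sample_id[i],
                            region_id = fr$id)
    list(support = sup, consistency = ipcr_consistency(sup, calls[i]))
  })
  pem <- pem[!vapply(pem, is.null, TRUE)]
  cons <- vapply(pem, `[[`, "", "consistency")
  ## stage 5: population genetics
  fh <- allele_freq_het(tab)
  u <- unrelated_samples(tab)
  cnt <- table(factor(tab$inv_call[u][tab$ploidy[u] == 2],
                      levels = c("Std/Std", "Std/Inv", "Inv/Inv")))
  hwe_p <- hwe_exact_test(cnt[1], cnt[2], cnt[3])
  mend <- vapply(which(!is.na(tab$samples$father_id)), function(ci) {
    fi <- match(tab$samples$father_id[ci], tab$samples$sample_id)
    mi <- match(tab$samples$mother_id[ci], tab$samples$sample_id)
    mendelian_check(tab$inv_call[ci], tab$inv_call[fi], tab$inv_call[mi],
                    chrom_type = tab$chrom_type,
                    child_sex = tab$samples$sex[ci])
  }, "")
  snpcls <- classify_snps_fixed_shared(tab)
  pis <- nucleotide_diversity(hs$haps, config$region_length_bp)
  fst <- fst_arrangements(hs$haps, n_permutations = n_permutations,
                          seed = seed + 5000003L)
  ld <- ld_r2_tags(hs$haps)
  ## stage 6: recurrence
  D <- hamming_matrix(hs$haps$haplotypes)
  rownames(D) <- colnames(D) <- sprintf("h%02d", seq_len(nrow(D)))
  tree <- nj_tree(D)
  labels <- stats::setNames(hs$haps$labels, rownames(D))
  events <- min_inversion_events(tree, labels, haps = hs$haps)
  net <- haplo_network(hs$haps)
  results <- list(
    seed = seed, config = config, assay = assay,
    truth_products = regsim$truth_products,
    genotyping = list(calls = calls, errors = genotyping_errors),
    pem_consistency = sprintf("%d/%d", sum(cons == "consistent"),
                              sum(cons != "not_evaluable")),
    popgen = list(inv_freq = fh$inv_freq, obs_het = fh$obs_het,
                  n_chromosomes = fh$n_chromosomes, hwe_p = hwe_p,
                  mendelian = sprintf("%d/%d", sum(mend == "pass"),
                                      sum(mend != "not_evaluable")),
                  snp_classes = snpcls$summary, pi = pis,
                  fst = fst$fst, fst_p = fst$p_value,
                  n_tag_snps = sum(ld$tag)),
    recurrence = list(min_events = events$min_events,
                      classification = events$classification,
                      true_events = hs$truth$event_count,
                      network_nodes = nrow(net$nodes)))
  if (!is.null(out_dir)) run_report(results, out_dir,
                                    extras = list(haps = hs$haps, table = tab,
                                                  ped = cohort$ped,
                                                  region = regsim$region,
                                                  tree = tree, net = net))
  invisible(results)
}

#' Write pipeline outputs and a run manifest
#'
#' Emits the genotyping summary and variation tables as TSV, the generated
#' inputs (haplotypes, VCF, PED, region file), the tree (newick) and network
#' (edge TSV), and a JSON manifest carrying the configuration, seed, package
#' version and the MD5 of the configuration so reruns are verifiable.
#'
#' @param results Result list from \code{\link{invrec_pipeline}}.
#' @param out_dir Output directory (created if needed).
#' @param extras Internal: generated objects to serialize alongside.
#' @return The output directory, invisibly.
#' @export
run_report <- function(results, out_dir, extras = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(out_dir, f)
  pg <- results$popgen
  genotyping <- data.frame(
    region = "SimInv", n_chromosomes = pg$n_chromosomes,
    inv_freq = round(pg$inv_freq, 4), obs_het = round(pg$obs_het, 4),
    hwe_p = signif(pg$hwe_p, 4), families = pg$mendelian,
    genotyping_errors = results$genotyping$errors,
    pem_consistency = results$pem_consistency)
  utils::write.table(genotyping, fp("genotyping_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  variation <- data.frame(
    region = "SimInv",
    n_snps = sum(pg$snp_classes), fixed = pg$snp_classes[["fixed"]],
    shared = pg$snp_classes[["shared"]],
    pi_all = signif(pg$pi$pi_all, 4), pi_std = signif(pg$pi$pi_std, 4),
    pi_inv = signif(pg$pi$pi_inv, 4), fst = round(pg$fst, 4),
    fst_p = signif(pg$fst_p, 4), n_tag_snps = pg$n_tag_snps,
    min_events = results$recurrence$min_events,
    classification = results$recurrence$classification)
  utils::write.table(variation, fp("variation_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(extras)) {
    write_haplotypes(extras$haps, fp("haplotypes.tsv"))
    write_genotypes_vcf(extras$table, fp("genotypes.vcf"))
    write_ped(extras$ped, fp("cohort.ped"))
    write_regions(stats::setNames(list(extras$region), extras$region$id),
                  fp("regions.tsv"))
    ape::write.tree(extras$tree, fp("haplotypes.nwk"))
    write_network(extras$net, fp("network.tsv"))
  }
  cfg_json <- jsonlite::toJSON(unclass(results$config), auto_unbox = TRUE,
                               digits = NA)
  cfg_file <- fp("config.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    package = "invrec",
    version = as.character(utils::packageVersion("invrec")),
    seed = results$seed,
    config_md5 = unname(tools::md5sum(cfg_file)),
    outputs = sort(setdiff(list.files(out_dir), "manifest.json")))
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, pretty = TRUE),
             fp("manifest.json"))
  invisible(out_dir)
}
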