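# Seeded generator of three-platform fold-change datasets with planted
# class structure: class-specific deregulated mRNAs, anti-correlated
# miRNA-target pairs, co-regulated proteins, and one enriched pathway per
# class. Every pipeline stage is testable against the recorded ground truth.

#' Configuration of the synthetic three-platform study
#'
#' Defaults emulate the study design the package targets: 2 genotoxic
#' carcinogens, 8 non-genotoxic carcinogens, 2 non-carcinogens and 3
#' undefined compounds, 3 replicate animals per compound, 2000 mRNA probes,
#' 300 miRNAs and a 158-antibody protein panel, with about 1% of protein
#' cells missing. Undefined compounds are generated with NGC-like profiles.
#'
#' @param n_compounds named counts per class (GC, NGC, NC, UNDEFINED).
#' @param replicates replicate samples per compound.
#' @param n_mrna,n_mirna,n_protein platform sizes.
#' @param n_genes gene-locus universe size.
#' @param n_planted_mrna planted informative mRNAs per class.
#' @param n_planted_pairs planted anti-correlated miRNA-target pairs per class.
#' @param n_planted_proteins planted co-regulated proteins per class (share
#'   their cognate mRNA's direction).
#' @param delta effect size: mean absolute log2 fold change of planted
#'   features (default 2).
#' @param compound_sd standard deviation of the Gaussian compound-level
#'   random effect shared by a compound's replicates (default 0.25).
#' @param noise_sd replicate-level Gaussian noise sd (default 0.5).
#' @param protein_missing fraction of protein cells deleted at random.
#' @param n_pathways,pathway_size_range random pathway catalogue dimensions.
#' @param targets_per_mirna mean number of (validated + predicted) targets
#'   drawn per miRNA for the background target map.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_compounds = c(GC = 2L, NGC = 8L, NC = 2L, UNDEFINED = 3L),
                             replicates = 3L,
                             n_mrna = 2000L, n_mirna = 300L, n_protein = 158L,
                             n_genes = 1500L,
                             n_planted_mrna = 10L, n_planted_pairs = 5L,
                             n_planted_proteins = 5L,
                             delta = 2.0, compound_sd = 0.25, noise_sd = 0.5,
                             protein_missing = 0.01,
                             n_pathways = 30L, pathway_size_range = c(10L, 40L),
                             targets_per_mirna = 4) {
  cfg <- as.list(environment())
  stopifnot(all(unlist(cfg[c("replicates", "n_mrna", "n_mirna", "n_protein",
                             "n_genes", "n_pathways")]) > 0),
            delta >= 0, compound_sd >= 0, noise_sd >= 0,
            protein_missing >= 0, protein_missing < 0.5)
  classes <- c("GC", "NGC", "NC")
  if (n_planted_mrna * length(classes) > n_mrna ||
      n_planted_pairs * length(classes) > min(n_mirna, n_planted_mrna * length(classes)) ||
      n_planted_proteins * length(classes) > n_protein)
    stop("planted feature counts exceed platform sizes")
  structure(cfg, class = "synthetic_config")
}

# deterministic alternating up/down signs for planted features
.plant_signs <- function(n) rep_len(c(1, -1), n)

#' Generate a synthetic three-platform fold-change dataset
#'
#' Each cell is `class effect + compound random effect + replicate noise`.
#' Planted mRNAs of a class carry a fixed effect of magnitude `delta`
#' (alternating sign); each planted miRNA-target pair gives the miRNA the
#' opposite sign of its target mRNA; planted proteins share their cognate
#' mRNA's sign; one pathway per class collects that class's planted mRNA
#' genes. UNDEFINED compounds reuse the NGC effects.
#'
#' @param config a [synthetic_config()].
#' @param seed integer master seed; same seed, bit-identical dataset.
#' @return list with `fc` (named list of [fold_change_matrix()]), `annot`,
#'   `genes`, `targets`, `pathways` and `truth` (planted features, pairs,
#'   proteins and pathways per class).
#' @export
generate_synthetic <- function(config = synthetic_config(), seed = 1L) {
  stopifnot(inherits(config, "synthetic_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cf <- config
  classes <- c("GC", "NGC", "NC")

  gene_ids <- sprintf("g%04d", seq_len(cf$n_genes))
  mrna_ids <- sprintf("m%04d", seq_len(cf$n_mrna))
  mirna_ids <- sprintf("mir%03d", seq_len(cf$n_mirna))
  prot_ids <- sprintf("p%03d", seq_len(cf$n_protein))

  # feature -> gene maps: mRNAs cycle over the gene universe; the protein
  # panel covers the first genes so cognate mRNAs exist
  gm <- rbind(
    data.frame(feature_id = mrna_ids, platform = "mRNA",
               gene_id = gene_ids[(seq_len(cf$n_mrna) - 1L) %% cf$n_genes + 1L],
               stringsAsFactors = FALSE),
    data.frame(feature_id = prot_ids, platform = "protein",
               gene_id = gene_ids[seq_len(cf$n_protein)],
               stringsAsFactors = FALSE))
  genes <- as_gene_map(gm)

  # compounds and samples
  annot <- do.call(rbind, lapply(names(cf$n_compounds), function(cl) {
    n <- cf$n_compounds[[cl]]
    if (n == 0L) return(NULL)
    do.call(rbind, lapply(seq_len(n), function(i) {
      cmp <- sprintf("%s%02d", cl, i)
      data.frame(sample_id = sprintf("%s_r%d", cmp, seq_len(cf$replicates)),
                 compound = cmp, class_label = cl, dosing_time = 7,
                 vehicle = "CO", is_control = FALSE, control_group_id = "ctrl",
                 stringsAsFactors = FALSE)
    }))
  }))
  annot <- as_sample_annotation(annot)
  samples <- annot$sample_id
  eff_class <- annot$class_label
  eff_class[eff_class == "UNDEFINED"] <- "NGC"

  # planted features per class, disjoint across classes
  planted <- list()
  idx_m <- split(seq_len(cf$n_planted_mrna * 3L),
                 rep(classes, each = cf$n_planted_mrna))
  for (cl in classes) {
    pm <- mrna_ids[idx_m[[cl]]]
    pmi <- mirna_ids[(match(cl, classes) - 1L) * cf$n_planted_pairs +
                       seq_len(cf$n_planted_pairs)]
    pp <- prot_ids[(match(cl, classes) - 1L) * cf$n_planted_proteins +
                     seq_len(cf$n_planted_proteins)]
    planted[[cl]] <- list(
      mrna = pm, signs = .plant_signs(length(pm)),
      pairs = data.frame(miRNA_id = pmi,
                         mrna = pm[seq_len(cf$n_planted_pairs)],
                         stringsAsFactors = FALSE),
      proteins = pp,
      protein_genes = genes$gene_id[match(pp, genes$feature_id)])
  }

  build <- function(ids, effect_of) {
    n_f <- length(ids)
    eff <- matrix(0, n_f, length(samples), dimnames = list(ids, samples))
    for (cl in classes) {
      cols <- eff_class == cl
      if (!any(cols)) next
      e <- effect_of(cl)
      eff[names(e), cols] <- e
    }
    cmp_eff <- matrix(stats::rnorm(n_f * length(unique(annot$compound)),
                                   sd = cf$compound_sd),
                      n_f, dimnames = list(ids, unique(annot$compound)))
    eff + cmp_eff[, annot$compound] +
      matrix(stats::rnorm(n_f * length(samples), sd = cf$noise_sd), n_f)
  }

  fc_mrna <- build(mrna_ids, function(cl)
    stats::setNames(cf$delta * planted[[cl]]$signs, planted[[cl]]$mrna))
  fc_mirna <- build(mirna_ids, function(cl) {
    pr <- planted[[cl]]$pairs
    tgt_sign <- planted[[cl]]$signs[match(pr$mrna, planted[[cl]]$mrna)]
    stats::setNames(-cf$delta * tgt_sign, pr$miRNA_id)
  })
  fc_prot <- build(prot_ids, function(cl) {
    pp <- planted[[cl]]$proteins
    cognate <- genes$gene_id[match(pp, genes$feature_id)]
    cog_mrna_sign <- vapply(cognate, function(g) {
      mr <- genes$feature_id[genes$platform == "mRNA" & genes$gene_id == g][1L]
      s <- planted[[cl]]$signs[match(mr, planted[[cl]]$mrna)]
      if (is.na(s)) 1 else s
    }, 0)
    stats::setNames(cf$delta * cog_mrna_sign, pp)
  })
  if (cf$protein_missing > 0) {
    holes <- stats::runif(length(fc_prot)) < cf$protein_missing
    fc_prot[holes] <- NA_real_
  }

  # target map: planted validated pairs + random background relations
  bg_n <- round(cf$n_mirna * cf$targets_per_mirna)
  bg <- data.frame(
    miRNA_id = sample(mirna_ids, bg_n, replace = TRUE),
    target_id = sample(mrna_ids, bg_n, replace = TRUE),
    evidence = sample(c("validated", "predicted"), bg_n, replace = TRUE),
    source = "synthetic-background", stringsAsFactors = FALSE)
  pl <- do.call(rbind, lapply(classes, function(cl)
    data.frame(miRNA_id = planted[[cl]]$pairs$miRNA_id,
               target_id = planted[[cl]]$pairs$mrna,
               evidence = "validated", source = "synthetic-planted",
               stringsAsFactors = FALSE)))
  targets <- merge_target_maps(as_target_map(pl), as_target_map(bg))

  # pathways: random sets over the gene universe plus one planted pathway
  # per class holding that class's planted mRNA genes
  size_hi <- min(cf$pathway_size_range[2L], cf$n_genes)
  size_lo <- min(cf$pathway_size_range[1L], size_hi)
  sets <- lapply(seq_len(cf$n_pathways), function(i)
    sample(gene_ids, sample(seq(size_lo, size_hi), 1L)))
  names(sets) <- sprintf("pw%03d", seq_len(cf$n_pathways))
  for (cl in classes) {
    pg <- genes$gene_id[match(planted[[cl]]$mrna, genes$feature_id)]
    pool <- setdiff(gene_ids, pg)
    filler <- sample(pool, min(10L, length(pool)))
    sets[[paste0("pw_", cl)]] <- c(pg, filler)
  }
  pathways <- pathway_collection(sets)

  list(fc = list(mRNA = fold_change_matrix(fc_mrna, "mRNA"),
                 miRNA = fold_change_matrix(fc_mirna, "miRNA"),
                 protein = fold_change_matrix(fc_prot, "protein")),
       annot = annot, genes = genes, targets = targets, pathways = pathways,
       truth = list(planted = planted,
                    pathway_of_class = stats::setNames(paste0("pw_", classes), classes)),
       config = cf, seed = seed)
}

#' Tiny deterministic worked-example fixture
#'
#' A hand-checkable dataset: 2 compounds per class (no undefined), 3
#' replicates, 20 mRNA / 6 miRNA / 8 protein features, 3 pathways. Used in
#' the documentation and tests; regeneration is idempotent. When `dir` is
#' given, all tables are written there as TSV/GMT.
#'
#' @param dir optional output directory.
#' @return the dataset list of [generate_synthetic()].
#' @export
worked_example <- function(dir = NULL) {
  cfg <- synthetic_config(
    n_compounds = c(GC = 2L, NGC = 2L, NC = 2L, UNDEFINED = 0L),
    replicates = 3L, n_mrna = 20L, n_mirna = 6L, n_protein = 8L,
    n_genes = 20L, n_planted_mrna = 2L, n_planted_pairs = 1L,
    n_planted_proteins = 1L, delta = 2, compound_sd = 0.25, noise_sd = 0.5,
    protein_missing = 0, n_pathways = 3L, pathway_size_range = c(4L, 6L),
    targets_per_mirna = 1)
  ds <- generate_synthetic(cfg, seed = 20140515L)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (p in names(ds$fc))
      write_fold_changes(ds$fc[[p]], file.path(dir, paste0("fc_", p, ".tsv")))
    utils::write.table(as.data.frame(ds$annot), file.path(dir, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(ds$genes), file.path(dir, "gene_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(ds$targets), file.path(dir, "target_map.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(vapply(names(ds$pathways$sets), function(id)
      paste(c(id, "synthetic pathway", ds$pathways$sets[[id]]), collapse = "\t"),
      ""), file.path(dir, "pathways.gmt"))
  }
  ds
}
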