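# Pathway-enrichment (PE) features: per-sample hypergeometric
# overrepresentation scores of pathways among deregulated genes unified
# across platforms.

#' Detect deregulated features in one sample
#'
#' A feature counts as significantly differentially expressed in a sample
#' when its absolute linear fold change exceeds `fc_threshold`, i.e.
#' `|log2FC| > log2(fc_threshold)` (strict).
#'
#' @param fc a [fold_change_matrix()].
#' @param sample_id one sample column of `fc`.
#' @param fc_threshold linear fold-change cutoff > 1 (default 2.5).
#' @return character vector of deregulated feature ids.
#' @export
detect_deregulated <- function(fc, sample_id, fc_threshold = 2.5) {
  stopifnot(inherits(fc, "fold_change_matrix"), fc_threshold > 1)
  if (!sample_id %in% colnames(fc$log_ratios))
    stop("unknown sample: ", sample_id)
  x <- fc$log_ratios[, sample_id]
  names(x)[!is.na(x) & abs(x) > log2(fc_threshold)]
}

# resolve miRNA targets to gene ids: target ids that are mRNA features go
# through the gene map, anything else is taken as a gene id directly
.target_genes <- function(mirnas, targets, genes) {
  tg <- targets[targets$miRNA_id %in% mirnas, , drop = FALSE]
  if (nrow(tg) == 0L) return(character())
  gm <- genes[genes$platform == "mRNA", , drop = FALSE]
  feat_hit <- tg$target_id %in% gm$feature_id
  via_map <- gm$gene_id[match(tg$target_id[feat_hit], gm$feature_id)]
  unique(c(via_map, tg$target_id[!feat_hit]))
}

#' Union of deregulated genes across platforms
#'
#' Maps deregulated mRNA and protein features to gene loci; deregulated
#' miRNAs, which canonical pathways do not contain, are represented by the
#' genes of their experimentally validated target mRNAs only. Unmapped
#' features are dropped and counted.
#'
#' @param deregulated named list of feature-id vectors per platform
#'   (`mRNA`, `miRNA`, `protein`; any may be absent).
#' @param genes a `gene_map`.
#' @param targets a `target_map`; only `evidence == "validated"` records are
#'   used here.
#' @return character vector of gene ids with attribute `"n_unmapped"`.
#' @export
combine_deregulated <- function(deregulated, genes, targets) {
  genes <- as_gene_map(as.data.frame(genes))
  targets <- as_target_map(as.data.frame(targets))
  targets <- targets[targets$evidence == "validated", , drop = FALSE]
  unmapped <- 0L
  out <- character()
  for (p in c("mRNA", "protein")) {
    feats <- deregulated[[p]]
    if (is.null(feats) || length(feats) == 0L) next
    gm <- genes[genes$platform == p, , drop = FALSE]
    hit <- feats %in% gm$feature_id
    unmapped <- unmapped + sum(!hit)
    out <- c(out, gm$gene_id[gm$feature_id %in% feats])
  }
  mir <- deregulated$miRNA
  if (!is.null(mir) && length(mir))
    out <- c(out, .target_genes(mir, targets, genes))
  structure(unique(out), n_unmapped = unmapped)
}

#' Upper-tail hypergeometric p-value for pathway overrepresentation
#'
#' With a universe of `N` genes of which `M` belong to the pathway, and `n`
#' deregulated genes of which `m` fall in the pathway, returns
#' `P(X >= m) = sum_{k=m}^{min(n,M)} C(M,k) C(N-M,n-k) / C(N,n)`,
#' evaluated through the log-space hypergeometric tail for numerical
#' stability. `m = 0` gives 1 by convention (the tail covers all outcomes).
#'
#' @param N universe size.
#' @param M pathway size within the universe.
#' @param n deregulated genes within the universe.
#' @param m deregulated genes inside the pathway.
#' @return p-value in (0, 1].
#' @export
hypergeometric_pvalue <- function(N, M, n, m) {
  stopifnot(length(N) == 1L, length(M) == 1L, length(n) == 1L, length(m) == 1L)
  if (m < 0 || M > N || n > N || m > min(n, M))
    stop(sprintf("invalid enrichment input: N=%d M=%d n=%d m=%d", N, M, n, m))
  if (m == 0) return(1)
  exp(.hyper_logp(N, M, n, m))
}

# log of the upper-tail p-value; kept in log space so -log10 scores stay
# finite even for extreme enrichments
.hyper_logp <- function(N, M, n, m) {
  if (m == 0) return(0)
  stats::phyper(m - 1, M, N - M, n, lower.tail = FALSE, log.p = TRUE)
}

#' Per-sample pathway-enrichment score vector
#'
#' Detects deregulated features in the sample on every platform, unifies
#' them to genes, and scores each pathway by `-log10` of the upper-tail
#' hypergeometric p-value. The universe is the union of all pathway gene
#' sets; deregulated genes outside it are excluded from `n`.
#'
#' @param sample_id sample to score.
#' @param fc_list named list of [fold_change_matrix()] per platform.
#' @param genes a `gene_map`.
#' @param targets a `target_map`.
#' @param pathways a `pathway_collection`.
#' @param fc_threshold linear fold-change cutoff (default 2.5).
#' @return named numeric vector of scores >= 0, ordered by pathway id, with
#'   attributes `"n_deregulated"` (genes inside the universe) and
#'   `"n_outside_universe"`.
#' @export
pe_vector <- function(sample_id, fc_list, genes, targets, pathways,
                      fc_threshold = 2.5) {
  stopifnot(inherits(pathways, "pathway_collection"))
  dereg <- lapply(fc_list, detect_deregulated, sample_id = sample_id,
                  fc_threshold = fc_threshold)
  names(dereg) <- vapply(fc_list, `[[`, "", "platform")
  gene_list <- combine_deregulated(dereg, genes, targets)
  universe <- pathways$universe
  inside <- intersect(gene_list, universe)
  N <- length(universe)
  n <- length(inside)
  ids <- sort(names(pathways$sets), method = "radix")
  scores <- vapply(ids, function(pid) {
    set <- pathways$sets[[pid]]
    M <- length(intersect(set, universe))
    m <- length(intersect(set, inside))
    if (m < 0 || M > N || n > N || m > min(n, M))
      stop(sprintf("invalid enrichment input: N=%d M=%d n=%d m=%d", N, M, n, m))
    -.hyper_logp(N, M, n, m) / log(10)
  }, 0)
  structure(scores, n_deregulated = n,
            n_outside_universe = length(gene_list) - n)
}

#' Pathway-enrichment feature matrix over samples
#'
#' Stacks [pe_vector()] results over samples. Feature ids are pathway ids
#' prefixed with the first letter of their source database (K/R/B, C for
#' custom).
#'
#' @inheritParams pe_vector
#' @param sample_ids samples to score; defaults to all treated samples in
#'   the first fold-change matrix.
#' @return a [feature_matrix()] with provenance `"PE"`.
#' @export
pe_matrix <- function(fc_list, genes, targets, pathways,
                      sample_ids = colnames(fc_list[[1L]]$log_ratios),
                      fc_threshold = 2.5) {
  vecs <- vapply(sample_ids, pe_vector, numeric(length(pathways$sets)),
                 fc_list = fc_list, genes = genes, targets = targets,
                 pathways = pathways, fc_threshold = fc_threshold)
  if (is.null(dim(vecs))) vecs <- matrix(vecs, ncol = length(sample_ids),
                                         dimnames = list(NULL, sample_ids))
  ids <- sort(names(pathways$sets), method = "radix")
  pref <- toupper(substr(pathways$source[ids], 1L, 1L))
  rownames(vecs) <- paste0("PE:", pref, ":", ids)
  feature_matrix(vecs, rep("PE", nrow(vecs)))
}
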