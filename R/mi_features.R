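# Molecular-interaction (MI) features: per-platform rescaling of log-ratios
# to [-1, 1] and per-sample interaction scores as products of scaled values.

#' Fit the per-platform scaling context
#'
#' Platforms differ in dynamic range, so log-ratios are mapped to a common
#' interval before cross-platform products are formed. The context records
#' the maximum absolute log-ratio over the reference set (in
#' cross-validation: the training fold only).
#'
#' @param fc a [fold_change_matrix()] (or numeric matrix/vector) of
#'   reference log-ratios.
#' @param platform platform tag when `fc` is a bare matrix.
#' @return a `scaling_context` with fields `platform` and `m_max`.
#' @export
fit_scaling <- function(fc, platform = NULL) {
  if (inherits(fc, "fold_change_matrix")) {
    x <- fc$log_ratios
    platform <- fc$platform
  } else x <- fc
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("cannot fit scaling: no finite log-ratios")
  structure(list(platform = platform, m_max = max(abs(x))),
            class = "scaling_context")
}

#' Rescale log-ratios to [-1, 1]
#'
#' Applies `g(x) = x / m_max`, clipping to \[-1, 1\] (clipping only matters
#' when the context was fitted on training data and `x` is a test value).
#' A degenerate all-zero reference set (`m_max = 0`) maps everything to 0.
#'
#' @param x numeric vector/matrix of log-ratios (NA preserved).
#' @param ctx a [fit_scaling()] context.
#' @return scaled values in \[-1, 1\], same shape as `x`.
#' @export
scale_log_ratios <- function(x, ctx) {
  stopifnot(inherits(ctx, "scaling_context"))
  if (ctx$m_max == 0) {
    out <- x * 0
  } else {
    out <- pmin(pmax(x / ctx$m_max, -1), 1)
  }
  out
}

#' Enumerate putative cross-layer interactions
#'
#' Builds the interaction catalogue from the target and gene maps:
#' miRNA-mRNA pairs (expected anti-correlated) for every target relation,
#' mRNA-protein pairs (expected co-regulated) sharing a gene locus, and
#' miRNA-protein pairs transitively inferred through the targeted mRNA.
#' Target ids may be mRNA feature ids or gene ids; gene ids are expanded to
#' all mRNA features mapped to them. Chains through different mediating
#' mRNAs stay distinct features.
#'
#' @param targets a `target_map`; use `evidence` to restrict.
#' @param genes a `gene_map` linking features to gene loci.
#' @param platform_features named list of feature-id vectors actually present
#'   per platform (`mRNA`, `miRNA`, `protein`).
#' @param evidence `"both"` (default), `"validated"` or `"predicted"`.
#' @return data frame of class `interaction_set`: columns `interaction_id`,
#'   `kind`, `member_a`, `platform_a`, `member_b`, `platform_b`,
#'   `expected_sign`, `evidence`.
#' @export
infer_interactions <- function(targets, genes, platform_features,
                               evidence = c("both", "validated", "predicted")) {
  evidence <- match.arg(evidence)
  targets <- as_target_map(as.data.frame(targets))
  genes <- as_gene_map(as.data.frame(genes))
  if (evidence != "both")
    targets <- targets[targets$evidence == evidence, , drop = FALSE]
  mrna_ids <- platform_features$mRNA %||% character()
  mirna_ids <- platform_features$miRNA %||% character()
  prot_ids <- platform_features$protein %||% character()

  gm_mrna <- genes[genes$platform == "mRNA" & genes$feature_id %in% mrna_ids, ]
  gm_prot <- genes[genes$platform == "protein" & genes$feature_id %in% prot_ids, ]

  # resolve each target record to concrete mRNA features on the platform
  direct <- targets$target_id %in% mrna_ids
  res_direct <- data.frame(miRNA_id = targets$miRNA_id[direct],
                           mrna = targets$target_id[direct],
                           evidence = targets$evidence[direct],
                           stringsAsFactors = FALSE)
  via_gene <- merge(targets[!direct, c("miRNA_id", "target_id", "evidence")],
                    gm_mrna[, c("feature_id", "gene_id")],
                    by.x = "target_id", by.y = "gene_id")
  res_gene <- data.frame(miRNA_id = via_gene$miRNA_id, mrna = via_gene$feature_id,
                         evidence = via_gene$evidence, stringsAsFactors = FALSE)
  mm <- rbind(res_direct, res_gene)
  mm <- mm[mm$miRNA_id %in% mirna_ids, , drop = FALSE]
  mm <- mm[order(mm$evidence != "validated"), , drop = FALSE]
  mm <- mm[!duplicated(mm[c("miRNA_id", "mrna")]), , drop = FALSE]

  mi_mm <- if (nrow(mm)) data.frame(
    interaction_id = sprintf("MI:%s|%s", mm$miRNA_id, mm$mrna),
    kind = "miRNA_mRNA", member_a = mm$miRNA_id, platform_a = "miRNA",
    member_b = mm$mrna, platform_b = "mRNA",
    expected_sign = -1L, evidence = mm$evidence, stringsAsFactors = FALSE) else NULL

  mp <- merge(gm_mrna[, c("feature_id", "gene_id")],
              gm_prot[, c("feature_id", "gene_id")],
              by = "gene_id", suffixes = c("_mrna", "_prot"))
  mi_mp <- if (nrow(mp)) data.frame(
    interaction_id = sprintf("MI:%s|%s", mp$feature_id_mrna, mp$feature_id_prot),
    kind = "mRNA_protein", member_a = mp$feature_id_mrna, platform_a = "mRNA",
    member_b = mp$feature_id_prot, platform_b = "protein",
    expected_sign = 1L, evidence = "locus", stringsAsFactors = FALSE) else NULL

  # transitive miRNA -> mRNA -> gene -> protein chains, named by the chain
  mi_tp <- NULL
  if (nrow(mm) && nrow(mp)) {
    ch <- merge(mm, mp, by.x = "mrna", by.y = "feature_id_mrna")
    if (nrow(ch)) mi_tp <- data.frame(
      interaction_id = sprintf("MI:%s|%s|%s", ch$miRNA_id, ch$mrna, ch$feature_id_prot),
      kind = "miRNA_protein", member_a = ch$miRNA_id, platform_a = "miRNA",
      member_b = ch$feature_id_prot, platform_b = "protein",
      expected_sign = -1L, evidence = ch$evidence, stringsAsFactors = FALSE)
  }
  out <- rbind(mi_mm, mi_mp, mi_tp)
  if (is.null(out))
    out <- data.frame(interaction_id = character(), kind = character(),
                      member_a = character(), platform_a = character(),
                      member_b = character(), platform_b = character(),
                      expected_sign = integer(), evidence = character(),
                      stringsAsFactors = FALSE)
  out <- out[!duplicated(out$interaction_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interaction_set", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# scaled value of one member across samples; chains score through endpoints
.member_values <- function(ids, platform, scaled, samples) {
  m <- scaled[[platform]]
  out <- matrix(NA_real_, length(ids), length(samples),
                dimnames = list(NULL, samples))
  hit <- ids %in% rownames(m)
  out[hit, ] <- m[ids[hit], samples, drop = FALSE]
  out
}

#' Score interactions as products of scaled log-ratios
#'
#' Per sample and interaction, the MI score is the product of the two
#' members' scaled log-ratios: close to +1 for strongly co-regulated pairs,
#' close to -1 for strong anti-correlation (the expectation for a miRNA and
#' its target). Any member missing in a sample gives a missing score.
#'
#' @param interactions an [infer_interactions()] result.
#' @param scaled named list of scaled fold-change matrices per platform
#'   (features x samples, values in \[-1, 1\]), identical sample columns.
#' @return a [feature_matrix()] with provenance `"MI"`.
#' @export
score_interactions <- function(interactions, scaled) {
  samples <- colnames(scaled[[1L]])
  for (m in scaled)
    if (!identical(colnames(m), samples))
      stop("scaled matrices must share identical sample columns")
  va <- matrix(NA_real_, nrow(interactions), length(samples))
  vb <- matrix(NA_real_, nrow(interactions), length(samples))
  for (p in unique(interactions$platform_a)) {
    idx <- interactions$platform_a == p
    va[idx, ] <- .member_values(interactions$member_a[idx], p, scaled, samples)
  }
  for (p in unique(interactions$platform_b)) {
    idx <- interactions$platform_b == p
    vb[idx, ] <- .member_values(interactions$member_b[idx], p, scaled, samples)
  }
  s <- va * vb
  dimnames(s) <- list(interactions$interaction_id, samples)
  feature_matrix(s, rep("MI", nrow(s)))
}

#' Scale all platforms and score the interaction catalogue
#'
#' Convenience wrapper: fits one scaling context per platform on the given
#' reference matrices (pass training-fold matrices in cross-validation),
#' applies it to the full matrices, and scores.
#'
#' @param interactions an [infer_interactions()] result.
#' @param fc_list named list of [fold_change_matrix()] per platform.
#' @param reference optional named list of matrices restricted to the
#'   reference (training) samples used to fit the scaling; defaults to
#'   `fc_list` itself.
#' @return a [feature_matrix()] (provenance MI) with the fitted contexts in
#'   attribute `"contexts"`.
#' @export
mi_feature_matrix <- function(interactions, fc_list, reference = NULL) {
  ctx <- lapply(names(fc_list), function(p) {
    ref <- if (is.null(reference)) fc_list[[p]]$log_ratios
           else reference[[p]]
    fit_scaling(ref, platform = p)
  })
  names(ctx) <- names(fc_list)
  scaled <- lapply(names(fc_list), function(p)
    scale_log_ratios(fc_list[[p]]$log_ratios, ctx[[p]]))
  names(scaled) <- names(fc_list)
  out <- score_interactions(interactions, scaled)
  attr(out, "contexts") <- ctx
  out
}

#' Report interactions with concordant, substantial deregulation
#'
#' An interaction is highlighted in a sample when both partners show at
#' least a `fold_threshold`-fold (default 1.5, i.e. 50%) increase or
#' decrease and the sign pattern matches the expectation for the interaction
#' kind (product sign equals the expected sign). This is a reporting filter;
#' scoring for machine learning never applies it.
#'
#' @param interactions an [infer_interactions()] result.
#' @param fc_list named list of [fold_change_matrix()] per platform.
#' @param fold_threshold linear fold-change threshold > 1.
#' @return data frame of (interaction_id, kind, sample_id, log2fc_a, log2fc_b).
#' @export
highlight_interactions <- function(interactions, fc_list, fold_threshold = 1.5) {
  stopifnot(fold_threshold > 1)
  thr <- log2(fold_threshold)
  samples <- colnames(fc_list[[1L]]$log_ratios)
  raw <- lapply(fc_list, `[[`, "log_ratios")
  va <- vb <- matrix(NA_real_, nrow(interactions), length(samples))
  for (p in unique(interactions$platform_a)) {
    idx <- interactions$platform_a == p
    va[idx, ] <- .member_values(interactions$member_a[idx], p, raw, samples)
  }
  for (p in unique(interactions$platform_b)) {
    idx <- interactions$platform_b == p
    vb[idx, ] <- .member_values(interactions$member_b[idx], p, raw, samples)
  }
  ok <- !is.na(va) & !is.na(vb) & abs(va) >= thr & abs(vb) >= thr &
    sign(va * vb) == matrix(interactions$expected_sign, nrow(va), ncol(va))
  hit <- which(ok, arr.ind = TRUE)
  data.frame(interaction_id = interactions$interaction_id[hit[, 1L]],
             kind = interactions$kind[hit[, 1L]],
             sample_id = samples[hit[, 2L]],
             log2fc_a = va[hit], log2fc_b = vb[hit],
             stringsAsFactors = FALSE)
}
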