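# End-to-end orchestration: feature arrangements, per-contrast nested CV,
# consensus signatures, undefined-compound classification, provenance
# manifest.

#' Build the seven feature-set arrangements
#'
#' Single-platform fold-change features, their combination, and the
#' combination extended with molecular-interaction and/or
#' pathway-enrichment features. Arrangements are assembled from cached
#' single-source matrices; combined arrangements are row-stacks of their
#' parts. Molecular-interaction scaling is data-dependent, so the MI block
#' is returned as a builder that refits the per-platform scaling on
#' whatever training samples it is given.
#'
#' @param fc_list named list of [fold_change_matrix()] per platform.
#' @param genes,targets,pathways interaction and pathway inputs.
#' @param fc_threshold linear deregulation cutoff for PE features.
#' @return list with `static` (named list of [feature_matrix()] for the
#'   arrangements without MI) and `builders` (named list of
#'   `function(train_ids)` for the arrangements with MI).
#' @export
feature_arrangements <- function(fc_list, genes, targets, pathways,
                                 fc_threshold = 2.5) {
  singles <- lapply(fc_list, as_feature_matrix)
  combined <- do.call(stack_features, unname(singles))
  pe <- pe_matrix(fc_list, genes, targets, pathways, fc_threshold = fc_threshold)
  inter <- infer_interactions(targets, genes,
    platform_features = lapply(fc_list, function(f) rownames(f$log_ratios)))
  mi_builder <- function(base) function(train_ids) {
    ref <- lapply(fc_list, function(f)
      f$log_ratios[, intersect(train_ids, colnames(f$log_ratios)), drop = FALSE])
    mi <- mi_feature_matrix(inter, fc_list, reference = ref)
    out <- if (is.null(base)) mi else stack_features(base, mi)
    attr(out, "contexts") <- attr(mi, "contexts")
    out
  }
  static <- list(mrna = singles$mRNA, mirna = singles$miRNA,
                 protein = singles$protein, combined = combined,
                 combined_pe = stack_features(combined, pe))
  builders <- list(combined_mi = mi_builder(combined),
                   combined_mi_pe = mi_builder(stack_features(combined, pe)))
  list(static = static, builders = builders, interactions = inter, pe = pe)
}

#' Run the full classification pipeline
#'
#' Generates or loads a three-platform dataset, builds the feature
#' arrangements, evaluates each requested arrangement on each contrast by
#' repeated nested compound-level cross-validation, extracts consensus
#' signatures, classifies undefined compounds, and (optionally) writes all
#' reports plus a provenance manifest to `out_dir`.
#'
#' @param dataset a dataset list as returned by [generate_synthetic()]
#'   (fields `fc`, `annot`, `genes`, `targets`, `pathways`).
#' @param contrasts contrast names to evaluate.
#' @param arrangements arrangement names among mrna, mirna, protein,
#'   combined, combined_mi, combined_pe, combined_mi_pe.
#' @param classifiers named list of [classifier_spec()]s.
#' @param n_reps cross-validation repetitions (default 10).
#' @param sizes signature-size grid.
#' @param seed master seed; all stage seeds derive from it.
#' @param out_dir optional output directory for reports.
#' @return list of per-contrast results (`cv` reports per arrangement,
#'   `signature`, `undefined`), plus a `manifest`.
#' @export
run_pipeline <- function(dataset,
                         contrasts = c("C_vs_NC", "NGC_vs_GC", "NGC_vs_NC"),
                         arrangements = c("mrna", "combined", "combined_mi_pe"),
                         classifiers = default_classifiers(),
                         n_reps = 10L, sizes = c(5L, 10L, 15L, 20L, 25L),
                         seed = 1L, out_dir = NULL) {
  arr <- feature_arrangements(dataset$fc, dataset$genes, dataset$targets,
                              dataset$pathways)
  known <- c(names(arr$static), names(arr$builders))
  bad <- setdiff(arrangements, known)
  if (length(bad)) stop("unknown arrangement(s): ", paste(bad, collapse = ", "))
  results <- list()
  for (cn in contrasts) {
    contrast <- make_contrast(cn)
    plans <- make_split_plan(dataset$annot, contrast, n_reps = n_reps,
                             seed = (seed * 131L + match(cn, contrasts)) %% 2147483647L)
    cv <- list()
    for (a in arrangements) {
      cv[[a]] <- if (a %in% names(arr$static))
        run_nested_cv(arr$static[[a]], dataset$annot, contrast,
                      classifiers = classifiers, plans = plans, sizes = sizes,
                      seed = seed)
      else
        run_nested_cv(NULL, dataset$annot, contrast, classifiers = classifiers,
                      plans = plans, sizes = sizes,
                      feature_builder = arr$builders[[a]], seed = seed)
    }
    best <- arrangements[length(arrangements)]
    sig_features <- if (best %in% names(arr$static)) arr$static[[best]]
                    else arr$builders[[best]](dataset$annot$sample_id[!dataset$annot$is_control])
    sig <- cv_consensus_signature(cv[[best]],
                                  provenance = sig_features$provenance)
    undef <- if (cn == "NGC_vs_GC")
      classify_undefined(sig_features, dataset$annot, contrast,
                         classifiers = classifiers,
                         signature_features = sig$feature_id, seed = seed)
    else NULL
    results[[cn]] <- list(cv = cv, signature = sig, undefined = undef)
  }
  manifest <- list(seed = seed, n_reps = n_reps, sizes = sizes,
                   contrasts = contrasts, arrangements = arrangements,
                   classifiers = names(classifiers),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (cn in names(results)) {
      for (a in names(results[[cn]]$cv)) {
        rep <- results[[cn]]$cv[[a]]
        utils::write.table(rep$scores,
          file.path(out_dir, sprintf("scores_%s_%s.tsv", cn, a)),
          sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
          list(contrast = cn, arrangement = a, auc = as.list(rep$auc),
               mean_auc = rep$mean_auc),
          file.path(out_dir, sprintf("cv_%s_%s.json", cn, a)),
          auto_unbox = TRUE, digits = NA)
      }
      utils::write.table(as.data.frame(results[[cn]]$signature),
        file.path(out_dir, sprintf("signature_%s.tsv", cn)),
        sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(results[[cn]]$undefined) &&
          nrow(results[[cn]]$undefined$samples))
        utils::write.table(results[[cn]]$undefined$samples,
          file.path(out_dir, sprintf("undefined_confidence_%s.tsv", cn)),
          sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(results = results, manifest = manifest)
}
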