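# Fold-change computation, protein-panel normalisation, kNN imputation and
# expression filtering.

.control_samples <- function(annot, group_id) {
  annot$sample_id[annot$is_control & annot$control_group_id == group_id]
}

#' Per-sample log2 fold changes against time-matched vehicle controls
#'
#' For every treated sample, subtracts the per-feature summary (mean or
#' median) of the log2 values of its time-matched vehicle control group.
#' Protein panels conventionally use the median; mRNA/miRNA default to the
#' mean. Missing inputs propagate as missing.
#'
#' @param expr an [expression_matrix()] on the log2 scale.
#' @param annot a `sample_annotation` covering the matrix columns.
#' @param control_stat `"mean"` or `"median"` control summary.
#' @return a [fold_change_matrix()] over the treated samples.
#' @export
compute_fold_changes <- function(expr, annot, control_stat = c("mean", "median")) {
  control_stat <- match.arg(control_stat)
  stopifnot(inherits(expr, "expression_matrix"))
  annot <- as_sample_annotation(as.data.frame(annot))
  v <- expr$values
  annot <- annot[annot$sample_id %in% colnames(v), , drop = FALSE]
  treated <- annot[!annot$is_control, , drop = FALSE]
  if (nrow(treated) == 0L) stop("no treated samples present in the matrix")
  statfun <- if (control_stat == "mean") {
    function(m) rowMeans(m, na.rm = TRUE)
  } else {
    function(m) apply(m, 1L, stats::median, na.rm = TRUE)
  }
  groups <- unique(treated$control_group_id)
  ctrl_stat <- matrix(NA_real_, nrow(v), length(groups),
                      dimnames = list(rownames(v), groups))
  for (g in groups) {
    cs <- intersect(.control_samples(annot, g), colnames(v))
    if (length(cs) == 0L) {
      bad <- treated$sample_id[treated$control_group_id == g][1L]
      stop(sprintf("treated sample '%s' has no control samples in group '%s'", bad, g))
    }
    ctrl_stat[, g] <- statfun(v[, cs, drop = FALSE])
  }
  lr <- v[, treated$sample_id, drop = FALSE] -
    ctrl_stat[, treated$control_group_id, drop = FALSE]
  colnames(lr) <- treated$sample_id
  lr[is.nan(lr)] <- NA_real_
  fold_change_matrix(lr, platform = expr$platform)
}

#' Normalise an antibody-panel protein matrix
#'
#' Divides each blank-corrected linear signal by the median of the matching
#' control-group samples measured with the same antibody and log2-transforms
#' the ratio. Cells where the secondary-antibody-only background reaches or
#' exceeds the combined signal are masked as missing.
#'
#' @param raw [expression_matrix()] of blank-corrected linear signals
#'   (antibodies x samples).
#' @param annot `sample_annotation` covering the columns.
#' @param background optional [expression_matrix()] of
#'   secondary-antibody-only signals aligned to `raw`; cells with
#'   `background >= raw` are masked.
#' @return [expression_matrix()] of log2 ratios with masked cells missing;
#'   detection flags mark unmasked cells.
#' @export
normalize_protein_panel <- function(raw, annot, background = NULL) {
  stopifnot(inherits(raw, "expression_matrix"))
  annot <- as_sample_annotation(as.data.frame(annot))
  v <- raw$values
  mask <- matrix(FALSE, nrow(v), ncol(v), dimnames = dimnames(v))
  if (!is.null(background)) {
    b <- background$values
    stopifnot(identical(dim(b), dim(v)))
    mask <- !is.na(b) & !is.na(v) & b >= v
  }
  annot <- annot[annot$sample_id %in% colnames(v), , drop = FALSE]
  groups <- unique(annot$control_group_id[!annot$is_control])
  out <- matrix(NA_real_, nrow(v), ncol(v), dimnames = dimnames(v))
  for (g in groups) {
    cs <- intersect(.control_samples(annot, g), colnames(v))
    if (length(cs) == 0L) stop("control group without samples: ", g)
    med <- apply(v[, cs, drop = FALSE], 1L, stats::median, na.rm = TRUE)
    if (any(!is.na(med) & med <= 0))
      stop("non-positive control median for antibody ",
           rownames(v)[which(!is.na(med) & med <= 0)][1L])
    cols <- annot$sample_id[annot$control_group_id == g]
    cols <- intersect(cols, colnames(v))
    out[, cols] <- log2(v[, cols, drop = FALSE] / med)
  }
  out[mask] <- NA_real_
  expression_matrix(out, platform = "protein", detection = !is.na(out),
                    unit = "log2 ratio vs control median")
}

#' k-nearest-neighbour imputation of missing fold-change cells
#'
#' Each missing cell is replaced by the unweighted mean of the values, in
#' that sample, of the `k` features nearest to the incomplete feature.
#' Nearness is the root-mean-square Euclidean distance over co-observed
#' samples, computed on row-standardised profiles so that high-amplitude
#' features do not dominate; donor features must be observed in the target
#' sample. Observed cells are never altered.
#'
#' @param fc a [fold_change_matrix()] with < 50% missing cells.
#' @param k number of neighbours (default 5).
#' @return a [fold_change_matrix()] without missing cells.
#' @export
knn_impute <- function(fc, k = 5L) {
  stopifnot(inherits(fc, "fold_change_matrix"), k >= 1L)
  x <- fc$log_ratios
  miss <- is.na(x)
  if (!any(miss)) return(fc)
  if (mean(miss) >= 0.5) stop("more than 50% of cells are missing")
  # row-standardise on observed values for the distance computation only
  mu <- rowMeans(x, na.rm = TRUE)
  sd <- apply(x, 1L, stats::sd, na.rm = TRUE)
  sd[is.na(sd) | sd == 0] <- 1
  z <- (x - mu) / sd
  need <- which(rowSums(miss) > 0L)
  out <- x
  for (i in need) {
    d2 <- rowMeans((z - matrix(z[i, ], nrow(z), ncol(z), byrow = TRUE))^2,
                   na.rm = TRUE)
    d2[i] <- Inf
    overlap <- rowSums(!is.na(z) &
                         matrix(!is.na(z[i, ]), nrow(z), ncol(z), byrow = TRUE))
    d2[overlap == 0L] <- Inf
    if (all(!is.finite(d2)))
      stop("feature '", rownames(x)[i], "' shares no observed samples with any other feature")
    ord <- order(d2, rownames(x))
    for (j in which(miss[i, ])) {
      donors <- ord[!is.na(x[ord, j]) & is.finite(d2[ord])]
      if (length(donors) == 0L)
        stop("no donor feature observed in sample '", colnames(x)[j],
             "' for feature '", rownames(x)[i], "'")
      out[i, j] <- mean(x[donors[seq_len(min(k, length(donors)))], j])
    }
  }
  fold_change_matrix(out, platform = fc$platform)
}

#' Drop features not expressed in any sample
#'
#' A feature is removed only when its detection flag is `FALSE` (or, absent
#' flags, its value below `floor`) in every sample; detection in a single
#' sample retains it.
#'
#' @param expr an [expression_matrix()].
#' @param floor numeric expression floor used when `expr` has no detection
#'   flags.
#' @return filtered [expression_matrix()].
#' @export
filter_unexpressed <- function(expr, floor = NULL) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (!is.null(expr$detection)) {
    keep <- rowSums(expr$detection, na.rm = TRUE) > 0L
  } else {
    if (is.null(floor)) stop("no detection flags; supply an expression floor")
    keep <- rowSums(expr$values >= floor, na.rm = TRUE) > 0L
  }
  expression_matrix(expr$values[keep, , drop = FALSE], platform = expr$platform,
                    detection = if (is.null(expr$detection)) NULL
                                else expr$detection[keep, , drop = FALSE],
                    unit = expr$unit)
}
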