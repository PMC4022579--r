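# Nested, stratified, compound-level 2x2 cross-validation with repetitions,
# score scaling and merging, ROC/AUC, views, and classification of
# undefined compounds.

# round-robin assignment of a permuted compound vector to two folds
.assign_two <- function(ids) {
  stats::setNames(rep_len(1:2, length(ids)), sample(ids))
}

#' Plan repeated 2x2 nested compound-level splits
#'
#' Splits are at the compound level (all replicate samples of a compound
#' travel together) and stratified by contrast side, so every outer fold
#' holds unseen test compounds of both classes. Each repetition draws a
#' fresh random split; plans are deterministic given the seed.
#'
#' @param annot `sample_annotation`.
#' @param contrast a [make_contrast()] object.
#' @param n_reps number of repetitions (default 10).
#' @param seed integer seed.
#' @return list of plans; each has `outer` (named fold 1/2 per compound) and
#'   `inner` (per outer fold, fold assignment of the training compounds).
#' @export
make_split_plan <- function(annot, contrast, n_reps = 10L, seed = 1L) {
  annot <- as_sample_annotation(as.data.frame(annot))
  treated <- annot[!annot$is_control, , drop = FALSE]
  side <- contrast_side(contrast, treated$class_label)
  cmp_side <- tapply(as.character(side[!is.na(side)]),
                     treated$compound[!is.na(side)], unique)
  pos <- names(cmp_side)[cmp_side == "pos"]
  neg <- names(cmp_side)[cmp_side == "neg"]
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need at least 2 compounds on each side of the contrast to stratify 2 folds")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lapply(seq_len(n_reps), function(r) {
    outer <- c(.assign_two(pos), .assign_two(neg))
    inner <- lapply(1:2, function(f) {
      train <- names(outer)[outer != f]
      c(.assign_two(intersect(train, pos)), .assign_two(intersect(train, neg)))
    })
    list(rep = r, outer = outer, inner = inner)
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Linearly scale prediction scores to the unit interval
#'
#' `(s - min) / (max - min)` within one fold; a degenerate all-equal fold
#' maps to 0.5. Scores are scaled per fold before merging across folds and
#' repetitions.
#'
#' @param x numeric scores.
#' @return scores in \[0, 1\].
#' @export
scale_scores <- function(x) {
  stopifnot(length(x) >= 1L)
  rng <- range(x)
  if (diff(rng) == 0) return(rep(0.5, length(x)))
  (x - rng[1L]) / diff(rng)
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Fraction of (positive, negative) pairs where the positive sample scores
#' higher, counting ties as one half.
#'
#' @param scores numeric prediction scores, larger = more positive-class.
#' @param labels factor/character with levels containing `"pos"`/`"neg"`, or
#'   logical (TRUE = positive).
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  pos <- if (is.logical(labels)) labels else labels == "pos"
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0L || n2 == 0L) stop("both classes must be present to compute AUC")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# classification threshold between the two training-score class means
.score_threshold <- function(scores, y) {
  (mean(scores[y == "pos"]) + mean(scores[y == "neg"])) / 2
}

# accuracy of one classifier/param/signature on an inner split
.inner_accuracy <- function(spec, params, x_tr, y_tr, x_te, y_te) {
  fit <- if (length(params)) spec$fit(x_tr, y_tr, params) else spec$fit(x_tr, y_tr, list())
  s_tr <- spec$score(fit, x_tr)
  thr <- .score_threshold(s_tr, y_tr)
  pred <- ifelse(spec$score(fit, x_te) > thr, "pos", "neg")
  mean(pred == as.character(y_te))
}

.samples_of <- function(annot, contrast, compounds) {
  treated <- annot[!annot$is_control, , drop = FALSE]
  side <- contrast_side(contrast, treated$class_label)
  keep <- treated$compound %in% compounds & !is.na(side)
  list(ids = treated$sample_id[keep], y = droplevels(side[keep]),
       compound = treated$compound[keep])
}

#' Run nested compound-level cross-validation
#'
#' For every repetition and outer fold: feature construction (optional
#' builder), row standardisation, SVM-RFE ranking and hyperparameter/size
#' tuning are fitted on the training compounds only; the held-out fold is
#' scored, scores are scaled to \[0, 1\] per fold, and merged across folds
#' and repetitions into one ROC per classifier. Signature size is chosen
#' per classifier by inner-fold accuracy and spline interpolation over the
#' candidate grid.
#'
#' @param features a [feature_matrix()] over all samples, or `NULL` when a
#'   `feature_builder` is given.
#' @param annot `sample_annotation`.
#' @param contrast a [make_contrast()] object.
#' @param classifiers named list of [classifier_spec()]s.
#' @param plans output of [make_split_plan()].
#' @param sizes candidate signature sizes (default 5, 10, 15, 20, 25).
#' @param step_fraction RFE elimination fraction per round.
#' @param rfe_cost SVM cost used inside RFE.
#' @param feature_builder optional `function(train_sample_ids)` returning a
#'   [feature_matrix()] over all samples whose data-dependent parts (e.g.
#'   molecular-interaction scaling) are fitted on the training samples only.
#' @param seed integer; controls classifier RNG (forests, network init).
#' @return a `cv_report`: merged scores, per-classifier and mean AUC,
#'   per-repetition AUCs, and per-fold training-side artifacts.
#' @export
run_nested_cv <- function(features = NULL, annot, contrast,
                          classifiers = default_classifiers(), plans,
                          sizes = c(5L, 10L, 15L, 20L, 25L),
                          step_fraction = 0.1, rfe_cost = 1,
                          feature_builder = NULL, seed = 1L) {
  annot <- as_sample_annotation(as.data.frame(annot))
  if (is.null(features) && is.null(feature_builder))
    stop("supply features or a feature_builder")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  score_rows <- list()
  fold_art <- list()
  for (plan in plans) {
    for (f in 1:2) {
      set.seed((seed * 1009L + plan$rep * 131L + f) %% 2147483647L)
      test_cmp <- names(plan$outer)[plan$outer == f]
      train_cmp <- names(plan$outer)[plan$outer != f]
      tr <- .samples_of(annot, contrast, train_cmp)
      te <- .samples_of(annot, contrast, test_cmp)
      fm <- if (is.null(feature_builder)) features else feature_builder(tr$ids)
      v <- fm$values
      miss <- setdiff(c(tr$ids, te$ids), colnames(v))
      if (length(miss)) stop("feature matrix lacks sample(s): ",
                             paste(miss, collapse = ", "))
      # classifiers need complete, non-degenerate data: keep features fully
      # observed and varying on the training side (judged on training
      # samples only, so held-out data cannot influence the feature set);
      # any residual test-side gap is neutralised at the training mean
      vtr <- v[, tr$ids, drop = FALSE]
      keep <- rowSums(is.na(vtr)) == 0L &
        apply(vtr, 1L, function(r) any(r != r[1L]))
      if (!any(keep)) {
        warning(sprintf("rep %d fold %d: no usable training features; fold skipped",
                        plan$rep, f))
        next
      }
      v <- v[keep, , drop = FALSE]
      st <- .standardize_rows(v[, tr$ids, drop = FALSE])
      x_tr <- st$values
      x_te <- (v[, te$ids, drop = FALSE] - st$center) / st$scale
      x_te[is.na(x_te)] <- 0
      sizes_f <- sizes[sizes <= nrow(v)]
      if (!length(sizes_f)) sizes_f <- nrow(v)
      ranking <- svm_rfe(x_tr, tr$y, target_size = min(sizes_f),
                         step_fraction = step_fraction, cost = rfe_cost)
      # inner evaluation: accuracy per classifier x param x size
      inner <- plan$inner[[f]]
      acc <- list()
      for (d in 1:2) {
        it_cmp <- names(inner)[inner != d]
        iv_cmp <- names(inner)[inner == d]
        itr <- .samples_of(annot, contrast, it_cmp)
        ite <- .samples_of(annot, contrast, iv_cmp)
        if (nlevels(itr$y) < 2L || min(table(itr$y)) < 2L ||
            length(ite$ids) == 0L) next
        ist <- .standardize_rows(v[, itr$ids, drop = FALSE])
        ix_tr <- ist$values
        ix_te <- (v[, ite$ids, drop = FALSE] - ist$center) / ist$scale
        irk <- svm_rfe(ix_tr, itr$y, target_size = min(sizes_f),
                       step_fraction = step_fraction, cost = rfe_cost)
        for (cn in names(classifiers)) {
          spec <- classifiers[[cn]]
          grid <- if (length(spec$grid)) spec$grid else list(list())
          for (gi in seq_along(grid)) for (si in seq_along(sizes_f)) {
            feats <- irk$feature_id[seq_len(sizes_f[si])]
            a <- try(.inner_accuracy(spec, grid[[gi]],
                                     t(ix_tr[feats, , drop = FALSE]), itr$y,
                                     t(ix_te[feats, , drop = FALSE]), ite$y),
                     silent = TRUE)
            if (!inherits(a, "try-error"))
              acc[[cn]] <- rbind(acc[[cn]],
                                 data.frame(param = gi, size = si, acc = a))
          }
        }
      }
      for (cn in names(classifiers)) {
        spec <- classifiers[[cn]]
        grid <- if (length(spec$grid)) spec$grid else list(list())
        a <- acc[[cn]]
        if (is.null(a)) {
          gi <- 1L
          size <- sizes_f[ceiling(length(sizes_f) / 2)]
        } else {
          am <- tapply(a$acc, list(a$param, a$size), mean)
          gi <- as.integer(rownames(am)[which.max(
            suppressWarnings(apply(am, 1L, max, na.rm = TRUE)))])
          accs <- am[as.character(gi), ]
          ok <- !is.na(accs)
          sz <- sizes_f[as.integer(colnames(am))[ok]]
          size <- if (sum(ok) >= 3L)
            optimize_signature_size(sz, pmin(pmax(accs[ok], 0), 1))
          else sz[which.max(accs[ok])]
        }
        feats <- ranking$feature_id[seq_len(min(size, nrow(ranking)))]
        fit <- try(spec$fit(t(x_tr[feats, , drop = FALSE]), tr$y, grid[[gi]]),
                   silent = TRUE)
        if (inherits(fit, "try-error")) {
          warning(sprintf("%s failed in rep %d fold %d; fold marked invalid",
                          cn, plan$rep, f))
          next
        }
        raw <- spec$score(fit, t(x_te[feats, , drop = FALSE]))
        score_rows[[length(score_rows) + 1L]] <- data.frame(
          classifier = cn, rep = plan$rep, fold = f,
          sample_id = te$ids, compound = te$compound,
          label = as.character(te$y), score = scale_scores(raw),
          stringsAsFactors = FALSE)
        fold_art[[length(fold_art) + 1L]] <- list(
          rep = plan$rep, fold = f, classifier = cn,
          train_compounds = sort(train_cmp), size = size, params = grid[[gi]],
          ranking_head = ranking$feature_id[seq_len(min(50L, nrow(ranking)))],
          center = st$center, scale = st$scale,
          contexts = attr(fm, "contexts"))
      }
    }
  }
  scores <- do.call(rbind, score_rows)
  cls <- names(classifiers)
  auc <- vapply(cls, function(cn) {
    s <- scores[scores$classifier == cn, ]
    roc_auc(s$score, s$label)
  }, 0)
  reps <- sort(unique(scores$rep))
  per_rep <- vapply(cls, function(cn) vapply(reps, function(r) {
    s <- scores[scores$classifier == cn & scores$rep == r, ]
    roc_auc(s$score, s$label)
  }, 0), numeric(length(reps)))
  per_rep <- matrix(per_rep, nrow = length(reps),
                    dimnames = list(reps, cls))
  structure(list(contrast = contrast$name, scores = scores, auc = auc,
                 mean_auc = mean(auc), per_rep_auc = per_rep,
                 rankings = lapply(fold_art, `[[`, "ranking_head"),
                 folds = fold_art, seed = seed, sizes = sizes),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> contrast %s, %d repetitions\n", x$contrast,
              nrow(x$per_rep_auc)))
  cat("  AUC per classifier:",
      paste(sprintf("%s=%.3f", names(x$auc), x$auc), collapse = ", "), "\n")
  cat(sprintf("  mean AUC: %.3f\n", x$mean_auc))
  invisible(x)
}

#' Consensus signature from a cross-validation report
#'
#' Averages the SVM-RFE rankings stored for every fold and repetition and
#' returns the top features at the consensus size (the median of the
#' per-fold selected sizes unless given).
#'
#' @param report a `cv_report`.
#' @param size signature size; default median of the per-fold sizes.
#' @param provenance optional named provenance tags.
#' @return a [consensus_signature()].
#' @export
cv_consensus_signature <- function(report, size = NULL, provenance = NULL) {
  # one ranking per (rep, fold); folds store one copy per classifier
  key <- vapply(report$folds, function(f) sprintf("%d.%d", f$rep, f$fold), "")
  keep <- !duplicated(key)
  rankings <- lapply(report$folds[keep], function(f)
    data.frame(feature_id = f$ranking_head,
               rank = seq_along(f$ranking_head), stringsAsFactors = FALSE))
  if (is.null(size))
    size <- stats::median(vapply(report$folds, `[[`, 0L, "size"))
  consensus_signature(rankings, size = as.integer(size),
                      contrast = report$contrast, provenance = provenance)
}

#' Classify compounds of undefined carcinogenic class
#'
#' Trains every classifier on all confidently labelled compounds of the
#' contrast (undefined compounds are excluded from training by
#' construction), restricted to a signature, and scores the undefined
#' samples. Confidences are the raw scores scaled to \[0, 1\] against the
#' training-score range; a compound-level majority call across classifiers
#' is reported.
#'
#' @param features [feature_matrix()] covering labelled and undefined samples.
#' @param annot `sample_annotation`.
#' @param contrast a [make_contrast()]; default NGC vs GC.
#' @param classifiers named list of [classifier_spec()]s.
#' @param signature_features character vector of feature ids to use (e.g. a
#'   consensus signature); `NULL` uses all features.
#' @param seed integer seed for classifier RNG.
#' @return list with `samples` (compound, sample, classifier, confidence)
#'   and `compounds` (majority call per compound).
#' @export
classify_undefined <- function(features, annot,
                               contrast = make_contrast("NGC_vs_GC"),
                               classifiers = default_classifiers(),
                               signature_features = NULL, seed = 1L) {
  annot <- as_sample_annotation(as.data.frame(annot))
  treated <- annot[!annot$is_control, , drop = FALSE]
  undef <- treated[treated$class_label == "UNDEFINED", , drop = FALSE]
  if (nrow(undef) == 0L)
    return(list(samples = data.frame(), compounds = data.frame()))
  lab_cmp <- unique(treated$compound[!is.na(contrast_side(contrast, treated$class_label))])
  tr <- .samples_of(annot, contrast, lab_cmp)
  v <- features$values
  if (!is.null(signature_features)) {
    miss <- setdiff(signature_features, rownames(v))
    if (length(miss)) stop("signature feature(s) absent from matrix: ",
                           paste(utils::head(miss, 3L), collapse = ", "))
    v <- v[signature_features, , drop = FALSE]
  }
  v <- v[rowSums(is.na(v[, tr$ids, drop = FALSE])) == 0L, , drop = FALSE]
  st <- .standardize_rows(v[, tr$ids, drop = FALSE])
  x_tr <- t(st$values)
  x_un <- t((v[, undef$sample_id, drop = FALSE] - st$center) / st$scale)
  x_un[is.na(x_un)] <- 0
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  rows <- list()
  for (cn in names(classifiers)) {
    spec <- classifiers[[cn]]
    grid <- if (length(spec$grid)) spec$grid else list(list())
    set.seed((seed * 1013L + match(cn, names(classifiers))) %% 2147483647L)
    # pick hyperparameters by 2-fold compound-level CV on the training side
    gi <- 1L
    if (length(grid) > 1L) {
      plan <- make_split_plan(annot[annot$sample_id %in% c(tr$ids,
                annot$sample_id[annot$is_control]), , drop = FALSE],
                contrast, n_reps = 1L, seed = seed)[[1L]]
      accs <- vapply(seq_along(grid), function(g) {
        a <- c()
        for (d in 1:2) {
          itr <- .samples_of(annot, contrast, names(plan$outer)[plan$outer != d])
          ite <- .samples_of(annot, contrast, names(plan$outer)[plan$outer == d])
          if (nlevels(itr$y) < 2L) next
          ist <- .standardize_rows(v[, itr$ids, drop = FALSE])
          r <- try(.inner_accuracy(spec, grid[[g]],
                 t(ist$values), itr$y,
                 t((v[, ite$ids, drop = FALSE] - ist$center) / ist$scale), ite$y),
                 silent = TRUE)
          if (!inherits(r, "try-error")) a <- c(a, r)
        }
        if (length(a)) mean(a) else NA_real_
      }, 0)
      if (any(!is.na(accs))) gi <- which.max(accs)
    }
    fit <- spec$fit(x_tr, tr$y, grid[[gi]])
    s_tr <- spec$score(fit, x_tr)
    s_un <- spec$score(fit, x_un)
    rng <- range(s_tr)
    conf <- if (diff(rng) == 0) rep(0.5, length(s_un))
            else pmin(pmax((s_un - rng[1L]) / diff(rng), 0), 1)
    rows[[cn]] <- data.frame(compound = undef$compound,
                             sample_id = undef$sample_id,
                             classifier = cn, confidence = conf,
                             stringsAsFactors = FALSE)
  }
  samples <- do.call(rbind, rows)
  rownames(samples) <- NULL
  agg <- stats::aggregate(confidence ~ compound + classifier, samples, mean)
  votes <- tapply(agg$confidence > 0.5, agg$compound, mean)
  compounds <- data.frame(compound = names(votes),
                          call = ifelse(votes > 0.5, contrast$positive[1L],
                                        contrast$negative[1L]),
                          vote_fraction = as.numeric(votes),
                          mean_confidence = as.numeric(
                            tapply(agg$confidence, agg$compound, mean)),
                          stringsAsFactors = FALSE)
  rownames(compounds) <- NULL
  list(samples = samples, compounds = compounds)
}

#' Two-dimensional PCA view of a signature feature space
#'
#' Centred principal component analysis of the samples restricted to a
#' signature; returns the first two component scores with a deterministic
#' sign convention (the largest-magnitude loading of each component is made
#' positive).
#'
#' @param features a [feature_matrix()].
#' @param signature_features optional feature-id subset.
#' @return list with `coords` (data frame sample_id, PC1, PC2) and
#'   `explained_variance` (fractions, all components).
#' @export
pca_view <- function(features, signature_features = NULL) {
  v <- features$values
  if (!is.null(signature_features)) v <- v[signature_features, , drop = FALSE]
  if (ncol(v) < 3L) stop("need at least 3 samples for a PCA view")
  pc <- stats::prcomp(t(v), center = TRUE, scale. = FALSE)
  for (j in seq_len(min(2L, ncol(pc$rotation)))) {
    top <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[top, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(2L, ncol(pc$x))
  coords <- data.frame(sample_id = colnames(v),
                       PC1 = pc$x[, 1L],
                       PC2 = if (k >= 2L) pc$x[, 2L] else 0,
                       stringsAsFactors = FALSE)
  rownames(coords) <- NULL
  list(coords = coords, explained_variance = ev)
}

#' Unsupervised clustering view of the most deregulated features
#'
#' Selects the `top_n` features per platform by mean absolute log2 fold
#' change across samples, applies complete-linkage hierarchical clustering
#' with Euclidean distance over samples, and picks the number of clusters
#' in `k_range` maximising the mean silhouette width.
#'
#' @param fc_list named list of [fold_change_matrix()] per platform with
#'   identical samples.
#' @param top_n features kept per platform (default 100).
#' @param k_range candidate cluster counts (default 2:8).
#' @return list with `k`, `assignment`, `silhouette` (mean width per k),
#'   `hclust` and `features`.
#' @export
cluster_view <- function(fc_list, top_n = 100L, k_range = 2:8) {
  samples <- colnames(fc_list[[1L]]$log_ratios)
  sel <- lapply(fc_list, function(fc) {
    stopifnot(identical(colnames(fc$log_ratios), samples))
    m <- fc$log_ratios
    score <- rowMeans(abs(m), na.rm = TRUE)
    keep <- utils::head(order(-score, rownames(m)), top_n)
    out <- m[keep, , drop = FALSE]
    rownames(out) <- paste(fc$platform, rownames(out), sep = ":")
    out
  })
  x <- do.call(rbind, sel)
  if (ncol(x) < max(k_range) + 1L)
    stop("need more samples than the largest candidate k")
  d <- stats::dist(t(x))
  hc <- stats::hclust(d, method = "complete")
  sil <- vapply(k_range, function(k) {
    cl <- stats::cutree(hc, k = k)
    mean(cluster::silhouette(cl, d)[, 3L])
  }, 0)
  names(sil) <- k_range
  k <- k_range[which.max(sil)]
  list(k = k, assignment = stats::cutree(hc, k = k), silhouette = sil,
       hclust = hc, features = rownames(x))
}
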