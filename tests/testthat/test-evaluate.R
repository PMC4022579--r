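test_that("split plans are compound-level, stratified and deterministic", {
  an <- toy_annot(c("A", "B", "C", "D"), c("NGC", "NGC", "NC", "NC"), reps = 3L)
  ct <- make_contrast("NGC_vs_NC")
  plans <- make_split_plan(an, ct, n_reps = 4L, seed = 5L)
  for (p in plans) {
    for (f in 1:2) {
      cmp <- names(p$outer)[p$outer == f]
      # with 2 compounds per class each fold holds exactly one of each
      expect_length(intersect(cmp, c("A", "B")), 1L)
      expect_length(intersect(cmp, c("C", "D")), 1L)
    }
  }
  expect_identical(plans, make_split_plan(an, ct, n_reps = 4L, seed = 5L))
  expect_false(identical(plans, make_split_plan(an, ct, n_reps = 4L, seed = 6L)))
  # a single-compound class cannot be stratified into two folds
  an2 <- toy_annot(c("A", "B", "C"), c("NGC", "NGC", "NC"), reps = 2L)
  expect_error(make_split_plan(an2, ct), "at least 2 compounds")
})

test_that("repeated splits differ across repetitions", {
  an <- toy_annot(sprintf("c%d", 1:8), rep(c("NGC", "NC"), each = 4L), reps = 2L)
  plans <- make_split_plan(an, make_contrast("NGC_vs_NC"), n_reps = 10L, seed = 2L)
  keys <- vapply(plans, function(p) paste(p$outer[sort(names(p$outer))],
                                          collapse = ""), "")
  expect_gte(length(unique(keys)), 5L)
})

test_that("score scaling maps any fold onto the unit interval", {
  expect_equal(scale_scores(c(-2, 0, 2)), c(0, 0.5, 1))
  expect_equal(scale_scores(c(7, 7)), c(0.5, 0.5))
  expect_equal(scale_scores(c(0, 0.25, 1)), c(0, 0.25, 1))
})

test_that("AUC equals exhaustive pair counting, ties worth one half", {
  expect_equal(roc_auc(c(0.1, 0.9), c("neg", "pos")), 1)
  expect_equal(roc_auc(rep(0.4, 6), rep(c("neg", "pos"), 3)), 0.5)
  set.seed(31)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)   # forces ties
    pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_identical(roc_auc(scores, pos), auc_pairs(scores, pos))
  }
  expect_error(roc_auc(1:3, c("pos", "pos", "pos")), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- runif(30); pos <- runif(30) > 0.5
  expect_equal(roc_auc(scores, pos),
               as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                              direction = "<"))))
})

small_ds <- function(seed = 21L, delta = 3) {
  generate_synthetic(synthetic_config(
    n_compounds = c(GC = 0L, NGC = 4L, NC = 4L, UNDEFINED = 0L),
    n_mrna = 80L, n_mirna = 10L, n_protein = 10L, n_genes = 80L,
    n_planted_mrna = 5L, n_planted_pairs = 2L, n_planted_proteins = 2L,
    delta = delta, n_pathways = 5L, pathway_size_range = c(5L, 10L)),
    seed = seed)
}

test_that("nested CV separates planted classes and averages per-classifier AUCs", {
  ds <- small_ds()
  ct <- make_contrast("NGC_vs_NC")
  plans <- make_split_plan(ds$annot, ct, n_reps = 2L, seed = 3L)
  fm <- as_feature_matrix(ds$fc$mRNA)
  rep2 <- run_nested_cv(fm, ds$annot, ct,
                        classifiers = default_classifiers(c("SVM", "BGLM")),
                        plans = plans, sizes = c(5L, 10L, 15L), seed = 3L)
  expect_true(all(rep2$auc >= 0.95))
  expect_equal(rep2$mean_auc, mean(rep2$auc))
  # every sample of the contrast is scored once per repetition per classifier
  counts <- table(rep2$scores$sample_id, rep2$scores$classifier)
  expect_true(all(counts == length(plans)))
  expect_true(all(rep2$scores$score >= 0 & rep2$scores$score <= 1))
  # a single classifier's mean AUC is its own AUC
  rep1 <- run_nested_cv(fm, ds$annot, ct,
                        classifiers = default_classifiers("SVM"),
                        plans = plans[1], sizes = c(5L, 10L, 15L), seed = 3L)
  expect_equal(rep1$mean_auc, unname(rep1$auc["SVM"]))
})

test_that("permuted labels give chance-level performance", {
  ds <- small_ds(seed = 6L, delta = 0)
  ct <- make_contrast("NGC_vs_NC")
  plans <- make_split_plan(ds$annot, ct, n_reps = 3L, seed = 6L)
  rep0 <- run_nested_cv(as_feature_matrix(ds$fc$mRNA), ds$annot, ct,
                        classifiers = default_classifiers("SVM"),
                        plans = plans, sizes = c(5L, 10L, 15L), seed = 6L)
  expect_gt(rep0$mean_auc, 0.2)
  expect_lt(rep0$mean_auc, 0.8)
})

test_that("undefined compounds resembling NGC profiles earn high NGC confidence", {
  ds <- generate_synthetic(synthetic_config(
    n_compounds = c(GC = 3L, NGC = 3L, NC = 2L, UNDEFINED = 2L),
    n_mrna = 80L, n_mirna = 10L, n_protein = 10L, n_genes = 80L,
    n_planted_mrna = 5L, n_planted_pairs = 2L, n_planted_proteins = 2L,
    delta = 3), seed = 11L)
  fm <- as_feature_matrix(ds$fc$mRNA)
  res <- classify_undefined(fm, ds$annot, make_contrast("NGC_vs_GC"),
                            classifiers = default_classifiers(c("SVM", "BGLM")),
                            seed = 11L)
  expect_true(all(res$samples$confidence >= 0 & res$samples$confidence <= 1))
  expect_true(all(res$compounds$call == "NGC"))
  expect_true(all(tapply(res$samples$confidence, res$samples$classifier, mean) > 0.5))
  # no undefined compounds: empty result
  ds2 <- small_ds()
  res2 <- classify_undefined(as_feature_matrix(ds2$fc$mRNA), ds2$annot,
                             make_contrast("NGC_vs_NC"),
                             classifiers = default_classifiers("SVM"))
  expect_equal(nrow(res2$samples), 0L)
})

test_that("PCA views are deterministic with variance bookkeeping", {
  line <- matrix(rep(seq(-2, 2, length.out = 6), each = 3) * c(1, 2, -1), 3,
                 dimnames = list(c("f1", "f2", "f3"), sprintf("s%d", 1:6)))
  fm <- feature_matrix(line, rep("mRNA", 3))
  pv <- pca_view(fm)
  expect_equal(pv$explained_variance[1L], 1)
  # duplicated sample lands on identical coordinates
  dup <- cbind(line, s7 = line[, 1L])
  pv2 <- pca_view(feature_matrix(dup, rep("mRNA", 3)))
  expect_equal(pv2$coords[pv2$coords$sample_id == "s7", -1L],
               pv2$coords[pv2$coords$sample_id == "s1", -1L],
               ignore_attr = TRUE)
  # sign convention: largest-magnitude loading positive, so PC1 scores
  # increase along the dominant direction deterministically
  expect_identical(pv$coords$PC1, sort(pv$coords$PC1))
})

test_that("silhouette-guided clustering finds planted sample groups", {
  set.seed(19)
  blob <- function(center, n) matrix(rnorm(20 * n, mean = center, sd = 0.3), 20, n)
  x <- cbind(blob(0, 5), blob(4, 5))
  dimnames(x) <- list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:10))
  cv <- cluster_view(list(fold_change_matrix(x, "mRNA")), top_n = 20L, k_range = 2:8)
  expect_equal(cv$k, 2L)
  expect_equal(unname(cv$assignment[1:5]), rep(cv$assignment[[1L]], 5))
  # three tight, well-separated blobs
  x3 <- cbind(blob(0, 4), blob(5, 4), blob(-5, 4))
  dimnames(x3) <- list(sprintf("f%02d", 1:20), sprintf("s%02d", 1:12))
  cv3 <- cluster_view(list(fold_change_matrix(x3, "mRNA")), top_n = 30L, k_range = 2:8)
  expect_equal(cv3$k, 3L)
  expect_length(cv3$features, 20L)      # top_n beyond feature count uses all
})
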