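test_that("deregulation detection uses a strict linear-scale threshold", {
  fc <- fcm(matrix(c(1.40, -1.40, log2(2.5), 0.5), 4, 1),
            features = c("a", "b", "c", "d"), samples = "s1")
  de <- detect_deregulated(fc, "s1", fc_threshold = 2.5)
  expect_setequal(de, c("a", "b"))          # 2^1.4 = 2.64 passes both signs
  expect_false("c" %in% de)                 # exactly 2.5-fold is excluded
  expect_error(detect_deregulated(fc, "nope"), "unknown sample")
})

test_that("deregulated genes unify across platforms with validated miRNA targets only", {
  genes <- as_gene_map(data.frame(
    feature_id = c("m1", "m2", "p1", "p2", "m4"),
    platform = c("mRNA", "mRNA", "protein", "protein", "mRNA"),
    gene_id = c("g1", "g2", "g2", "g3", "g4"), stringsAsFactors = FALSE))
  targets <- as_target_map(data.frame(
    miRNA_id = c("mir1", "mir2"), target_id = c("m4", "m2"),
    evidence = c("validated", "predicted"), source = "db"))
  u <- combine_deregulated(list(mRNA = c("m1", "m2"), protein = c("p1", "p2"),
                                miRNA = "mir1"), genes, targets)
  expect_setequal(as.character(u), c("g1", "g2", "g3", "g4"))
  # a miRNA with only predicted targets contributes nothing
  u2 <- combine_deregulated(list(miRNA = "mir2"), genes, targets)
  expect_length(u2, 0L)
  expect_length(combine_deregulated(list(), genes, targets), 0L)
})

test_that("hypergeometric p-values match combinatorial enumeration", {
  expect_equal(hypergeometric_pvalue(10, 5, 4, 0), 1)
  expect_equal(hypergeometric_pvalue(10, 5, 4, 4), 5 / choose(10, 4),
               tolerance = 1e-14)
  expect_equal(hypergeometric_pvalue(8, 8, 3, 2), 1)  # M = N: certain overlap
  expect_error(hypergeometric_pvalue(10, 11, 4, 2), "invalid")
  expect_error(hypergeometric_pvalue(10, 5, 4, 5), "invalid")
  for (N in 4:8) for (M in 1:N) for (n in 1:N) for (m in 0:min(n, M))
    expect_equal(hypergeometric_pvalue(N, M, n, m), hyper_enum(N, M, n, m),
                 tolerance = 1e-13)
})

test_that("the upper tail is non-increasing in the overlap count", {
  for (case in list(c(20, 7, 9), c(50, 20, 10), c(12, 3, 6))) {
    p <- vapply(0:min(case[2], case[3]), function(m)
      hypergeometric_pvalue(case[1], case[2], case[3], m), 0)
    expect_true(all(diff(p) <= 1e-15))
  }
})

pe_fixture <- function() {
  genes <- as_gene_map(data.frame(
    feature_id = sprintf("m%d", 1:9), platform = "mRNA",
    gene_id = sprintf("g%d", 1:9), stringsAsFactors = FALSE))
  targets <- as_target_map(data.frame(
    miRNA_id = "mir1", target_id = "m1", evidence = "validated", source = "db"))
  pw <- pathway_collection(list(pwA = c("g1", "g2", "g3"),
                                pwB = c("g4", "g5", "g6"),
                                pwC = c("g7", "g8", "g9")))
  list(genes = genes, targets = targets, pw = pw)
}

test_that("per-sample enrichment vectors rank the loaded pathway on top", {
  fx <- pe_fixture()
  m <- matrix(0, 9, 2, dimnames = list(sprintf("m%d", 1:9), c("s1", "s2")))
  m[c("m1", "m2", "m3"), "s1"] <- 3      # s1 deregulates exactly pathway A
  fc <- list(fold_change_matrix(m, "mRNA"))
  v1 <- pe_vector("s1", fc, fx$genes, fx$targets, fx$pw)
  expect_equal(unname(which.max(v1)), which(names(v1) == "pwA"))
  expect_equal(v1[["pwA"]], -log10(hyper_enum(9, 3, 3, 3)), tolerance = 1e-12)
  # no deregulated genes: all-zero scores
  v2 <- pe_vector("s2", fc, fx$genes, fx$targets, fx$pw)
  expect_true(all(v2 == 0))
  # determinism: identical samples give identical vectors
  expect_identical(v1, pe_vector("s1", fc, fx$genes, fx$targets, fx$pw))
})

test_that("genes outside the pathway universe never affect the scores", {
  fx <- pe_fixture()
  genes2 <- as_gene_map(rbind(as.data.frame(fx$genes),
    data.frame(feature_id = "m10", platform = "mRNA", gene_id = "gX")))
  m <- matrix(0, 10, 1, dimnames = list(sprintf("m%d", 1:10), "s1"))
  m[c("m1", "m2"), 1] <- 3
  base <- pe_vector("s1", list(fold_change_matrix(m[1:9, , drop = FALSE], "mRNA")),
                    fx$genes, fx$targets, fx$pw)
  m[10, 1] <- 5                          # gX is outside the universe
  with_extra <- pe_vector("s1", list(fold_change_matrix(m, "mRNA")),
                          genes2, fx$targets, fx$pw)
  expect_equal(unname(base), unname(with_extra), ignore_attr = TRUE,
               tolerance = 0)
})

test_that("the PE matrix stacks samples with source-prefixed ids", {
  fx <- pe_fixture()
  m <- matrix(0, 9, 2, dimnames = list(sprintf("m%d", 1:9), c("s1", "s2")))
  m[1:3, 1] <- 3
  pe <- pe_matrix(list(fold_change_matrix(m, "mRNA")), fx$genes, fx$targets, fx$pw)
  expect_equal(dim(pe$values), c(3L, 2L))
  expect_true(all(startsWith(rownames(pe$values), "PE:C:")))
  expect_true(all(pe$values[, "s2"] == 0))
  expect_true(all(pe$provenance == "PE"))
})
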