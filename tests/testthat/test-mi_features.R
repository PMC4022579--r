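toy_maps <- function() {
  list(targets = as_target_map(data.frame(
         miRNA_id = "mir1", target_id = "m1", evidence = "validated",
         source = "db", stringsAsFactors = FALSE)),
       genes = as_gene_map(data.frame(
         feature_id = c("m1", "p1"), platform = c("mRNA", "protein"),
         gene_id = "g1", stringsAsFactors = FALSE)))
}

test_that("scaling context records the maximum absolute log-ratio", {
  expect_equal(fit_scaling(fcm(matrix(c(2, -4, 1), 1)))$m_max, 4)
  expect_equal(fit_scaling(fcm(matrix(0, 2, 2)))$m_max, 0)
  expect_equal(fit_scaling(fcm(matrix(-3.5, 1, 1)))$m_max, 3.5)
  expect_error(fit_scaling(fcm(matrix(NA_real_, 1, 1))), "no finite")
})

test_that("rescaling maps onto [-1, 1] with clipping for out-of-range values", {
  ctx <- fit_scaling(fcm(matrix(c(2, -4, 1), 1)))
  expect_equal(scale_log_ratios(4, ctx), 1)
  expect_equal(scale_log_ratios(0, ctx), 0)
  expect_equal(scale_log_ratios(2, ctx), 0.5)
  expect_equal(scale_log_ratios(-9, ctx), -1)   # test value beyond training range
  ctx0 <- fit_scaling(fcm(matrix(0, 1, 1)))
  expect_equal(scale_log_ratios(3, ctx0), 0)
  expect_true(is.na(scale_log_ratios(NA_real_, ctx)))
})

test_that("interaction inference enumerates pairs and transitive chains", {
  mp <- toy_maps()
  plat <- list(mRNA = "m1", miRNA = "mir1", protein = "p1")
  ints <- infer_interactions(mp$targets, mp$genes, plat)
  expect_equal(nrow(ints), 3L)
  expect_setequal(ints$kind, c("miRNA_mRNA", "mRNA_protein", "miRNA_protein"))
  expect_equal(ints$expected_sign[ints$kind == "mRNA_protein"], 1L)
  expect_equal(ints$expected_sign[ints$kind == "miRNA_mRNA"], -1L)

  # no miRNA platform: only the locus pair remains
  ints2 <- infer_interactions(mp$targets, mp$genes,
                              list(mRNA = "m1", protein = "p1"))
  expect_identical(ints2$kind, "mRNA_protein")

  # target mRNA absent from the platform: no miRNA pairs at all
  ints3 <- infer_interactions(mp$targets, mp$genes,
                              list(mRNA = "m9", miRNA = "mir1", protein = character()))
  expect_equal(nrow(ints3), 0L)
})

test_that("interaction scores are products of scaled member values", {
  mp <- toy_maps()
  ints <- infer_interactions(mp$targets, mp$genes,
                             list(mRNA = "m1", miRNA = "mir1", protein = "p1"))
  sc <- list(mRNA = matrix(c(-1, 0.5, 0), 1, 3,
                           dimnames = list("m1", c("s1", "s2", "s3"))),
             miRNA = matrix(c(1, 0.5, 0.7), 1, 3,
                            dimnames = list("mir1", c("s1", "s2", "s3"))),
             protein = matrix(c(0.2, NA, 0), 1, 3,
                              dimnames = list("p1", c("s1", "s2", "s3"))))
  fm <- score_interactions(ints, sc)
  v <- fm$values
  expect_equal(v["MI:mir1|m1", "s1"], -1)        # anticorrelation extreme
  expect_equal(v["MI:mir1|m1", "s2"], 0.25)
  expect_equal(v["MI:m1|p1", "s3"], 0)           # annihilation by a zero member
  expect_true(is.na(v["MI:m1|p1", "s2"]))        # missing member -> missing score
  expect_true(all(fm$provenance == "MI"))
})

test_that("MI scores obey range, sign rule and scale invariance", {
  set.seed(5)
  for (rep in 1:20) {
    xa <- runif(50, -6, 6); xb <- runif(50, -6, 6)
    ca <- fit_scaling(fcm(matrix(xa, 5))); cb <- fit_scaling(fcm(matrix(xb, 5)))
    s <- scale_log_ratios(xa, ca) * scale_log_ratios(xb, cb)
    expect_true(all(s >= -1 & s <= 1))
    expect_identical(sign(s), sign(xa) * sign(xb))
    # positive rescaling of one platform with a refitted context is a no-op
    c_resc <- fit_scaling(fcm(matrix(3.7 * xa, 5)))
    s2 <- scale_log_ratios(3.7 * xa, c_resc) * scale_log_ratios(xb, cb)
    expect_equal(s2, s, tolerance = 1e-12)
  }
})

test_that("planted miRNA-target pairs score negative in carcinogens only", {
  ds <- generate_synthetic(synthetic_config(
    n_compounds = c(GC = 3L, NGC = 3L, NC = 3L, UNDEFINED = 0L),
    n_mrna = 150L, n_mirna = 40L, n_protein = 30L, n_genes = 150L), seed = 9L)
  ints <- infer_interactions(ds$targets, ds$genes,
    lapply(ds$fc, function(f) rownames(f$log_ratios)))
  mi <- mi_feature_matrix(ints, ds$fc)
  planted_ids <- unlist(lapply(c("GC", "NGC"), function(cl) {
    pr <- ds$truth$planted[[cl]]$pairs
    sprintf("MI:%s|%s", pr$miRNA_id, pr$mrna)
  }))
  carc <- ds$annot$sample_id[ds$annot$class_label %in% c("GC", "NGC")]
  nc <- ds$annot$sample_id[ds$annot$class_label == "NC"]
  m_carc <- mean(mi$values[planted_ids, carc])
  m_nc <- mean(mi$values[planted_ids, nc])
  expect_lt(m_carc, -0.05)
  expect_lt(abs(m_nc), abs(m_carc) / 3)
})

test_that("highlighting requires 1.5-fold change in both partners and sign concordance", {
  mp <- toy_maps()
  ints <- infer_interactions(mp$targets, mp$genes,
                             list(mRNA = "m1", miRNA = "mir1", protein = "p1"))
  fc <- list(
    mRNA = fcm(matrix(c(-1, -1, 2), 1, 3), "mRNA", "m1", c("s1", "s2", "s3")),
    miRNA = fcm(matrix(c(1, 0.3, 1), 1, 3), "miRNA", "mir1", c("s1", "s2", "s3")),
    protein = fcm(matrix(c(-1, -1, 1), 1, 3), "protein", "p1", c("s1", "s2", "s3")))
  h <- highlight_interactions(ints, fc, fold_threshold = 1.5)
  h_mm <- h[h$kind == "miRNA_mRNA", ]
  # s1: both partners beyond log2(1.5) ~ 0.585 with opposite signs
  expect_true("s1" %in% h_mm$sample_id)
  # s2: miRNA at +0.3 is below the threshold
  expect_false("s2" %in% h_mm$sample_id)
  # s3: both partners up, violating the expected anti-correlation
  expect_false("s3" %in% h_mm$sample_id)
  # mRNA/protein co-up in s3 is concordant for the locus pair
  expect_true("s3" %in% h$sample_id[h$kind == "mRNA_protein"])
})
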