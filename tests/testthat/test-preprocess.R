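mk_expr <- function(values, platform = "mRNA") {
  expression_matrix(values, platform)
}

annot_1t3c <- function() {
  as_sample_annotation(data.frame(
    sample_id = c("t1", "c1", "c2", "c3"),
    compound = c("PB", "veh", "veh", "veh"),
    class_label = c("NGC", "NC", "NC", "NC"),
    is_control = c(FALSE, TRUE, TRUE, TRUE),
    control_group_id = "g1", stringsAsFactors = FALSE))
}

test_that("fold changes subtract the control-group summary", {
  v <- matrix(c(6, 4, 4, 4), 1, dimnames = list("f1", c("t1", "c1", "c2", "c3")))
  fc <- compute_fold_changes(mk_expr(v), annot_1t3c(), "median")
  expect_equal(fc$log_ratios["f1", "t1"], 2)

  # value equal to the control median gives zero
  v2 <- v; v2[1, "t1"] <- 4
  expect_equal(compute_fold_changes(mk_expr(v2), annot_1t3c(),
                                    "median")$log_ratios[1, 1], 0)

  # mean rule: controls {3, 5}, value 5 -> 1
  v3 <- matrix(c(5, 3, 5), 1, dimnames = list("f1", c("t1", "c1", "c2")))
  an <- annot_1t3c()[1:3, ]
  expect_equal(compute_fold_changes(mk_expr(v3), an, "mean")$log_ratios[1, 1], 1)

  # treated sample without controls errors by name
  an2 <- annot_1t3c(); an2$control_group_id[1] <- "missing"
  expect_error(compute_fold_changes(mk_expr(v), an2), "t1")
})

test_that("a control equal to its own odd-sized group's median maps to zero", {
  an <- as_sample_annotation(data.frame(
    sample_id = c("c1", "c2", "c3", "t1"), compound = c("veh", "veh", "veh", "PB"),
    class_label = c("NC", "NC", "NC", "NGC"),
    is_control = c(TRUE, TRUE, TRUE, FALSE), control_group_id = "g1"))
  v <- matrix(c(1, 2, 3, 9), 1, dimnames = list("f", c("c1", "c2", "c3", "t1")))
  # treat the median control as if it were a treated sample of the group
  an2 <- an; an2$is_control[2] <- FALSE; an2$class_label[2] <- "NGC"
  an2$compound[2] <- "X"
  fc <- compute_fold_changes(mk_expr(v), an2, "median")
  expect_equal(fc$log_ratios["f", "c2"], 0)
})

test_that("protein panel normalisation forms log2 ratios and masks background", {
  raw <- mk_expr(matrix(c(200, 100, 100, 100), 1,
                        dimnames = list("ab1", c("t1", "c1", "c2", "c3"))),
                 platform = "protein")
  out <- normalize_protein_panel(raw, annot_1t3c())
  expect_equal(out$values["ab1", "t1"], 1)       # log2(200/100)
  expect_equal(out$values["ab1", "c1"], 0)       # equals control median

  bg <- mk_expr(matrix(c(250, 50, 50, 50), 1,
                       dimnames = list("ab1", c("t1", "c1", "c2", "c3"))),
                platform = "protein")
  out2 <- normalize_protein_panel(raw, annot_1t3c(), background = bg)
  expect_true(is.na(out2$values["ab1", "t1"]))   # background >= combined signal
  expect_false(is.na(out2$values["ab1", "c1"]))

  raw0 <- mk_expr(matrix(c(200, 0, 0, 0), 1,
                         dimnames = list("ab1", c("t1", "c1", "c2", "c3"))),
                  platform = "protein")
  expect_error(normalize_protein_panel(raw0, annot_1t3c()), "non-positive")
})

test_that("kNN imputation fills holes from nearest features only", {
  m <- matrix(c(1, 2, 3, 4,
                1.1, 2.1, 3.1, 4.1,
                10, 9, 8, 7,
                1, 2, NA, 4), 4, 4, byrow = TRUE,
              dimnames = list(sprintf("f%d", 1:4), sprintf("s%d", 1:4)))
  fc <- fcm(m)
  out <- knn_impute(fc, k = 1L)
  # brute-force nearest neighbour on standardised rows over co-observed samples
  z <- t(apply(m, 1, function(r) (r - mean(r, na.rm = TRUE)) / sd(r, na.rm = TRUE)))
  d <- sapply(1:3, function(j) sqrt(mean((z[4, c(1, 2, 4)] - z[j, c(1, 2, 4)])^2)))
  nn <- which.min(d)
  expect_equal(out$log_ratios["f4", "s3"], m[nn, 3])
  # observed cells untouched
  expect_identical(out$log_ratios[-4, ], m[-4, ])
  expect_identical(out$log_ratios["f4", c("s1", "s2", "s4")],
                   m["f4", c("s1", "s2", "s4")])

  # no missing cells: identity
  expect_identical(knn_impute(fcm(m[1:3, ]), 2L)$log_ratios, m[1:3, ])

  # two equal nearest neighbours with value 1.5 impute 1.5
  m2 <- matrix(c(1, 2, 1.5,
                 1, 2, 1.5,
                 5, -3, 2,
                 1, 2, NA), 4, 3, byrow = TRUE,
               dimnames = list(sprintf("f%d", 1:4), sprintf("s%d", 1:3)))
  expect_equal(knn_impute(fcm(m2), 2L)$log_ratios["f4", "s3"], 1.5)
})

test_that("imputed values stay within the donor neighbourhood range", {
  set.seed(3)
  m <- matrix(rnorm(300), 30, 10,
              dimnames = list(sprintf("f%02d", 1:30), sprintf("s%02d", 1:10)))
  holes <- cbind(sample(30, 8), sample(10, 8, replace = TRUE))
  mh <- m; mh[holes] <- NA
  out <- knn_impute(fcm(mh), k = 4L)$log_ratios
  for (i in seq_len(nrow(holes))) {
    s <- holes[i, 2]
    expect_gte(out[holes[i, 1], s], min(mh[, s], na.rm = TRUE))
    expect_lte(out[holes[i, 1], s], max(mh[, s], na.rm = TRUE))
  }
})

test_that("imputation error stays below the residual noise level at ~1% missingness", {
  set.seed(41)
  # correlated feature blocks so neighbours are informative
  base <- matrix(rnorm(40 * 12, sd = 2), 40, 12)
  m <- base[rep(1:40, each = 5), ] + matrix(rnorm(200 * 12, sd = 0.4), 200, 12)
  dimnames(m) <- list(sprintf("f%03d", 1:200), sprintf("s%02d", 1:12))
  holes <- which(matrix(runif(length(m)) < 0.01, nrow(m)), arr.ind = TRUE)
  mh <- m; mh[holes] <- NA
  out <- knn_impute(fcm(mh), k = 5L)$log_ratios
  rmse <- sqrt(mean((out[holes] - m[holes])^2))
  # imputing from within-block neighbours must beat the marginal feature
  # spread (~2) by a wide margin; the within-block noise floor is 0.4
  expect_lt(rmse, 1)
})

test_that("only features unexpressed everywhere are filtered", {
  v <- matrix(rnorm(30), 3, 10, dimnames = list(c("a", "b", "c"), sprintf("s%d", 1:10)))
  det <- matrix(FALSE, 3, 10, dimnames = dimnames(v))
  det["a", 4] <- TRUE                       # detected once in ten: retained
  det["b", ] <- TRUE
  em <- expression_matrix(v, "miRNA", detection = det)
  out <- filter_unexpressed(em)
  expect_setequal(rownames(out$values), c("a", "b"))
  det["c", 1] <- TRUE
  em2 <- expression_matrix(v, "miRNA", detection = det)
  expect_identical(filter_unexpressed(em2)$values, v)
})
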