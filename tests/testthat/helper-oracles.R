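# Independent oracles used across tests; deliberately naive implementations
# that never share code with the package internals.

# upper-tail hypergeometric by direct combinatorial summation
hyper_enum <- function(N, M, n, m) {
  if (m == 0) return(1)
  k <- m:min(n, M)
  sum(choose(M, k) * choose(N - M, n - k)) / choose(N, n)
}

# AUC by exhaustive pair counting, ties worth one half
auc_pairs <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(sp) * length(sn))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# small fold-change matrix builder for hand-made cases
fcm <- function(values, platform = "mRNA", features = NULL, samples = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = length(values))
  if (is.null(features))
    features <- rownames(values) %||% sprintf("f%02d", seq_len(nrow(values)))
  if (is.null(samples))
    samples <- colnames(values) %||% sprintf("s%02d", seq_len(ncol(values)))
  dimnames(values) <- list(features, samples)
  fold_change_matrix(values, platform)
}

# minimal annotation for hand-made cases: compounds each with `reps`
# replicate samples, plus one shared control group
toy_annot <- function(compounds, classes, reps = 1L) {
  rows <- do.call(rbind, Map(function(cmp, cl) {
    data.frame(sample_id = if (reps == 1L) cmp else sprintf("%s_r%d", cmp, seq_len(reps)),
               compound = cmp, class_label = cl, dosing_time = 7,
               vehicle = "CO", is_control = FALSE, control_group_id = "ctrl",
               stringsAsFactors = FALSE)
  }, compounds, classes))
  as_sample_annotation(rows)
}
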