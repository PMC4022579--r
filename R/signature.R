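# SVM-based recursive feature elimination, spline signature-size
# optimisation, and average-rank consensus signatures.

# linear-SVM feature weights; x is samples x features
.svm_weights <- function(x, y, cost) {
  fit <- e1071::svm(x = x, y = y, kernel = "linear", cost = cost,
                    scale = FALSE, type = "C-classification")
  w <- crossprod(fit$coefs, fit$SV)
  drop(w)
}

.standardize_rows <- function(m, center = NULL, scale = NULL) {
  if (is.null(center)) center <- rowMeans(m, na.rm = TRUE)
  if (is.null(scale)) {
    scale <- apply(m, 1L, stats::sd, na.rm = TRUE)
    scale[is.na(scale) | scale == 0] <- 1
  }
  list(values = (m - center) / scale, center = center, scale = scale)
}

#' Rank features by SVM recursive feature elimination
#'
#' Repeatedly trains a linear maximum-margin classifier, ranks features by
#' squared weight, and removes the least informative ones until
#' `target_size` features remain. Per round, `max(1, floor(step_fraction *
#' remaining))` features are eliminated; once at most twice the target size
#' remain, elimination proceeds one feature at a time. The final ranking
#' lists survivors first (by final-fit weight), then eliminated features in
#' reverse elimination order; ties within a round break by weight magnitude,
#' then feature id.
#'
#' @param x feature matrix, features x samples (a [feature_matrix()] or bare
#'   matrix); rows are standardised internally on the given data.
#' @param y binary labels, one per sample (factor or coercible).
#' @param target_size stop eliminating at this many features (default 1,
#'   i.e. rank everything).
#' @param step_fraction fraction of remaining features dropped per round.
#' @param cost SVM regularisation constant, frozen across rounds.
#' @return data frame of class `ranked_features`: `feature_id`, `rank`,
#'   `round` (elimination round; 0 for survivors).
#' @export
svm_rfe <- function(x, y, target_size = 1L, step_fraction = 0.1, cost = 1) {
  if (inherits(x, "feature_matrix")) x <- x$values
  y <- factor(y)
  stopifnot(nlevels(y) == 2L, ncol(x) == length(y), min(table(y)) >= 2L)
  if (target_size > nrow(x))
    stop("target_size exceeds the number of features")
  xs <- .standardize_rows(x)$values
  remaining <- rownames(x)
  eliminated <- character(0)       # appended least-informative-first per round
  elim_round <- integer(0)
  round <- 0L
  w_final <- NULL
  repeat {
    round <- round + 1L
    w <- .svm_weights(t(xs[remaining, , drop = FALSE]), y, cost)
    names(w) <- remaining
    ord <- order(w^2, remaining)   # ascending informativeness, id tie-break
    if (length(remaining) <= target_size) { w_final <- w; break }
    n_elim <- if (length(remaining) <= 2L * target_size) 1L
              else max(1L, floor(step_fraction * length(remaining)))
    n_elim <- min(n_elim, length(remaining) - target_size)
    drop_ids <- remaining[ord[seq_len(n_elim)]]
    eliminated <- c(eliminated, drop_ids)
    elim_round <- c(elim_round, rep(round, n_elim))
    remaining <- setdiff(remaining, drop_ids)
    if (length(remaining) <= target_size) {
      w_final <- .svm_weights(t(xs[remaining, , drop = FALSE]), y, cost)
      names(w_final) <- remaining
      break
    }
  }
  surv_ord <- order(-w_final[remaining]^2, remaining)
  ids <- c(remaining[surv_ord], rev(eliminated))
  rounds <- c(rep(0L, length(remaining)), rev(elim_round))
  out <- data.frame(feature_id = ids, rank = seq_along(ids), round = rounds,
                    stringsAsFactors = FALSE)
  class(out) <- c("ranked_features", "data.frame")
  out
}

#' Approximate the optimal signature size by spline interpolation
#'
#' Fits a cubic interpolating spline through (size, accuracy) grid points,
#' evaluates it on every integer between the smallest and largest candidate
#' size, and returns the argmax (ties resolved toward the smallest size).
#' With fewer than three grid points the argmax over the grid is returned.
#'
#' @param sizes strictly increasing positive integer candidate sizes
#'   (default grid 5, 10, 15, 20, 25).
#' @param accuracies cross-validated accuracy per size, in \[0, 1\].
#' @return selected integer size.
#' @export
optimize_signature_size <- function(sizes, accuracies) {
  stopifnot(length(sizes) == length(accuracies), all(diff(sizes) > 0),
            all(accuracies >= 0 & accuracies <= 1))
  if (length(sizes) < 3L)
    return(sizes[which.max(accuracies)])
  f <- stats::splinefun(sizes, accuracies, method = "fmm")
  grid <- seq(min(sizes), max(sizes))
  vals <- f(grid)
  grid[which.max(vals)]       # which.max takes the first, i.e. smallest, tie
}

#' Consensus signature by average rank
#'
#' Merges the rankings from all cross-validation folds and repetitions:
#' features are ordered by their average rank (a feature absent from a
#' ranking receives that ranking's feature count + 1, a pessimal rank), and
#' the best `size` features form the consensus signature. Ties break by
#' feature id.
#'
#' @param rankings list of [svm_rfe()] results.
#' @param size signature size.
#' @param contrast optional contrast name recorded on the signature.
#' @param provenance optional named provenance tags per feature id.
#' @return data frame of class `consensus_signature`: `feature_id`,
#'   `mean_rank`, `rank`, and `provenance` when supplied.
#' @export
consensus_signature <- function(rankings, size, contrast = NULL, provenance = NULL) {
  stopifnot(length(rankings) >= 1L)
  all_ids <- sort(unique(unlist(lapply(rankings, `[[`, "feature_id"))))
  if (size > length(all_ids))
    stop("size exceeds the union of ranked features")
  rk <- vapply(rankings, function(r) {
    v <- r$rank[match(all_ids, r$feature_id)]
    v[is.na(v)] <- nrow(r) + 1L
    v
  }, numeric(length(all_ids)))
  if (is.null(dim(rk))) rk <- matrix(rk, ncol = length(rankings))
  avg <- rowMeans(rk)
  ord <- order(avg, all_ids)[seq_len(size)]
  out <- data.frame(feature_id = all_ids[ord], mean_rank = avg[ord],
                    rank = seq_len(size), stringsAsFactors = FALSE)
  if (!is.null(provenance)) out$provenance <- unname(provenance[out$feature_id])
  attr(out, "contrast") <- contrast
  class(out) <- c("consensus_signature", "data.frame")
  out
}
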