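# The five classifier backends used for signature evaluation. Each spec has
# a name, a hyperparameter grid (tuned on inner folds only), a fit contract
# (samples x features matrix + binary factor -> model) and a score contract
# (model + matrix -> one continuous score per sample, larger = more
# positive-class).

#' Define a classifier for signature evaluation
#'
#' @param name display name.
#' @param grid list of hyperparameter settings (each a named list); an empty
#'   list means no tuning.
#' @param fit `function(x, y, params)` with `x` samples x features and `y` a
#'   factor with levels `c("neg", "pos")`; returns a fitted model.
#' @param score `function(model, x)` returning one numeric score per row of
#'   `x`, larger meaning more positive-class.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(name, grid, fit, score) {
  structure(list(name = name, grid = grid, fit = fit, score = score),
            class = "classifier_spec")
}

# orient raw decision values so that larger = positive class, judged on
# training data (decision-value sign in e1071 depends on label order)
.orient <- function(scores, y) {
  if (mean(scores[y == "pos"]) >= mean(scores[y == "neg"])) 1 else -1
}

.spec_svm <- function() classifier_spec(
  "SVM",
  grid = lapply(c(0.01, 0.1, 1, 10), function(C) list(cost = C)),
  fit = function(x, y, params) {
    m <- e1071::svm(x = x, y = y, kernel = "linear", cost = params$cost,
                    scale = FALSE, type = "C-classification")
    dv <- attr(stats::predict(m, x, decision.values = TRUE), "decision.values")[, 1L]
    list(model = m, orient = .orient(dv, y))
  },
  score = function(fit, x) {
    dv <- attr(stats::predict(fit$model, x, decision.values = TRUE),
               "decision.values")[, 1L]
    fit$orient * dv
  })

.spec_rf <- function() classifier_spec(
  "RF",
  grid = list(list(mtry_rule = "sqrt"), list(mtry_rule = "third")),
  fit = function(x, y, params) {
    # randomForest cannot split on constant columns and stalls when every
    # predictor is constant; such columns carry no information anyway
    ok <- apply(x, 2L, function(c) any(c != c[1L]))
    if (!any(ok)) stop("all features constant in the training data")
    x <- x[, ok, drop = FALSE]
    p <- ncol(x)
    mtry <- max(1L, if (params$mtry_rule == "sqrt") floor(sqrt(p)) else floor(p / 3))
    list(model = randomForest::randomForest(x = x, y = y, ntree = 500L,
                                            mtry = mtry), ok = ok)
  },
  score = function(fit, x)
    stats::predict(fit$model, x[, fit$ok, drop = FALSE], type = "prob")[, "pos"])

.spec_nn <- function() classifier_spec(
  "NN",
  grid = do.call(c, lapply(c(3L, 5L, 10L), function(s)
    lapply(c(0.1, 0.01), function(d) list(size = s, decay = d)))),
  fit = function(x, y, params) {
    nnet::nnet(x = x, y = as.numeric(y == "pos"), size = params$size,
               decay = params$decay, maxit = 200L, trace = FALSE,
               entropy = TRUE, MaxNWts = 10000L)
  },
  score = function(fit, x) drop(stats::predict(fit, x)))

# Bayesian logistic regression as the MAP estimate under a weakly
# informative Gaussian coefficient prior (ridge penalty); no tuning grid.
.spec_bglm <- function() classifier_spec(
  "BGLM",
  grid = list(),
  fit = function(x, y, params) {
    # small compound cohorts are the norm here; glmnet's small-class caution
    # would fire on every fold
    suppressWarnings(
      glmnet::glmnet(x = x, y = y, family = "binomial", alpha = 0,
                     lambda = 1 / nrow(x), standardize = FALSE))
  },
  score = function(fit, x)
    drop(stats::predict(fit, newx = x, type = "response")))

.spec_pcr <- function() classifier_spec(
  "PCR",
  grid = lapply(1:10, function(k) list(ncomp = k)),
  fit = function(x, y, params) {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    k <- min(params$ncomp, ncol(pc$x), nrow(x) - 1L)
    df <- data.frame(y = as.numeric(y == "pos"), pc$x[, seq_len(k), drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    list(pc = pc, k = k, glm = fit)
  },
  score = function(fit, x) {
    sc <- scale(x, center = fit$pc$center, scale = FALSE) %*%
      fit$pc$rotation[, seq_len(fit$k), drop = FALSE]
    drop(suppressWarnings(
      stats::predict(fit$glm, newdata = as.data.frame(sc), type = "response")))
  })

#' Default classifier panel
#'
#' Linear SVM, random forest, single-hidden-layer neural network, Bayesian
#' logistic regression (Gaussian-prior MAP), and principal component
#' logistic regression.
#'
#' @param names subset of `c("SVM", "RF", "NN", "BGLM", "PCR")`.
#' @return named list of [classifier_spec()] objects.
#' @export
default_classifiers <- function(names = c("SVM", "RF", "NN", "BGLM", "PCR")) {
  all <- list(SVM = .spec_svm(), RF = .spec_rf(), NN = .spec_nn(),
              BGLM = .spec_bglm(), PCR = .spec_pcr())
  bad <- setdiff(names, names(all))
  if (length(bad)) stop("unknown classifier(s): ", paste(bad, collapse = ", "))
  all[names]
}
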