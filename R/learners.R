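#' Tree-ensemble classifier specification
#'
#' Describes one of the two supported learner families together with its
#' hyperparameters and the seed that makes fitting deterministic.
#'
#' @param learner `"rf"` (bagged tree ensemble / random forest, via ranger)
#'   or `"gbt"` (gradient-boosted tree ensemble, via xgboost).
#' @param seed Integer seed used for every fit under this spec.
#' @param ... Hyperparameter overrides. For `"rf"`: `num_trees` (default
#'   200; [mda_select()] documentation discusses lighter settings for the
#'   permutation loop), `mtry` (default: floor(sqrt(p))). For `"gbt"`:
#'   `nrounds` (default 50), `max_depth` (4), `eta` (0.3), `max_bin` (64;
#'   histogram splits keep wide gene-family matrices tractable).
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(learner = c("rf", "gbt"), seed = 1L, ...) {
  learner <- match.arg(learner)
  defaults <- switch(learner,
    rf = list(num_trees = 200L, mtry = NULL),
    gbt = list(nrounds = 50L, max_depth = 4L, eta = 0.3, max_bin = 64L)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  abort_if_not(length(unknown) == 0,
               sprintf("unknown hyperparameter(s) for '%s': %s", learner,
                       paste(unknown, collapse = ", ")))
  params <- utils::modifyList(defaults, over)
  structure(list(learner = learner, seed = as.integer(seed), params = params),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  cat(sprintf("<classifier_spec> %s (seed %d)\n", x$learner, x$seed))
  utils::str(x$params, give.attr = FALSE)
  invisible(x)
}

# Fit one ensemble on a samples x features matrix. `y` is a factor over
# trophic_levels(); unused levels are allowed (>= 2 observed classes
# required). Returns an opaque fit handle.
fit_learner <- function(x, y, spec, case_weights = NULL) {
  stopifnot(inherits(spec, "classifier_spec"))
  abort_if_not(length(unique(as.character(y))) >= 2,
               "training data must contain at least 2 classes")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  levels_all <- levels(y)
  if (spec$learner == "rf") {
    # always a probability forest: class calls are made here by argmax with
    # the fixed label-order tie-break (ranger's internal majority vote
    # resolves ties non-reproducibly)
    fit <- ranger::ranger(
      x = x, y = droplevels(y),
      num.trees = spec$params$num_trees,
      mtry = spec$params$mtry,
      probability = TRUE,
      case.weights = case_weights,
      seed = spec$seed, num.threads = 1
    )
  } else {
    dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L,
                                   weight = case_weights, nthread = 1)
    fit <- xgboost::xgb.train(
      params = list(objective = "multi:softprob",
                    num_class = length(levels_all),
                    max_depth = spec$params$max_depth,
                    eta = spec$params$eta,
                    tree_method = "hist",
                    max_bin = spec$params$max_bin,
                    seed = spec$seed, nthread = 1, verbosity = 0),
      data = dtrain, nrounds = spec$params$nrounds
    )
  }
  structure(list(learner = spec$learner, fit = fit, levels = levels_all),
            class = "trophomode_fit")
}

# Class-score matrix (n x length(levels), rows sum to 1) for new profiles.
predict_scores <- function(fit, x) {
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  levels_all <- fit$levels
  if (fit$learner == "rf") {
    p <- stats::predict(fit$fit, data = x, num.threads = 1)$predictions
    scores <- matrix(0, nrow = nrow(p), ncol = length(levels_all),
                     dimnames = list(NULL, levels_all))
    scores[, colnames(p)] <- p
  } else {
    pm <- stats::predict(fit$fit, newdata = xgboost::xgb.DMatrix(x, nthread = 1))
    if (!is.matrix(pm)) {  # older API: row-major vector of class scores
      pm <- matrix(pm, nrow = nrow(x), ncol = length(levels_all), byrow = TRUE)
    }
    scores <- pm
    dimnames(scores) <- list(NULL, levels_all)
  }
  scores
}

# Predicted class labels; ties broken by fixed level order
# (heterotrophy < mixotrophy < phototrophy) via which.max on ordered columns.
predict_classes <- function(fit, x) {
  scores <- predict_scores(fit, x)
  factor(fit$levels[max.col(scores, ties.method = "first")],
         levels = fit$levels)
}

# Stratified k-fold assignment, deterministic under fold_seed. Every class
# must have at least k members.
stratified_folds <- function(y, k, fold_seed) {
  abort_if_not(k >= 2, "`k` must be at least 2")
  counts <- table(droplevels(y))
  small <- names(counts)[counts < k]
  if (length(small) > 0) {
    rlang::abort(sprintf(
      "class(es) with fewer than k = %d members: %s; use a smaller k",
      k, paste(small, collapse = ", ")
    ))
  }
  folds <- integer(length(y))
  withr::with_seed(fold_seed, {
    for (cl in names(counts)) {
      idx <- sample(which(as.character(y) == cl))
      folds[idx] <- rep(sample(k), length.out = length(idx))
    }
  })
  folds
}

# Per-fold held-out accuracy for a fixed fold partition (samples x features
# matrix interface used by the MDA loop).
cv_accuracy_xy <- function(x, y, spec, folds) {
  k <- max(folds)
  vapply(seq_len(k), function(f) {
    test <- folds == f
    fit <- fit_learner(x[!test, , drop = FALSE], y[!test], spec)
    pred <- predict_classes(fit, x[test, , drop = FALSE])
    mean(as.character(pred) == as.character(y[test]))
  }, numeric(1))
}

#' Cross-validated classification accuracy
#'
#' Stratified k-fold cross-validation: the fold partition is fixed by
#' `fold_seed`, each fold is held out once, and accuracy is measured on the
#' held-out samples only. Identical inputs and seeds give an identical
#' partition and (because the learner itself is seeded) identical
#' accuracies.
#'
#' @param ts A [training_set].
#' @param spec A [classifier_spec].
#' @param k Number of folds (default 5; every class needs >= k members).
#' @param fold_seed Integer seed fixing the partition.
#' @return List with `mean_accuracy`, `fold_accuracy` (length k) and
#'   `folds` (the partition, for reuse).
#' @export
cv_accuracy <- function(ts, spec, k = 5, fold_seed = 1L) {
  stopifnot(inherits(ts, "trophic_training_set"))
  x <- t(ts$matrix$values)
  y <- ts$labels
  folds <- stratified_folds(y, k, fold_seed)
  acc <- cv_accuracy_xy(x, y, spec, folds)
  list(mean_accuracy = mean(acc), fold_accuracy = acc, folds = folds)
}
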