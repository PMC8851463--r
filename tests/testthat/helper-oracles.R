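# Independently coded permute-and-score loop used as the oracle for
# mda_select: direct ranger/xgboost fits, manual accuracy, same fold
# partition and the same documented seed derivation
# (bitwXor(perm_seed, j) for feature j), but none of the package's
# selection code.
brute_force_mda <- function(ts, spec, k, perm_seed, fold_seed) {
  x <- t(ts$matrix$values)
  y <- ts$labels
  folds <- trophomode:::stratified_folds(y, k, fold_seed)
  score <- function(xmat) {
    accs <- numeric(k)
    for (f in seq_len(k)) {
      tr <- folds != f
      if (spec$learner == "rf") {
        fit <- ranger::ranger(x = xmat[tr, , drop = FALSE],
                              y = droplevels(y[tr]),
                              num.trees = spec$params$num_trees,
                              mtry = spec$params$mtry, probability = TRUE,
                              seed = spec$seed, num.threads = 1)
        pm <- predict(fit, data = xmat[!tr, , drop = FALSE],
                      num.threads = 1)$predictions
        full <- matrix(0, nrow(pm), 3, dimnames = list(NULL, levels(y)))
        full[, colnames(pm)] <- pm
        pred <- levels(y)[max.col(full, ties.method = "first")]
      } else {
        dtr <- xgboost::xgb.DMatrix(xmat[tr, , drop = FALSE],
                                    label = as.integer(y[tr]) - 1L,
                                    nthread = 1)
        fit <- xgboost::xgb.train(
          params = list(objective = "multi:softprob", num_class = 3,
                        max_depth = spec$params$max_depth,
                        eta = spec$params$eta, tree_method = "hist",
                        max_bin = spec$params$max_bin,
                        seed = spec$seed, nthread = 1, verbosity = 0),
          data = dtr, nrounds = spec$params$nrounds)
        pm <- predict(fit, newdata = xgboost::xgb.DMatrix(
          xmat[!tr, , drop = FALSE], nthread = 1))
        if (!is.matrix(pm)) pm <- matrix(pm, ncol = 3, byrow = TRUE)
        pred <- levels(y)[max.col(pm, ties.method = "first")]
      }
      accs[f] <- mean(pred == as.character(y[!tr]))
    }
    mean(accs)
  }
  baseline <- score(x)
  keep <- character(0)
  for (j in seq_len(ncol(x))) {
    ord <- withr::with_seed(bitwXor(as.integer(perm_seed), j) %%
                              .Machine$integer.max, sample.int(nrow(x)))
    xp <- x
    xp[, j] <- x[ord, j]
    if (score(xp) < baseline) keep <- c(keep, colnames(x)[j])
  }
  list(baseline = baseline, keep = keep)
}

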