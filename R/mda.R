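#' Permute-and-score (mean decrease in accuracy) feature selection
#'
#' Train–test permutation importance with cross-validated accuracy: a
#' baseline mean accuracy is computed by stratified k-fold cross-validation,
#' then each gene family's values are randomly shuffled across all samples
#' (once per feature by default) and the cross-validated accuracy is
#' recomputed with the *same* fold partition. A family is retained if and
#' only if the permuted accuracy is strictly lower than the baseline —
#' "any decrease" is read literally, so ties are dropped, which is the
#' aggressive pruning that keeps a ~9,000-family feature space from
#' swamping a few-hundred-sample training set.
#'
#' Per-feature permutation seeds derive deterministically from
#' `bitwXor(perm_seed, feature_index)`, so a rerun with identical seeds is
#' bit-identical and single features can be re-examined in isolation.
#'
#' @param ts A [training_set].
#' @param spec A [classifier_spec]. For wide matrices a lighter ensemble
#'   (e.g. `classifier_spec("rf", num_trees = 64)`) keeps the
#'   one-fit-per-feature-per-fold loop tractable; importance ranks are
#'   stable well below the forest sizes used for final models.
#' @param k Cross-validation folds (default 5).
#' @param perm_seed Seed stream for the per-feature permutations.
#' @param fold_seed Seed fixing the fold partition shared by the baseline
#'   and all permuted runs (so fold noise cannot drive retention).
#' @param permutations Number of permutations averaged per feature
#'   (default 1, the described single-pass behavior; replicate r of
#'   feature j is seeded by `bitwXor(perm_seed, j) + r - 1`).
#' @param verbose Emit progress every 200 features.
#' @return A [feature_set] whose provenance records the learner, seeds,
#'   baseline accuracy and the per-feature permuted accuracies.
#' @export
mda_select <- function(ts, spec, k = 5, perm_seed = 1L, fold_seed = 1L,
                       permutations = 1L, verbose = FALSE) {
  stopifnot(inherits(ts, "trophic_training_set"),
            inherits(spec, "classifier_spec"))
  abort_if_not(length(unique(as.character(ts$labels))) >= 2,
               "feature selection needs at least 2 classes")
  x <- t(ts$matrix$values)
  y <- ts$labels
  n <- nrow(x)
  p <- ncol(x)
  folds <- stratified_folds(y, k, fold_seed)

  # Pre-split the fold matrices once; each permutation then only patches the
  # permuted feature's column in place, so the per-feature cost is the k
  # ensemble fits themselves.
  splits <- purrr::map(seq_len(k), function(f) {
    test <- folds == f
    list(xtr = x[!test, , drop = FALSE], ytr = y[!test],
         xte = x[test, , drop = FALSE], yte = y[test],
         tr_idx = which(!test), te_idx = which(test))
  })
  score_folds <- function() {
    mean(vapply(splits, function(s) {
      fit <- fit_learner(s$xtr, s$ytr, spec)
      mean(as.character(predict_classes(fit, s$xte)) ==
             as.character(s$yte))
    }, numeric(1)))
  }
  baseline <- score_folds()

  permuted <- numeric(p)
  accs <- numeric(permutations)
  for (j in seq_len(p)) {
    for (r in seq_len(permutations)) {
      ord <- withr::with_seed(mix_seed(perm_seed, j) + r - 1L, sample.int(n))
      xj <- x[ord, j]
      for (f in seq_len(k)) {
        splits[[f]]$xtr[, j] <- xj[splits[[f]]$tr_idx]
        splits[[f]]$xte[, j] <- xj[splits[[f]]$te_idx]
      }
      accs[r] <- score_folds()
    }
    for (f in seq_len(k)) {  # restore the unpermuted column
      splits[[f]]$xtr[, j] <- x[splits[[f]]$tr_idx, j]
      splits[[f]]$xte[, j] <- x[splits[[f]]$te_idx, j]
    }
    permuted[j] <- mean(accs[seq_len(permutations)])
    if (verbose && j %% 200 == 0) {
      message(sprintf("mda_select: %d/%d features scored", j, p))
    }
  }
  names(permuted) <- colnames(x)
  retained <- colnames(x)[permuted < baseline]
  feature_set(
    retained,
    name = sprintf("mda_%s", spec$learner),
    provenance = list(
      learner = spec$learner, learner_seed = spec$seed, k = k,
      perm_seed = perm_seed, fold_seed = fold_seed,
      permutations = permutations,
      baseline_accuracy = baseline, permuted_accuracy = permuted
    )
  )
}

#' Feature selection across several under-sampled datasets
#'
#' Runs [undersample()] (on the phototroph class) followed by
#' [mda_select()] for each requested under-sample size and combines the
#' per-size retained sets. At paper scale the sizes are 80, 100, 120 and
#' 140 against 275 phototrophic transcriptomes; the merge rule defaults to
#' the union and is configurable (`"majority"` keeps families retained in
#' more than half of the runs).
#'
#' @param ts A [training_set].
#' @param spec A [classifier_spec].
#' @param n_values Integer vector of phototroph under-sample sizes.
#' @param combine `"union"`, `"intersection"` or `"majority"`.
#' @param k,perm_seed,fold_seed As in [mda_select()].
#' @param under_seed Base seed for the under-samples (run i uses
#'   `under_seed + i - 1`).
#' @param target_class Class being under-sampled (default phototrophy).
#' @param ... Passed on to [mda_select()].
#' @return A [feature_set]; provenance records every per-size run.
#' @export
mda_multi <- function(ts, spec, n_values,
                      combine = c("union", "intersection", "majority"),
                      k = 5, perm_seed = 1L, fold_seed = 1L,
                      under_seed = 1L, target_class = "phototrophy", ...) {
  combine <- match.arg(combine)
  abort_if_not(length(n_values) >= 1, "`n_values` must be nonempty")
  runs <- purrr::imap(n_values, function(n, i) {
    sub <- undersample(ts, target_class, n, seed = under_seed + i - 1L)
    mda_select(sub, spec, k = k, perm_seed = perm_seed,
               fold_seed = fold_seed, ...)
  })
  sets <- purrr::map(runs, "members")
  members <- switch(combine,
    union = Reduce(union, sets),
    intersection = Reduce(intersect, sets),
    majority = {
      tab <- table(unlist(sets))
      names(tab)[tab > length(sets) / 2]
    }
  )
  feature_set(
    members,
    name = sprintf("mda_%s_%s", spec$learner, combine),
    provenance = list(
      learner = spec$learner, n_values = n_values, combine = combine,
      under_seed = under_seed, runs = purrr::map(runs, "provenance")
    )
  )
}
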