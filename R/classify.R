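#' Train a trophic-mode classifier on a reduced feature set
#'
#' Fits the ensemble on [subset_features]`(ts, fs)` (feature-set members
#' absent from the training matrix are zero-filled and recorded). The final
#' model trains on the full labeled set; class imbalance is handled by
#' optional inverse-frequency case weights (the default), rather than by
#' under-sampling, so no labeled transcriptome is discarded.
#'
#' @param ts A [training_set] with at least 2 classes.
#' @param fs A [feature_set].
#' @param spec A [classifier_spec]. The deployed configuration in the
#'   original study pairs the gradient-boosted ensemble with the combined
#'   feature set; the bagged forest remains available for consensus calls.
#' @param weights `"balanced"` (inverse class frequency) or `"none"`.
#' @return A `trophic_model`: the fitted ensemble, its feature set, and a
#'   manifest (class counts, seeds, feature-list hash, versions, time)
#'   sufficient to retrain bit-compatibly from the same data.
#' @export
train_classifier <- function(ts, fs, spec, weights = c("balanced", "none")) {
  stopifnot(inherits(ts, "trophic_training_set"),
            inherits(fs, "feature_set"),
            inherits(spec, "classifier_spec"))
  weights <- match.arg(weights)
  abort_if_not(length(unique(as.character(ts$labels))) >= 2,
               "training needs at least 2 classes")
  red <- subset_features(ts$matrix, fs)
  zero_filled <- attr(red, "zero_filled")
  if (length(zero_filled) > 0) {
    rlang::inform(sprintf(
      "%d feature-set member(s) absent from training data were zero-filled",
      length(zero_filled)
    ))
  }
  x <- t(red$values)
  y <- ts$labels
  cw <- NULL
  if (weights == "balanced") {
    freq <- table(droplevels(y))
    cw <- as.numeric(length(y) / (length(freq) * freq[as.character(y)]))
  }
  fit <- fit_learner(x, y, spec, case_weights = cw)
  manifest <- list(
    learner = spec$learner, seed = spec$seed, params = spec$params,
    weights = weights,
    class_counts = as.list(table(y)),
    n_features = length(fs$members),
    feature_hash = rlang::hash(fs$members),
    zero_filled = zero_filled,
    r_version = as.character(getRversion()),
    engine_version = as.character(utils::packageVersion(
      if (spec$learner == "rf") "ranger" else "xgboost")),
    created = format(Sys.time(), tz = "UTC")
  )
  structure(list(spec = spec, feature_set = fs, fit = fit,
                 classes = trophic_levels(), manifest = manifest),
            class = "trophic_model")
}

#' @export
print.trophic_model <- function(x, ...) {
  cat(sprintf("<trophic_model> %s over %d gene families\n",
              x$spec$learner, length(x$feature_set$members)))
  cat("training class counts:",
      paste(names(x$manifest$class_counts), unlist(x$manifest$class_counts),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Predict trophic mode for expression profiles
#'
#' Profiles are reduced to the model's feature set (absent families
#' zero-filled), scored, and assigned the argmax class; score ties are
#' broken by the fixed label order heterotrophy < mixotrophy < phototrophy.
#' Profiles in which every model feature is zero carry no usable signal:
#' they are flagged `no_signal` with an `NA` prediction and are excluded
#' from downstream proportion aggregation.
#'
#' @param object A `trophic_model`.
#' @param profiles A [trophic_matrix] of expression profiles (an empty
#'   sample set yields an empty tibble).
#' @param ... Unused.
#' @return A tibble with one row per profile: `sample_id`, `predicted`,
#'   `score_het`, `score_mix`, `score_phot` (non-negative, summing to 1),
#'   `no_signal`.
#' @export
predict.trophic_model <- function(object, profiles, ...) {
  stopifnot(inherits(profiles, "trophic_matrix"))
  if (ncol(profiles$values) == 0) {
    return(tibble::tibble(
      sample_id = character(), predicted = as_trophic_label(character()),
      score_het = numeric(), score_mix = numeric(), score_phot = numeric(),
      no_signal = logical()
    ))
  }
  red <- subset_features(profiles, object$feature_set)
  x <- t(red$values)
  no_signal <- rowSums(x) == 0
  scores <- predict_scores(object$fit, x)
  predicted <- factor(object$classes[max.col(scores, ties.method = "first")],
                      levels = object$classes)
  predicted[no_signal] <- NA
  tibble::tibble(
    sample_id = sample_ids(profiles),
    predicted = predicted,
    score_het = scores[, "heterotrophy"],
    score_mix = scores[, "mixotrophy"],
    score_phot = scores[, "phototrophy"],
    no_signal = unname(no_signal)
  )
}

#' Cohen's kappa from a confusion matrix
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` where `p_o` is the
#' observed accuracy (trace over total) and `p_e` the expected agreement
#' from the row/column marginals. Equals 1 for a diagonal matrix, 0 under
#' exact independence of predictions and truth, and is invariant to class
#' relabeling.
#'
#' @param confusion Square numeric matrix, truth in rows, predictions in
#'   columns.
#' @return Kappa in \[-1, 1\].
#' @export
cohens_kappa <- function(confusion) {
  confusion <- as.matrix(confusion)
  abort_if_not(nrow(confusion) == ncol(confusion),
               "confusion matrix must be square")
  total <- sum(confusion)
  abort_if_not(total > 0, "confusion matrix must not be empty")
  po <- sum(diag(confusion)) / total
  pe <- sum(rowSums(confusion) * colSums(confusion)) / total^2
  if (pe == 1) return(1)
  (po - pe) / (1 - pe)
}

#' Cross-validated evaluation with the full metric report
#'
#' Stratified k-fold cross-validation aggregating held-out predictions into
#' one confusion matrix, from which accuracy, per-class precision/recall,
#' macro-averaged precision and Cohen's kappa are computed.
#'
#' @param ts A [training_set].
#' @param fs A [feature_set] the data are reduced to first.
#' @param spec A [classifier_spec].
#' @param k Folds (default 5).
#' @param fold_seed Seed fixing the partition.
#' @param weights Class weighting passed to the per-fold fits.
#' @return A `trophic_cv` object: `fold_accuracy`, `mean_accuracy`,
#'   `confusion` (truth x predicted), `by_class` tibble (precision,
#'   recall), `macro_precision`, `kappa`. Has [generics::tidy()] and
#'   [generics::glance()] methods.
#' @export
cross_validate <- function(ts, fs, spec, k = 5, fold_seed = 1L,
                           weights = c("none", "balanced")) {
  stopifnot(inherits(ts, "trophic_training_set"))
  weights <- match.arg(weights)
  red <- subset_features(ts$matrix, fs)
  x <- t(red$values)
  y <- ts$labels
  folds <- stratified_folds(y, k, fold_seed)
  levels_all <- levels(y)
  confusion <- matrix(0L, 3, 3, dimnames = list(truth = levels_all,
                                                predicted = levels_all))
  fold_acc <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds == f
    cw <- NULL
    if (weights == "balanced") {
      freq <- table(droplevels(y[!test]))
      cw <- as.numeric(length(y[!test]) /
                         (length(freq) * freq[as.character(y[!test])]))
    }
    fit <- fit_learner(x[!test, , drop = FALSE], y[!test], spec,
                       case_weights = cw)
    pred <- predict_classes(fit, x[test, , drop = FALSE])
    fold_acc[f] <- mean(as.character(pred) == as.character(y[test]))
    confusion <- confusion + table(factor(y[test], levels_all),
                                   factor(pred, levels_all))
  }
  precision <- diag(confusion) / pmax(colSums(confusion), 1)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  by_class <- tibble::tibble(
    class = levels_all,
    n = as.integer(rowSums(confusion)),
    precision = as.numeric(precision),
    recall = as.numeric(recall)
  )
  structure(
    list(fold_accuracy = fold_acc, mean_accuracy = mean(fold_acc),
         accuracy = sum(diag(confusion)) / sum(confusion),
         confusion = confusion, by_class = by_class,
         macro_precision = mean(precision[rowSums(confusion) > 0]),
         kappa = cohens_kappa(confusion),
         k = k, learner = spec$learner),
    class = "trophic_cv"
  )
}

#' @export
print.trophic_cv <- function(x, ...) {
  cat(sprintf(
    "<trophic_cv> %s, %d-fold: accuracy %.3f (folds %s), kappa %.3f\n",
    x$learner, x$k, x$mean_accuracy,
    paste(sprintf("%.2f", x$fold_accuracy), collapse = "/"), x$kappa
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trophic_cv <- function(x, ...) x$by_class

#' @exportS3Method generics::glance
glance.trophic_cv <- function(x, ...) {
  tibble::tibble(
    mean_accuracy = x$mean_accuracy, accuracy = x$accuracy,
    macro_precision = x$macro_precision, kappa = x$kappa, k = x$k,
    learner = x$learner
  )
}

#' Compare metric distributions across runs
#'
#' Omnibus Kruskal–Wallis H test over the groups, followed by post-hoc
#' pairwise Wilcoxon rank-sum tests with Benjamini–Hochberg correction.
#' Rank-sum p-values use exact enumeration when both groups have at most
#' 10 values and no ties, and the normal approximation with tie correction
#' otherwise.
#'
#' @param groups Named list (>= 2 entries) of numeric vectors (>= 2 values
#'   each), e.g. accuracy across resampling runs per model family.
#' @param alpha Significance level for the decision column.
#' @return List with `kruskal` (statistic, df, p.value) and `pairs`, a
#'   tibble of pairwise comparisons (p.value, p.adjusted, significant).
#' @export
compare_runs <- function(groups, alpha = 0.05) {
  abort_if_not(is.list(groups) && length(groups) >= 2,
               "`groups` must be a named list of at least 2 groups")
  abort_if_not(!is.null(names(groups)) && all(nzchar(names(groups))),
               "`groups` must be named")
  sizes <- lengths(groups)
  if (any(sizes < 2)) {
    rlang::abort(sprintf("group(s) with fewer than 2 values: %s",
                         paste(names(groups)[sizes < 2], collapse = ", ")))
  }
  if (length(unique(unlist(groups))) == 1) {
    # every observation tied: no rank signal, H = 0 by convention
    kw <- list(statistic = c("Kruskal-Wallis chi-squared" = 0),
               parameter = c(df = length(groups) - 1), p.value = 1)
  } else {
    kw <- stats::kruskal.test(groups)
  }
  pair_idx <- utils::combn(names(groups), 2, simplify = FALSE)
  pairs <- purrr::map_dfr(pair_idx, function(pr) {
    a <- groups[[pr[1]]]
    b <- groups[[pr[2]]]
    ties <- anyDuplicated(c(a, b)) > 0
    exact <- length(a) <= 10 && length(b) <= 10 && !ties
    if (length(unique(c(a, b))) == 1) {
      wt <- list(statistic = c(W = length(a) * length(b) / 2), p.value = 1)
    } else {
      wt <- suppressWarnings(
        stats::wilcox.test(a, b, exact = exact, correct = !exact)
      )
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2],
                   statistic = unname(wt$statistic), p.value = wt$p.value,
                   exact = exact)
  })
  pairs$p.adjusted <- stats::p.adjust(pairs$p.value, method = "BH")
  pairs$significant <- pairs$p.adjusted < alpha
  list(
    kruskal = tibble::tibble(statistic = unname(kw$statistic),
                             df = unname(kw$parameter),
                             p.value = kw$p.value),
    pairs = pairs, alpha = alpha
  )
}

#' Consensus call between two models' predictions
#'
#' @param a,b Prediction tibbles from [predict.trophic_model()] over the
#'   same sample set (an error lists any difference).
#' @return Tibble: `sample_id`, `predicted_a`, `predicted_b`, `consensus`
#'   (the shared label where the two models agree, `"none"` otherwise;
#'   pairs involving an `NA`/no-signal prediction yield `"none"`).
#' @export
consensus <- function(a, b) {
  only_a <- setdiff(a$sample_id, b$sample_id)
  only_b <- setdiff(b$sample_id, a$sample_id)
  if (length(only_a) > 0 || length(only_b) > 0) {
    rlang::abort(sprintf(
      "sample sets differ; only in a: [%s]; only in b: [%s]",
      paste(only_a, collapse = ", "), paste(only_b, collapse = ", ")
    ))
  }
  merged <- dplyr::inner_join(
    dplyr::select(a, "sample_id", predicted_a = "predicted"),
    dplyr::select(b, "sample_id", predicted_b = "predicted"),
    by = "sample_id"
  )
  dplyr::mutate(
    merged,
    consensus = dplyr::if_else(
      !is.na(.data$predicted_a) & !is.na(.data$predicted_b) &
        .data$predicted_a == .data$predicted_b,
      as.character(.data$predicted_a), "none"
    )
  )
}

#' Majority vote across replicate predictions
#'
#' Aggregates prediction records over grouping columns (experiment,
#' species, bin, ...) into one call per group: under `rule = "majority"`
#' the label must win strictly more than half of the votes, under
#' `"plurality"` it only needs the (unique) maximum. Ties and failed
#' majorities give `"unresolved"`.
#'
#' @param records Prediction tibble with a `predicted` column (NA rows are
#'   ignored) plus the grouping columns.
#' @param ... Grouping columns (tidy-select); each group must be nonempty.
#' @param rule `"majority"` (strict, > 1/2) or `"plurality"`.
#' @return Tibble of groups with vote counts `n_het`, `n_mix`, `n_phot`,
#'   total `n_votes`, and `vote`.
#' @export
majority_vote <- function(records, ..., rule = c("majority", "plurality")) {
  rule <- match.arg(rule)
  abort_if_not(nrow(records) > 0, "empty prediction group")
  grouped <- dplyr::group_by(records, ...)
  out <- dplyr::summarise(
    grouped,
    n_het = sum(.data$predicted == "heterotrophy", na.rm = TRUE),
    n_mix = sum(.data$predicted == "mixotrophy", na.rm = TRUE),
    n_phot = sum(.data$predicted == "phototrophy", na.rm = TRUE),
    .groups = "drop"
  )
  counts <- as.matrix(out[, c("n_het", "n_mix", "n_phot")])
  total <- rowSums(counts)
  top <- apply(counts, 1, max)
  tied <- rowSums(counts == top) > 1
  winner <- trophic_levels()[max.col(counts, ties.method = "first")]
  vote <- dplyr::case_when(
    total == 0 | tied ~ "unresolved",
    rule == "majority" & top <= total / 2 ~ "unresolved",
    .default = winner
  )
  dplyr::mutate(out, n_votes = total, vote = vote)
}

#' Persist and reload a trained model
#'
#' Writes a model directory holding `manifest.json`, the feature list, and
#' the learner-native serialized ensemble (`xgboost` binary for the
#' gradient-boosted learner, RDS for the bagged forest). Loading verifies
#' the manifest's feature-list hash.
#'
#' @param model A `trophic_model`.
#' @param dir Model directory (created if needed).
#' @return [save_trophic_model()] returns `dir` invisibly;
#'   [load_trophic_model()] returns the model.
#' @export
save_trophic_model <- function(model, dir) {
  stopifnot(inherits(model, "trophic_model"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(model$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  write_feature_set(model$feature_set, file.path(dir, "features.txt"))
  if (model$spec$learner == "gbt") {
    xgboost::xgb.save(model$fit$fit, file.path(dir, "model.xgb"))
  } else {
    saveRDS(model$fit$fit, file.path(dir, "model.rds"))
  }
  saveRDS(model$spec, file.path(dir, "spec.rds"))
  invisible(dir)
}

#' @rdname save_trophic_model
#' @export
load_trophic_model <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fs <- read_feature_set(file.path(dir, "features.txt"))
  abort_if_not(identical(rlang::hash(fs$members), manifest$feature_hash),
               "feature list does not match the manifest hash")
  spec <- readRDS(file.path(dir, "spec.rds"))
  raw <- if (manifest$learner == "gbt") {
    xgboost::xgb.load(file.path(dir, "model.xgb"))
  } else {
    readRDS(file.path(dir, "model.rds"))
  }
  fit <- structure(list(learner = manifest$learner, fit = raw,
                        levels = trophic_levels()),
                   class = "trophomode_fit")
  structure(list(spec = spec, feature_set = fs, fit = fit,
                 classes = trophic_levels(), manifest = manifest),
            class = "trophic_model")
}
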