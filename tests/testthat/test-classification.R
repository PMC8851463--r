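test_that("training is deterministic and zero-fills absent feature-set members", {
  gen <- planted_training(n_per_class = 10, seed = 11)
  ts <- gen$training
  fs <- feature_set(feature_ids(ts$matrix)[1:12], "probe")
  spec <- classifier_spec("gbt", nrounds = 20, seed = 3)
  m1 <- train_classifier(ts, fs, spec)
  m2 <- train_classifier(ts, fs, spec)
  probe <- ts$matrix
  expect_identical(predict(m1, probe), predict(m2, probe))

  # absent member: trains after zero-fill and records it
  fs2 <- feature_set(c(fs$members, "PFABSENT"), "probe2")
  expect_message(m3 <- train_classifier(ts, fs2, spec), "zero-filled")
  expect_identical(m3$manifest$zero_filled, "PFABSENT")

  # single-class input is rejected
  phot <- names(ts$labels)[ts$labels == "phototrophy"]
  one <- training_set(
    trophic_matrix(ts$matrix$values[, phot], units = ts$matrix$units),
    ts$labels[phot]
  )
  expect_error(train_classifier(one, fs, spec), "2 classes")
})

test_that("a separable synthetic training set is fitted nearly perfectly", {
  gen <- planted_training(n_per_class = 12, seed = 21)
  ts <- gen$training
  fs <- feature_set(gen$truth$features$feature_id, "all")
  for (learner in c("rf", "gbt")) {
    model <- train_classifier(ts, fs, classifier_spec(learner, seed = 2))
    preds <- predict(model, ts$matrix)
    acc <- mean(as.character(preds$predicted) == as.character(ts$labels))
    expect_gte(acc, 0.95)
  }
})

test_that("prediction records satisfy their score and flag contracts", {
  gen <- planted_training(n_per_class = 8, seed = 31)
  ts <- gen$training
  fs <- feature_set(gen$truth$features$feature_id[1:12], "blocks")
  model <- train_classifier(ts, fs, classifier_spec("gbt", nrounds = 10,
                                                    seed = 1))
  preds <- predict(model, ts$matrix)
  expect_identical(nrow(preds), ncol(ts$matrix$values))
  sums <- preds$score_het + preds$score_mix + preds$score_phot
  expect_true(all(abs(sums - 1) < 1e-6))
  # argmax equals the predicted label for classified records
  scores <- as.matrix(preds[, c("score_het", "score_mix", "score_phot")])
  arg <- trophic_levels()[max.col(scores, ties.method = "first")]
  ok <- !preds$no_signal
  expect_identical(as.character(preds$predicted[ok]), arg[ok])

  # empty input -> empty output
  empty <- trophic_matrix(matrix(numeric(0), nrow = 3, ncol = 0,
                                 dimnames = list(c("a", "b", "c"), NULL)))
  expect_identical(nrow(predict(model, empty)), 0L)

  # all-zero profile on the model features -> no-signal flag
  probe_vals <- matrix(0, nrow = nrow(ts$matrix$values), ncol = 1,
                       dimnames = list(feature_ids(ts$matrix), "dead"))
  probe_vals[setdiff(feature_ids(ts$matrix), fs$members), 1] <- 10
  dead <- predict(model, trophic_matrix(probe_vals))
  expect_true(dead$no_signal[1])
  expect_true(is.na(dead$predicted[1]))
})

test_that("a generated phototroph profile is recovered with a confident score", {
  gen <- planted_training(n_per_class = 12, seed = 41)
  ts <- gen$training
  fs <- feature_set(gen$truth$features$feature_id, "all")
  model <- train_classifier(ts, fs, classifier_spec("gbt", seed = 6))
  fresh <- planted_training(n_per_class = 3, seed = 999)$training
  phot_id <- names(fresh$labels)[fresh$labels == "phototrophy"][1]
  probe <- trophic_matrix(fresh$matrix$values[, phot_id, drop = FALSE],
                          units = fresh$matrix$units)
  pred <- predict(model, probe)
  expect_identical(as.character(pred$predicted), "phototrophy")
  expect_gte(pred$score_phot, 0.5)
})

test_that("Cohen's kappa hits its closed-form anchors and invariances", {
  # diagonal -> 1
  expect_equal(cohens_kappa(diag(c(5, 8, 13))), 1)
  # exact independence (outer product of marginals) -> 0
  r <- c(10, 20, 30); cmarg <- c(15, 25, 20)
  indep <- outer(r, cmarg) / sum(r)
  expect_equal(cohens_kappa(indep), 0, tolerance = 1e-9)
  # random matrix equals an independently coded p_o/p_e computation
  withr::with_seed(12, for (i in 1:5) {
    cm <- matrix(rpois(9, 20), 3, 3)
    po <- sum(diag(cm)) / sum(cm)
    pe <- sum(rowSums(cm) / sum(cm) * colSums(cm) / sum(cm))
    expect_equal(cohens_kappa(cm), (po - pe) / (1 - pe), tolerance = 1e-12)
    # invariance to simultaneous class relabeling
    p <- sample(3)
    expect_equal(cohens_kappa(cm[p, p]), cohens_kappa(cm), tolerance = 1e-12)
  })
})

test_that("cross_validate reports a coherent confusion matrix, precision and kappa", {
  ts <- label_encoding_training(n_per_class = 10)
  fs <- feature_set(feature_ids(ts$matrix), "all")
  rep <- cross_validate(ts, fs, classifier_spec("rf", num_trees = 50,
                                                seed = 2),
                        k = 5, fold_seed = 4)
  expect_equal(rep$mean_accuracy, 1)
  expect_equal(rep$kappa, 1)
  expect_identical(unname(rowSums(rep$confusion)), c(10, 10, 10))
  expect_equal(rep$accuracy, sum(diag(rep$confusion)) / sum(rep$confusion))
  g <- glance(rep)
  expect_identical(nrow(g), 1L)
  expect_identical(nrow(tidy(rep)), 3L)

  # noisy case: confusion row sums still equal class counts
  gen <- planted_training(n_per_class = 8, effect = 1, seed = 3)
  rep2 <- cross_validate(gen$training,
                         feature_set(feature_ids(gen$training$matrix)),
                         classifier_spec("rf", num_trees = 30, seed = 1),
                         k = 4, fold_seed = 9)
  expect_identical(unname(rowSums(rep2$confusion)), c(8, 8, 8))
  expect_gte(rep2$kappa, -1)
  expect_lte(rep2$kappa, 1)
})

test_that("compare_runs reproduces exact rank-sum enumeration and the BH step-up rule", {
  # omnibus + pairwise on clearly separated groups
  res <- compare_runs(list(lo = c(1, 2, 3, 4, 5), hi = c(11, 12, 13, 14, 15)))
  # exact enumeration oracle over all C(10,5) assignments of ranks
  ranks <- 1:10
  obs <- sum(1:5)
  combos <- utils::combn(10, 5)
  null_sums <- colSums(matrix(ranks[combos], nrow = 5))
  p_exact <- mean(null_sums <= obs) + mean(null_sums >= sum(ranks) - obs)
  expect_equal(res$pairs$p.value, p_exact, tolerance = 1e-12)
  expect_true(res$pairs$exact)

  # all-constant groups: no signal, nothing significant
  flat <- compare_runs(list(a = c(2, 2, 2), b = c(2, 2, 2), c = c(2, 2, 2)))
  expect_equal(flat$kruskal$statistic, 0)
  expect_false(any(flat$pairs$significant))

  # BH on (0.01, 0.02, 0.03) -> (0.03, 0.03, 0.03)
  expect_equal(p.adjust(c(0.01, 0.02, 0.03), "BH"), rep(0.03, 3))
  # BH monotonicity on the pairwise table
  withr::with_seed(5, {
    g <- list(a = rnorm(6), b = rnorm(6, 1), c = rnorm(6, 2), d = rnorm(6))
    many <- compare_runs(g)
    ord <- order(many$pairs$p.value)
    expect_true(all(diff(many$pairs$p.adjusted[ord]) >= -1e-12))
    expect_true(all(many$pairs$p.adjusted <= 1))
  })

  expect_error(compare_runs(list(a = 1, b = c(1, 2))), "fewer than 2")
  expect_error(compare_runs(list(a = c(1, 2))), "at least 2 groups")
})

test_that("consensus agrees only where both models agree", {
  a <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                      predicted = factor(c("phototrophy", "phototrophy",
                                           "mixotrophy"), trophic_levels()))
  b <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                      predicted = factor(c("phototrophy", "heterotrophy",
                                           "mixotrophy"), trophic_levels()))
  cons <- consensus(a, b)
  expect_identical(cons$consensus, c("phototrophy", "none", "mixotrophy"))

  # counting oracle on 100 random pairs
  withr::with_seed(30, {
    ra <- sample(trophic_levels(), 100, replace = TRUE)
    rb <- sample(trophic_levels(), 100, replace = TRUE)
  })
  ids <- sprintf("r%03d", 1:100)
  cons2 <- consensus(
    tibble::tibble(sample_id = ids, predicted = factor(ra, trophic_levels())),
    tibble::tibble(sample_id = ids, predicted = factor(rb, trophic_levels()))
  )
  expect_identical(sum(cons2$consensus != "none"), sum(ra == rb))

  expect_error(consensus(a, b[1:2, ]), "s3")
})

test_that("majority_vote distinguishes strict majority, plurality and ties", {
  rec <- tibble::tibble(
    group = c("g1", "g1", "g1", "g2", "g2"),
    predicted = factor(c("mixotrophy", "mixotrophy", "phototrophy",
                         "phototrophy", "heterotrophy"), trophic_levels())
  )
  maj <- majority_vote(rec, group)
  expect_identical(maj$vote[maj$group == "g1"], "mixotrophy")
  expect_identical(maj$vote[maj$group == "g2"], "unresolved")
  plu <- majority_vote(rec, group, rule = "plurality")
  expect_identical(plu$vote[plu$group == "g1"], "mixotrophy")
  expect_identical(plu$vote[plu$group == "g2"], "unresolved")

  # 7 random labels vs counting oracle
  withr::with_seed(44, for (i in 1:10) {
    labs <- sample(trophic_levels(), 7, replace = TRUE)
    v <- majority_vote(tibble::tibble(group = "g",
                                      predicted = factor(labs,
                                                         trophic_levels())),
                       group)
    counts <- table(factor(labs, trophic_levels()))
    top <- max(counts)
    expected <- if (sum(counts == top) > 1 || top <= 7 / 2) "unresolved" else
      names(counts)[which.max(counts)]
    expect_identical(v$vote, expected)
  })
  expect_error(majority_vote(tibble::tibble(predicted = factor(character(),
                                                               trophic_levels()))),
               "empty")
})

test_that("models persist to disk and reload with a verified feature hash", {
  gen <- planted_training(n_per_class = 8, seed = 77)
  ts <- gen$training
  fs <- feature_set(gen$truth$features$feature_id[1:10], "persist")
  dir <- withr::local_tempdir()
  for (learner in c("rf", "gbt")) {
    model <- train_classifier(ts, fs, classifier_spec(learner, seed = 8))
    mdir <- file.path(dir, learner)
    save_trophic_model(model, mdir)
    back <- load_trophic_model(mdir)
    p1 <- predict(model, ts$matrix)
    p2 <- predict(back, ts$matrix)
    expect_equal(p2$score_phot, p1$score_phot, tolerance = 1e-6)
    expect_identical(as.character(p2$predicted), as.character(p1$predicted))
  }
  # hash mismatch is detected
  writeLines(c("# name: persist", "PFTAMPERED"),
             file.path(dir, "rf", "features.txt"))
  expect_error(load_trophic_model(file.path(dir, "rf")), "hash")
})
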