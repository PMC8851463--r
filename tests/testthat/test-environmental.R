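# Build a bin with controlled per-profile nonzero counts at one station.
make_bin <- function(bin_id, nonzeros, n_features = 1200, station = "st1",
                     latitude = 25, training_related = TRUE, seed = 1) {
  ids <- sprintf("%s_p%d", bin_id, seq_along(nonzeros))
  vals <- matrix(0, n_features, length(nonzeros),
                 dimnames = list(sprintf("PF%05d", seq_len(n_features)), ids))
  withr::with_seed(seed, {
    for (i in seq_along(nonzeros)) {
      vals[sample(n_features, nonzeros[i]), i] <- runif(nonzeros[i], 1, 100)
    }
  })
  meta <- tibble::tibble(sample_id = ids, station = station,
                         latitude = latitude,
                         local_time = 6 * (seq_along(nonzeros) - 1) %% 24)
  bin_profile_set(bin_id, trophic_matrix(vals, sample_meta = meta),
                  training_related)
}

test_that("the completeness boundary is >= 800: 799 is dropped, 800 is kept", {
  bin <- make_bin("b1", c(799, 800, 1000, 950, 900))
  res <- filter_bins(list(bin), completeness = 800, min_profiles = 4)
  expect_length(res$bins, 1)
  expect_identical(sample_ids(res$bins[[1]]$profiles),
                   c("b1_p2", "b1_p3", "b1_p4", "b1_p5"))
  expect_identical(res$report$sample_id, "b1_p1")
  expect_identical(res$report$reason, "completeness")
})

test_that("bins below the replication minimum and unrelated bins are dropped with reasons", {
  three <- make_bin("few", c(900, 900, 900))        # only 3 passing profiles
  unrel <- make_bin("far", c(900, 900, 900, 900, 900),
                    training_related = FALSE)
  good <- make_bin("ok", c(900, 900, 900, 900))
  res <- filter_bins(list(three, unrel, good))
  expect_identical(purrr::map_chr(res$bins, "bin_id"), "ok")
  reasons <- stats::setNames(res$report$reason, res$report$sample_id)
  expect_true(all(reasons[startsWith(names(reasons), "few")] == "replication"))
  expect_true(all(reasons[startsWith(names(reasons), "far")] ==
                    "unrelated-to-training"))
  # every excluded profile appears exactly once in the report
  expect_identical(anyDuplicated(res$report$sample_id), 0L)

  # empty input -> empty output and report
  empty <- filter_bins(list())
  expect_length(empty$bins, 0)
  expect_identical(nrow(empty$report), 0L)
})

test_that("composite filtering equals completeness-then-replication applied in order", {
  bins <- list(
    make_bin("a", c(799, 850, 820, 810, 805), seed = 2),   # 4 pass
    make_bin("b", c(700, 799, 900, 880, 870), seed = 3),   # 3 pass -> dropped
    make_bin("c", c(900, 901, 902, 903, 904, 700), seed = 4)
  )
  composite <- filter_bins(bins)
  # stepwise: completeness with no replication rule, then replication only
  step1 <- filter_bins(bins, completeness = 800, min_profiles = 1)
  step2 <- filter_bins(step1$bins, completeness = 0, min_profiles = 4)
  expect_identical(purrr::map_chr(composite$bins, "bin_id"),
                   purrr::map_chr(step2$bins, "bin_id"))
  for (i in seq_along(composite$bins)) {
    expect_identical(sample_ids(composite$bins[[i]]$profiles),
                     sample_ids(step2$bins[[i]]$profiles))
  }
})

test_that("bin proportions are counting arithmetic and always normalize to 1", {
  rec <- tibble::tibble(
    bin_id = c(rep("b1", 6), rep("b2", 4)),
    predicted = factor(c(rep("heterotrophy", 6),
                         rep("heterotrophy", 3), "mixotrophy"),
                       trophic_levels()),
    no_signal = FALSE
  )
  s <- bin_proportions(rec)
  b1 <- s[s$bin_id == "b1", ]
  expect_identical(c(b1$p_het, b1$p_mix, b1$p_phot), c(1, 0, 0))
  b2 <- s[s$bin_id == "b2", ]
  expect_identical(c(b2$p_het, b2$p_mix, b2$p_phot), c(0.75, 0.25, 0))
  expect_true(all(abs(s$p_het + s$p_mix + s$p_phot - 1) < 1e-9))
  expect_identical(s$n, s$n_het + s$n_mix + s$n_phot)

  # no-signal records are excluded before counting
  rec$no_signal[1] <- TRUE
  s2 <- bin_proportions(rec)
  expect_identical(s2$n[s2$bin_id == "b1"], 5L)

  expect_error(bin_proportions(rec, group_vars = "station"), "station")
})

test_that("conflict exclusion flags phot/het splits lacking mixotrophy, with strict boundaries", {
  s <- tibble::tibble(
    bin_id = c("conflict", "pure", "boundary", "mixy"),
    n_het = c(35, 0, 60, 30), n_mix = c(0, 0, 15, 40), n_phot = c(40, 10, 25, 30)
  ) |>
    dplyr::mutate(n = n_het + n_mix + n_phot,
                  p_het = n_het / n, p_mix = n_mix / n, p_phot = n_phot / n)
  out <- conflict_exclusion(s, threshold = 0.25, mix_floor = 0.05)
  flags <- stats::setNames(out$excluded, out$bin_id)
  expect_true(flags[["conflict"]])            # (0.40 phot, ~0.47 het, 0 mix)
  expect_false(flags[["pure"]])               # (1, 0, 0)
  expect_false(flags[["boundary"]])           # phot exactly 0.25: strict >
  expect_false(flags[["mixy"]])               # plenty of mixotrophy
  expect_identical(out$exclusion_reason[out$bin_id == "conflict"],
                   "phot/het conflict")

  # the quoted proportions: (0.40, 0.35, 0.00) excluded, (0.25, 0.60, 0.15) kept
  q <- tibble::tibble(bin_id = c("x", "y"),
                      n_het = c(35, 60), n_mix = c(0, 15), n_phot = c(40, 25),
                      n = c(75, 100),
                      p_phot = c(0.40, 0.25), p_het = c(0.35, 0.60),
                      p_mix = c(0.00, 0.15))
  qo <- conflict_exclusion(q)
  expect_identical(qo$excluded, c(TRUE, FALSE))

  expect_error(conflict_exclusion(s, threshold = 1.5), "\\(0, 1\\)")
})

test_that("latitude_trend recovers exact quadratics and is honest about null trends", {
  lat <- seq(20, 40, length.out = 12)
  truth <- function(x) 0.02 * x^2 - 1.1 * x + 16
  p_het <- truth(lat)
  s <- tibble::tibble(bin_id = "b", latitude = lat,
                      p_het = p_het, p_mix = 1 - p_het - 0.1, p_phot = 0.1)
  tr <- latitude_trend(s, degree = 2)
  co <- tidy(tr)
  het_co <- co$estimate[co$class == "heterotrophy"]
  expect_equal(het_co, c(16, -1.1, 0.02), tolerance = 1e-9)

  # constant proportions: vanishing higher-order terms, non-significant trend
  s2 <- tibble::tibble(latitude = lat, p_het = 0.4, p_mix = 0.35,
                       p_phot = 0.25)
  tr2 <- latitude_trend(s2)
  co2 <- tidy(tr2)
  expect_lt(max(abs(co2$estimate[co2$term != "latitude^0"])), 1e-9)
  expect_true(all(glance(tr2)$p.value > 0.5))

  expect_error(latitude_trend(s[1:3, ]), "distinct latitudes")
})

test_that("trend confidence bands achieve nominal coverage on noisy quadratics", {
  lat <- seq(22, 38, length.out = 15)
  truth <- 0.002 * (lat - 30)^2 + 0.3
  eval_lat <- seq(23, 37, length.out = 10)
  truth_eval <- 0.002 * (eval_lat - 30)^2 + 0.3
  hits <- 0; total <- 0
  withr::with_seed(202, for (rep in 1:200) {
    y <- truth + rnorm(length(lat), sd = 0.05)
    s <- tibble::tibble(latitude = lat, p_het = y, p_mix = 0.3,
                        p_phot = 0.4)
    band <- predict(latitude_trend(s), latitude = eval_lat)
    band <- band[band$class == "heterotrophy", ]
    hits <- hits + sum(band$lwr <= truth_eval & truth_eval <= band$upr)
    total <- total + length(eval_lat)
  })
  expect_gt(hits / total, 0.91)
  expect_lt(hits / total, 0.99)
})

test_that("diel aggregation groups by hour across days and by day/night", {
  # 4 days x samples at 06:00 and 18:30
  rec <- tibble::tibble(
    bin_id = "b",
    predicted = factor(rep(c("mixotrophy", "heterotrophy"), 4),
                       trophic_levels()),
    no_signal = FALSE,
    local_time = rep(c(6, 18.5), 4)
  )
  hourly <- diel_aggregate(rec, by = "hour")
  expect_identical(hourly$n[hourly$hour == 6], 4L)
  expect_identical(hourly$n[hourly$hour == 18], 4L)
  period <- diel_aggregate(rec, by = "period")
  expect_identical(period$p_mix[period$period == "day"], 1)
  expect_identical(period$p_het[period$period == "night"], 1)

  # identical labels -> every group (1, 0, 0) in the het slot
  rec2 <- dplyr::mutate(rec, predicted = factor("heterotrophy",
                                                trophic_levels()))
  h2 <- diel_aggregate(rec2, by = "hour")
  expect_true(all(h2$p_het == 1))

  # random labels match the counting oracle
  withr::with_seed(61, {
    labs <- sample(trophic_levels(), 40, replace = TRUE)
    hrs <- sample(c(0, 6, 12, 18), 40, replace = TRUE)
  })
  rr <- tibble::tibble(bin_id = "b",
                       predicted = factor(labs, trophic_levels()),
                       no_signal = FALSE, local_time = hrs)
  hh <- diel_aggregate(rr, by = "hour")
  for (i in seq_len(nrow(hh))) {
    sel <- hrs == hh$hour[i]
    expect_identical(hh$n_mix[i], sum(labs[sel] == "mixotrophy"))
  }

  expect_error(diel_aggregate(dplyr::mutate(rec, local_time = NA)),
               "local_time")
})
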