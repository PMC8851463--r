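#' Species-level environmental transcriptome bin
#'
#' A taxonomic bin couples a species-level identifier with the expression
#' profiles of its environmental transcriptome replicates and per-profile
#' site metadata (station, latitude, local time, size fraction, ...)
#' carried in the profile matrix's `sample_meta`. The `training_related`
#' flag states whether the bin is closely related to a training-set
#' species; it is supplied by the user (the package does no phylogenetics)
#' and unrelated bins are dropped at deployment.
#'
#' @param bin_id Species-level bin identifier.
#' @param profiles A [trophic_matrix], one column per replicate.
#' @param training_related Logical flag.
#' @return A `bin_profile_set` object.
#' @export
bin_profile_set <- function(bin_id, profiles, training_related = TRUE) {
  stopifnot(inherits(profiles, "trophic_matrix"))
  abort_if_not(is.character(bin_id) && length(bin_id) == 1 && nzchar(bin_id),
               "`bin_id` must be a nonempty string")
  structure(list(bin_id = bin_id, profiles = profiles,
                 training_related = isTRUE(training_related)),
            class = "bin_profile_set")
}

#' @export
print.bin_profile_set <- function(x, ...) {
  cat(sprintf("<bin_profile_set> '%s': %d profiles%s\n", x$bin_id,
              ncol(x$profiles$values),
              if (x$training_related) "" else " (not training-related)"))
  invisible(x)
}

#' Completeness, replication, and relatedness filtering of bins
#'
#' Applies the deployment gatekeeping rules: profiles whose nonzero
#' gene-family count falls below the completeness cutoff are dropped
#' (default cutoff 800, compared as `>=` so a profile with exactly 800
#' nonzero families passes); bins not related to the training set are
#' dropped whole; and within each grouping unit (by default the `station`
#' metadata column; `group_vars = NULL` treats the bin as one unit) a bin
#' must keep at least `min_profiles` surviving profiles or those profiles
#' are dropped too. Every dropped profile appears in exactly one exclusion
#' report row.
#'
#' @param bins List of [bin_profile_set]s.
#' @param completeness Minimum nonzero gene-family count per profile.
#' @param min_profiles Minimum surviving profiles per bin and grouping
#'   unit (default 4 replicate transcriptomes).
#' @param group_vars Metadata columns defining the grouping unit.
#' @return List with `bins` (retained, possibly with fewer profiles) and
#'   `report` (tibble: bin_id, sample_id, reason; reason is one of
#'   `"completeness"`, `"replication"`, `"unrelated-to-training"`).
#' @export
filter_bins <- function(bins, completeness = 800, min_profiles = 4,
                        group_vars = "station") {
  report <- tibble::tibble(bin_id = character(), sample_id = character(),
                           reason = character())
  kept <- list()
  for (bin in bins) {
    stopifnot(inherits(bin, "bin_profile_set"))
    ids <- sample_ids(bin$profiles)
    if (!bin$training_related) {
      report <- dplyr::bind_rows(report, tibble::tibble(
        bin_id = bin$bin_id, sample_id = ids,
        reason = "unrelated-to-training"))
      next
    }
    nz <- vapply(ids, function(s) nonzero_feature_count(bin$profiles, s),
                 numeric(1))
    pass <- nz >= completeness
    if (any(!pass)) {
      report <- dplyr::bind_rows(report, tibble::tibble(
        bin_id = bin$bin_id, sample_id = ids[!pass],
        reason = "completeness"))
    }
    meta <- bin$profiles$sample_meta[pass, , drop = FALSE]
    surv <- ids[pass]
    if (length(surv) > 0) {
      if (is.null(group_vars)) {
        unit <- rep("all", length(surv))
      } else {
        missing_gv <- setdiff(group_vars, names(meta))
        abort_if_not(length(missing_gv) == 0,
                     sprintf("grouping column(s) missing from metadata: %s",
                             paste(missing_gv, collapse = ", ")))
        unit <- do.call(paste, c(meta[group_vars], sep = "\r"))
      }
      unit_n <- table(unit)
      ok <- unit_n[unit] >= min_profiles
      if (any(!ok)) {
        report <- dplyr::bind_rows(report, tibble::tibble(
          bin_id = bin$bin_id, sample_id = surv[!ok],
          reason = "replication"))
      }
      surv <- surv[ok]
    }
    if (length(surv) > 0) {
      keep_idx <- match(surv, ids)
      sub <- trophic_matrix(bin$profiles$values[, keep_idx, drop = FALSE],
                            units = bin$profiles$units,
                            sample_meta = bin$profiles$sample_meta[keep_idx, ])
      kept[[length(kept) + 1]] <- bin_profile_set(bin$bin_id, sub,
                                                  bin$training_related)
    }
  }
  list(bins = kept, report = report)
}

#' Predict trophic mode for every profile of every bin
#'
#' Convenience wrapper running [predict.trophic_model()] over a list of
#' bins and binding the per-profile site metadata onto the prediction
#' records, ready for [bin_proportions()].
#'
#' @param model A `trophic_model`.
#' @param bins List of [bin_profile_set]s (typically the output of
#'   [filter_bins()]).
#' @return Prediction tibble with `bin_id` and all site metadata columns.
#' @export
deploy_model <- function(model, bins) {
  purrr::map_dfr(bins, function(bin) {
    preds <- stats::predict(model, bin$profiles)
    dplyr::left_join(
      dplyr::mutate(preds, bin_id = bin$bin_id, .before = 1),
      bin$profiles$sample_meta, by = "sample_id"
    )
  })
}

#' Aggregate predictions into per-bin trophic-mode proportions
#'
#' Sums the per-transcriptome predictions for each taxonomic bin within
#' each grouping unit (site, latitude, day/night, diel hour, ...) into
#' counts and proportions per trophic mode. No-signal records are excluded
#' before counting; proportions over the classified records sum to 1.
#'
#' @param records Prediction tibble (e.g. from [deploy_model()]) with
#'   `bin_id`, `predicted`, `no_signal`, and the grouping columns.
#' @param group_vars Character vector of grouping columns besides
#'   `bin_id` (may be empty).
#' @return Summary tibble: grouping columns, counts `n_het`, `n_mix`,
#'   `n_phot`, `n` classified, proportions `p_het`, `p_mix`, `p_phot`,
#'   and `excluded`/`exclusion_reason` placeholders (see
#'   [conflict_exclusion()]).
#' @export
bin_proportions <- function(records, group_vars = character()) {
  needed <- c("bin_id", "predicted", group_vars)
  missing_cols <- setdiff(needed, names(records))
  abort_if_not(length(missing_cols) == 0,
               sprintf("record column(s) missing: %s",
                       paste(missing_cols, collapse = ", ")))
  if ("no_signal" %in% names(records)) {
    records <- dplyr::filter(records, !.data$no_signal)
  }
  records <- dplyr::filter(records, !is.na(.data$predicted))
  out <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("bin_id", group_vars)))) |>
    dplyr::summarise(
      n_het = sum(.data$predicted == "heterotrophy"),
      n_mix = sum(.data$predicted == "mixotrophy"),
      n_phot = sum(.data$predicted == "phototrophy"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n = .data$n_het + .data$n_mix + .data$n_phot,
      p_het = .data$n_het / .data$n,
      p_mix = .data$n_mix / .data$n,
      p_phot = .data$n_phot / .data$n,
      excluded = FALSE,
      exclusion_reason = NA_character_
    )
  out
}

#' Exclude bins with conflicting phototrophy/heterotrophy predictions
#'
#' A bin summary whose classified profiles split into substantial
#' phototrophy *and* heterotrophy fractions while essentially lacking
#' mixotrophic predictions sits on the model's decision boundary and is
#' flagged for exclusion: `excluded` is set when the phototrophy
#' proportion and the heterotrophy proportion are each strictly greater
#' than `threshold` (default 0.25) and the mixotrophy proportion is at
#' most `mix_floor`. The floor defaults to 0.05; a strict reading of
#' "lacking mixotrophic predictions" is available with `mix_floor = 0`.
#'
#' @param summaries Summary tibble from [bin_proportions()].
#' @param threshold Conflict threshold in (0, 1), strict `>` at the
#'   boundary.
#' @param mix_floor Maximum tolerated mixotrophy proportion.
#' @return The summaries with `excluded`/`exclusion_reason` set
#'   (`"phot/het conflict"`) or cleared.
#' @export
conflict_exclusion <- function(summaries, threshold = 0.25,
                               mix_floor = 0.05) {
  abort_if_not(is.numeric(threshold) && threshold > 0 && threshold < 1,
               "`threshold` must lie in (0, 1)")
  abort_if_not(is.numeric(mix_floor) && mix_floor >= 0 && mix_floor < 1,
               "`mix_floor` must lie in [0, 1)")
  dplyr::mutate(
    summaries,
    excluded = .data$p_phot > threshold & .data$p_het > threshold &
      .data$p_mix <= mix_floor,
    exclusion_reason = dplyr::if_else(.data$excluded, "phot/het conflict",
                                      NA_character_)
  )
}

#' Polynomial latitude trend of trophic-mode proportions
#'
#' Fits, for each trophic mode, a least-squares polynomial (default second
#' order) of prediction proportion against station latitude, with a
#' pointwise 95% confidence band and an overall trend p-value from the
#' F-test of the polynomial model against the intercept-only model.
#'
#' @param summaries Summary tibble with a `latitude` column and the
#'   proportion columns `p_het`, `p_mix`, `p_phot` (excluded rows are
#'   dropped first).
#' @param degree Polynomial degree (default 2); at least `degree + 2`
#'   distinct latitudes are required.
#' @param conf_level Confidence level of the band.
#' @return A `trophic_trend` object with per-class `lm` fits; methods:
#'   [generics::tidy()] (coefficients), [generics::glance()] (per-class
#'   F-test p, R^2), `predict()` (fit + CI band on a latitude grid),
#'   [ggplot2::autoplot()].
#' @export
latitude_trend <- function(summaries, degree = 2, conf_level = 0.95) {
  abort_if_not("latitude" %in% names(summaries),
               "`summaries` must have a latitude column")
  if ("excluded" %in% names(summaries)) {
    summaries <- dplyr::filter(summaries, !.data$excluded)
  }
  lat <- summaries$latitude
  abort_if_not(length(unique(lat)) >= degree + 2,
               sprintf("need at least %d distinct latitudes for degree %d",
                       degree + 2, degree))
  fits <- purrr::map(
    stats::setNames(c("p_het", "p_mix", "p_phot"), trophic_levels()),
    function(col) {
      df <- data.frame(latitude = lat, p = summaries[[col]])
      stats::lm(p ~ poly(latitude, degree, raw = TRUE), data = df)
    }
  )
  structure(list(fits = fits, degree = degree, conf_level = conf_level,
                 latitude_range = range(lat)),
            class = "trophic_trend")
}

#' @export
print.trophic_trend <- function(x, ...) {
  cat(sprintf("<trophic_trend> degree-%d fits over latitude [%.2f, %.2f]\n",
              x$degree, x$latitude_range[1], x$latitude_range[2]))
  print(glance(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.trophic_trend <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, cls) {
    tibble::tibble(class = cls, term = paste0("latitude^", 0:x$degree),
                   estimate = unname(stats::coef(fit)))
  })
}

#' @exportS3Method generics::glance
glance.trophic_trend <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(fit, cls) {
    y <- fit$model$p
    rss1 <- sum(stats::residuals(fit)^2)
    rss0 <- sum((y - mean(y))^2)
    # degenerate fits: no improvement over the intercept (possibly both
    # residual sums ~ 0, e.g. exactly constant proportions) -> F = 0, p = 1;
    # an exact polynomial fit of varying data -> p = 0
    if (rss0 - rss1 <= 1e-12 * max(rss0, 1e-12)) {
      fstat <- 0; pval <- 1
    } else if (rss1 <= 1e-12 * rss0) {
      fstat <- Inf; pval <- 0
    } else {
      an <- stats::anova(stats::lm(y ~ 1), fit)
      fstat <- an$F[2]; pval <- an$`Pr(>F)`[2]
    }
    tibble::tibble(class = cls,
                   r.squared = if (rss0 > 0) 1 - rss1 / rss0 else 0,
                   f.statistic = fstat,
                   p.value = pval)
  })
}

#' @export
predict.trophic_trend <- function(object, latitude = NULL, ...) {
  if (is.null(latitude)) {
    latitude <- seq(object$latitude_range[1], object$latitude_range[2],
                    length.out = 100)
  }
  purrr::imap_dfr(object$fits, function(fit, cls) {
    pr <- stats::predict(fit, newdata = data.frame(latitude = latitude),
                         interval = "confidence",
                         level = object$conf_level)
    tibble::tibble(class = cls, latitude = latitude,
                   fit = pr[, "fit"], lwr = pr[, "lwr"], upr = pr[, "upr"])
  })
}

#' Diel aggregation of trophic-mode predictions
#'
#' Groups prediction records by hour of day across days (e.g. samples
#' taken every 4 h over 4 days give n = 4 per hour group) or by a
#' day/night split at configurable sunrise/sunset hours, and returns
#' trophic-mode proportions per group.
#'
#' @param records Prediction tibble with a numeric `local_time` column
#'   (hour of day, 0-24) plus `bin_id`, `predicted`, `no_signal`.
#' @param by `"hour"` or `"period"` (day/night).
#' @param day_start,day_end Daytime window for the day/night split
#'   (default 06:00-18:00 local).
#' @param per_bin Aggregate per bin (default) or community-wide.
#' @return Summary tibble as in [bin_proportions()] with an `hour` or
#'   `period` column; `n` counts the classified records per group.
#' @export
diel_aggregate <- function(records, by = c("hour", "period"),
                           day_start = 6, day_end = 18, per_bin = TRUE) {
  by <- match.arg(by)
  abort_if_not("local_time" %in% names(records),
               "`records` must have a local_time column")
  abort_if_not(!anyNA(records$local_time),
               "missing local_time value(s) in records")
  records <- dplyr::mutate(
    records,
    hour = floor(as.numeric(.data$local_time)) %% 24,
    period = dplyr::if_else(.data$hour >= day_start & .data$hour < day_end,
                            "day", "night")
  )
  if (!per_bin) records$bin_id <- "community"
  bin_proportions(records, group_vars = by)
}
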