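#' Ordered condition-based labeling rules
#'
#' A label rule maps growth-condition metadata to a trophic mode. Rules are
#' ordered and the first matching rule wins; a sample matching no rule stays
#' unlabeled. A rule matches when every field named in `when` is present,
#' non-missing, and equal to the stated value in the sample's metadata row.
#'
#' @param when Named list of metadata field/value requirements.
#' @param label The trophic mode the rule assigns.
#' @return A `label_rule` object.
#' @export
label_rule <- function(when, label) {
  abort_if_not(is.list(when) && length(when) > 0 && !is.null(names(when)),
               "`when` must be a named list of field requirements")
  label <- as.character(as_trophic_label(label))
  structure(list(when = when, label = label), class = "label_rule")
}

#' Default labeling rules for culture transcriptomes
#'
#' Reproduces the condition-based rules used to label culture transcriptomes:
#' a known mixotroph grown in the light with bacteria present is labeled
#' mixotrophic; the same organism grown in the light without bacteria is
#' labeled phototrophic; otherwise a curated literature label
#' (`literature_label` column) is passed through. Users can extend or
#' replace the rule table ([read_label_rules()]) without code changes.
#'
#' @return Ordered list of [label_rule()]s.
#' @export
default_label_rules <- function() {
  list(
    label_rule(list(known_mixotroph = TRUE, light = TRUE,
                    bacteria_present = TRUE), "mixotrophy"),
    label_rule(list(known_mixotroph = TRUE, light = TRUE,
                    bacteria_present = FALSE), "phototrophy"),
    label_rule(list(literature_label = "heterotrophy"), "heterotrophy"),
    label_rule(list(literature_label = "mixotrophy"), "mixotrophy"),
    label_rule(list(literature_label = "phototrophy"), "phototrophy")
  )
}

#' Read labeling rules from a YAML file
#'
#' The file is a YAML list of `{when: {field: value, ...}, label: mode}`
#' entries, in priority order.
#'
#' @param path Path to the YAML rule table.
#' @return Ordered list of [label_rule()]s.
#' @export
read_label_rules <- function(path) {
  abort_if_not(file.exists(path), sprintf("file not found: %s", path))
  raw <- yaml::read_yaml(path)
  purrr::map(raw, function(r) label_rule(r$when, r$label))
}

rule_matches <- function(rule, row) {
  for (field in names(rule$when)) {
    if (!field %in% names(row)) return(FALSE)
    v <- row[[field]]
    if (is.null(v) || length(v) != 1 || is.na(v)) return(FALSE)
    if (!identical(unname(v == rule$when[[field]]), TRUE)) return(FALSE)
  }
  TRUE
}

#' Labeled training set
#'
#' Couples an expression matrix with one trophic-mode label per sample.
#' `"unlabeled"` is never allowed here.
#'
#' @param matrix A [trophic_matrix].
#' @param labels Character or factor vector of trophic modes, one per
#'   sample of `matrix` (recycled names are matched by sample id when
#'   named).
#' @return An object of class `trophic_training_set` with fields `matrix`,
#'   `labels` (factor over [trophic_levels()] named by sample id) and
#'   `class_counts`.
#' @export
training_set <- function(matrix, labels) {
  stopifnot(inherits(matrix, "trophic_matrix"))
  ids <- sample_ids(matrix)
  if (!is.null(names(labels))) {
    missing <- setdiff(ids, names(labels))
    abort_if_not(length(missing) == 0,
                 sprintf("no label for sample(s): %s",
                         paste(missing, collapse = ", ")))
    labels <- labels[ids]
  } else {
    abort_if_not(length(labels) == ncol(matrix$values),
                 "`labels` must have one entry per sample")
  }
  labels <- as_trophic_label(labels)
  abort_if_not(!anyNA(labels), "labels must not contain NA/unlabeled")
  names(labels) <- ids
  structure(
    list(matrix = matrix, labels = labels,
         class_counts = table(labels)),
    class = "trophic_training_set"
  )
}

#' @export
print.trophic_training_set <- function(x, ...) {
  cat(sprintf("<trophic_training_set> %d features x %d samples\n",
              nrow(x$matrix$values), ncol(x$matrix$values)))
  print(x$class_counts)
  invisible(x)
}

#' Assign trophic-mode labels from growth-condition metadata
#'
#' Applies an ordered rule table to each sample's metadata row
#' (first-matching-rule-wins). Samples matching no rule are reported as
#' unlabeled with reason `"insufficient metadata"`. When several matching
#' rules disagree, the first rule still wins but a warning is emitted;
#' under `strict = TRUE` such samples are instead reported unlabeled with
#' reason `"conflicting rules"` (mirroring the exclusion of conflicting
#' literature-based classifications). Labeling is per transcriptome, so one
#' species may carry different labels under different growth conditions.
#'
#' @param matrix A [trophic_matrix] of culture transcriptomes.
#' @param meta Metadata tibble with a `sample_id` column and whatever
#'   fields the rules reference; every sample of `matrix` must have a row.
#' @param rules Ordered list of [label_rule()]s
#'   (default [default_label_rules()]).
#' @param strict Turn rule conflicts into unlabeled samples.
#' @return List with `training` (a [training_set] over the labeled
#'   subset, or `NULL` if nothing was labeled), `unlabeled` (tibble:
#'   sample_id, reason) and `trace` (tibble: sample_id, label, rule_index
#'   — the audit trail of which rule fired).
#' @export
assign_labels <- function(matrix, meta, rules = default_label_rules(),
                          strict = FALSE) {
  stopifnot(inherits(matrix, "trophic_matrix"))
  meta <- tibble::as_tibble(meta)
  abort_if_not("sample_id" %in% names(meta),
               "`meta` must have a sample_id column")
  ids <- sample_ids(matrix)
  missing <- setdiff(ids, meta$sample_id)
  abort_if_not(length(missing) == 0,
               sprintf("sample(s) missing from metadata: %s",
                       paste(missing, collapse = ", ")))
  meta <- meta[match(ids, meta$sample_id), ]

  res <- purrr::map(seq_along(ids), function(i) {
    row <- as.list(meta[i, ])
    hits <- which(vapply(rules, rule_matches, logical(1), row = row))
    if (length(hits) == 0) {
      return(list(label = NA_character_, rule = NA_integer_,
                  reason = "insufficient metadata"))
    }
    labs <- unique(vapply(rules[hits], `[[`, character(1), "label"))
    if (length(labs) > 1) {
      if (strict) {
        return(list(label = NA_character_, rule = NA_integer_,
                    reason = "conflicting rules"))
      }
      rlang::warn(sprintf(
        "sample '%s': rules %s disagree (%s); first rule wins",
        ids[i], paste(hits, collapse = ","), paste(labs, collapse = " vs ")
      ))
    }
    list(label = rules[[hits[1]]]$label, rule = hits[1], reason = NA_character_)
  })

  label <- vapply(res, `[[`, character(1), "label")
  rule_index <- vapply(res, `[[`, integer(1), "rule")
  reason <- vapply(res, `[[`, character(1), "reason")
  labeled <- !is.na(label)

  trace <- tibble::tibble(sample_id = ids[labeled], label = label[labeled],
                          rule_index = rule_index[labeled])
  unlabeled <- tibble::tibble(sample_id = ids[!labeled],
                              reason = reason[!labeled])
  training <- NULL
  if (any(labeled)) {
    sub <- trophic_matrix(
      matrix$values[, labeled, drop = FALSE], units = matrix$units,
      sample_meta = matrix$sample_meta[labeled, ]
    )
    training <- training_set(sub, stats::setNames(label[labeled], ids[labeled]))
  }
  list(training = training, unlabeled = unlabeled, trace = trace)
}

#' Under-sample one class of a labeled training set
#'
#' Retains exactly `n` samples of the target class, chosen uniformly
#' without replacement under a seed, and all samples of the other classes.
#' Used to balance the dominant phototroph class before feature selection
#' (at paper scale, n = 80, 100, 120 and 140 against 275 phototrophic,
#' 93 mixotrophic and 78 heterotrophic transcriptomes).
#'
#' @param ts A [training_set].
#' @param target_class Trophic mode to down-sample.
#' @param n Number of target-class samples to keep (`n <=` class count).
#' @param seed Integer seed; the same seed always yields the same subset.
#' @return A [training_set]; feature values are untouched, only sample
#'   membership changes, and column order is preserved.
#' @export
undersample <- function(ts, target_class, n, seed) {
  stopifnot(inherits(ts, "trophic_training_set"))
  target_class <- as.character(as_trophic_label(target_class))
  in_class <- which(as.character(ts$labels) == target_class)
  if (n > length(in_class)) {
    rlang::abort(sprintf(
      "n = %d exceeds the %s class count (%d)", n, target_class,
      length(in_class)
    ))
  }
  keep_class <- withr::with_seed(seed, sort(sample(in_class, n)))
  keep <- sort(c(keep_class, which(as.character(ts$labels) != target_class)))
  sub <- trophic_matrix(ts$matrix$values[, keep, drop = FALSE],
                        units = ts$matrix$units,
                        sample_meta = ts$matrix$sample_meta[keep, ])
  training_set(sub, ts$labels[keep])
}
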