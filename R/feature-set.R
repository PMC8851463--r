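#' Named set of gene families with provenance
#'
#' A feature set is an ordered collection of unique gene-family identifiers
#' together with provenance describing how it was produced (learner,
#' under-sample sizes, seeds, baseline and per-feature permuted accuracies
#' for sets produced by [mda_select()]; empty for user-supplied sets).
#'
#' @param members Character vector of gene-family identifiers (duplicates
#'   are dropped, first occurrence wins). May be empty: an empty set is a
#'   valid *result* (e.g. the common set of disjoint selections), though
#'   operations reject empty *inputs*.
#' @param name Short name for the set.
#' @param provenance Named list of provenance fields.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(members, name = "feature_set", provenance = list()) {
  members <- as.character(members)
  members <- members[!duplicated(members)]
  structure(list(name = name, members = members, provenance = provenance),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat(sprintf("<feature_set> '%s': %d gene families\n", x$name,
              length(x$members)))
  if (length(x$provenance) > 0) {
    cat("provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.feature_set <- function(x) length(x$members)

#' Combine two feature sets into the common or combined set
#'
#' The common set is the intersection of the two member lists and the
#' combined set their union, mirroring the overlap/combination of the
#' families retained by the bagged-forest and gradient-boosted selection
#' runs. Sizes obey inclusion-exclusion:
#' `|combined| = |a| + |b| - |common|`.
#'
#' @param a,b Nonempty [feature_set]s.
#' @param mode `"common"` (intersection) or `"combined"` (union).
#' @return A [feature_set]; member order follows `a` then new members of
#'   `b`; provenance of both inputs is concatenated.
#' @export
combine_feature_sets <- function(a, b, mode = c("common", "combined")) {
  mode <- match.arg(mode)
  stopifnot(inherits(a, "feature_set"), inherits(b, "feature_set"))
  abort_if_not(length(a$members) > 0 && length(b$members) > 0,
               "both feature sets must be nonempty")
  members <- switch(mode,
    common = a$members[a$members %in% b$members],
    combined = c(a$members, setdiff(b$members, a$members))
  )
  feature_set(
    members,
    name = sprintf("%s(%s,%s)", mode, a$name, b$name),
    provenance = list(mode = mode, inputs = list(a$provenance, b$provenance),
                      input_sizes = c(length(a$members), length(b$members)))
  )
}

#' Read or write a feature-set file
#'
#' Plain-text format: one gene-family identifier per line; lines starting
#' with `#` are provenance headers of the form `# key: value` and are
#' restored into the provenance list on read.
#'
#' @param path File path.
#' @param fs A [feature_set] (for writing).
#' @param name Name for the set read from file (defaults to the file name).
#' @return [read_feature_set()] returns a [feature_set];
#'   [write_feature_set()] returns `path` invisibly.
#' @export
read_feature_set <- function(path, name = basename(path)) {
  abort_if_not(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path)
  prov_lines <- grep("^#", lines, value = TRUE)
  members <- trimws(grep("^#", lines, value = TRUE, invert = TRUE))
  members <- members[nzchar(members)]
  prov <- list()
  for (ln in prov_lines) {
    kv <- sub("^#\\s*", "", ln)
    sep <- regexpr(":", kv, fixed = TRUE)
    if (sep > 0) {
      prov[[trimws(substr(kv, 1, sep - 1))]] <- trimws(substring(kv, sep + 1))
    }
  }
  feature_set(members, name = name, provenance = prov)
}

#' @rdname read_feature_set
#' @export
write_feature_set <- function(fs, path) {
  stopifnot(inherits(fs, "feature_set"))
  scalar <- Filter(function(v) is.atomic(v) && length(v) >= 1, fs$provenance)
  header <- c(
    sprintf("# name: %s", fs$name),
    vapply(names(scalar), function(k) {
      sprintf("# %s: %s", k, paste(format(scalar[[k]]), collapse = ","))
    }, character(1))
  )
  writeLines(c(header, fs$members), path)
  invisible(path)
}
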