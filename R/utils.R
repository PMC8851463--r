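#' Trophic mode vocabulary
#'
#' The closed label vocabulary used throughout the package, in the fixed
#' order used to break prediction-score ties deterministically
#' (heterotrophy < mixotrophy < phototrophy).
#'
#' @return Character vector of the three trophic modes.
#' @export
trophic_levels <- function() {
  c("heterotrophy", "mixotrophy", "phototrophy")
}

# Coerce a label vector to the closed factor vocabulary, optionally allowing
# "unlabeled" (metadata only, never in a training set).
as_trophic_label <- function(x, allow_unlabeled = FALSE) {
  levels <- trophic_levels()
  if (allow_unlabeled) levels <- c(levels, "unlabeled")
  bad <- setdiff(unique(as.character(x)), c(levels, NA_character_))
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "unknown trophic label(s): %s (allowed: %s)",
      paste(bad, collapse = ", "), paste(levels, collapse = ", ")
    ))
  }
  factor(as.character(x), levels = levels)
}

# Deterministic per-feature permutation seed: XOR of the user stream seed with
# the 1-based feature index, kept in 32-bit integer range.
mix_seed <- function(seed, j) {
  bitwXor(as.integer(seed), as.integer(j)) %% .Machine$integer.max
}

abort_if_not <- function(cond, msg, class = "trophomode_error") {
  if (!isTRUE(cond)) rlang::abort(msg, class = class)
}

`%||%` <- rlang::`%||%`

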