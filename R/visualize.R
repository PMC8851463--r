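#' t-SNE embedding of labeled transcriptomes over a feature set
#'
#' Reduces the training matrix to a feature set, log10-transforms
#' (pseudocount 1), standardizes each feature (zero mean, unit variance;
#' configurable), and embeds the samples in two dimensions with t-SNE. A
#' high perplexity (default 100) emphasizes global relationships between
#' transcriptomes; when the sample count does not support the requested
#' perplexity (n must exceed 3 * perplexity) it is reduced with a warning.
#' The embedding is deterministic under `seed`; only neighborhood
#' structure, not coordinate scale, is meaningful.
#'
#' @param ts A [training_set] with at least 5 samples.
#' @param fs A [feature_set].
#' @param perplexity t-SNE perplexity (default 100).
#' @param seed Integer seed.
#' @param scaling `"standardize"` (default), `"minmax"`, or `"none"`.
#' @return A `trophic_embedding`: `coords` tibble (sample_id, x, y,
#'   label) and the parameters used. Has an [ggplot2::autoplot()] method
#'   drawing points with per-mode density contours.
#' @export
tsne_embed <- function(ts, fs, perplexity = 100, seed = 1L,
                       scaling = c("standardize", "minmax", "none")) {
  stopifnot(inherits(ts, "trophic_training_set"))
  scaling <- match.arg(scaling)
  n <- ncol(ts$matrix$values)
  abort_if_not(n >= 5, "need at least 5 samples to embed")
  max_perp <- floor((n - 1) / 3)
  if (perplexity > max_perp) {
    rlang::warn(sprintf(
      "perplexity %g too large for %d samples; reduced to %d",
      perplexity, n, max_perp
    ))
    perplexity <- max_perp
  }
  red <- log_transform(subset_features(ts$matrix, fs))
  x <- t(red$values)
  x <- switch(scaling,
    standardize = {
      s <- apply(x, 2, stats::sd)
      scale(x, center = TRUE, scale = ifelse(s > 0, s, 1))
    },
    minmax = apply(x, 2, function(v) {
      r <- diff(range(v))
      if (r > 0) (v - min(v)) / r else v * 0
    }),
    none = x
  )
  emb <- withr::with_seed(seed, Rtsne::Rtsne(
    x, dims = 2, perplexity = perplexity, pca = FALSE,
    check_duplicates = FALSE, num_threads = 1
  ))
  structure(
    list(
      coords = tibble::tibble(
        sample_id = sample_ids(ts$matrix),
        x = emb$Y[, 1], y = emb$Y[, 2],
        label = ts$labels
      ),
      parameters = list(perplexity = perplexity, seed = seed,
                        scaling = scaling, n_features = length(fs))
    ),
    class = "trophic_embedding"
  )
}

#' @export
print.trophic_embedding <- function(x, ...) {
  cat(sprintf("<trophic_embedding> %d samples (perplexity %g, seed %d)\n",
              nrow(x$coords), x$parameters$perplexity, x$parameters$seed))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.trophic_embedding <- function(object, ...) {
  ggplot2::ggplot(object$coords,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$label)) +
    ggplot2::geom_density_2d(alpha = 0.6) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "t-SNE 1", y = "t-SNE 2", colour = "trophic mode") +
    ggplot2::theme_minimal()
}

#' Hierarchically clustered median expression by trophic mode
#'
#' For each selected gene family, computes the median TPM per trophic mode
#' across the training set, removes families whose median is zero in every
#' mode, log10-transforms (pseudocount 1), and orders the rows by
#' agglomerative hierarchical clustering (default: average linkage on
#' correlation distance; families with no variance across the three modes
#' are assigned the maximum distance to everything except themselves).
#'
#' @param ts A [training_set] in which all three trophic modes occur.
#' @param fs A [feature_set].
#' @param linkage Agglomeration method for [stats::hclust()].
#' @param metric `"correlation"` or `"euclidean"` row distance.
#' @return A `trophic_heatmap`: `matrix` (features x modes, log10 median
#'   TPM, rows in cluster order), `hclust` (the linkage tree), `dropped`
#'   (families removed by the zero-median rule). Has an
#'   [ggplot2::autoplot()] method.
#' @export
median_cluster_heatmap <- function(ts, fs, linkage = "average",
                                   metric = c("correlation", "euclidean")) {
  stopifnot(inherits(ts, "trophic_training_set"))
  metric <- match.arg(metric)
  present <- unique(as.character(ts$labels))
  missing_cls <- setdiff(trophic_levels(), present)
  abort_if_not(length(missing_cls) == 0,
               sprintf("trophic mode(s) absent from training set: %s",
                       paste(missing_cls, collapse = ", ")))
  red <- subset_features(ts$matrix, fs)
  med <- vapply(trophic_levels(), function(cls) {
    apply(red$values[, as.character(ts$labels) == cls, drop = FALSE], 1,
          stats::median)
  }, numeric(nrow(red$values)))
  keep <- rowSums(med > 0) > 0
  dropped <- rownames(med)[!keep]
  med <- med[keep, , drop = FALSE]
  abort_if_not(nrow(med) >= 2,
               "fewer than 2 gene families with nonzero median expression")
  logmed <- log10(med + 1)
  d <- if (metric == "correlation") {
    cc <- suppressWarnings(stats::cor(t(logmed)))
    cc[!is.finite(cc)] <- -1  # zero-variance rows: maximally distant
    diag(cc) <- 1
    stats::as.dist(1 - cc)
  } else {
    stats::dist(logmed)
  }
  hc <- stats::hclust(d, method = linkage)
  structure(
    list(matrix = logmed[hc$order, , drop = FALSE], hclust = hc,
         dropped = dropped, linkage = linkage, metric = metric),
    class = "trophic_heatmap"
  )
}

#' @export
print.trophic_heatmap <- function(x, ...) {
  cat(sprintf(
    "<trophic_heatmap> %d gene families x %d modes (%s linkage, %s distance; %d zero-median families removed)\n",
    nrow(x$matrix), ncol(x$matrix), x$linkage, x$metric, length(x$dropped)
  ))
  invisible(x)
}

#' @exportS3Method ggplot2::autoplot
autoplot.trophic_heatmap <- function(object, ...) {
  df <- tibble::as_tibble(object$matrix, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "mode",
                        values_to = "log10_median_tpm") |>
    dplyr::mutate(feature_id = factor(.data$feature_id,
                                      levels = rownames(object$matrix)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mode, y = .data$feature_id,
                                   fill = .data$log10_median_tpm)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log10(median TPM + 1)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "gene family (cluster order)")
}

#' Write embedding coordinates or heatmap matrices to disk
#'
#' Coordinates go to a TSV (sample_id, x, y, label); the heatmap matrix to
#' a TSV and its linkage tree to JSON (nested-list dialect of the merge
#' structure).
#'
#' @param x A `trophic_embedding` or `trophic_heatmap`.
#' @param path Output TSV path (for heatmaps the linkage JSON is written
#'   alongside with extension `.linkage.json`).
#' @return `path`, invisibly.
#' @export
write_view <- function(x, path) {
  if (inherits(x, "trophic_embedding")) {
    readr::write_tsv(x$coords, path)
  } else if (inherits(x, "trophic_heatmap")) {
    readr::write_tsv(tibble::as_tibble(x$matrix, rownames = "feature_id"),
                     path)
    jsonlite::write_json(
      list(merge = x$hclust$merge, height = x$hclust$height,
           order = x$hclust$order, labels = x$hclust$labels),
      sub("\\.tsv$", ".linkage.json", path), digits = NA
    )
  } else {
    rlang::abort("`x` must be a trophic_embedding or trophic_heatmap")
  }
  invisible(path)
}
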