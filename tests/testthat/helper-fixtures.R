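# Small in-code fixtures shared across test files.

# A tiny expression matrix with known values.
tiny_matrix <- function(units = "raw") {
  vals <- matrix(
    c(0, 10, 90,
      5,  0,  5,
      1,  2,  3),
    nrow = 3, byrow = TRUE,
    dimnames = list(c("PF00001", "PF00002", "PF00003"),
                    c("s1", "s2", "s3"))
  )
  trophic_matrix(vals, units = units)
}

# A separable training set: one block per class strongly elevated, a given
# number of pure-noise features. Returns the training set and the truth
# feature blocks.
planted_training <- function(n_per_class = 10, n_noise = 4, effect = 3,
                             seed = 1) {
  spec <- synthetic_spec(
    n_features = 3 * 4 + n_noise,
    block_sizes = c(het_mix = 4, phot_mix = 4, mix_specific = 4),
    class_counts = c(phototrophy = n_per_class, mixotrophy = n_per_class,
                     heterotrophy = n_per_class),
    effect = effect, dropout = 0, dispersion = 0.2, seed = seed
  )
  generate_training(spec)
}

# A one-feature matrix that exactly encodes the class label.
label_encoding_training <- function(n_per_class = 10, n_noise = 3,
                                    seed = 5) {
  labels <- rep(trophic_levels(), each = n_per_class)
  n <- length(labels)
  vals <- withr::with_seed(seed, rbind(
    encode = as.integer(factor(labels, trophic_levels())) * 100,
    matrix(runif(n_noise * n), n_noise, n,
           dimnames = list(paste0("noise", seq_len(n_noise)), NULL))
  ))
  colnames(vals) <- sprintf("s%03d", seq_len(n))
  ts <- training_set(trophic_matrix(vals, units = "raw"),
                     stats::setNames(labels, colnames(vals)))
  ts
}

# Cached heavy objects (computed at most once per test run).
.cache <- new.env(parent = emptyenv())

cache_get <- function(key, compute) {
  if (!exists(key, envir = .cache)) {
    assign(key, compute(), envir = .cache)
  }
  get(key, envir = .cache)
}

default_generation <- function() {
  cache_get("default_generation", function() {
    generate_training(synthetic_spec())
  })
}

# Full-scale permutation selection on the default synthetic spec, shared by
# the feature-selection power, classifier-calibration, and end-to-end
# recovery checks. The small 32-tree forest is the documented setting for
# the permutation loop (see the methods vignette on selection sensitivity).
default_mda <- function() {
  cache_get("default_mda", function() {
    gen <- default_generation()
    mda_select(gen$training, classifier_spec("rf", num_trees = 32, seed = 7),
               k = 5, perm_seed = 101, fold_seed = 11)
  })
}
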