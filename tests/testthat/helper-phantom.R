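# Shared phantom fixtures, memoised for the whole test run. Heavy cohorts are
# computed once (first use) and reused across test files.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# reduced-size phantom for fast structural checks; not the study conditions
small_phantom_config <- function(...) {
  phantom_config(n_slices = 6L, slice_shape = c(64L, 64L),
                 correlation_length_px = 4, ...)
}

# feature table under the study's default phantom conditions
phantom_table <- function(n_per_class, seed = 1L) {
  memo(paste0("table_default_", n_per_class, "_", seed),
       build_feature_table(phantom_config(), n_per_class, seed = seed))
}

# feature table under the reduced phantom, for pipeline-shape tests
small_phantom_table <- function(n_per_class, seed = 1L) {
  memo(paste0("table_small_", n_per_class, "_", seed),
       build_feature_table(small_phantom_config(), n_per_class, seed = seed))
}

# synthetic (non-image) feature table: 4 classes, Gaussian class means;
# cheap stand-in for classifier/selection mechanics
synthetic_feature_table <- function(n_per_class, n_features = 3,
                                    effect = 2, sd = 1, seed = 7L) {
  set.seed(seed)
  classes <- rep(c("a", "b", "c", "d"), each = n_per_class)
  X <- sapply(seq_len(n_features), function(j)
    as.integer(factor(classes)) * effect / j + rnorm(length(classes), sd = sd))
  colnames(X) <- paste0("f", seq_len(n_features))
  cbind(data.frame(exam_id = seq_along(classes),
                   density = factor(classes, levels = c("a", "b", "c", "d"))),
        as.data.frame(X))
}
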