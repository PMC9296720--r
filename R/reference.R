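#' Reference worked-example tables from the original density study
#'
#' The package ships the summary tables printed by the published
#' photon-counting breast-CT density study it replicates (its raw images are
#' not publicly deposited): the test-set confusion matrix of its multinomial
#' density classifier, the two reader-study confusion matrices (each expert
#' reader versus the radiology resident, 60 examinations), the worst
#' Bonferroni-adjusted pairwise ANOVA p-value per feature, and the Spearman
#' correlations of the candidate features with density. These serve as inputs
#' for worked-example arithmetic — recomputing recalls, agreements, kappas and
#' the feature-selection replay — not as fitted outputs of this package.
#'
#' Values printed as "< 0.001" are encoded as 0.0005 (any value below the 0.05
#' cut gives the same decision). The inter-feature correlation table contains
#' the numerically stated pairs (GLN-RLN 0.8, GLN-skewness 0.51) plus
#' qualitative statements encoded as moderate/high magnitudes; its `basis`
#' column distinguishes `stated` from `encoded_*` entries.
#'
#' @param which one of `"test_confusion"`, `"reader1"`, `"reader2"`,
#'   `"anova_p"`, `"density_spearman"`, `"feature_spearman"`.
#' @return `reference_confusion()` returns an integer matrix with class
#'   labels; the other accessors return data frames;
#'   `reference_feature_cor_matrix()` assembles the full symmetric candidate
#'   correlation matrix (unstated pairs 0, diagonal 1).
#' @name reference_tables
NULL

reference_path <- function(file) {
  system.file("extdata", file, package = "bcttexture", mustWork = TRUE)
}

#' @rdname reference_tables
#' @export
reference_confusion <- function(which = c("test_confusion", "reader1",
                                          "reader2")) {
  which <- match.arg(which)
  f <- switch(which,
              test_confusion = "reference_test_confusion.csv",
              reader1 = "reference_reader1_confusion.csv",
              reader2 = "reference_reader2_confusion.csv")
  tb <- utils::read.csv(reference_path(f), check.names = FALSE)
  m <- as.matrix(tb[, -1])
  storage.mode(m) <- "integer"
  rownames(m) <- tb[[1]]
  as_confusion(m)
}

#' @rdname reference_tables
#' @export
reference_anova_pvalues <- function() {
  utils::read.csv(reference_path("reference_anova_adjusted_p.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_density_spearman <- function() {
  utils::read.csv(reference_path("reference_density_spearman.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @export
reference_feature_spearman <- function() {
  utils::read.csv(reference_path("reference_feature_spearman.csv"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_tables
#' @param candidates feature names spanning the matrix (default: the
#'   features listed in the density-correlation table).
#' @export
reference_feature_cor_matrix <- function(candidates =
                                           reference_density_spearman()$feature) {
  m <- diag(length(candidates))
  dimnames(m) <- list(candidates, candidates)
  pairs <- reference_feature_spearman()
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$feature_a[i]; b <- pairs$feature_b[i]
    if (a %in% candidates && b %in% candidates)
      m[a, b] <- m[b, a] <- pairs$rho[i]
  }
  m
}

#' Replay the feature-selection cascade on the reference summary tables
#'
#' Applies [select_features()] to the published per-feature worst adjusted
#' ANOVA p-values, density Spearman correlations, and the stated inter-feature
#' correlations. With the published inputs this retains exactly
#' `{GLN, skewness}` out of 11 Step-1 candidates.
#'
#' @inheritParams select_features
#' @return a [select_features()] result.
#' @export
replay_reference_selection <- function(rho_threshold = 0.50,
                                       p_threshold = 0.05,
                                       redundancy_threshold = 0.80) {
  anv <- reference_anova_pvalues()
  anova_pass <- stats::setNames(anv$max_p_adjusted < 0.05, anv$feature)
  sp <- reference_density_spearman()
  rho <- stats::setNames(sp$rho, sp$feature)
  p <- stats::setNames(sp$p, sp$feature)
  select_features(anova_pass, rho, p, reference_feature_cor_matrix(sp$feature),
                  rho_threshold = rho_threshold, p_threshold = p_threshold,
                  redundancy_threshold = redundancy_threshold)
}
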