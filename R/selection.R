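#' One-way ANOVA across density classes with Bonferroni pairwise post hoc
#'
#' Standard one-way ANOVA of a linear model of one feature on the four density
#' classes, followed by pooled-variance two-sample t-tests for all 6 class
#' pairs with Bonferroni adjustment (p times 6, capped at 1). A feature passes
#' the retention rule iff every adjusted pairwise p is below `alpha`.
#'
#' @param table feature table with a `density` factor column (see
#'   [build_feature_table()]).
#' @param feature feature column name.
#' @param alpha significance level (default 0.05).
#' @return list: `F`, `p`, `pairwise` (data frame of the 6 class pairs with
#'   raw and adjusted p), `pass`, `degenerate` (zero within- and
#'   between-class variance).
#' @export
anova_with_bonferroni <- function(table, feature, alpha = 0.05) {
  x <- table[[feature]]
  g <- droplevels(factor(table$density))
  if (any(tabulate(g) < 2)) stop("every class needs at least 2 rows")
  if (stats::var(x) == 0) {
    pairs <- t(utils::combn(levels(g), 2))
    return(list(F = NaN, p = NaN,
                pairwise = data.frame(class1 = pairs[, 1], class2 = pairs[, 2],
                                      p = NaN, p_adjusted = NaN),
                pass = FALSE, degenerate = TRUE))
  }
  av <- stats::anova(stats::lm(x ~ g))
  pairs <- t(utils::combn(levels(g), 2))
  praw <- apply(pairs, 1, function(pr) {
    stats::t.test(x[g == pr[1]], x[g == pr[2]], var.equal = TRUE)$p.value
  })
  padj <- stats::p.adjust(praw, method = "bonferroni")
  list(F = av$`F value`[1], p = av$`Pr(>F)`[1],
       pairwise = data.frame(class1 = pairs[, 1], class2 = pairs[, 2],
                             p = praw, p_adjusted = padj),
       pass = all(padj < alpha), degenerate = FALSE)
}

# Spearman rho with average ranks, plus a p-value: exact enumeration of all
# permutations for n <= 7, t-approximation beyond. The pipeline's own tables
# (n >= 40, heavily tied density) always take the t-branch.
spearman_rho_p <- function(x, y) {
  n <- length(x)
  if (n < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = 0, p = 1, degenerate = TRUE))
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n <= 7) {
    perms <- permutations_of(n)
    rho_perm <- apply(perms, 1, function(pm) stats::cor(rx, ry[pm]))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, degenerate = FALSE)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Spearman correlation of one feature with the ordinal density level
#'
#' Density is coded ordinally a = 1 to d = 4; ties get average ranks. A
#' constant feature is reported as `rho = 0`, `p = 1` and flagged.
#'
#' @inheritParams anova_with_bonferroni
#' @return list: `rho`, `p`, `degenerate`.
#' @export
spearman_vs_density <- function(table, feature) {
  y <- as.integer(factor(table$density, levels = density_classes()))
  spearman_rho_p(table[[feature]], y)
}

#' Verbal strength label for a Spearman correlation
#'
#' `|rho| > 0.80` strong; `0.51-0.80` moderate; `0.11-0.50` weak;
#' `<= 0.10` absent. The sign is reported separately.
#'
#' @param rho correlation in `[-1, 1]`.
#' @return list: `label`, `sign` (`"positive"`, `"negative"` or `"none"`).
#' @export
correlation_strength_label <- function(rho) {
  if (!is.finite(rho) || abs(rho) > 1) stop("rho must lie in [-1, 1]")
  a <- abs(rho)
  label <- if (a > 0.80) "strong" else if (a > 0.50) "moderate" else
    if (a > 0.10) "weak" else "absent"
  sign <- if (label == "absent") "none" else
    if (rho > 0) "positive" else "negative"
  list(label = label, sign = sign)
}

#' Inter-feature Spearman matrix and hierarchical clustering
#'
#' Pairwise Spearman correlations among the candidate features, clustered by
#' average linkage on the distance `1 - |rho|`.
#'
#' @param table feature table.
#' @param candidates character vector of >= 2 feature names.
#' @return list: `matrix` (Spearman rho), `hclust`, `order` (leaf order).
#' @export
feature_correlation_cluster <- function(table, candidates) {
  if (length(candidates) < 2) stop("need at least 2 candidate features")
  m <- stats::cor(as.matrix(table[candidates]), method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - abs(m)), method = "average")
  list(matrix = m, hclust = hc, order = candidates[hc$order])
}

#' The three-step feature-selection cascade on summary statistics
#'
#' Step 1 drops ANOVA failures (some Bonferroni-adjusted pairwise p >= 0.05).
#' Step 2 drops features whose Spearman correlation with density is
#' non-significant (`p >= p_threshold`) or below moderate strength
#' (`|rho| <= rho_threshold`). Step 3 resolves redundancy: while any surviving
#' pair correlates with `|rho| >= redundancy_threshold`, the member with the
#' larger mean absolute correlation to all other Step-1 candidates (the less
#' independent one) is rejected; ties go to the member with the lower
#' `|rho|` versus density, then to the alphabetically later name.
#'
#' @param anova_pass named logical over all features (Step-1 retention).
#' @param rho,p named numerics over the Step-1 candidates: Spearman rho and p
#'   versus density.
#' @param cor_matrix symmetric inter-feature Spearman matrix over the Step-1
#'   candidates.
#' @param rho_threshold Step-2 strength cut (default 0.50, exclusive).
#' @param p_threshold Step-2 significance cut (default 0.05).
#' @param redundancy_threshold Step-3 cut (default 0.80, inclusive).
#' @return list: `candidates` (Step-1 survivors), `step2` (Step-2 survivors),
#'   `retained`, and `rejected` (data frame `feature`, `reason` with
#'   machine-readable reasons `anova_fail`, `nonsignificant_rho`,
#'   `redundant_with:<name>`).
#' @export
select_features <- function(anova_pass, rho, p, cor_matrix,
                            rho_threshold = 0.50, p_threshold = 0.05,
                            redundancy_threshold = 0.80) {
  features <- names(anova_pass)
  rejected <- data.frame(feature = character(0), reason = character(0),
                         stringsAsFactors = FALSE)
  candidates <- features[anova_pass]
  for (f in setdiff(features, candidates))
    rejected <- rbind(rejected, data.frame(feature = f, reason = "anova_fail"))

  keep2 <- candidates[p[candidates] < p_threshold &
                        abs(rho[candidates]) > rho_threshold]
  for (f in setdiff(candidates, keep2))
    rejected <- rbind(rejected,
                      data.frame(feature = f, reason = "nonsignificant_rho"))

  # independence score: mean |rho| against all other Step-1 candidates
  score <- function(f) mean(abs(cor_matrix[f, setdiff(candidates, f)]))
  survivors <- sort(keep2)
  repeat {
    if (length(survivors) < 2) break
    pairs <- t(utils::combn(survivors, 2))
    rr <- abs(cor_matrix[pairs])
    hot <- which(rr >= redundancy_threshold)
    if (length(hot) == 0) break
    # handle the most redundant pair first, deterministically
    pr <- pairs[hot[order(-rr[hot])][1], ]
    s1 <- score(pr[1]); s2 <- score(pr[2])
    reject <- if (s1 > s2) pr[1] else if (s2 > s1) pr[2] else
      if (abs(rho[pr[1]]) < abs(rho[pr[2]])) pr[1] else
        if (abs(rho[pr[2]]) < abs(rho[pr[1]])) pr[2] else max(pr)
    keepee <- setdiff(pr, reject)
    rejected <- rbind(rejected, data.frame(
      feature = reject, reason = paste0("redundant_with:", keepee)))
    survivors <- setdiff(survivors, reject)
  }
  list(candidates = candidates, step2 = keep2, retained = survivors,
       rejected = rejected)
}

#' Run the full feature-selection cascade on a feature table
#'
#' Computes the per-feature ANOVA/Bonferroni results, Spearman correlations
#' with density, the candidate inter-feature correlation matrix with its
#' average-linkage clustering, and applies [select_features()].
#'
#' @inheritParams anova_with_bonferroni
#' @param features feature columns to consider (default: the 19 names).
#' @return object of class `selection_report`: `anova` (per-feature list),
#'   `spearman` (data frame `feature`, `rho`, `p`, `strength`, `sign`),
#'   `cluster` (from [feature_correlation_cluster()], `NULL` when fewer than
#'   two candidates), and the [select_features()] fields.
#' @export
run_feature_selection <- function(table, features = texture_feature_names(),
                                  alpha = 0.05) {
  anv <- lapply(features, function(f) anova_with_bonferroni(table, f, alpha))
  names(anv) <- features
  anova_pass <- vapply(anv, `[[`, logical(1), "pass")
  candidates <- features[anova_pass]
  sp <- lapply(candidates, function(f) spearman_vs_density(table, f))
  rho <- vapply(sp, `[[`, numeric(1), "rho"); names(rho) <- candidates
  p <- vapply(sp, `[[`, numeric(1), "p"); names(p) <- candidates
  labels <- lapply(rho, correlation_strength_label)
  cluster <- if (length(candidates) >= 2)
    feature_correlation_cluster(table, candidates) else NULL
  cm <- if (is.null(cluster)) {
    m <- diag(length(candidates))
    dimnames(m) <- list(candidates, candidates)
    m
  } else cluster$matrix
  sel <- select_features(anova_pass, rho, p, cm)
  structure(
    c(list(anova = anv,
           spearman = data.frame(
             feature = candidates, rho = rho, p = p,
             strength = vapply(labels, `[[`, character(1), "label"),
             sign = vapply(labels, `[[`, character(1), "sign"),
             row.names = NULL),
           cluster = cluster),
      sel),
    class = "selection_report")
}

#' @export
print.selection_report <- function(x, ...) {
  cat("<selection_report>\n")
  cat("  step 1 candidates:", length(x$candidates), "of",
      length(x$anova), "\n")
  cat("  step 2 survivors: ", paste(x$step2, collapse = ", "), "\n")
  cat("  retained:         ", paste(x$retained, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a selection report
#'
#' Writes the report as JSON plus two CSV tables (per-feature ANOVA summary
#' and Spearman summary) and the candidate correlation matrix as CSV.
#'
#' @param report a [run_feature_selection()] result.
#' @param dir output directory (created if missing).
#' @export
write_selection_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  anova_tab <- data.frame(
    feature = names(report$anova),
    F = vapply(report$anova, `[[`, numeric(1), "F"),
    p = vapply(report$anova, `[[`, numeric(1), "p"),
    max_pairwise_p_adjusted = vapply(report$anova, function(a)
      suppressWarnings(max(a$pairwise$p_adjusted)), numeric(1)),
    pass = vapply(report$anova, `[[`, logical(1), "pass"),
    row.names = NULL)
  utils::write.csv(anova_tab, file.path(dir, "anova_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(report$spearman, file.path(dir, "spearman_summary.csv"),
                   row.names = FALSE)
  if (!is.null(report$cluster))
    utils::write.csv(report$cluster$matrix,
                     file.path(dir, "feature_correlation_matrix.csv"))
  jsonlite::write_json(
    list(candidates = report$candidates, step2 = report$step2,
         retained = report$retained, rejected = report$rejected),
    file.path(dir, "selection_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
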