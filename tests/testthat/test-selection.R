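four_group_table <- function(groups) {
  data.frame(density = factor(rep(c("a", "b", "c", "d"),
                                  times = vapply(groups, length, integer(1))),
                              levels = c("a", "b", "c", "d")),
             x = unlist(groups))
}

test_that("one-way ANOVA F matches the between/within mean-square ratio", {
  tb <- four_group_table(list(c(1, 2, 3), c(2, 3, 4), c(3, 4, 5), c(4, 5, 6)))
  res <- anova_with_bonferroni(tb, "x")
  # direct formula oracle
  gm <- mean(tb$x)
  means <- tapply(tb$x, tb$density, mean)
  ssb <- sum(3 * (means - gm)^2)
  ssw <- sum((tb$x - means[tb$density])^2)
  F_oracle <- (ssb / 3) / (ssw / 8)
  expect_equal(res$F, F_oracle)
  expect_equal(res$F, 5)  # frozen hand value
  expect_equal(nrow(res$pairwise), 6)
  # adjusted p equals raw p times 6, capped at 1
  expect_equal(res$pairwise$p_adjusted, pmin(1, res$pairwise$p * 6))
})

test_that("degenerate (zero-variance) features are flagged and fail", {
  tb <- four_group_table(list(c(1, 1), c(1, 1), c(1, 1), c(1, 1)))
  res <- anova_with_bonferroni(tb, "x")
  expect_true(res$degenerate)
  expect_false(res$pass)
  expect_error(anova_with_bonferroni(
    four_group_table(list(1, c(1, 2), c(1, 2), c(1, 2))), "x"), "2 rows")
})

test_that("Spearman correlation handles ties, signs and constants", {
  tb <- data.frame(density = factor(c("a", "b", "c", "d"),
                                    levels = c("a", "b", "c", "d")),
                   up = c(10, 20, 30, 40), down = c(4, 3, 2, 1))
  expect_equal(spearman_vs_density(tb, "up")$rho, 1)
  expect_equal(spearman_vs_density(tb, "down")$rho, -1)

  # tied data: rho equals the Pearson correlation of average ranks
  x <- c(1, 1, 2, 2); y <- c(1, 2, 3, 4)
  got <- bcttexture:::spearman_rho_p(x, y)
  expect_equal(got$rho, cor(rank(x), rank(y)))
  expect_equal(got$rho, cor(c(1.5, 1.5, 3.5, 3.5), 1:4))

  # exact permutation p at tiny n: monotone 4 points, two-sided
  ex <- bcttexture:::spearman_rho_p(1:4, c(2, 4, 6, 8))
  expect_equal(ex$rho, 1)
  expect_equal(ex$p, 2 / 24)  # 2 of 4! permutations reach |rho| = 1
  # t-approximation branch agrees with cor.test on untied data
  set.seed(5)
  x2 <- rnorm(30); y2 <- x2 + rnorm(30)
  got2 <- bcttexture:::spearman_rho_p(x2, y2)
  ref <- suppressWarnings(cor.test(x2, y2, method = "spearman"))
  expect_equal(got2$rho, unname(ref$estimate))

  const <- data.frame(density = factor(rep(c("a", "b", "c", "d"), 2),
                                       levels = c("a", "b", "c", "d")),
                      x = rep(1, 8))
  res <- spearman_vs_density(const, "x")
  expect_true(res$degenerate)
  expect_equal(res$rho, 0)
  expect_equal(res$p, 1)
})

test_that("correlation strength bands follow the study's scale", {
  expect_equal(correlation_strength_label(-0.81),
               list(label = "strong", sign = "negative"))
  expect_equal(correlation_strength_label(-0.59),
               list(label = "moderate", sign = "negative"))
  expect_equal(correlation_strength_label(0.05),
               list(label = "absent", sign = "none"))
  expect_equal(correlation_strength_label(0.43)$label, "weak")
  expect_equal(correlation_strength_label(0.803)$label, "strong")
  expect_error(correlation_strength_label(1.2), "\\[-1, 1\\]")
})

test_that("correlation clustering merges duplicated features first", {
  set.seed(6)
  base <- rnorm(40)
  tb <- data.frame(density = factor(rep(c("a", "b", "c", "d"), 10)),
                   f1 = base, f2 = base, f3 = rnorm(40))
  cl <- feature_correlation_cluster(tb, c("f1", "f2", "f3"))
  expect_equal(diag(cl$matrix), c(f1 = 1, f2 = 1, f3 = 1))
  expect_equal(cl$matrix, t(cl$matrix))
  expect_equal(cl$matrix["f1", "f2"], 1)
  # first merge joins the identical pair
  expect_setequal(abs(cl$hclust$merge[1, ]), c(1, 2))
  expect_equal(cl$hclust$height[1], 0)
  # average linkage by hand on the 3x3 distance matrix
  d13 <- 1 - abs(cl$matrix["f1", "f3"])
  d23 <- 1 - abs(cl$matrix["f2", "f3"])
  expect_equal(cl$hclust$height[2], mean(c(d13, d23)))
  expect_error(feature_correlation_cluster(tb, "f1"), "at least 2")
})

test_that("the cascade rejects with machine-readable reasons", {
  feats <- c("f1", "f2", "f3", "f4")
  anova_pass <- c(f1 = TRUE, f2 = TRUE, f3 = TRUE, f4 = FALSE)
  rho <- c(f1 = -0.9, f2 = 0.7, f3 = 0.3)
  p <- c(f1 = 0.001, f2 = 0.001, f3 = 0.001)
  cm <- diag(3); dimnames(cm) <- list(names(rho), names(rho))
  sel <- select_features(anova_pass, rho, p, cm)
  expect_setequal(sel$retained, c("f1", "f2"))
  expect_equal(sel$rejected$reason[sel$rejected$feature == "f4"], "anova_fail")
  expect_equal(sel$rejected$reason[sel$rejected$feature == "f3"],
               "nonsignificant_rho")

  # exact duplicates: exactly one survives, logged as redundant
  cm2 <- matrix(c(1, 1, 1, 1), 2, 2,
                dimnames = list(c("f1", "f2"), c("f1", "f2")))
  sel2 <- select_features(c(f1 = TRUE, f2 = TRUE),
                          c(f1 = 0.8, f2 = 0.8), c(f1 = 0.01, f2 = 0.01), cm2)
  expect_length(sel2$retained, 1)
  expect_match(sel2$rejected$reason, "redundant_with:")

  # all mutually uncorrelated and moderate: step 3 vacuous
  cm3 <- diag(3); dimnames(cm3) <- list(names(rho), names(rho))
  sel3 <- select_features(anova_pass[1:3] & TRUE,
                          c(f1 = 0.6, f2 = -0.7, f3 = 0.55),
                          c(f1 = 0.01, f2 = 0.01, f3 = 0.01), cm3)
  expect_setequal(sel3$retained, c("f1", "f2", "f3"))
})

test_that("redundancy resolution drops the less independent member", {
  # f1 and f2 highly correlated; f2 also entangled with f3 -> reject f2
  feats <- c("f1", "f2", "f3")
  cm <- matrix(c(1, 0.85, 0.05,
                 0.85, 1, 0.7,
                 0.05, 0.7, 1), 3, 3, dimnames = list(feats, feats))
  sel <- select_features(
    stats::setNames(rep(TRUE, 3), feats),
    c(f1 = 0.6, f2 = 0.9, f3 = 0.2),
    c(f1 = 0.01, f2 = 0.01, f3 = 0.3), cm)
  expect_equal(sel$retained, "f1")
  expect_equal(sel$rejected$reason[sel$rejected$feature == "f2"],
               "redundant_with:f1")
  # step 3 never reinstates a dropped feature
  expect_false("f3" %in% sel$retained)
})

test_that("selection replay on the published summary tables", {
  sel <- replay_reference_selection()
  expect_length(sel$candidates, 11)
  expect_setequal(sel$candidates,
                  c("variance", "skewness", "kurtosis", "entropy", "contrast",
                    "correlation", "energy", "homogeneity", "GLN", "RLN",
                    "SRLGE"))
  expect_setequal(sel$step2, c("skewness", "GLN", "RLN"))
  expect_setequal(sel$retained, c("skewness", "GLN"))
  expect_equal(sel$rejected$reason[sel$rejected$feature == "RLN"],
               "redundant_with:GLN")
  expect_equal(sel$rejected$reason[sel$rejected$feature == "SRLGE"],
               "nonsignificant_rho")
})

test_that("full cascade on a feature table is deterministic and serializable", {
  tb <- synthetic_feature_table(15, n_features = 4)
  names(tb)[3:6] <- c("skewness", "GLN", "RLN", "variance")
  rep1 <- run_feature_selection(tb, features = c("skewness", "GLN", "RLN",
                                                 "variance"))
  rep2 <- run_feature_selection(tb, features = c("skewness", "GLN", "RLN",
                                                 "variance"))
  expect_identical(rep1$retained, rep2$retained)
  expect_identical(rep1$spearman, rep2$spearman)
  d <- withr::local_tempdir()
  write_selection_report(rep1, d)
  expect_true(file.exists(file.path(d, "selection_report.json")))
  expect_true(file.exists(file.path(d, "anova_summary.csv")))
  js <- jsonlite::read_json(file.path(d, "selection_report.json"),
                            simplifyVector = TRUE)
  expect_equal(sort(js$retained), sort(rep1$retained))
})

test_that("skewness survives step 2 on a default phantom cohort", {
  tb <- phantom_table(10)
  sp <- spearman_vs_density(tb, "skewness")
  expect_lt(sp$rho, -0.5)
  expect_lt(sp$p, 0.05)
  rep <- run_feature_selection(tb)
  expect_true("skewness" %in% rep$step2)
})
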