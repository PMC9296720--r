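full_mask <- function(...) array(TRUE, c(...))

test_that("normalisation maps the clipped range onto 1..N_g", {
  # constant region: sigma = 0 convention
  st <- image_stack(matrix(7, 5, 5))
  q <- normalize_and_quantize(st, full_mask(5, 5, 1), 64)
  expect_true(all(q$levels[q$mask] == 1L))
  expect_identical(first_order_features(q),
                   c(variance = 0, skewness = 0, kurtosis = 0, entropy = 0))

  # two-valued region in equal proportion: symmetric about the bin midrange
  st2 <- image_stack(matrix(rep(c(0, 100), 50), 10, 10))
  q2 <- normalize_and_quantize(st2, full_mask(10, 10, 1), 64)
  lv <- sort(unique(q2$levels[q2$mask]))
  expect_length(lv, 2)
  expect_equal(sum(lv), 1 + 64)  # symmetric about (1 + N_g) / 2

  # extreme outliers are clipped into range
  st3 <- image_stack(matrix(c(rep(0, 98), -1e7, 1e7), 10, 10))
  q3 <- normalize_and_quantize(st3, full_mask(10, 10, 1), 32)
  expect_true(all(q3$levels[q3$mask] >= 1 & q3$levels[q3$mask] <= 32))

  expect_error(normalize_and_quantize(st, array(FALSE, c(5, 5, 1))), "empty")
})

test_that("first-order features match hand computation", {
  q <- qroi_from_levels(matrix(c(1L, 1L, 2L, 2L), 2, 2), 2)
  fo <- first_order_features(q)
  expect_equal(fo[["variance"]], 0.25)
  expect_equal(fo[["skewness"]], 0)
  expect_equal(fo[["kurtosis"]], -2)
  expect_equal(fo[["entropy"]], 1)

  # symmetric histograms have zero skewness
  set.seed(1)
  for (rep in 1:5) {
    half <- sample(1:8, 30, replace = TRUE)
    lv <- c(half, 9L - half)   # mirror-symmetric about 4.5
    q <- qroi_from_levels(matrix(as.integer(lv), 6, 10), 8)
    expect_equal(first_order_features(q)[["skewness"]], 0, tolerance = 1e-12)
  }
})

test_that("GLCM counts, symmetry and probability conservation", {
  q <- qroi_from_levels(matrix(c(1L, 1L, 2L, 2L), 2, 2), 2)  # [[1,2],[1,2]]
  g <- compute_glcm(q, 1, "0")
  expect_equal(g$P, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  gf <- glcm_features(g)
  expect_equal(gf[["contrast"]], 1)
  expect_equal(gf[["energy"]], 0.5)
  expect_equal(gf[["homogeneity"]], 0.5)

  # constant region: single cell, correlation convention
  qc <- qroi_from_levels(matrix(3L, 4, 4), 4)
  gc <- compute_glcm(qc)
  expect_equal(gc$P[3, 3], 1)
  expect_identical(glcm_features(gc),
                   c(contrast = 0, correlation = 1, energy = 1,
                     homogeneity = 1))

  # duplicated slices leave probabilities unchanged
  sl <- matrix(sample(1:4, 36, replace = TRUE), 6, 6)
  q1 <- qroi_from_levels(sl, 4)
  q2 <- qroi_from_levels(array(rep(sl, 2), c(6, 6, 2)), 4)
  expect_equal(compute_glcm(q1)$P, compute_glcm(q2)$P)

  # conservation and symmetry on random masked inputs
  set.seed(2)
  for (rep in 1:5) {
    lv <- matrix(sample(c(NA, 1:4), 64, replace = TRUE), 8, 8)
    q <- qroi_from_levels(lv, 4)
    g <- compute_glcm(q)
    expect_equal(sum(g$P), 1, tolerance = 1e-12)
    expect_equal(g$P, t(g$P))
  }

  # mask too sparse for any pair
  lv <- matrix(NA_integer_, 3, 3); lv[1, 1] <- 1L; lv[3, 3] <- 2L
  expect_error(compute_glcm(qroi_from_levels(lv, 2), 1, "0"), "no valid")
})

test_that("GLRLM runs respect mask gaps and direction structure", {
  row6 <- array(c(1L, 1L, 1L, 2L, 2L, 3L), c(1, 6, 1))
  r <- compute_glrlm(qroi_from_levels(row6, 3), "0")
  expect_equal(r$N_r, 3)
  expect_equal(r$N_p, 6)
  expect_equal(r$p[1, 3], 1); expect_equal(r$p[2, 2], 1)
  expect_equal(r$p[3, 1], 1)
  rf <- glrlm_features(r)
  expect_equal(rf[["SRE"]], (1 / 9 + 1 / 4 + 1) / 3)
  expect_equal(rf[["LRE"]], (9 + 4 + 1) / 3)
  expect_equal(rf[["GLN"]], 1)
  expect_equal(rf[["RLN"]], 1)
  expect_equal(rf[["RP"]], 0.5)

  # a mask gap splits a run: 1 . 1 2 2 3
  gap <- array(c(1L, 1L, 1L, 2L, 2L, 3L), c(1, 6, 1))
  gap[1, 2, 1] <- NA
  rg <- compute_glrlm(qroi_from_levels(gap, 3), "0")
  expect_equal(rg$N_r, 4)
  expect_equal(rg$p[1, 1], 2)  # two split runs of level 1

  # checkerboard: all runs have length 1
  cb <- outer(1:6, 1:6, function(i, j) ((i + j) %% 2) + 1L)
  rc <- compute_glrlm(qroi_from_levels(cb, 2), "0")
  expect_equal(ncol(rc$p), 1)
  expect_equal(rc$N_r, rc$N_p)

  # single run collapses every feature to 1
  r1 <- compute_glrlm(qroi_from_levels(array(1L, c(1, 1, 1)), 1), "0")
  expect_equal(unname(glrlm_features(r1)), rep(1, 11))
})

test_that("pixel-count conservation holds in every direction", {
  set.seed(3)
  for (rep in 1:5) {
    lv <- array(sample(c(NA, 1:3), 8 * 8 * 2, replace = TRUE), c(8, 8, 2))
    q <- qroi_from_levels(lv, 3)
    for (dir in c("0", "45", "90", "135")) {
      r <- compute_glrlm(q, dir)
      expect_equal(sum(r$p %*% seq_len(ncol(r$p))), sum(!is.na(lv)))
    }
    r4 <- compute_glrlm(q)
    expect_equal(sum(r4$p %*% seq_len(ncol(r4$p))), r4$N_p)
  }
})

test_that("all 19 features agree with the brute-force oracle", {
  set.seed(4)
  for (rep in 1:20) {
    ng <- sample(2:4, 1)
    lv <- array(sample(c(NA, seq_len(ng)), 8 * 8, replace = TRUE,
                       prob = c(0.3, rep(0.7 / ng, ng))), c(8, 8, 1))
    if (sum(!is.na(lv)) < 10) next
    got <- package_all_features(lv, ng)
    want <- oracle_all_features(lv, ng)
    expect_equal(got[texture_feature_names()],
                 want[texture_feature_names()], tolerance = 1e-9)
  }
})

test_that("features are invariant to intensity shifts and scalings", {
  cfg <- small_phantom_config()
  ex <- generate_phantom_exam(cfg, "b", 17)
  roi <- phantom_roi(cfg)
  f0 <- extract_features(ex$stack, roi)
  shifted <- ex$stack; shifted$voxels <- shifted$voxels + 500
  expect_equal(extract_features(shifted, roi), f0, tolerance = 1e-9)
  scaled <- ex$stack; scaled$voxels <- scaled$voxels * 3.7 - 20
  expect_equal(extract_features(scaled, roi), f0, tolerance = 1e-9)
})

test_that("phantom density classes separate by skewness sign", {
  cfg <- phantom_config(n_slices = 10L)
  roi <- phantom_roi(cfg)
  fa <- extract_features(generate_phantom_exam(cfg, "a", 31)$stack, roi)
  fd <- extract_features(generate_phantom_exam(cfg, "d", 32)$stack, roi)
  expect_gt(fa[["skewness"]], 0)   # mass at the fat peak, right tail
  expect_lt(fd[["skewness"]], 0)
  expect_length(fa, 19)
  expect_named(fa, texture_feature_names())
})

test_that("feature tables round-trip through CSV", {
  tb <- small_phantom_table(2)
  expect_equal(nrow(tb), 8)
  f <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tb, f)
  back <- read_feature_table(f)
  expect_equal(back$density, tb$density)
  expect_equal(back$skewness, tb$skewness, tolerance = 1e-12)
})
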