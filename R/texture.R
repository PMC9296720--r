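#' The 19 texture feature names
#'
#' Four first-order (histogram) features, four grey-level co-occurrence matrix
#' (GLCM) features and eleven grey-level run-length matrix (GLRLM) features.
#'
#' @return character vector of length 19.
#' @export
texture_feature_names <- function() {
  c("variance", "skewness", "kurtosis", "entropy",
    "contrast", "correlation", "energy", "homogeneity",
    "SRE", "LRE", "GLN", "RLN", "RP",
    "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE")
}

#' Grey-level normalisation and quantisation of a masked stack
#'
#' Pools the masked pixel values over all analysed slices, clips them to
#' `mean +/- 3 sd`, and maps the clipped range linearly onto integer levels
#' `1..n_levels` (value `mu - 3 sigma` to level 1, `mu + 3 sigma` to level
#' `n_levels`). A constant region (`sigma = 0`) maps to level 1 everywhere.
#' This makes every downstream feature invariant to affine changes of the
#' scanner intensity scale.
#'
#' @param stack an [image_stack()].
#' @param mask logical array of the stack's dimensions with at least one
#'   `TRUE` pixel.
#' @param n_levels number of grey levels `N_g` (default 64).
#' @return an object of class `quantized_roi`: integer `levels` array (`NA`
#'   outside the mask), `mask`, `n_levels`, `n_masked_pixels`.
#' @export
normalize_and_quantize <- function(stack, mask, n_levels = 64L) {
  stopifnot(inherits(stack, "image_stack"))
  if (!any(mask)) stop("empty mask")
  n_levels <- as.integer(n_levels)
  vals <- stack$voxels[mask]
  mu <- mean(vals); sigma <- stats::sd(vals)
  lev <- array(NA_integer_, dim(stack$voxels))
  if (!is.finite(sigma) || sigma == 0) {
    lev[mask] <- 1L
  } else {
    lo <- mu - 3 * sigma; hi <- mu + 3 * sigma
    f <- (pmin(pmax(vals, lo), hi) - lo) / (hi - lo)
    lev[mask] <- pmin(n_levels, floor(f * n_levels) + 1L)
  }
  structure(list(levels = lev, mask = mask, n_levels = n_levels,
                 n_masked_pixels = length(vals)),
            class = "quantized_roi")
}

# restrict a quantized ROI to the bounding box of its mask; pure speed-up:
# pairs and runs never cross the all-NA frame outside the box
crop_to_mask <- function(qroi) {
  idx <- which(qroi$mask, arr.ind = TRUE)
  r <- range(idx[, 1]); c <- range(idx[, 2]); s <- range(idx[, 3])
  qroi$levels <- qroi$levels[r[1]:r[2], c[1]:c[2], s[1]:s[2], drop = FALSE]
  qroi$mask <- qroi$mask[r[1]:r[2], c[1]:c[2], s[1]:s[2], drop = FALSE]
  qroi
}

#' First-order (histogram) features
#'
#' Population moments of the pooled masked levels: variance
#' `(1/N) sum (x - mu)^2`, skewness `(1/N) sum (x - mu)^3 / sigma^3`, excess
#' kurtosis `(1/N) sum (x - mu)^4 / sigma^4 - 3`, and Shannon entropy (bits) of
#' the normalized level histogram. A constant region returns all zeros.
#'
#' @param qroi a [normalize_and_quantize()] result.
#' @return named numeric: `variance`, `skewness`, `kurtosis`, `entropy`.
#' @export
first_order_features <- function(qroi) {
  x <- qroi$levels[qroi$mask]
  if (length(x) == 0L) stop("empty input")
  n <- length(x)
  mu <- mean(x)
  v <- sum((x - mu)^2) / n
  if (v == 0) return(c(variance = 0, skewness = 0, kurtosis = 0, entropy = 0))
  s <- sqrt(v)
  h <- tabulate(x, nbins = qroi$n_levels) / n
  h <- h[h > 0]
  c(variance = v,
    skewness = sum((x - mu)^3) / n / s^3,
    kurtosis = sum((x - mu)^4) / n / s^4 - 3,
    entropy = -sum(h * log2(h)))
}

# in-plane direction name -> (d_row, d_col) offset for unit distance;
# rows grow downwards so 45 degrees (up-right) is (-1, +1)
direction_offsets <- function(directions, distance = 1L) {
  base <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
               `90` = c(-1L, 0L), `135` = c(-1L, -1L))
  if (!all(directions %in% names(base)))
    stop("directions must be among 0, 45, 90, 135")
  lapply(base[as.character(directions)], function(o) o * as.integer(distance))
}

# co-occurrence counts for one offset, pooled over slices; pairs touching an
# unmasked (NA level) pixel are skipped
offset_pair_counts <- function(levels, dr, dc, ng) {
  .glcm_counts_cpp(levels, dim(levels), as.integer(dr), as.integer(dc),
                   as.integer(ng))
}

#' Grey-level co-occurrence matrix
#'
#' Counts pairs of levels at the given offset(s) where both pixels are masked,
#' accumulated over all analysed slices and directions, symmetrized (each pair
#' counted in both orders) and normalized to probabilities.
#'
#' @param qroi a [normalize_and_quantize()] result.
#' @param distance pixel offset distance (default 1).
#' @param directions subset of `c("0", "45", "90", "135")` degrees in-plane.
#' @return object of class `glcm`: probability matrix `P` (`N_g x N_g`),
#'   raw symmetric `counts`, and the accumulation metadata.
#' @export
compute_glcm <- function(qroi, distance = 1L,
                         directions = c("0", "45", "90", "135")) {
  if (distance < 1) stop("distance must be >= 1")
  ng <- qroi$n_levels
  counts <- matrix(0, ng, ng)
  for (off in direction_offsets(directions, distance))
    counts <- counts + offset_pair_counts(qroi$levels, off[1], off[2], ng)
  counts <- counts + t(counts)  # symmetrize: both orders of every pair
  total <- sum(counts)
  if (total == 0) stop("no valid pixel pair at the requested offset(s)")
  structure(list(P = counts / total, counts = counts, distance = distance,
                 directions = directions, symmetric = TRUE),
            class = "glcm")
}

#' GLCM features
#'
#' `contrast = sum (i-j)^2 P(i,j)`, `energy = sum P^2`,
#' `homogeneity = sum P/(1+|i-j|)`, and `correlation` of the level indices
#' under `P` (marginal means/sds; defined as 1 when a marginal sd is 0).
#'
#' @param g a [compute_glcm()] result (normalized).
#' @return named numeric: `contrast`, `correlation`, `energy`, `homogeneity`.
#' @export
glcm_features <- function(g) {
  P <- g$P
  if (abs(sum(P) - 1) > 1e-8) stop("GLCM is not normalized")
  ng <- nrow(P)
  i <- matrix(seq_len(ng), ng, ng)
  j <- t(i)
  px <- rowSums(P)
  mu_x <- sum(seq_len(ng) * px)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  py <- colSums(P)
  mu_y <- sum(seq_len(ng) * py)
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  corr <- if (sd_x * sd_y == 0) 1 else
    sum((i - mu_x) * (j - mu_y) * P) / (sd_x * sd_y)
  c(contrast = sum((i - j)^2 * P),
    correlation = corr,
    energy = sum(P^2),
    homogeneity = sum(P / (1 + abs(i - j))))
}

# run-length counts (N_g x max line length) for one direction, accumulated
# over slices; scan lines: rows (0), columns (90), up-right anti-diagonals
# (45), down-right diagonals (135); an unmasked pixel terminates a run
direction_run_counts <- function(levels, direction, ng) {
  code <- match(as.character(direction), c("0", "90", "45", "135")) - 1L
  if (is.na(code)) stop("directions must be among 0, 45, 90, 135")
  .glrlm_counts_cpp(levels, dim(levels), code, as.integer(ng))
}

#' Grey-level run-length matrix
#'
#' Scans maximal runs of equal levels among masked pixels (an unmasked pixel
#' terminates a run) along each direction of each analysed slice, and
#' accumulates the run counts `p(i, j)` over slices and directions.
#'
#' @inheritParams compute_glcm
#' @return object of class `glrlm`: count matrix `p` (`N_g x J_max`), total
#'   run count `N_r`, and `N_p` = total masked pixels times the number of
#'   directions.
#' @export
compute_glrlm <- function(qroi, directions = c("0", "45", "90", "135")) {
  if (length(directions) == 0L) stop("directions must be non-empty")
  if (!any(qroi$mask)) stop("empty mask")
  ng <- qroi$n_levels
  p <- Reduce(`+`, lapply(as.character(directions), function(d)
    direction_run_counts(qroi$levels, d, ng)))
  jmax <- max(which(colSums(p) > 0), 1L)
  p <- p[, seq_len(jmax), drop = FALSE]
  structure(list(p = p, N_r = sum(p),
                 N_p = qroi$n_masked_pixels * length(directions),
                 directions = directions),
            class = "glrlm")
}

#' GLRLM features
#'
#' The eleven run-length statistics over `p(i, j)` (level `i`, run length `j`),
#' each normalized by the total run count `N_r`; run percentage `RP = N_r/N_p`.
#'
#' @param r a [compute_glrlm()] result with `N_r > 0`.
#' @return named numeric: `SRE`, `LRE`, `GLN`, `RLN`, `RP`, `LGRE`, `HGRE`,
#'   `SRLGE`, `SRHGE`, `LRLGE`, `LRHGE`.
#' @export
glrlm_features <- function(r) {
  if (r$N_r <= 0) stop("empty run-length matrix")
  p <- r$p
  ng <- nrow(p); jm <- ncol(p)
  i2 <- matrix(seq_len(ng)^2, ng, jm)
  j2 <- matrix(seq_len(jm)^2, ng, jm, byrow = TRUE)
  nr <- r$N_r
  c(SRE = sum(p / j2) / nr,
    LRE = sum(p * j2) / nr,
    GLN = sum(rowSums(p)^2) / nr,
    RLN = sum(colSums(p)^2) / nr,
    RP = nr / r$N_p,
    LGRE = sum(p / i2) / nr,
    HGRE = sum(p * i2) / nr,
    SRLGE = sum(p / (i2 * j2)) / nr,
    SRHGE = sum(p * i2 / j2) / nr,
    LRLGE = sum(p * j2 / i2) / nr,
    LRHGE = sum(p * i2 * j2) / nr)
}

#' Extract the 19 texture features of one examination
#'
#' Composes the full per-examination pipeline: ROI mask derivation (skin-margin
#' erosion + propagation), grey-level normalisation/quantisation, first-order
#' features, GLCM (distance 1, four in-plane directions) and GLRLM (same four
#' directions) features. Histograms and matrix counts are pooled over all
#' analysed slices, giving one 19-vector per examination.
#'
#' @param stack an [image_stack()].
#' @param roi an [roi_spec()].
#' @param n_levels grey levels for quantisation (default 64).
#' @param distance GLCM offset distance (default 1).
#' @param directions in-plane directions for GLCM and GLRLM.
#' @return named numeric of length 19 ([texture_feature_names()]).
#' @export
extract_features <- function(stack, roi, n_levels = 64L, distance = 1L,
                             directions = c("0", "45", "90", "135")) {
  mask <- derive_roi_mask(stack, roi)
  qroi <- normalize_and_quantize(stack, mask, n_levels)
  qroi <- crop_to_mask(qroi)
  fv <- c(first_order_features(qroi),
          glcm_features(compute_glcm(qroi, distance, directions)),
          glrlm_features(compute_glrlm(qroi, directions)))
  fv[texture_feature_names()]
}

#' Build the examinations-by-features table for a phantom cohort
#'
#' Streams through the cohort (generate one examination, extract its features,
#' discard the pixel data) so that arbitrarily large cohorts use the memory of
#' a single examination.
#'
#' @inheritParams generate_cohort
#' @param margin_mm skin margin applied to the phantom ROI (default 5).
#' @param n_levels,distance,directions passed to [extract_features()].
#' @return data frame with columns `exam_id`, `density` (factor a-d),
#'   `true_gland_fraction`, and the 19 feature columns.
#' @export
build_feature_table <- function(config, n_per_class, seed = config$seed,
                                margin_mm = 5, n_levels = 64L, distance = 1L,
                                directions = c("0", "45", "90", "135")) {
  plan <- cohort_plan(n_per_class, seed)
  roi <- phantom_roi(config, margin_mm = margin_mm)
  rows <- vector("list", nrow(plan))
  gf <- numeric(nrow(plan))
  for (i in seq_len(nrow(plan))) {
    ex <- generate_phantom_exam(config, plan$class[i], plan$seed[i])
    gf[i] <- ex$true_gland_fraction
    rows[[i]] <- extract_features(ex$stack, roi, n_levels, distance, directions)
  }
  out <- cbind(
    data.frame(exam_id = plan$exam_id,
               density = factor(plan$class, levels = density_classes()),
               true_gland_fraction = gf, stringsAsFactors = FALSE),
    as.data.frame(do.call(rbind, rows)))
  out
}

#' Write / read a feature table as CSV
#'
#' One row per examination: `exam_id`, `density`, then the 19 feature columns.
#'
#' @param table a [build_feature_table()] result.
#' @param path CSV path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tb <- utils::read.csv(path, stringsAsFactors = FALSE)
  tb$density <- factor(tb$density, levels = density_classes())
  tb
}
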