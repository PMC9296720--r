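#' Overall percent agreement of a rating confusion matrix
#'
#' `100 * trace / total`; the integer-rounded value is reported alongside the
#' raw percentage.
#'
#' @param cm K x K count matrix (rows = rater A, columns = rater B).
#' @return list: `percent` (raw), `percent_rounded` (nearest integer),
#'   `n` (total).
#' @export
percent_agreement <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty matrix")
  p <- 100 * sum(diag(cm)) / total
  list(percent = p, percent_rounded = round(p), n = total)
}

#' Cohen's kappa with verbal agreement label
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with the chance agreement `p_e` from the
#' marginal products. Labels follow the Landis-Koch scale (0.61-0.80
#' substantial, 0.81-1.00 almost perfect, ...). When both raters use a single
#' category (`p_e = 1`), kappa is undefined and flagged.
#'
#' @inheritParams percent_agreement
#' @return list: `kappa`, `p_o`, `p_e`, `label`, `undefined`.
#' @export
cohens_kappa <- function(cm) {
  cm <- as.matrix(cm)
  total <- sum(cm)
  if (total == 0) stop("empty matrix")
  p_o <- sum(diag(cm)) / total
  p_e <- sum(rowSums(cm) * colSums(cm)) / total^2
  if (1 - p_e < .Machine$double.eps * 100)
    return(list(kappa = NA_real_, p_o = p_o, p_e = p_e,
                label = "undefined", undefined = TRUE))
  k <- (p_o - p_e) / (1 - p_e)
  label <- if (k < 0) "poor" else if (k <= 0.20) "slight" else
    if (k <= 0.40) "fair" else if (k <= 0.60) "moderate" else
      if (k <= 0.80) "substantial" else "almost perfect"
  list(kappa = k, p_o = p_o, p_e = p_e, label = label, undefined = FALSE)
}

#' Intraclass correlation ICC(2,1), absolute agreement
#'
#' Two-way random effects, absolute agreement, single rater, from the standard
#' mean-square decomposition (items = rows, raters = columns):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the
#' conventional F-based confidence interval (Satterthwaite df for the lower
#' denominator).
#'
#' @param ratings numeric matrix, items x raters (>= 2 each), no missing
#'   cells.
#' @param conf confidence level (default 0.95).
#' @return list: `icc`, `lower`, `upper`, `conf`, and the mean squares
#'   `MSR`, `MSC`, `MSE`.
#' @export
icc_absolute <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 items and >= 2 raters")
  if (anyNA(ratings)) stop("missing cells are not supported")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings); col_m <- colMeans(ratings)
  SSR <- k * sum((row_m - grand)^2)          # between items
  SSC <- n * sum((col_m - grand)^2)          # between raters
  SST <- sum((ratings - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR <= 0) stop("zero between-item variance")
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)

  alpha <- 1 - conf
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * MSC + b * MSE)^2 /
    ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, lower = lower, upper = upper, conf = conf,
       MSR = MSR, MSC = MSC, MSE = MSE)
}

#' Inter-reader coefficient of variation for one feature
#'
#' Per item, `CV = 100 * sd(readers) / mean(readers)` (the sign of the mean is
#' carried, so negative-valued features such as skewness can yield negative
#' CVs); the per-feature summary is the mean of the per-item CVs. Items with
#' zero mean are flagged and excluded from the summary.
#'
#' @param values numeric matrix, items x readers (>= 2 readers).
#' @return list: `cv` (mean percent CV over usable items), `per_item`
#'   (percent CV per item, `NA` where flagged), `excluded_items` (indices
#'   with zero mean).
#' @export
interreader_feature_cv <- function(values) {
  values <- as.matrix(values)
  if (ncol(values) < 2) stop("need >= 2 readers")
  m <- rowMeans(values)
  s <- apply(values, 1, stats::sd)
  per_item <- ifelse(m != 0, 100 * s / m, NA_real_)
  excluded <- which(m == 0)
  list(cv = mean(per_item[m != 0]), per_item = per_item,
       excluded_items = excluded)
}

#' Inter-reader CV table over many features
#'
#' @param per_reader list of per-reader data frames sharing an item order and
#'   the same feature columns.
#' @param features feature columns (default: the 19 texture names).
#' @return data frame `feature`, `cv` (mean percent CV over items).
#' @export
interreader_cv_table <- function(per_reader, features = texture_feature_names()) {
  stopifnot(length(per_reader) >= 2)
  data.frame(
    feature = features,
    cv = vapply(features, function(f) {
      interreader_feature_cv(sapply(per_reader, function(df) df[[f]]))$cv
    }, numeric(1)),
    row.names = NULL)
}
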