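#' Configuration for the synthetic breast-CT phantom
#'
#' The phantom emulates coronal breast-CT examinations: 50 coronal slices of
#' 0.3 mm isotropic pixels, a roughly disk-shaped breast cross-section, and a
#' two-component tissue intensity model (a low fat peak and a high gland peak)
#' whose gland volume fraction grows with the four-level density class a-d.
#' Gland/fat texture is spatially correlated: a per-slice Gaussian random field
#' is smoothed to `correlation_length_px` and thresholded at the
#' `1 - gland_fraction` quantile, producing connected gland regions interleaved
#' by fatty septae.
#'
#' @param n_slices slices per examination (default 50).
#' @param slice_shape `c(rows, cols)` in pixels (default 256 x 256).
#' @param pixel_spacing_mm in-plane spacing (default 0.3).
#' @param breast_radius_frac breast-disk radius as a fraction of the half-width
#'   (default 0.9).
#' @param gland_fraction_by_class named fractions in `[0, 1]` for classes
#'   a-d; must be strictly increasing a to d
#'   (defaults a 0.10, b 0.35, c 0.60, d 0.85).
#' @param fat_mean,gland_mean tissue intensities in arbitrary units
#'   (defaults 30 and 70; `gland_mean > fat_mean`).
#' @param noise_sd additive Gaussian noise sd (default 5, > 0).
#' @param correlation_length_px smoothing sigma of the texture field in pixels
#'   (default 10, >= 1).
#' @param seed default master seed carried by the config.
#' @return an object of class `phantom_config`.
#' @export
phantom_config <- function(n_slices = 50L,
                           slice_shape = c(256L, 256L),
                           pixel_spacing_mm = 0.3,
                           breast_radius_frac = 0.9,
                           gland_fraction_by_class =
                             c(a = 0.10, b = 0.35, c = 0.60, d = 0.85),
                           fat_mean = 30,
                           gland_mean = 70,
                           noise_sd = 5,
                           correlation_length_px = 10,
                           seed = 1L) {
  if (n_slices < 1 || any(slice_shape < 8)) stop("non-positive dimensions")
  g <- gland_fraction_by_class
  if (!all(c("a", "b", "c", "d") %in% names(g)))
    stop("gland_fraction_by_class needs entries a, b, c, d")
  g <- g[c("a", "b", "c", "d")]
  if (any(g < 0 | g > 1)) stop("gland fractions must lie in [0, 1]")
  if (any(diff(g) <= 0)) stop("gland fractions must increase strictly a -> d")
  if (gland_mean <= fat_mean) stop("gland_mean must exceed fat_mean")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (correlation_length_px < 1) stop("correlation_length_px must be >= 1")
  structure(
    list(n_slices = as.integer(n_slices),
         slice_shape = as.integer(slice_shape),
         pixel_spacing_mm = pixel_spacing_mm,
         breast_radius_frac = breast_radius_frac,
         gland_fraction_by_class = g,
         fat_mean = fat_mean, gland_mean = gland_mean,
         noise_sd = noise_sd,
         correlation_length_px = correlation_length_px,
         seed = as.integer(seed)),
    class = "phantom_config")
}

density_classes <- function() c("a", "b", "c", "d")

# breast support: pixels whose center lies within the breast disk
phantom_support <- function(config) {
  nr <- config$slice_shape[1]; nc <- config$slice_shape[2]
  cy <- (nr - 1) / 2; cx <- (nc - 1) / 2
  R <- config$breast_radius_frac * (min(nr, nc) / 2)
  yy <- matrix(0:(nr - 1), nr, nc)
  xx <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  list(mask = (xx - cx)^2 + (yy - cy)^2 <= R^2, center = c(cx, cy), radius = R)
}

#' Generate one synthetic phantom examination
#'
#' For each slice a smoothed Gaussian random field is thresholded at the
#' `1 - gland_fraction` quantile within the breast support; gland pixels take
#' `gland_mean`, fat pixels `fat_mean`, independent Gaussian noise of sd
#' `noise_sd` is added, and pixels outside the support are 0. Deterministic
#' given `(config, density_class, seed)`.
#'
#' @param config a [phantom_config()].
#' @param density_class one of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param seed integer seed for this examination.
#' @param gland_fraction optional override of the class gland fraction
#'   (e.g. 0 or 1 for degenerate checks).
#' @return an object of class `phantom_exam` with fields `stack`
#'   ([image_stack()]), `density_label`, `true_gland_fraction` (the realized
#'   within-support gland pixel fraction) and `seed`.
#' @export
generate_phantom_exam <- function(config, density_class, seed,
                                  gland_fraction = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!density_class %in% density_classes())
    stop("unknown density class: ", density_class)
  g <- gland_fraction %||% config$gland_fraction_by_class[[density_class]]
  nr <- config$slice_shape[1]; nc <- config$slice_shape[2]
  sup <- phantom_support(config)$mask
  n_sup <- sum(sup)

  set.seed(as.integer(seed))
  noise_field <- array(stats::rnorm(nr * nc * config$n_slices),
                       c(nr, nc, config$n_slices))
  sigma <- config$correlation_length_px
  ksize <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  kern <- EBImage::makeBrush(ksize, "gaussian", sigma = sigma)
  field <- EBImage::filter2(noise_field, kern, boundary = "circular")

  vox <- array(0, c(nr, nc, config$n_slices))
  n_gland <- 0L
  gauss <- stats::rnorm(n_sup * config$n_slices, sd = config$noise_sd)
  for (k in seq_len(config$n_slices)) {
    f <- field[, , k]
    gland <- if (g >= 1) sup else if (g <= 0) sup & FALSE else
      sup & (f > stats::quantile(f[sup], 1 - g))
    n_gland <- n_gland + sum(gland)
    sl <- matrix(0, nr, nc)
    sl[sup] <- config$fat_mean +
      (config$gland_mean - config$fat_mean) * gland[sup] +
      gauss[(k - 1L) * n_sup + seq_len(n_sup)]
    vox[, , k] <- sl
  }
  structure(
    list(stack = image_stack(vox, config$pixel_spacing_mm),
         density_label = density_class,
         true_gland_fraction = n_gland / (n_sup * config$n_slices),
         seed = as.integer(seed)),
    class = "phantom_exam")
}

#' @export
print.phantom_exam <- function(x, ...) {
  cat(sprintf("<phantom_exam> class %s, gland fraction %.3f, seed %d\n",
              x$density_label, x$true_gland_fraction, x$seed))
  invisible(x)
}

# reproducible per-exam seed stream below 2^31
derive_exam_seed <- function(master_seed, index) {
  as.integer((as.numeric(master_seed) * 10007 + index * 7919) %% 2147483629 + 1)
}

#' Generate a balanced phantom cohort
#'
#' `4 * n_per_class` examinations, `n_per_class` of each density class, with
#' per-exam seeds derived reproducibly from the master seed.
#'
#' @inheritParams generate_phantom_exam
#' @param n_per_class examinations per density class (>= 1).
#' @param seed master seed (defaults to `config$seed`).
#' @return list of [generate_phantom_exam()] results, classes in order
#'   a, b, c, d repeated.
#' @export
generate_cohort <- function(config, n_per_class, seed = config$seed) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  plan <- cohort_plan(n_per_class, seed)
  lapply(seq_len(nrow(plan)), function(i)
    generate_phantom_exam(config, plan$class[i], plan$seed[i]))
}

# exam id / class / seed table shared by generate_cohort and the streaming path
cohort_plan <- function(n_per_class, seed) {
  classes <- rep(density_classes(), each = n_per_class)
  data.frame(
    exam_id = sprintf("%s%02d", classes, rep(seq_len(n_per_class), times = 4)),
    class = classes,
    seed = vapply(seq_along(classes), function(i) derive_exam_seed(seed, i),
                  integer(1)),
    stringsAsFactors = FALSE)
}

#' Default circular ROI for a phantom examination
#'
#' The drawn ROI of a phantom is the boundary of its breast-support disk,
#' approximated by a regular polygon; the skin margin is applied downstream by
#' [derive_roi_mask()].
#'
#' @param config a [phantom_config()].
#' @param margin_mm skin margin (default 5).
#' @param n_vertices polygon resolution (default 72).
#' @return an [roi_spec()].
#' @export
phantom_roi <- function(config, margin_mm = 5, n_vertices = 72L) {
  sup <- phantom_support(config)
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  poly <- cbind(sup$center[1] + sup$radius * cos(th),
                sup$center[2] + sup$radius * sin(th))
  # clamp just inside the raster for tangent circles
  poly[, 1] <- pmin(pmax(poly[, 1], 0), config$slice_shape[2] - 1)
  poly[, 2] <- pmin(pmax(poly[, 2], 0), config$slice_shape[1] - 1)
  roi_spec(poly, margin_mm = margin_mm)
}

#' Write a phantom cohort to disk
#'
#' Writes one stack file per examination plus a cohort manifest CSV with
#' columns `exam_id`, `class`, `seed`, `true_gland_fraction`, `path`.
#'
#' @inheritParams generate_cohort
#' @param out_dir output directory (created if missing).
#' @param format `"nii"` (default, lossless float + spacing) or `"tif"`
#'   (16-bit integer grey values).
#' @return the manifest data frame, invisibly.
#' @export
write_cohort <- function(config, n_per_class, out_dir, seed = config$seed,
                         format = c("nii", "tif")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  plan <- cohort_plan(n_per_class, seed)
  plan$true_gland_fraction <- NA_real_
  plan$path <- NA_character_
  for (i in seq_len(nrow(plan))) {
    ex <- generate_phantom_exam(config, plan$class[i], plan$seed[i])
    p <- file.path(out_dir, paste0(plan$exam_id[i], ".", format))
    st <- ex$stack
    if (format == "tif") st$voxels <- pmax(round(st$voxels), 0)
    write_image_stack(st, p)
    plan$true_gland_fraction[i] <- ex$true_gland_fraction
    plan$path[i] <- p
  }
  utils::write.csv(plan, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(plan)
}
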