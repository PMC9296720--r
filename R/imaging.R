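#' Construct a coronal image stack
#'
#' An examination is represented as a stack of coronal grey-value slices with a
#' common in-plane pixel spacing. Voxels are stored as a 3-D numeric array
#' `[row, column, slice]`.
#'
#' @param voxels numeric 3-D array `[row, column, slice]`, or a matrix for a
#'   single-slice stack.
#' @param pixel_spacing_mm in-plane pixel spacing in millimetres (> 0).
#' @return an object of class `image_stack` with fields `voxels`,
#'   `pixel_spacing_mm` and `n_slices`.
#' @export
image_stack <- function(voxels, pixel_spacing_mm = 0.3) {
  if (is.matrix(voxels)) voxels <- array(voxels, c(dim(voxels), 1L))
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a matrix or a 3-D array [row, column, slice]")
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1L ||
      !is.finite(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop("pixel_spacing_mm must be a single positive number")
  structure(
    list(voxels = voxels, pixel_spacing_mm = pixel_spacing_mm,
         n_slices = dim(voxels)[3L]),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_stack> %d slice(s) of %d x %d px, %.3g mm/px\n",
              d[3L], d[1L], d[2L], x$pixel_spacing_mm))
  invisible(x)
}

slice_shape <- function(stack) dim(stack$voxels)[1:2]

#' Read an image stack from a multi-page TIFF or NIfTI file
#'
#' Grey values of integer-typed inputs are preserved losslessly. Pixel spacing
#' is taken from the NIfTI header when available; TIFF files carry no reliable
#' spacing metadata, so the `pixel_spacing_mm` argument is used as fallback.
#'
#' @param path path to a `.tif`/`.tiff` or `.nii`/`.nii.gz` file.
#' @param pixel_spacing_mm fallback spacing when the file has none (default 0.3).
#' @return an [image_stack()].
#' @export
read_image_stack <- function(path, pixel_spacing_mm = 0.3) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    shapes <- vapply(pages, function(p) dim(p)[1:2], integer(2))
    if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
      stop("mixed slice shapes in ", path)
    vox <- array(0, c(shapes[, 1], length(pages)))
    for (k in seq_along(pages)) vox[, , k] <- pages[[k]]
    image_stack(vox, pixel_spacing_mm)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    vox <- as.array(img)
    if (length(dim(vox)) == 2L) vox <- array(vox, c(dim(vox), 1L))
    if (length(dim(vox)) != 3L) stop("expected a 2-D or 3-D NIfTI volume")
    sp <- RNifti::pixdim(img)[1L]
    if (!is.finite(sp) || sp <= 0) sp <- pixel_spacing_mm
    image_stack(vox, sp)
  } else {
    stop("unsupported stack format (need .tif/.tiff or .nii/.nii.gz): ", path)
  }
}

#' Write an image stack to TIFF or NIfTI
#'
#' TIFF output is 16-bit; grey values are rounded to integers and must lie in
#' 0..65535 (lossless round trip for integer stacks). NIfTI output stores the
#' voxel values as-is together with the pixel spacing.
#'
#' @param stack an [image_stack()].
#' @param path output path ending in `.tif`, `.tiff`, `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    v <- round(stack$voxels)
    if (min(v) < 0 || max(v) > 65535)
      stop("TIFF output requires grey values in 0..65535")
    pages <- lapply(seq_len(stack$n_slices), function(k) v[, , k] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(stack$voxels)
    RNifti::pixdim(img) <- rep(stack$pixel_spacing_mm, 3)
    RNifti::writeNifti(img, path)
  } else {
    stop("unsupported stack format: ", path)
  }
  invisible(path)
}

#' Specify a polygonal region of interest
#'
#' Vertices are 0-based `(column = x, row = y)` pixel coordinates; pixel
#' membership is decided at pixel centers (integer coordinates) by the even-odd
#' rule. The skin margin is applied by morphological erosion in
#' [derive_roi_mask()].
#'
#' @param polygon two-column matrix (or list of `c(x, y)` pairs) of vertices.
#' @param margin_mm skin margin in millimetres (default 5).
#' @param slices optional 1-based indices of the slices to analyse
#'   (default: all).
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(polygon, margin_mm = 5, slices = NULL) {
  if (is.list(polygon)) polygon <- do.call(rbind, polygon)
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("polygon needs at least 3 (x, y) vertices")
  if (!is.numeric(margin_mm) || margin_mm < 0)
    stop("margin_mm must be non-negative")
  structure(list(polygon = polygon, margin_mm = margin_mm, slices = slices),
            class = "roi_spec")
}

#' Read / write an ROI specification as JSON
#'
#' Format: `{"polygon": [[x, y], ...], "margin_mm": 5, "slices": [i, ...]}`.
#'
#' @param path JSON file path.
#' @return [read_roi_json()] returns an [roi_spec()]; [write_roi_json()]
#'   returns `path` invisibly.
#' @export
read_roi_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  roi_spec(j$polygon, margin_mm = j$margin_mm %||% 5, slices = j$slices)
}

#' @rdname read_roi_json
#' @param roi an [roi_spec()].
#' @export
write_roi_json <- function(roi, path) {
  jsonlite::write_json(
    list(polygon = unname(roi$polygon), margin_mm = roi$margin_mm,
         slices = roi$slices),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize a polygon onto one slice
#'
#' A pixel belongs to the mask iff its center `(x = column - 1, y = row - 1)`
#' satisfies the even-odd (ray crossing) rule for the polygon.
#'
#' @param roi an [roi_spec()] (or bare vertex matrix).
#' @param shape `c(n_rows, n_cols)` of the slice.
#' @return logical matrix of the given shape.
#' @export
polygon_to_mask <- function(roi, shape) {
  poly <- if (inherits(roi, "roi_spec")) roi$polygon else as.matrix(roi)
  if (nrow(poly) < 3L) stop("polygon needs at least 3 vertices")
  # shoelace: reject degenerate (zero-area) polygons
  xs <- poly[, 1]; ys <- poly[, 2]
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  if (abs(sum(xs * y2 - x2 * ys)) / 2 < .Machine$double.eps * 100)
    stop("zero-area polygon")
  nr <- shape[1]; nc <- shape[2]
  if (min(xs) < 0 || max(xs) > nc - 1 || min(ys) < 0 || max(ys) > nr - 1)
    stop("polygon vertices outside raster bounds")
  px <- rep(0:(nc - 1), each = nr)   # column-major over [row, col]
  py <- rep(0:(nr - 1), times = nc)
  inside <- rep(FALSE, nr * nc)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- xs[i]; yi <- ys[i]; xj <- xs[j]; yj <- ys[j]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nr, nc)
}

# disk structuring element of the given pixel radius (center distance <= r)
disk_kernel <- function(r) {
  d <- -r:r
  outer(d, d, function(a, b) as.numeric(a * a + b * b <= r * r))
}

erosion_radius_px <- function(margin_mm, pixel_spacing_mm) {
  as.integer(round(margin_mm / pixel_spacing_mm))
}

#' Derive the analysis mask for a stack from a polygonal ROI
#'
#' Rasterizes the polygon on one slice, erodes it by the skin margin
#' (`round(margin_mm / pixel_spacing_mm)` pixels, disk structuring element) and
#' propagates the eroded mask unchanged to every analysed slice, mirroring the
#' single drawn ROI reused across a multislice examination.
#'
#' @param stack an [image_stack()].
#' @param roi an [roi_spec()]. If `roi$slices` is set, slices not listed get an
#'   all-`FALSE` mask and are excluded from analysis.
#' @return logical 3-D array of the stack's dimensions.
#' @export
derive_roi_mask <- function(stack, roi) {
  stopifnot(inherits(stack, "image_stack"), inherits(roi, "roi_spec"))
  m <- polygon_to_mask(roi, slice_shape(stack))
  r <- erosion_radius_px(roi$margin_mm, stack$pixel_spacing_mm)
  if (r > 0) {
    m <- EBImage::erode(m * 1, disk_kernel(r)) > 0.5
  }
  if (!any(m))
    stop("eroded ROI is empty: ROI too small for a ", roi$margin_mm,
         " mm margin at ", stack$pixel_spacing_mm, " mm spacing")
  slices <- roi$slices %||% seq_len(stack$n_slices)
  if (any(slices < 1 | slices > stack$n_slices)) stop("slice index out of range")
  mask <- array(FALSE, dim(stack$voxels))
  for (k in slices) mask[, , k] <- m
  mask
}
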