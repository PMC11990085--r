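#' Morphological texture map
#'
#' Smooths the image with a disk structuring element so that intensity
#' variations smaller than the disk are removed: closing (dilation then
#' erosion, filling dark gaps) followed by opening (erosion then dilation,
#' removing small bright features). The resulting map responds to textured
#' tissue and is flat over empty background, which makes it a robust basis
#' for thresholding. NaN pixels are pre-filled with the background minimum
#' for the morphology and set back to NaN afterwards.
#'
#' @param image Numeric matrix (may contain NaN).
#' @param disk_radius Disk radius in pixels; must not exceed half the
#'   smaller image dimension.
#' @param order `"close_open"` (default) or `"open_close"`; the alternative
#'   order is exposed because either convention is defensible.
#' @return Numeric matrix of the same shape (NaN where the input was NaN).
#' @export
texture_map <- function(image, disk_radius = 15L,
                        order = c("close_open", "open_close")) {
  order <- match.arg(order)
  if (!is.matrix(image) || !is.numeric(image))
    sf_stop("argument", "image must be a numeric matrix")
  if (disk_radius > min(dim(image)) / 2)
    sf_stop("argument",
            "disk_radius (%d) exceeds half the smaller image dimension (%d)",
            as.integer(disk_radius), min(dim(image)))
  nanm <- !is.finite(image)
  x <- image
  if (any(nanm)) x[nanm] <- min(image[!nanm])
  se <- disk_se(disk_radius)
  out <- if (order == "close_open") morph_open(morph_close(x, se), se)
         else morph_close(morph_open(x, se), se)
  out[nanm] <- NaN
  out
}

#' Binarize a texture map into a tissue mask
#'
#' Thresholds the texture map (Otsu by default), then smooths the mask
#' boundary with a small morphological opening, fills holes, and removes
#' connected components below a minimum area.
#'
#' @param texture Texture map from [texture_map()].
#' @param method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold used when `method = "fixed"`.
#' @param smooth_radius Disk radius (px) of the boundary-smoothing opening.
#' @param min_area Minimum connected-component area (px) kept.
#' @param fill_holes Fill enclosed holes in the mask.
#' @param disk_radius_used Recorded provenance (radius used by the texture map).
#' @return A `tissue_mask`: list with logical `mask`, `coverage`,
#'   `disk_radius_used`, `threshold_used`.
#' @export
binarize_mask <- function(texture, method = c("otsu", "fixed"),
                          fixed_threshold = NULL, smooth_radius = 3L,
                          min_area = 25L, fill_holes = TRUE,
                          disk_radius_used = NA_integer_) {
  method <- match.arg(method)
  fin <- is.finite(texture)
  vals <- texture[fin]
  if (method == "otsu") {
    rng <- range(vals)
    if (diff(rng) == 0)
      sf_stop("degenerate_input", "texture map has a single value; Otsu thresholding is undefined")
    thr <- EBImage::otsu(matrix((vals - rng[1]) / diff(rng)), range = c(0, 1)) *
      diff(rng) + rng[1]
  } else {
    if (is.null(fixed_threshold) || !is.finite(fixed_threshold))
      sf_stop("argument", "fixed_threshold must be supplied for method = 'fixed'")
    thr <- fixed_threshold
  }
  mask <- !is.na(texture) & texture > thr
  mask[!fin] <- FALSE
  if (any(mask) && smooth_radius >= 1L && min(dim(mask)) > 2 * smooth_radius) {
    sm <- morph_open(mask + 0, disk_se(smooth_radius)) > 0.5
    if (any(sm)) mask <- sm   # don't let smoothing annihilate a small mask
  }
  if (fill_holes && any(mask)) mask <- EBImage::fillHull(mask + 0L) > 0L
  if (any(mask) && min_area > 1L) {
    lab <- label8_cpp(mask)
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_area)
    mask <- matrix(lab %in% keep & lab > 0L, nrow(mask), ncol(mask))
  }
  if (!any(mask))
    sf_stop("no_tissue", "no tissue detected after mask cleanup; consider a lower threshold")
  structure(list(mask = mask, coverage = mean(mask),
                 disk_radius_used = disk_radius_used, threshold_used = thr),
            class = "tissue_mask")
}

mask_matrix <- function(mask, dim = NULL) {
  m <- if (inherits(mask, "tissue_mask")) mask$mask else mask
  if (!is.null(dim) && !identical(base::dim(m), dim))
    sf_stop("argument", "mask shape does not match image shape")
  m
}

#' Apply a tissue mask to an image
#'
#' Pixels outside the mask are flagged as excluded (set to NaN) so that all
#' downstream per-row/per-column means ignore them.
#'
#' @param image Numeric matrix.
#' @param mask A `tissue_mask` or logical matrix of the same shape.
#' @return Numeric matrix with background set to NaN.
#' @export
masked_image <- function(image, mask) {
  m <- mask_matrix(mask, dim(image))
  image[!m] <- NaN
  image
}
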