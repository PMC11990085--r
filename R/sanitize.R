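#' Pipeline configuration
#'
#' Collects every tunable of the correction pipeline with its default.
#' Defaults follow the method description: 1% of pixels withheld, Otsu
#' tissue thresholding on a disk-texture map, tile periods of at least
#' 64 px considered, a refinement moving-average window of 51 px.
#'
#' @param withhold_fraction Fraction of finite pixels temporarily withheld
#'   (brightest first) before processing; in (0, 0.5).
#' @param disk_radius_texture Disk radius (px) of the texture filter used to
#'   isolate tissue.
#' @param mask_threshold_method `"otsu"` or `"fixed"`.
#' @param fixed_threshold Threshold used when `mask_threshold_method = "fixed"`.
#' @param morphology_order `"close_open"` (closing then opening) or
#'   `"open_close"`; see [texture_map()].
#' @param min_tile_period Smallest tile period (px) the detector may report.
#' @param prominence_frac A spectral peak qualifies as the tile frequency when
#'   its prominence is at least this fraction of the largest non-DC magnitude.
#' @param period_rows,period_cols Optional user-supplied tile periods (px);
#'   used directly and as fallback when detection finds no periodicity.
#' @param offset_rows,offset_cols Optional grid offsets (px); estimated from
#'   the profile troughs when `NULL`.
#' @param envelope_smooth_window Moving-average window (px) for the envelope
#'   lines; `NULL` picks `max(31, round(period / 10))`.
#' @param multiplier_cap Correction multipliers are clipped to
#'   `[1/cap, cap]`; must be > 1.
#' @param refine_enabled Run the optional top-hat refinement stage
#'   (finishing touches) after the envelope passes.
#' @param refine_window Moving-average window (px, odd) for the residual
#'   refinement profiles.
#' @param bright_quantile Quantile defining the bright-spot suppression
#'   threshold in the refinement stage.
#' @param min_mask_coverage If the tissue mask covers less than this fraction
#'   of pixels (or masking fails), the pipeline falls back to treating every
#'   finite pixel as tissue.
#' @param background_ratio_max The mask is only honoured when the mean
#'   intensity of the excluded background is at most this fraction of the
#'   mean tissue intensity. Genuinely empty background (glass, outside-ROI
#'   padding) is several-fold dimmer than tissue; a "background" that is
#'   merely 2–3x dimmer is usually the shaded part of the content itself
#'   (the vignette), and masking it out would remove exactly the regions
#'   the correction needs to see, so the whole frame is used instead.
#' @param mask_downsample Integer stride used to downsample the image for
#'   tissue detection only (the mask is upsampled back); `NULL` picks
#'   automatically so the short side stays below ~1536 px. Tissue texture
#'   is coarse, so detection tolerates downsampling well, and on large
#'   mosaics it dominates the runtime otherwise.
#' @param force_unit_multipliers Diagnostic switch: skip all correction
#'   (multipliers forced to 1) while exercising the full pipeline plumbing.
#' @param verbose Emit progress messages.
#' @param seed Unused by the deterministic pipeline; recorded for provenance.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(withhold_fraction = 0.01,
                            disk_radius_texture = 15L,
                            mask_threshold_method = c("otsu", "fixed"),
                            fixed_threshold = NULL,
                            morphology_order = c("close_open", "open_close"),
                            min_tile_period = 64L,
                            prominence_frac = 0.1,
                            period_rows = NULL, period_cols = NULL,
                            offset_rows = NULL, offset_cols = NULL,
                            envelope_smooth_window = NULL,
                            multiplier_cap = 5,
                            refine_enabled = FALSE,
                            refine_window = 51L,
                            bright_quantile = 0.99,
                            min_mask_coverage = 0.01,
                            background_ratio_max = 0.2,
                            mask_downsample = NULL,
                            force_unit_multipliers = FALSE,
                            verbose = FALSE,
                            seed = NULL) {
  cfg <- list(
    withhold_fraction = withhold_fraction,
    disk_radius_texture = as.integer(disk_radius_texture),
    mask_threshold_method = match.arg(mask_threshold_method),
    fixed_threshold = fixed_threshold,
    morphology_order = match.arg(morphology_order),
    min_tile_period = as.integer(min_tile_period),
    prominence_frac = prominence_frac,
    period_rows = period_rows, period_cols = period_cols,
    offset_rows = offset_rows, offset_cols = offset_cols,
    envelope_smooth_window = envelope_smooth_window,
    multiplier_cap = multiplier_cap,
    refine_enabled = isTRUE(refine_enabled),
    refine_window = as.integer(refine_window),
    bright_quantile = bright_quantile,
    min_mask_coverage = min_mask_coverage,
    background_ratio_max = background_ratio_max,
    mask_downsample = if (!is.null(mask_downsample)) as.integer(mask_downsample),
    force_unit_multipliers = isTRUE(force_unit_multipliers),
    verbose = isTRUE(verbose),
    seed = seed
  )
  if (!is.numeric(cfg$withhold_fraction) || cfg$withhold_fraction <= 0 ||
      cfg$withhold_fraction >= 0.5)
    sf_stop("argument", "withhold_fraction must lie in (0, 0.5)")
  if (cfg$disk_radius_texture < 1L || cfg$min_tile_period < 1L ||
      cfg$refine_window < 3L)
    sf_stop("argument", "radii and windows must be positive integers")
  if (cfg$multiplier_cap <= 1) sf_stop("argument", "multiplier_cap must be > 1")
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Sanitize a mosaic before processing
#'
#' NaN pixels are left untouched (and excluded from all statistics), Inf
#' pixels are set to the maximum finite value, and the brightest pixels —
#' the top `withhold_fraction` of finite intensities, or all fully saturated
#' pixels if those are more numerous — are temporarily withheld: replaced by
#' the mean tissue intensity and recorded so [restore_rescale()] can put the
#' original values back. Ties at the cutoff are broken by scan (row-major)
#' order so the operation is deterministic.
#'
#' @param m A [mosaic_image()] or numeric matrix.
#' @param cfg A [pipeline_config()].
#' @param tissue_mean Replacement value; the mean intensity of the tissue if
#'   a mask is available, else the mean of all finite pixels (the default,
#'   used as a provisional estimate because the mask is built later).
#' @return A list with `image` (sanitized [mosaic_image()]) and `record`
#'   (class `sanitization_record`: data frame `withheld` with columns
#'   `row`, `col`, `value`, plus `replacement_value`, `inf_count`,
#'   `withheld_fraction`, `work_range`).
#' @export
sanitize_mosaic <- function(m, cfg = pipeline_config(), tissue_mean = NULL) {
  m <- as_mosaic(m)
  p <- m$pixels
  fin <- is.finite(p)
  n_fin <- sum(fin)
  if (n_fin == 0L) sf_stop("empty_image", "image has no finite pixels")
  inf_idx <- which(is.infinite(p))
  max_fin <- max(p[fin])
  if (length(inf_idx)) {
    p[inf_idx] <- max_fin
    fin <- is.finite(p)
    n_fin <- sum(fin)
  }
  if (is.null(tissue_mean)) tissue_mean <- mean(p[fin])
  if (!is.numeric(tissue_mean) || length(tissue_mean) != 1L || !is.finite(tissue_mean))
    sf_stop("argument", "tissue_mean must be a finite scalar")

  n_sat <- if (!is.null(m$saturation_level)) {
    sum(p[fin] >= m$saturation_level)
  } else {
    length(inf_idx)  # no known ceiling: only formerly-Inf pixels count
  }
  n_wh <- max(ceiling(cfg$withhold_fraction * n_fin), n_sat)
  n_wh <- min(n_wh, n_fin)

  fin_idx <- which(fin)
  ord <- order(p[fin_idx], fin_idx, decreasing = c(TRUE, FALSE), method = "radix")
  wh_idx <- fin_idx[ord[seq_len(n_wh)]]
  keep_idx <- fin_idx[ord[-seq_len(n_wh)]]
  work_range <- if (length(keep_idx)) range(p[keep_idx]) else range(p[wh_idx])

  rc <- arrayInd(wh_idx, dim(p))
  record <- structure(list(
    withheld = data.frame(row = rc[, 1], col = rc[, 2], value = p[wh_idx]),
    replacement_value = tissue_mean,
    inf_count = length(inf_idx),
    withheld_fraction = n_wh / n_fin,
    work_range = work_range
  ), class = "sanitization_record")

  p[wh_idx] <- tissue_mean
  out <- mosaic_image(p, saturation_level = m$saturation_level)
  out$source_range <- m$source_range  # keep the original range on record
  list(image = out, record = record)
}

empty_sanitization_record <- function(work_range) {
  structure(list(
    withheld = data.frame(row = integer(), col = integer(), value = numeric()),
    replacement_value = NA_real_, inf_count = 0L,
    withheld_fraction = 0, work_range = work_range
  ), class = "sanitization_record")
}

#' Restore withheld pixels and re-normalize to the original range
#'
#' The corrected image is mapped by a single global affine transform back
#' into the original intensity range, after which every withheld pixel is
#' set back to its recorded original value. Because the correction
#' multipliers lift shaded pixels to (approximately) their ideal values in
#' the input's own units, the corrected image is already on the input's
#' scale; the affine therefore anchors the minimum exactly to the original
#' minimum and only *expands* the upper end toward the original range when
#' the correction left the image narrower than the input — pixels the
#' correction legitimately brightened beyond the non-withheld working range
#' are never compressed back (doing so would undo the correction for the
#' image's brightest content, and an affine anchored on a single amplified
#' pixel can darken the whole image). Values are finally clipped to the
#' original source range. When the correction was the identity the anchors
#' coincide and the pixels are returned untouched, bit-exactly. Because the
#' withheld set contains the brightest original pixels (including the
#' original maximum) and never the minimum, the output's finite min/max
#' equal the input's. NaN pixels remain NaN.
#'
#' @param corrected Corrected image ([mosaic_image()] or matrix).
#' @param record The `sanitization_record` from [sanitize_mosaic()] (or from
#'   `empty_sanitization_record()` when nothing was withheld).
#' @param original The original input [mosaic_image()].
#' @return A restored [mosaic_image()].
#' @export
restore_rescale <- function(corrected, record, original) {
  corrected <- as_mosaic(corrected)
  original <- as_mosaic(original)
  if (!identical(dim(corrected$pixels), dim(original$pixels)))
    sf_stop("argument", "corrected and original images must have the same shape")
  p <- corrected$pixels
  fin <- is.finite(p)
  wh <- record$withheld
  # Anchors come from the pixels that remain in the output: withheld
  # positions currently hold corrected placeholder values that are about to
  # be overwritten by their originals, so they must not drive the map.
  sel <- fin
  if (nrow(wh)) sel[cbind(wh$row, wh$col)] <- FALSE
  if (!any(sel)) sel <- fin
  cr <- range(p[sel])
  src_rng <- original$source_range
  tmin <- record$work_range[1]
  tmax <- min(max(record$work_range[2], cr[2]), src_rng[2])
  if (diff(cr) == 0) {
    warning("corrected image is constant; renormalization maps it to the range minimum")
    p[fin] <- tmin
  } else if (!(cr[1] == tmin && cr[2] == tmax)) {
    p[fin] <- (p[fin] - cr[1]) / diff(cr) * (tmax - tmin) + tmin
  }  # else: identity map, leave values untouched bit-exactly
  p[fin] <- pmin(pmax(p[fin], src_rng[1]), src_rng[2])
  if (nrow(wh)) p[cbind(wh$row, wh$col)] <- wh$value
  p[original$nan_mask] <- NaN
  mosaic_image(p, saturation_level = original$saturation_level)
}
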