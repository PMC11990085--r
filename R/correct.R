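log_msg <- function(cfg, ...) if (isTRUE(cfg$verbose)) message(sprintf(...))

# Build the tissue mask with graceful fallback. Masking exists to exclude
# *empty* background (non-rectangular ROIs, slide glass); it is only
# honoured when the excluded pixels are substantially darker than the
# tissue. Sparse or texture-free images (particle fields, flat phantoms)
# defeat Otsu on the texture map, in which case every finite pixel is
# treated as tissue.
build_tissue_mask <- function(pixels, cfg) {
  # Tissue detection may run on a downsampled copy (the texture scale is
  # coarse anyway); the boolean mask is then upsampled to full resolution.
  ds <- cfg$mask_downsample %||% max(1L, ceiling(min(dim(pixels)) / 1536))
  res <- tryCatch({
    pxd <- if (ds > 1L)
      pixels[seq(1L, nrow(pixels), by = ds), seq(1L, ncol(pixels), by = ds)]
    else pixels
    tex <- texture_map(pxd, cfg$disk_radius_texture, order = cfg$morphology_order)
    mk <- binarize_mask(tex, method = cfg$mask_threshold_method,
                        fixed_threshold = cfg$fixed_threshold,
                        disk_radius_used = cfg$disk_radius_texture)
    if (ds > 1L) {
      mk$mask <- mk$mask[(seq_len(nrow(pixels)) - 1L) %/% ds + 1L,
                         (seq_len(ncol(pixels)) - 1L) %/% ds + 1L]
      mk$mask <- mk$mask & is.finite(pixels)
      mk$coverage <- mean(mk$mask)
      if (!any(mk$mask)) sf_stop("no_tissue", "no tissue detected")
    }
    mk
  }, stitchflat_error = function(e) e)
  reason <- NULL
  if (inherits(res, "tissue_mask")) {
    if (res$coverage >= cfg$min_mask_coverage) {
      bg <- pixels[!res$mask & is.finite(pixels)]
      ts <- pixels[res$mask & is.finite(pixels)]
      if (length(bg) == 0L || mean(ts) <= 0 ||
          mean(bg) <= cfg$background_ratio_max * mean(ts))
        return(res)
      reason <- sprintf("excluded background not empty (mean %.3g vs tissue %.3g)",
                        mean(bg), mean(ts))
    } else {
      reason <- sprintf("coverage %.4f below %.4f", res$coverage, cfg$min_mask_coverage)
    }
  } else reason <- conditionMessage(res)
  log_msg(cfg, "tissue mask fallback (%s): treating all finite pixels as tissue", reason)
  mask <- is.finite(pixels)
  structure(list(mask = mask, coverage = mean(mask),
                 disk_radius_used = NA_integer_, threshold_used = NA_real_),
            class = "tissue_mask")
}

detect_axis <- function(profile, cfg, user_period, user_offset) {
  if (!is.null(user_period)) {
    period <- user_period
    prominence <- NA_real_
  } else {
    det <- detect_period(profile, cfg$min_tile_period, cfg$prominence_frac)
    period <- det$period
    prominence <- det$prominence
  }
  offset <- user_offset %||% estimate_offset(profile, period)
  list(period = period, offset = offset, prominence = prominence)
}

#' Detect the stitched-tile grid of a mosaic
#'
#' Sanitizes the image, isolates tissue, computes the per-row and
#' per-column mean intensity profiles and recovers the tile period along
#' each axis from their frequency spectra. User-supplied periods/offsets in
#' the config short-circuit detection (and serve as fallback targets).
#'
#' @param m A [mosaic_image()] or numeric matrix.
#' @param cfg A [pipeline_config()].
#' @return A `tile_grid` (see [build_grid()]).
#' @export
detect_tile_grid <- function(m, cfg = pipeline_config()) {
  m <- as_mosaic(m)
  san <- sanitize_mosaic(m, cfg)
  mask <- build_tissue_mask(san$image$pixels, cfg)
  prof <- axis_profiles(masked_image(san$image$pixels, mask), mask)
  rows <- detect_axis(prof$rows, cfg, cfg$period_rows, cfg$offset_rows)
  cols <- detect_axis(prof$cols, cfg, cfg$period_cols, cfg$offset_cols)
  build_grid(rows$period, cols$period, rows$offset, cols$offset,
             shape = dim(m$pixels),
             prominence_rows = rows$prominence, prominence_cols = cols$prominence)
}

unit_multiplier <- function(n, axis, cap) {
  structure(list(values = rep(1, n), axis = axis, cap_used = cap),
            class = "multiplier1d")
}

axis_pass <- function(pixels, mask, axis, period, cfg) {
  prof <- axis_profiles(masked_image(pixels, mask), mask)[[axis]]
  ext <- find_extrema(prof, period)
  env <- build_envelope(prof, ext, period, smooth_window = cfg$envelope_smooth_window)
  envelope_multiplier(prof, env, cap = cfg$multiplier_cap,
                      smooth_window = cfg$envelope_smooth_window)
}

#' Correct vignetting on a stitched mosaic
#'
#' Full correction pipeline: sanitize (Inf handling, bright-pixel
#' withholding), tissue masking, tile-grid detection, sequential envelope
#' correction (the vertical multiplier from the per-row profile is applied
#' first, then the horizontal multiplier is derived from the corrected
#' image), optional top-hat refinement, and final restoration of the
#' withheld pixels with renormalization to the original intensity range.
#'
#' @param m A [mosaic_image()], numeric matrix, or path readable by
#'   [read_mosaic()].
#' @param cfg A [pipeline_config()].
#' @return An object of class `vignette_correction`: list with `image`
#'   (corrected [mosaic_image()]), `grid`, `mask`, `record`, and `report`
#'   (detected periods and prominences, multiplier ranges, and
#'   before/after profile flatness).
#' @examples
#' sim <- simulate_mosaic(sim_config(grid_n = 3, tile_px = 128, seed = 1))
#' res <- correct_vignetting(sim$image, pipeline_config(min_tile_period = 64))
#' res$report$period_rows
#' @export
correct_vignetting <- function(m, cfg = pipeline_config()) {
  if (is.character(m)) m <- read_mosaic(m)
  m <- as_mosaic(m)
  t0 <- proc.time()[["elapsed"]]

  san <- sanitize_mosaic(m, cfg)
  record <- san$record
  pixels <- san$image$pixels
  log_msg(cfg, "sanitize: %d px withheld (%.2f%%), %d Inf replaced",
          nrow(record$withheld), 100 * record$withheld_fraction, record$inf_count)

  mask <- build_tissue_mask(pixels, cfg)
  log_msg(cfg, "tissue mask: coverage %.3f", mask$coverage)

  prof <- axis_profiles(masked_image(pixels, mask), mask)
  rows <- detect_axis(prof$rows, cfg, cfg$period_rows, cfg$offset_rows)
  cols <- detect_axis(prof$cols, cfg, cfg$period_cols, cfg$offset_cols)
  grid <- build_grid(rows$period, cols$period, rows$offset, cols$offset,
                     shape = dim(pixels),
                     prominence_rows = rows$prominence,
                     prominence_cols = cols$prominence)
  log_msg(cfg, "tile grid: %d x %d tiles, periods %.1f / %.1f px (prominence %.2f / %.2f)",
          grid$n_rows, grid$n_cols, grid$period_rows, grid$period_cols,
          grid$peak_prominence_rows, grid$peak_prominence_cols)

  flat_before <- profile_flatness(m$pixels, mask, grid)

  if (cfg$force_unit_multipliers) {
    mult_r <- unit_multiplier(nrow(pixels), "rows", cfg$multiplier_cap)
    mult_c <- unit_multiplier(ncol(pixels), "cols", cfg$multiplier_cap)
    corrected <- pixels
  } else {
    mult_r <- axis_pass(pixels, mask, "rows", grid$period_rows, cfg)
    corrected <- apply_axis_multiplier(pixels, mult_r)
    mult_c <- axis_pass(corrected, mask, "cols", grid$period_cols, cfg)
    corrected <- apply_axis_multiplier(corrected, mult_c)
  }
  log_msg(cfg, "multipliers: rows [%.3f, %.3f], cols [%.3f, %.3f]",
          min(mult_r$values), max(mult_r$values),
          min(mult_c$values), max(mult_c$values))

  refined <- FALSE
  if (cfg$refine_enabled && !cfg$force_unit_multipliers) {
    thr <- quantile(corrected[is.finite(corrected)], cfg$bright_quantile,
                    names = FALSE)
    suppressed <- suppress_bright(corrected, thr)
    min_period <- min(grid$period_rows, grid$period_cols)
    disk_r <- max(1L, round(min_period / 2))
    if (disk_r <= min(dim(pixels)) / 2) {
      baseline <- tophat_baseline(suppressed, disk_r,
                                  max(1L, round(grid$period_cols)))
      field <- refine_multiplier(baseline, corrected, window = cfg$refine_window,
                                 mask = mask, period_rows = grid$period_rows,
                                 period_cols = grid$period_cols,
                                 cap = cfg$multiplier_cap)
      corrected <- apply_refinement(corrected, field)
      refined <- TRUE
      log_msg(cfg, "refinement applied: disk %d px, line %d px, window %d",
              disk_r, round(grid$period_cols), field$window_used)
    } else {
      log_msg(cfg, "refinement skipped: tile period too large for the image")
    }
  } else {
    log_msg(cfg, "refinement stage disabled; skipping")
  }

  restored <- restore_rescale(mosaic_image(corrected), record, m)
  flat_after <- profile_flatness(restored$pixels, mask, grid)

  report <- list(
    period_rows = grid$period_rows, period_cols = grid$period_cols,
    offset_rows = grid$offset_rows, offset_cols = grid$offset_cols,
    n_rows = grid$n_rows, n_cols = grid$n_cols,
    peak_prominence_rows = grid$peak_prominence_rows,
    peak_prominence_cols = grid$peak_prominence_cols,
    mask_coverage = mask$coverage,
    multiplier_range_rows = range(mult_r$values),
    multiplier_range_cols = range(mult_c$values),
    refined = refined,
    cv_rows_before = flat_before$cv_rows, cv_cols_before = flat_before$cv_cols,
    cv_rows_after = flat_after$cv_rows, cv_cols_after = flat_after$cv_cols,
    boundary_step_before = flat_before$boundary_step,
    boundary_step_after = flat_after$boundary_step,
    elapsed_s = proc.time()[["elapsed"]] - t0
  )
  structure(list(image = restored, grid = grid, mask = mask,
                 record = record, report = report,
                 multipliers = list(rows = mult_r, cols = mult_c)),
            class = "vignette_correction")
}

#' @export
print.vignette_correction <- function(x, ...) {
  r <- x$report
  cat(sprintf(paste0(
    "vignette_correction: %d x %d px\n",
    "  grid: %d x %d tiles, periods %.1f / %.1f px\n",
    "  profile CV rows %.4f -> %.4f, cols %.4f -> %.4f\n",
    "  boundary step %.4g -> %.4g%s\n"),
    x$image$shape[1], x$image$shape[2], r$n_rows, r$n_cols,
    r$period_rows, r$period_cols,
    r$cv_rows_before, r$cv_rows_after, r$cv_cols_before, r$cv_cols_after,
    r$boundary_step_before, r$boundary_step_after,
    if (r$refined) " (refined)" else ""))
  invisible(x)
}
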