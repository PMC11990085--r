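#' Suppress bright spots
#'
#' Pixels above a brightness threshold are replaced by the median of the
#' finite values in their 5x5 neighbourhood, computed on the unmodified
#' input (so clustered hot pixels do not contaminate each other's
#' replacements). Bright, sparse features would otherwise dominate the
#' top-hat baseline.
#'
#' @param image Numeric matrix (may contain NaN).
#' @param threshold Brightness threshold; must not lie below the image
#'   minimum (that would replace every pixel).
#' @return Matrix with bright spots replaced.
#' @export
suppress_bright <- function(image, threshold) {
  fin <- is.finite(image)
  if (!any(fin)) sf_stop("empty_image", "image has no finite pixels")
  if (threshold < min(image[fin]))
    sf_stop("argument", "threshold %g is below the image minimum %g; it would replace every pixel",
            threshold, min(image[fin]))
  idx <- which(fin & image > threshold, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(image)
  out <- image
  nr <- nrow(image); nc <- ncol(image)
  for (i in seq_len(nrow(idx))) {
    r <- idx[i, 1]; c <- idx[i, 2]
    win <- image[max(1, r - 2):min(nr, r + 2), max(1, c - 2):min(nc, c + 2)]
    win <- win[is.finite(win)]
    out[r, c] <- median(win)
  }
  out
}

#' Top-hat baseline image
#'
#' White top-hat filters the image with a disk and with a horizontal line
#' structuring element and takes their ratio. Both top-hats retain features
#' smaller than their element, but do so differently for anisotropic
#' structure, so the ratio is a flat tissue image preserving only coarse
#' morphology. The line top-hat (denominator) is floored at 5% of the
#' median of its positive values; a constant input, for which both top-hats
#' vanish identically, yields a baseline of ones by convention.
#'
#' @param image Numeric matrix (NaN pixels are pre-filled with the
#'   background minimum and restored afterwards).
#' @param disk_radius Disk element radius (px); typically half the tile
#'   period.
#' @param line_length Horizontal line element length (px); typically one
#'   tile period.
#' @return Baseline matrix (NaN where the input was NaN).
#' @export
tophat_baseline <- function(image, disk_radius, line_length) {
  if (disk_radius < 1L || line_length < 1L)
    sf_stop("argument", "structuring element sizes must be >= 1")
  nanm <- !is.finite(image)
  x <- image
  if (any(nanm)) x[nanm] <- min(image[!nanm])
  th_disk <- morph_tophat(x, disk_se(disk_radius))
  th_line <- morph_tophat(x, line_se(line_length, "horizontal"))
  if (max(abs(th_disk)) == 0 && max(abs(th_line)) == 0) {
    baseline <- matrix(1, nrow(x), ncol(x))
  } else {
    pos <- th_line[th_line > 0]
    if (length(pos) == 0L)
      sf_stop("numeric_guard",
              "line top-hat is nonpositive everywhere; cannot form a baseline ratio")
    baseline <- th_disk / pmax(th_line, 0.05 * median(pos))
  }
  baseline[nanm] <- NaN
  baseline
}

# Smooth, normalize to mean 1 over usable positions, constrain peaks to the
# mean peak height, clip to [1/cap, cap]; excluded positions get 1.
constrain_residual <- function(values, counts, window, period, cap) {
  ok <- is.finite(values) & counts > 0
  if (!any(ok)) sf_stop("degenerate_profile", "residual profile has no usable positions")
  v <- approx(which(ok), values[ok], xout = seq_along(values), rule = 2)$y
  v <- moving_average(v, window)
  v <- v / mean(v[ok])
  if (!is.null(period)) v <- constrain_peaks(v, period)
  v <- pmin(pmax(v, 1 / cap), cap)
  v[!ok] <- 1
  v
}

#' Residual refinement multipliers from the baseline
#'
#' Forms the divisor image baseline / current (denominator floored at 5% of
#' its median over tissue), reduces it to per-axis mean profiles over
#' tissue, smooths them with a moving-average window, normalizes them to
#' mean 1 (only the shape is meaningful; the global scale is absorbed by
#' the final renormalization), and applies the same peak-averaging
#' constraint and cap as the envelope multipliers.
#'
#' @param baseline Baseline image from [tophat_baseline()].
#' @param current Current working image (same shape).
#' @param window Moving-average window (px, odd).
#' @param mask Optional `tissue_mask` or logical matrix.
#' @param period_rows,period_cols Tile periods used by the peak constraint
#'   (`NULL` skips it).
#' @param cap Multiplier cap.
#' @return A `refine_field`: list with `baseline`, `divisor`,
#'   `residual_rows`, `residual_cols` (multiplier1d), `window_used`.
#' @export
refine_multiplier <- function(baseline, current, window = 51L, mask = NULL,
                              period_rows = NULL, period_cols = NULL, cap = 5) {
  if (!identical(dim(baseline), dim(current)))
    sf_stop("argument", "baseline and current image must have the same shape")
  if (window %% 2L == 0L) window <- window + 1L
  m <- if (is.null(mask)) is.finite(current) else mask_matrix(mask, dim(current))
  fin_pos <- current[m & is.finite(current) & current > 0]
  floor_cur <- if (length(fin_pos)) 0.05 * median(fin_pos) else .Machine$double.eps
  divisor <- baseline / pmax(current, floor_cur)
  prof <- axis_profiles(divisor, m)
  res_r <- constrain_residual(prof$rows$values, prof$rows$counts, window, period_rows, cap)
  res_c <- constrain_residual(prof$cols$values, prof$cols$counts, window, period_cols, cap)
  structure(list(
    baseline = baseline, divisor = divisor,
    residual_rows = structure(list(values = res_r, axis = "rows", cap_used = cap),
                              class = "multiplier1d"),
    residual_cols = structure(list(values = res_c, axis = "cols", cap_used = cap),
                              class = "multiplier1d"),
    window_used = as.integer(window)
  ), class = "refine_field")
}

#' Apply the refinement multipliers
#'
#' Sequential row-wise then column-wise multiplication by the residual
#' profiles, pulling the image toward the top-hat baseline while preserving
#' fine detail.
#'
#' @param image Numeric matrix.
#' @param field A [refine_multiplier()] result.
#' @return Refined matrix.
#' @export
apply_refinement <- function(image, field) {
  out <- apply_axis_multiplier(image, field$residual_rows)
  apply_axis_multiplier(out, field$residual_cols)
}
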