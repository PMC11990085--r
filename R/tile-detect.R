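#' Mean intensity profiles over tissue
#'
#' Per-row and per-column mean intensities computed over tissue pixels only.
#' Positions contributed to by no tissue pixel are excluded (NaN value,
#' count 0) and are ignored or interpolated by downstream steps.
#'
#' @param image Numeric matrix (background may already be NaN).
#' @param mask A `tissue_mask` or logical matrix; `NULL` uses every finite
#'   pixel.
#' @return A list with elements `rows` and `cols`, each an `axis_profile`:
#'   list of `values` (mean per position), `counts` (tissue pixels per
#'   position) and `axis`.
#' @export
axis_profiles <- function(image, mask = NULL) {
  if (is.null(mask)) mask <- is.finite(image)
  m <- mask_matrix(mask, dim(image))
  use <- m & is.finite(image)
  x <- image
  x[!use] <- 0
  cnt_r <- rowSums(use)
  cnt_c <- colSums(use)
  val_r <- ifelse(cnt_r > 0, rowSums(x) / cnt_r, NaN)
  val_c <- ifelse(cnt_c > 0, colSums(x) / cnt_c, NaN)
  list(rows = structure(list(values = val_r, counts = cnt_r, axis = "rows"),
                        class = "axis_profile"),
       cols = structure(list(values = val_c, counts = cnt_c, axis = "cols"),
                        class = "axis_profile"))
}

# Fill excluded/NaN positions by linear interpolation (flat extrapolation).
fill_profile <- function(profile) {
  v <- profile$values
  ok <- is.finite(v) & profile$counts > 0
  if (!any(ok)) sf_stop("degenerate_profile", "profile has no usable positions")
  if (all(ok)) return(v)
  approx(which(ok), v[ok], xout = seq_along(v), rule = 2)$y
}

# Local maxima of y with topographic prominence. Plateaus report their
# centre sample; signal ends count as lower neighbours. The prominence of a
# peak is its height above the higher of the two saddles separating it from
# higher ground (or from the signal ends).
local_peaks <- function(y) {
  n <- length(y)
  idx <- integer()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && y[j + 1L] == y[i]) j <- j + 1L  # plateau [i, j]
    left <- if (i == 1L) -Inf else y[i - 1L]
    right <- if (j == n) -Inf else y[j + 1L]
    if (y[i] > left && y[i] > right) idx <- c(idx, (i + j) %/% 2L)
    i <- j + 1L
  }
  prom <- vapply(idx, function(i) {
    h <- y[i]
    lb <- h; j <- i
    while (j > 1L && y[j - 1L] <= h) { j <- j - 1L; if (y[j] < lb) lb <- y[j] }
    rb <- h; j <- i
    while (j < n && y[j + 1L] <= h) { j <- j + 1L; if (y[j] < rb) rb <- y[j] }
    h - max(lb, rb)
  }, numeric(1))
  data.frame(idx = idx, height = y[idx], prominence = prom)
}

#' Detect the tile period of an intensity profile
#'
#' The profile is linearly interpolated over excluded positions, mean-
#' detrended, and Fourier transformed. Searching upward from the lowest
#' frequency, the first local maximum of the magnitude spectrum whose
#' topographic prominence reaches `prominence_frac` times the largest non-DC
#' magnitude is taken as the tile frequency; the period is its reciprocal in
#' pixels. Frequencies corresponding to periods below `min_tile_period` are
#' not considered (they belong to tissue features, not tiling).
#'
#' @param profile An `axis_profile` from [axis_profiles()].
#' @param min_tile_period Smallest admissible period (px).
#' @param prominence_frac Relative prominence a peak must reach to qualify.
#' @return List with `period` (px, possibly fractional) and `prominence`
#'   (relative to the strongest non-DC component).
#' @export
detect_period <- function(profile, min_tile_period = 64L, prominence_frac = 0.1) {
  v <- profile$values
  usable <- sum(is.finite(v) & profile$counts > 0)
  if (usable < 2L * min_tile_period)
    sf_stop("degenerate_profile",
            "profile has %d usable positions; need at least 2 * min_tile_period = %d",
            usable, 2L * min_tile_period)
  x <- fill_profile(profile)
  n <- length(x)
  x <- x - mean(x)
  mag <- Mod(fft(x))[seq_len(n %/% 2) + 1L]  # k = 1 .. n/2 cycles
  gmax <- max(mag)
  if (gmax == 0)
    sf_stop("no_periodicity", "profile is constant; no periodicity detected")
  kmax <- min(length(mag), floor(n / min_tile_period))
  if (kmax < 1L) sf_stop("no_periodicity", "profile too short for min_tile_period")
  pk <- local_peaks(mag[seq_len(min(length(mag), kmax + 1L))])
  pk <- pk[pk$idx <= kmax & pk$prominence >= prominence_frac * gmax, , drop = FALSE]
  if (nrow(pk) == 0L)
    sf_stop("no_periodicity",
            "no spectral peak with prominence >= %.2f of the maximum below the tile-frequency cap",
            prominence_frac)
  k <- pk$idx[1]
  list(period = n / k, prominence = pk$prominence[1] / gmax)
}

#' Estimate the tile-grid offset along one axis
#'
#' Tile boundaries sit at the troughs of the mean intensity profile, so the
#' offset is chosen as the circular shift of the boundary comb that
#' minimizes the mean profile value at boundary positions.
#'
#' @param profile An `axis_profile`.
#' @param period Tile period (px).
#' @return Offset in px (0-based, in `[0, period)`).
#' @export
estimate_offset <- function(profile, period) {
  x <- fill_profile(profile)
  n <- length(x)
  shifts <- seq(0L, max(0L, ceiling(period) - 1L))
  score <- vapply(shifts, function(o) {
    pos <- round(o + period * (0:floor((n - o) / period)))
    pos <- pos[pos >= 1 & pos <= n]
    if (!length(pos)) return(Inf)
    mean(x[pos])
  }, numeric(1))
  shifts[which.min(score)]
}

#' Build a tile grid from detected periods
#'
#' Boundary coordinates are `offset + k * period` for every integer `k`
#' keeping the coordinate strictly inside the image extent; the number of
#' tiles per axis is the extent divided by the period, rounded.
#'
#' @param period_rows,period_cols Tile periods (px).
#' @param offset_rows,offset_cols Grid offsets (px).
#' @param shape Image shape `c(rows, cols)`.
#' @param prominence_rows,prominence_cols Optional detection prominences,
#'   carried for reporting.
#' @return A `tile_grid` list.
#' @export
build_grid <- function(period_rows, period_cols,
                       offset_rows = 0, offset_cols = 0,
                       shape,
                       prominence_rows = NA_real_, prominence_cols = NA_real_) {
  if (period_rows <= 0 || period_cols <= 0)
    sf_stop("argument", "tile periods must be positive")
  one_axis <- function(period, offset, extent) {
    if (period > extent) {
      warning("tile period exceeds the image extent; assuming a single tile")
      return(list(boundaries = numeric(), n = 1L))
    }
    b <- offset + period * (0:ceiling(extent / period))
    b <- b[b > 0 & b < extent]
    list(boundaries = b, n = max(1L, as.integer(round(extent / period))))
  }
  rows <- one_axis(period_rows, offset_rows, shape[1])
  cols <- one_axis(period_cols, offset_cols, shape[2])
  structure(list(
    period_rows = period_rows, period_cols = period_cols,
    offset_rows = offset_rows, offset_cols = offset_cols,
    n_rows = rows$n, n_cols = cols$n,
    boundaries_rows = rows$boundaries, boundaries_cols = cols$boundaries,
    peak_prominence_rows = prominence_rows, peak_prominence_cols = prominence_cols
  ), class = "tile_grid")
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("tile_grid: %d x %d tiles, period %.1f x %.1f px, offsets (%.0f, %.0f)\n",
              x$n_rows, x$n_cols, x$period_rows, x$period_cols,
              x$offset_rows, x$offset_cols))
  invisible(x)
}
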