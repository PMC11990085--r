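#' Centred moving average
#'
#' Moving average with an odd window; at the signal ends the window shrinks
#' to the in-bounds samples so the output has the same length and no edge
#' bias toward zero.
#'
#' @param x Numeric vector (finite).
#' @param window Window width in samples (forced odd).
#' @return Smoothed vector of the same length.
#' @export
moving_average <- function(x, window) {
  n <- length(x)
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  h <- (window - 1L) %/% 2L
  if (h == 0L || n == 1L) return(x)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(1L, i - h)
  hi <- pmin(n, i + h)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Greedy enforcement of a minimum index separation, keeping the most
# extreme candidates first (ties broken by index).
greedy_separate <- function(idx, height, minsep) {
  ord <- order(-height, idx)
  kept <- integer()
  for (i in idx[ord]) {
    if (!length(kept) || all(abs(kept - i) >= minsep)) kept <- c(kept, i)
  }
  sort(kept)
}

# Extrema of a plain numeric vector with a minimum separation, greedy from
# the most extreme value down. Used on profiles and on multipliers.
extrema_separated <- function(x, minsep, maxima = TRUE) {
  y <- if (maxima) x else -x
  pk <- local_peaks(y)
  if (nrow(pk) == 0L) return(integer())
  greedy_separate(pk$idx, pk$height, minsep)
}

#' Find tile-scale extrema of an intensity profile
#'
#' Local minima and maxima with an enforced minimum separation of 3/4 of
#' the tile period, so that tissue-feature wiggles inside a tile are
#' rejected and one trough per tile boundary / one peak per tile centre
#' survive. (True same-kind extrema are a full period apart; a half-period
#' rule would still admit ripple maxima sitting in the troughs, anywhere
#' between P/2 and P from a real peak.) Profile ends are handled by
#' reflecting the profile by half a period.
#'
#' @param profile An `axis_profile` (excluded positions are interpolated).
#' @param period Tile period in px (from [detect_period()] or user override).
#' @return List with `minima` and `maxima`, integer index vectors.
#' @export
find_extrema <- function(profile, period) {
  x <- fill_profile(profile)
  n <- length(x)
  hp <- max(2L, min(n - 1L, round(period / 2)))
  ext <- c(x[(hp + 1L):2L], x, x[(n - 1L):(n - hp)])
  minsep <- max(1L, round(period * 0.75))
  one_kind <- function(maxima) {
    pk <- local_peaks(if (maxima) ext else -ext)
    pk$idx <- pk$idx - hp              # back to original coordinates
    pk <- pk[pk$idx >= 1L & pk$idx <= n, , drop = FALSE]  # drop pad copies
    if (nrow(pk) == 0L) return(integer())
    greedy_separate(pk$idx, pk$height, minsep)
  }
  maxima <- one_kind(TRUE)
  minima <- one_kind(FALSE)
  if (length(minima) < 2L || length(maxima) < 2L)
    sf_stop("degenerate_profile",
            "fewer than 2 minima or maxima at the tile scale; profile has no tile structure")
  list(minima = minima, maxima = maxima)
}

#' Build the profile envelope
#'
#' The upper (lower) envelope is a monotone shape-preserving piecewise-cubic
#' interpolation through the profile maxima (minima), smoothed with a moving
#' average; the midline is their pointwise mean and represents the ideal
#' vignette-free profile.
#'
#' @param profile An `axis_profile`.
#' @param extrema Extrema from [find_extrema()] (or hand-picked knots).
#' @param period Tile period (px), recorded and used for the default
#'   smoothing window `max(31, round(period / 10))`.
#' @param smooth_window Moving-average window override (px).
#' @return An `envelope`: list with `upper`, `lower`, `midline`,
#'   `extrema_min_idx`, `extrema_max_idx`, `period_used`.
#' @export
build_envelope <- function(profile, extrema, period, smooth_window = NULL) {
  x <- fill_profile(profile)
  n <- length(x)
  w <- smooth_window %||% max(31L, round(period / 10))
  interp <- function(idx) {
    if (length(idx) == 1L) return(rep(x[idx], n))
    f <- splinefun(idx, x[idx], method = "monoH.FC")
    f(seq_len(n))
  }
  upper <- moving_average(interp(extrema$maxima), w)
  lower <- moving_average(interp(extrema$minima), w)
  structure(list(
    upper = upper, lower = lower, midline = (upper + lower) / 2,
    extrema_min_idx = extrema$minima, extrema_max_idx = extrema$maxima,
    period_used = period
  ), class = "envelope")
}

# Constrain the above-1 bumps of a multiplier so that no peak exceeds the
# mean peak height: the vignetting effect is assumed consistent between
# tiles, so an outsized per-tile peak is not trusted. Bumps are the
# contiguous runs above 1 (runs containing several separated peaks are
# split at the minima between them), each measured by its run maximum, and
# over-mean bumps are scaled down; sub-mean bumps are left alone — scaling
# a barely-above-1 noise bump up to the mean would inflate it by a huge
# factor and stamp an artifact band into the image.
constrain_peaks <- function(values, period) {
  peaks <- extrema_separated(values, max(1L, round(period / 2)), maxima = TRUE)
  peaks <- peaks[values[peaks] > 1]
  if (length(peaks) < 2L) return(values)
  n <- length(values)
  # split points: minima between consecutive peaks
  cuts <- vapply(seq_len(length(peaks) - 1L), function(i) {
    seg <- peaks[i]:peaks[i + 1L]
    seg[which.min(values[seg])]
  }, integer(1))
  lo_bound <- c(1L, cuts)
  hi_bound <- c(cuts, n)
  segs <- lapply(seq_along(peaks), function(i) {
    p <- peaks[i]
    lo <- p; while (lo > lo_bound[i] && values[lo - 1L] > 1) lo <- lo - 1L
    hi <- p; while (hi < hi_bound[i] && values[hi + 1L] > 1) hi <- hi + 1L
    lo:hi
  })
  heights <- vapply(segs, function(seg) max(values[seg]), numeric(1))
  mean_peak <- mean(heights)
  for (i in seq_along(segs)) {
    if (heights[i] <= mean_peak) next
    s <- (mean_peak - 1) / (heights[i] - 1)
    values[segs[[i]]] <- 1 + (values[segs[[i]]] - 1) * s
  }
  values
}

#' Correction multiplier from a profile envelope
#'
#' Divides the envelope midline by the smoothed profile (floored at 5% of
#' the midline), so that troughs — the shaded tile boundaries — are lifted
#' onto the midline. Smoothing the denominator with the same window as the
#' envelope keeps sampling noise in sparsely populated rows/columns out of
#' the multiplier. The multiplier's local peaks (one per tile boundary) are
#' then constrained so that none exceeds the mean peak height — the
#' vignetting effect is assumed consistent between tiles, so an outsized
#' per-tile peak is not trusted — and the result is clipped to
#' `[1/cap, cap]`. Positions with no tissue pixels get multiplier 1.
#'
#' @param profile The `axis_profile` the envelope was built from.
#' @param env An [build_envelope()] result.
#' @param cap Multiplier cap (> 1).
#' @param smooth_window Moving-average window for the denominator profile;
#'   `NULL` uses the same default as the envelope lines,
#'   `max(31, round(period / 10))` — wide enough to average out content
#'   variation (how much tissue happens to lie in each row) while still
#'   tracking the tile-scale trough shape.
#' @return A `multiplier1d`: list with positive `values`, `axis`, `cap_used`.
#' @export
envelope_multiplier <- function(profile, env, cap = 5, smooth_window = NULL) {
  if (cap <= 1) sf_stop("argument", "cap must be > 1")
  w <- smooth_window %||% max(31L, round(env$period_used / 10))
  x <- moving_average(fill_profile(profile), w)
  denom <- pmax(x, 0.05 * env$midline)
  if (any(denom <= 0) || any(!is.finite(env$midline)))
    sf_stop("numeric_guard",
            "nonpositive profile/midline after flooring (profile range [%g, %g], midline range [%g, %g])",
            min(x), max(x), min(env$midline), max(env$midline))
  raw <- env$midline / denom
  raw <- constrain_peaks(raw, env$period_used)
  vals <- pmin(pmax(raw, 1 / cap), cap)
  vals[!(is.finite(profile$values) & profile$counts > 0)] <- 1
  structure(list(values = vals, axis = profile$axis, cap_used = cap),
            class = "multiplier1d")
}

#' Apply a per-axis multiplier to an image
#'
#' Every pixel in row r (for a rows-axis multiplier) is multiplied by
#' `values[r]`; columns analogously. NaN pixels propagate NaN.
#'
#' @param image Numeric matrix.
#' @param mult A `multiplier1d` (or a plain numeric vector plus `axis`).
#' @param axis Used when `mult` is a plain vector.
#' @return The scaled matrix.
#' @export
apply_axis_multiplier <- function(image, mult, axis = NULL) {
  if (inherits(mult, "multiplier1d")) {
    axis <- mult$axis
    v <- mult$values
  } else v <- mult
  margin <- if (identical(axis, "rows")) 1L
            else if (identical(axis, "cols")) 2L
            else sf_stop("argument", "axis must be 'rows' or 'cols'")
  if (length(v) != dim(image)[margin])
    sf_stop("argument", "multiplier length %d does not match image extent %d",
            length(v), dim(image)[margin])
  sweep(image, margin, v, `*`)
}
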