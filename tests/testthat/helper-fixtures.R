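# Shared fixtures and independent oracles for the test suite.

# Brute-force grayscale morphology oracle: min/max over the structuring
# element, ignoring out-of-bounds neighbours. Deliberately naive.
brute_morph <- function(x, se, maximum) {
  r <- (nrow(se) - 1L) %/% 2L
  cth <- (ncol(se) - 1L) %/% 2L
  out <- x
  for (i in seq_len(nrow(x))) {
    for (j in seq_len(ncol(x))) {
      vals <- numeric()
      for (di in -r:r) {
        for (dj in -cth:cth) {
          if (!se[di + r + 1L, dj + cth + 1L]) next
          ii <- i + di; jj <- j + dj
          if (ii >= 1 && ii <= nrow(x) && jj >= 1 && jj <= ncol(x))
            vals <- c(vals, x[ii, jj])
        }
      }
      out[i, j] <- if (maximum) max(vals) else min(vals)
    }
  }
  out
}

brute_erode <- function(x, se) brute_morph(x, se, FALSE)
brute_dilate <- function(x, se) brute_morph(x, se, TRUE)
brute_open <- function(x, se) brute_dilate(brute_erode(x, se), se)
brute_close <- function(x, se) brute_erode(brute_dilate(x, se), se)

# Wrap a plain vector as an axis_profile (full counts).
as_profile <- function(values, axis = "rows", counts = rep(1L, length(values))) {
  structure(list(values = values, counts = counts, axis = axis),
            class = "axis_profile")
}

# Periodic trough-shaped gain with unit peaks: dips to (1 - dip) at tile
# boundaries, peaks at 1 mid-tile.
trough_gain <- function(x, period, dip) {
  t <- ((x - 1) %% period - period / 2) / (period / 2)
  1 - dip * t^2
}

# Flat-tissue image under a separable periodic gain.
separable_gain_image <- function(n, period, dip, level = 100) {
  level * outer(trough_gain(seq_len(n), period, dip),
                trough_gain(seq_len(n), period, dip))
}

# Small, fast simulation configuration used across tests.
small_sim <- function(seed, grid_n = 3L, tile_px = 256L, ...) {
  simulate_mosaic(sim_config(grid_n = grid_n, tile_px = tile_px,
                             seed = seed, ...))
}

scaled_pipeline_config <- function(...) {
  pipeline_config(min_tile_period = 64L, ...)
}
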