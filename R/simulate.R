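#' Simulation configuration
#'
#' Parameters of the synthetic vignetted-mosaic generator: a square grid of
#' square tiles, each seeded with 30–50 randomly placed particles of 4–10 px
#' diameter whose intensity scales with diameter, blurred by a truncated
#' Gaussian PSF (radius 21 px, sigma 2 px), overlaid with additive Gaussian
#' noise at 1% of the maximum intensity, and attenuated per tile by an
#' exponential off-centre vignette.
#'
#' @param grid_n Tiles per side.
#' @param tile_px Tile edge length (px).
#' @param particles_min,particles_max Particle count range per tile.
#' @param diam_min_px,diam_max_px Particle diameter range (px).
#' @param psf_radius_px,psf_sigma_px Truncation radius and sigma (px) of the
#'   Gaussian PSF.
#' @param noise_sigma_frac Noise standard deviation as a fraction of the
#'   image maximum.
#' @param vignette_decay Exponential decay rate k > 0: the per-tile gain is
#'   `exp(-k * d / D)` with `d` the distance from the tile's vignette centre
#'   and `D` the tile half-diagonal.
#' @param vignette_center_offset Offset (dr, dc) in px of the vignette
#'   centre from the tile centre; default `round(tile_px * c(0.05, 0.03))`
#'   so the off-centre pattern scales with the tile.
#' @param particles_per_image If `TRUE`, the particle count range applies to
#'   the whole mosaic instead of per tile.
#' @param seed Integer seed; every stochastic stage derives its stream from
#'   it (particles at `seed`, noise at `seed + 1`).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(grid_n = 5L, tile_px = 1024L,
                       particles_min = 30L, particles_max = 50L,
                       diam_min_px = 4, diam_max_px = 10,
                       psf_radius_px = 21L, psf_sigma_px = 2,
                       noise_sigma_frac = 0.01,
                       vignette_decay = 2,
                       vignette_center_offset = NULL,
                       particles_per_image = FALSE,
                       seed = NULL) {
  if (is.null(vignette_center_offset))
    vignette_center_offset <- round(tile_px * c(0.05, 0.03))
  cfg <- list(grid_n = as.integer(grid_n), tile_px = as.integer(tile_px),
              particles_min = as.integer(particles_min),
              particles_max = as.integer(particles_max),
              diam_min_px = diam_min_px, diam_max_px = diam_max_px,
              psf_radius_px = as.integer(psf_radius_px),
              psf_sigma_px = psf_sigma_px,
              noise_sigma_frac = noise_sigma_frac,
              vignette_decay = vignette_decay,
              vignette_center_offset = vignette_center_offset,
              particles_per_image = isTRUE(particles_per_image),
              seed = seed)
  if (cfg$grid_n < 1L || cfg$tile_px < 8L)
    sf_stop("argument", "grid_n must be >= 1 and tile_px >= 8")
  if (cfg$particles_min > cfg$particles_max || cfg$particles_min < 0L)
    sf_stop("argument", "particle count range invalid")
  if (cfg$diam_min_px > cfg$diam_max_px || cfg$diam_min_px <= 0)
    sf_stop("argument", "diameter range invalid")
  if (cfg$noise_sigma_frac < 0) sf_stop("argument", "noise_sigma_frac must be >= 0")
  structure(cfg, class = c("sim_config", "list"))
}

seed_stage <- function(seed, offset) {
  if (!is.null(seed)) set.seed(as.integer(seed) + offset)
}

#' Generate ground-truth particles
#'
#' Tiles are visited in row-major order; for each tile a particle count is
#' drawn uniformly from `[particles_min, particles_max]`, then for each
#' particle its centre (uniform within the tile), diameter (uniform in the
#' diameter range) and intensity `u * diameter` with `u ~ U(0.5, 1)` —
#' larger particles appear brighter.
#'
#' @param cfg A [sim_config()].
#' @return Data frame with columns `row`, `col` (continuous centre
#'   coordinates), `diameter`, `intensity`, `tile_row`, `tile_col`.
#' @export
generate_particles <- function(cfg) {
  seed_stage(cfg$seed, 0L)
  t <- cfg$tile_px
  draw <- function(n, r0, c0, tr, tc) {
    data.frame(row = r0 + runif(n) * t, col = c0 + runif(n) * t,
               diameter = runif(n, cfg$diam_min_px, cfg$diam_max_px),
               tile_row = tr, tile_col = tc)
  }
  if (cfg$particles_per_image) {
    n <- sample(cfg$particles_min:cfg$particles_max, 1L)
    s <- cfg$grid_n * t
    out <- data.frame(row = runif(n) * s, col = runif(n) * s,
                      diameter = runif(n, cfg$diam_min_px, cfg$diam_max_px),
                      tile_row = NA_integer_, tile_col = NA_integer_)
  } else {
    parts <- list()
    for (tr in seq_len(cfg$grid_n)) {
      for (tc in seq_len(cfg$grid_n)) {
        n <- sample(cfg$particles_min:cfg$particles_max, 1L)
        parts[[length(parts) + 1L]] <- draw(n, (tr - 1L) * t, (tc - 1L) * t, tr, tc)
      }
    }
    out <- do.call(rbind, parts)
  }
  out$intensity <- runif(nrow(out), 0.5, 1) * out$diameter
  rownames(out) <- NULL
  out[, c("row", "col", "diameter", "intensity", "tile_row", "tile_col")]
}

gaussian_kernel_1d <- function(radius, sigma) {
  g <- dnorm(seq(-radius, radius), sd = sigma)
  g / sum(g)
}

#' Render the clean particle mosaic
#'
#' Each particle is rasterized as a filled disk of its diameter at its base
#' intensity on a zero background (overlapping particles combine by
#' maximum), then the mosaic is convolved with the normalized truncated
#' Gaussian PSF.
#'
#' @param particles Data frame from [generate_particles()].
#' @param cfg A [sim_config()].
#' @return Numeric matrix of size `(grid_n * tile_px)^2`.
#' @export
render_mosaic <- function(particles, cfg) {
  s <- cfg$grid_n * cfg$tile_px
  img <- matrix(0, s, s)
  for (i in seq_len(nrow(particles))) {
    r0 <- particles$row[i]; c0 <- particles$col[i]
    rad <- particles$diameter[i] / 2
    rr <- max(1L, floor(r0 - rad)):min(s, ceiling(r0 + rad))
    cc <- max(1L, floor(c0 - rad)):min(s, ceiling(c0 + rad))
    d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
    patch <- img[rr, cc, drop = FALSE]
    hit <- d2 <= rad * rad
    patch[hit] <- pmax(patch[hit], particles$intensity[i])
    img[rr, cc] <- patch
  }
  if (nrow(particles) == 0L) return(img)
  conv_sep_cpp(img, gaussian_kernel_1d(cfg$psf_radius_px, cfg$psf_sigma_px))
}

#' Apply the per-tile exponential vignette
#'
#' Every tile is attenuated by the same gain pattern
#' `exp(-k * d / D)`, where `d` is the Euclidean distance from the tile's
#' vignette centre (tile centre plus the configured offset) and `D` the
#' tile half-diagonal, so the gain is 1 at the vignette centre and decays
#' toward the tile edges.
#'
#' @param image Mosaic matrix whose extent is divisible into
#'   `grid_n x grid_n` tiles.
#' @param cfg A [sim_config()].
#' @return List with `image` (attenuated) and `gain` (the full gain field).
#' @export
apply_vignette <- function(image, cfg) {
  if (cfg$vignette_decay <= 0) sf_stop("argument", "vignette_decay must be > 0")
  t <- cfg$tile_px
  if (nrow(image) %% t != 0L || ncol(image) %% t != 0L)
    sf_stop("argument", "image extent is not divisible into tiles of %d px", t)
  ctr <- (t + 1) / 2 + cfg$vignette_center_offset
  d <- sqrt(outer((seq_len(t) - ctr[1])^2, (seq_len(t) - ctr[2])^2, `+`))
  gain_tile <- exp(-cfg$vignette_decay * d / (t * sqrt(2) / 2))
  gain <- gain_tile[rep(seq_len(t), nrow(image) %/% t),
                    rep(seq_len(t), ncol(image) %/% t)]
  list(image = image * gain, gain = gain)
}

#' Add acquisition noise
#'
#' Additive zero-mean Gaussian noise with standard deviation
#' `noise_sigma_frac` times the image maximum; the result is floored at 0.
#'
#' @param image Mosaic matrix.
#' @param cfg A [sim_config()].
#' @return Noisy matrix.
#' @export
add_noise <- function(image, cfg) {
  if (cfg$noise_sigma_frac == 0) return(image)
  seed_stage(cfg$seed, 1L)
  s <- cfg$noise_sigma_frac * max(image, na.rm = TRUE)
  out <- image + rnorm(length(image), 0, s)
  out[out < 0] <- 0
  dim(out) <- dim(image)
  out
}

#' Simulate a vignetted stitched mosaic with ground truth
#'
#' Orchestrates [generate_particles()], [render_mosaic()], [add_noise()]
#' and [apply_vignette()] in that order: the blurred particle field picks
#' up acquisition noise and the optical gain then attenuates signal and
#' noise together, so the shaded margins are genuinely darker, not merely
#' noisier. Returns the final image alongside every ground-truth component.
#'
#' @param cfg A [sim_config()].
#' @return List with `image` (vignetted noisy mosaic), `clean` (blurred,
#'   noise- and vignette-free), `gain` (true gain field), `particles`
#'   (ground-truth table) and `config`.
#' @export
simulate_mosaic <- function(cfg = sim_config()) {
  particles <- generate_particles(cfg)
  clean <- render_mosaic(particles, cfg)
  noisy <- add_noise(clean, cfg)
  vig <- apply_vignette(noisy, cfg)
  list(image = vig$image, clean = clean, gain = vig$gain,
       particles = particles, config = cfg)
}

#' Tissue-like phantom with known support
#'
#' Places non-overlapping textured disks ("tissue blobs") on a flat zero
#' background; the true support mask is returned so segmentation quality
#' can be scored exactly. Optionally the area outside an inscribed circular
#' region of interest is set to NaN, emulating the non-rectangular scan
#' ROIs some acquisition systems produce.
#'
#' @param shape Image shape `c(rows, cols)`.
#' @param blob_count Number of blobs (connected support components).
#' @param seed Integer seed.
#' @param nan_border Set pixels outside the inscribed circular ROI to NaN.
#' @return List with `image` and logical `support`.
#' @export
tissue_phantom <- function(shape = c(256L, 256L), blob_count = 3L,
                           seed = NULL, nan_border = FALSE) {
  if (blob_count < 1L) sf_stop("argument", "blob_count must be >= 1")
  seed_stage(seed, 0L)
  nr <- shape[1]; nc <- shape[2]
  roi_r <- min(nr, nc) / 2 - 1
  ctr <- c((nr + 1) / 2, (nc + 1) / 2)
  rmin <- min(nr, nc) / 14; rmax <- min(nr, nc) / 8
  blobs <- matrix(numeric(), ncol = 3)
  tries <- 0L
  while (nrow(blobs) < blob_count && tries < 10000L) {
    tries <- tries + 1L
    rad <- runif(1, rmin, rmax)
    margin <- rad + 2
    r0 <- runif(1, 1 + margin, nr - margin)
    c0 <- runif(1, 1 + margin, nc - margin)
    if (nan_border && sqrt((r0 - ctr[1])^2 + (c0 - ctr[2])^2) + margin > roi_r) next
    if (nrow(blobs) > 0) {
      dd <- sqrt((blobs[, 1] - r0)^2 + (blobs[, 2] - c0)^2)
      if (any(dd < blobs[, 3] + rad + 4)) next
    }
    blobs <- rbind(blobs, c(r0, c0, rad))
  }
  if (nrow(blobs) < blob_count)
    sf_stop("argument", "could not place %d non-overlapping blobs in a %d x %d image",
            blob_count, nr, nc)
  support <- matrix(FALSE, nr, nc)
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  for (i in seq_len(nrow(blobs)))
    support <- support |
      ((rows - blobs[i, 1])^2 + (cols - blobs[i, 2])^2 <= blobs[i, 3]^2)
  image <- matrix(0, nr, nc)
  tex <- 100 + 20 * sin(rows / 5) + 20 * cos(cols / 7) +
    matrix(rnorm(nr * nc, 0, 5), nr, nc)
  image[support] <- pmax(tex[support], 1)
  if (nan_border) {
    outside <- (rows - ctr[1])^2 + (cols - ctr[2])^2 > roi_r^2
    image[outside & !support] <- NaN
  }
  list(image = image, support = support)
}
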