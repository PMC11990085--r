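#' Profile flatness metrics
#'
#' Coefficient of variation (sd/mean) of the per-axis mean tissue intensity
#' profiles, plus the mean absolute profile jump across the detected tile
#' boundaries (profile value 5 px after minus 5 px before each boundary).
#' Both drop when vignetting is removed.
#'
#' @param image Numeric matrix.
#' @param mask `tissue_mask`, logical matrix, or `NULL` (all finite pixels).
#' @param grid A `tile_grid`; `NULL` skips the boundary step (reported NA).
#' @param w Half-offset (px) for the boundary step.
#' @return List with `cv_rows`, `cv_cols`, `boundary_step`.
#' @export
profile_flatness <- function(image, mask = NULL, grid = NULL, w = 5L) {
  prof <- axis_profiles(image, mask)
  cv <- function(p) {
    v <- p$values[is.finite(p$values) & p$counts > 0]
    if (length(v) < 2L || mean(v) == 0) return(NA_real_)
    sd(v) / mean(v)
  }
  step <- NA_real_
  if (!is.null(grid)) {
    one <- function(p, boundaries) {
      v <- fill_profile(p)
      b <- round(boundaries)
      b <- b[b - w >= 1 & b + w <= length(v)]
      if (!length(b)) return(numeric())
      abs(v[b + w] - v[b - w])
    }
    steps <- c(one(prof$rows, grid$boundaries_rows),
               one(prof$cols, grid$boundaries_cols))
    if (length(steps)) step <- mean(steps)
  }
  list(cv_rows = cv(prof$rows), cv_cols = cv(prof$cols), boundary_step = step)
}

#' Detect particles by thresholding and connected components
#'
#' Otsu (or fixed) thresholding, 8-connected component labelling, and
#' removal of components below a minimum area. Per particle the centroid,
#' equivalent diameter `2 * sqrt(area / pi)` and total intensity are
#' reported. A blank image yields an empty set, not an error.
#'
#' @param image Nonnegative numeric matrix.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold Threshold for `"fixed"`.
#' @param min_area_px Minimum component area kept (px).
#' @return A `particle_set`: list with data frame `particles`
#'   (`centroid_row`, `centroid_col`, `equivalent_diameter_px`, `area_px`,
#'   `total_intensity`) and `detector_params`.
#' @export
detect_particles <- function(image, threshold_method = c("otsu", "fixed"),
                             threshold = NULL, min_area_px = 4L) {
  threshold_method <- match.arg(threshold_method)
  fin <- is.finite(image)
  if (any(image[fin] < 0)) sf_stop("argument", "image must be nonnegative")
  empty <- data.frame(centroid_row = numeric(), centroid_col = numeric(),
                      equivalent_diameter_px = numeric(), area_px = integer(),
                      total_intensity = numeric())
  vals <- image[fin]
  if (threshold_method == "otsu") {
    rng <- range(vals)
    if (diff(rng) == 0) {
      threshold <- rng[1]  # constant image: nothing exceeds the threshold
    } else {
      threshold <- EBImage::otsu(matrix((vals - rng[1]) / diff(rng)),
                                 range = c(0, 1)) * diff(rng) + rng[1]
    }
  } else if (is.null(threshold)) {
    sf_stop("argument", "threshold must be supplied for method 'fixed'")
  }
  bin <- fin & image > threshold
  params <- list(threshold_method = threshold_method, threshold = threshold,
                 min_area_px = as.integer(min_area_px))
  if (!any(bin))
    return(structure(list(particles = empty, detector_params = params),
                     class = "particle_set"))
  lab <- label8_cpp(bin)
  sizes <- tabulate(lab)
  keep <- which(sizes >= min_area_px)
  if (!length(keep))
    return(structure(list(particles = empty, detector_params = params),
                     class = "particle_set"))
  idx <- which(lab > 0L)
  l <- lab[idx]
  sel <- l %in% keep
  idx <- idx[sel]; l <- l[sel]
  rc <- arrayInd(idx, dim(image))
  f <- factor(l, levels = keep)
  area <- sizes[keep]
  df <- data.frame(
    centroid_row = as.numeric(tapply(rc[, 1], f, mean)),
    centroid_col = as.numeric(tapply(rc[, 2], f, mean)),
    equivalent_diameter_px = 2 * sqrt(area / pi),
    area_px = area,
    total_intensity = as.numeric(tapply(image[idx], f, sum)))
  rownames(df) <- NULL
  structure(list(particles = df, detector_params = params),
            class = "particle_set")
}

#' Per-tile particle density map
#'
#' Maps each particle position modulo the tile period into the unit tile,
#' histograms the folded positions into `bins x bins`, and normalizes the
#' map to sum 1 — the average distribution of particles within a tile.
#'
#' @param ps A `particle_set` or a data frame with particle positions
#'   (columns `centroid_row`/`centroid_col` or `row`/`col`).
#' @param grid A `tile_grid` (periods and offsets are used).
#' @param bins Bins per axis (>= 2).
#' @return `bins x bins` matrix summing to 1 (all zero, with attribute
#'   `empty = TRUE`, when there are no particles).
#' @export
tile_density_map <- function(ps, grid, bins = 32L) {
  if (bins < 2L) sf_stop("argument", "bins must be >= 2")
  df <- if (inherits(ps, "particle_set")) ps$particles else ps
  r <- df[["centroid_row"]] %||% df[["row"]]
  c_ <- df[["centroid_col"]] %||% df[["col"]]
  out <- matrix(0, bins, bins)
  if (is.null(r) || length(r) == 0L) {
    attr(out, "empty") <- TRUE
    return(out)
  }
  fold <- function(x, period, offset)
    ((x - 1 - offset) %% period) / period
  u <- fold(r, grid$period_rows, grid$offset_rows)
  v <- fold(c_, grid$period_cols, grid$offset_cols)
  bi <- pmin(bins, floor(u * bins) + 1L)
  bj <- pmin(bins, floor(v * bins) + 1L)
  for (i in seq_along(bi)) out[bi[i], bj[i]] <- out[bi[i], bj[i]] + 1
  out / sum(out)
}

#' Compare two density maps
#'
#' Root mean square error and Pearson correlation of the flattened maps.
#' With a zero-variance input the correlation is undefined and reported as
#' `NA`, never as 0.
#'
#' @param d,d_truth Density maps of the same shape.
#' @return List with `rmse` and `pcc`.
#' @export
compare_density_maps <- function(d, d_truth) {
  if (!identical(dim(d), dim(d_truth)))
    sf_stop("argument", "density maps must have the same shape")
  rmse <- sqrt(mean((d - d_truth)^2))
  pcc <- if (sd(d) == 0 || sd(d_truth) == 0) NA_real_
         else cor(as.vector(d), as.vector(d_truth))
  list(rmse = rmse, pcc = pcc)
}

#' Gaussian mixture decomposition of the intensity histogram
#'
#' Fits a k-component Gaussian mixture (unequal variances, EM) to the
#' tissue-pixel intensities. Components are returned sorted by mean,
#' together with the equal-posterior crossing thresholds between adjacent
#' components, which separate background, shaded tile-edge pixels and
#' bright tile-centre pixels.
#'
#' @param image Numeric matrix.
#' @param mask Optional `tissue_mask`/logical matrix restricting the pixels.
#' @param k Number of mixture components (>= 1).
#' @param max_pixels Intensities are strided down to at most this many
#'   samples before fitting (deterministic subsampling).
#' @return Data frame with columns `weight`, `mean`, `sd` (one row per
#'   component, sorted by mean) and attribute `thresholds` (length k-1).
#' @export
histogram_components <- function(image, mask = NULL, k = 3L, max_pixels = 2e5) {
  if (k < 1L) sf_stop("argument", "k must be >= 1")
  use <- is.finite(image)
  if (!is.null(mask)) use <- use & mask_matrix(mask, dim(image))
  x <- image[use]
  if (length(x) < 2L) sf_stop("argument", "need at least 2 pixels to fit")
  if (length(x) > max_pixels)
    x <- x[seq(1L, length(x), length.out = max_pixels)]
  if (sd(x) == 0) {
    if (k > 1L) warning("constant intensities; returning a single degenerate component")
    out <- data.frame(weight = 1, mean = x[1], sd = 0)
    attr(out, "thresholds") <- numeric()
    return(out)
  }
  fit <- tryCatch(
    mclust::Mclust(x, G = k, modelNames = "V", verbose = FALSE),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- mclust::Mclust(x, G = k, modelNames = "E", verbose = FALSE)
  if (is.null(fit))
    sf_stop("numeric_guard", "mixture fit failed for k = %d", k)
  par <- fit$parameters
  sds <- sqrt(rep(par$variance$sigmasq, length.out = k))
  ord <- order(par$mean)
  out <- data.frame(weight = par$pro[ord], mean = as.numeric(par$mean)[ord],
                    sd = sds[ord])
  thr <- numeric(0)
  if (k > 1L) {
    thr <- vapply(seq_len(k - 1L), function(i) {
      w1 <- out$weight[i]; m1 <- out$mean[i]; s1 <- max(out$sd[i], 1e-12)
      w2 <- out$weight[i + 1L]; m2 <- out$mean[i + 1L]; s2 <- max(out$sd[i + 1L], 1e-12)
      f <- function(z) log(w1) + dnorm(z, m1, s1, log = TRUE) -
                       log(w2) - dnorm(z, m2, s2, log = TRUE)
      if (m2 > m1 && is.finite(f(m1)) && is.finite(f(m2)) &&
          sign(f(m1)) != sign(f(m2))) {
        uniroot(f, c(m1, m2))$root
      } else {
        (m1 + m2) / 2
      }
    }, numeric(1))
  }
  attr(out, "thresholds") <- thr
  out
}
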