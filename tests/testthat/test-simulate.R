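test_that("particle generation honours the configured ranges and seeding", {
  cfg <- sim_config(grid_n = 4, tile_px = 64, seed = 7)
  p1 <- generate_particles(cfg)
  p2 <- generate_particles(cfg)
  expect_identical(p1, p2)
  counts <- table(paste(p1$tile_row, p1$tile_col))
  expect_equal(length(counts), 16L)
  expect_true(all(counts >= 30 & counts <= 50))
  expect_true(all(p1$diameter >= 4 & p1$diameter <= 10))
  expect_true(all(p1$row > 0 & p1$row <= 256 & p1$col > 0 & p1$col <= 256))
  # intensity = u * diameter with u in (0.5, 1]
  u <- p1$intensity / p1$diameter
  expect_true(all(u > 0.5 - 1e-12 & u <= 1))
  cfg2 <- sim_config(grid_n = 4, tile_px = 64, seed = 8)
  expect_false(identical(generate_particles(cfg2), p1))
})

test_that("rendering produces the right canvas and conserves kernel mass", {
  cfg <- sim_config(grid_n = 2, tile_px = 64, seed = 1)
  img <- render_mosaic(generate_particles(cfg), cfg)
  expect_equal(dim(img), c(128L, 128L))
  empty <- render_mosaic(generate_particles(cfg)[0, ], cfg)
  expect_equal(empty, matrix(0, 128, 128))

  # single centred particle: blur conserves total mass (kernel normalized);
  # oracle = direct dense convolution
  cfg1 <- sim_config(grid_n = 1, tile_px = 128, particles_min = 1,
                     particles_max = 1, psf_radius_px = 10, psf_sigma_px = 2,
                     seed = 3)
  pt <- data.frame(row = 64.2, col = 63.7, diameter = 8, intensity = 5,
                   tile_row = 1L, tile_col = 1L)
  img1 <- render_mosaic(pt, cfg1)
  disk <- matrix(0, 128, 128)
  d2 <- outer((1:128 - 64.2)^2, (1:128 - 63.7)^2, `+`)
  disk[d2 <= 16] <- 5
  expect_equal(sum(img1), sum(disk), tolerance = 1e-6)
  g <- dnorm(-10:10, sd = 2); g <- g / sum(g)
  oracle <- matrix(0, 128, 128)
  for (i in 1:128) for (j in 1:128) {
    if (disk[i, j] == 0) next
    ri <- max(1, i - 10):min(128, i + 10)
    cj <- max(1, j - 10):min(128, j + 10)
    oracle[ri, cj] <- oracle[ri, cj] +
      disk[i, j] * outer(g[ri - i + 11], g[cj - j + 11])
  }
  expect_equal(img1, oracle, tolerance = 1e-10)
})

test_that("the vignette gain follows the exponential distance law", {
  cfg <- sim_config(grid_n = 2, tile_px = 64, vignette_decay = 1.5,
                    vignette_center_offset = c(5, 3), seed = 1)
  img <- matrix(1, 128, 128)
  v <- apply_vignette(img, cfg)
  ctr <- (64 + 1) / 2 + c(5, 3)
  D <- 64 * sqrt(2) / 2
  expect_equal(v$gain[round(ctr[1]), round(ctr[2])],
               exp(-1.5 * sqrt(sum((round(ctr) - ctr)^2)) / D))
  d_corner <- sqrt((1 - ctr[1])^2 + (1 - ctr[2])^2)
  expect_equal(v$gain[1, 1], exp(-1.5 * d_corner / D))
  # identical pattern tiled across the mosaic
  expect_equal(v$gain[1:64, 1:64], v$gain[65:128, 65:128])
  expect_equal(v$image, v$gain)
  # monotonicity in k
  cfg2 <- sim_config(grid_n = 2, tile_px = 64, vignette_decay = 3,
                     vignette_center_offset = c(5, 3), seed = 1)
  v2 <- apply_vignette(img, cfg2)
  off_center <- v$gain != max(v$gain)
  expect_true(all(v2$gain[off_center] < v$gain[off_center]))
  expect_error(apply_vignette(img, sim_config(grid_n = 2, tile_px = 64,
                                              vignette_decay = -1)),
               class = "stitchflat_argument")
  expect_error(apply_vignette(matrix(1, 100, 100), cfg),
               class = "stitchflat_argument")
})

test_that("noise is seeded, zero-mean before flooring, and optional", {
  cfg0 <- sim_config(grid_n = 2, tile_px = 64, noise_sigma_frac = 0, seed = 5)
  img <- matrix(50, 128, 128)
  expect_identical(add_noise(img, cfg0), img)
  cfg <- sim_config(grid_n = 2, tile_px = 64, noise_sigma_frac = 0.01, seed = 5)
  n1 <- add_noise(img, cfg); n2 <- add_noise(img, cfg)
  expect_identical(n1, n2)
  # mean of the added noise within 3 standard errors of 0 (no flooring at 50)
  delta <- n1 - img
  se <- 0.5 / sqrt(length(delta))
  expect_lt(abs(mean(delta)), 3 * se)
  expect_true(all(add_noise(matrix(0.001, 64, 64),
                            sim_config(grid_n = 1, tile_px = 64,
                                       noise_sigma_frac = 0.5, seed = 1)) >= 0))
})

test_that("simulate_mosaic is deterministic and internally consistent", {
  s1 <- small_sim(9, grid_n = 2, tile_px = 128)
  s2 <- small_sim(9, grid_n = 2, tile_px = 128)
  expect_identical(s1$image, s2$image)
  expect_identical(s1$particles, s2$particles)
  expect_equal(dim(s1$image), c(256L, 256L))
  expect_true(all(s1$gain > 0 & s1$gain <= 1))
  # with noise switched off the final image is exactly clean x gain
  s0 <- small_sim(9, grid_n = 2, tile_px = 128, noise_sigma_frac = 0)
  expect_identical(s0$image, s0$clean * s0$gain)
  expect_identical(s0$particles, s1$particles)
})

test_that("tissue phantom has the requested support structure", {
  ph1 <- tissue_phantom(c(256, 256), blob_count = 1, seed = 2)
  expect_equal(max(stitchflat:::label8_cpp(ph1$support)), 1L)
  expect_true(all(ph1$image[!ph1$support] == 0))
  expect_true(all(ph1$image[ph1$support] > 0))
  ph2 <- tissue_phantom(c(256, 256), blob_count = 1, seed = 2)
  expect_identical(ph1$image, ph2$image)
  ph3 <- tissue_phantom(c(256, 256), blob_count = 4, seed = 3)
  expect_equal(max(stitchflat:::label8_cpp(ph3$support)), 4L)
  phn <- tissue_phantom(c(128, 128), blob_count = 1, seed = 4, nan_border = TRUE)
  expect_gt(sum(is.nan(phn$image)), 0)
  expect_true(all(is.finite(phn$image[phn$support])))
})
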