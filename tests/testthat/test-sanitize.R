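test_that("mosaic_image records NaN mask, range, and rejects bad input", {
  m <- mosaic_image(matrix(c(1, 2, 3, 4), 2, 2))
  expect_equal(m$source_range, c(1, 4))
  expect_equal(sum(m$nan_mask), 0)
  x <- matrix(runif(16), 4, 4); x[1, 1] <- NaN
  m2 <- mosaic_image(x)
  expect_true(m2$nan_mask[1, 1])
  expect_equal(sum(m2$nan_mask), 1)
  expect_error(mosaic_image(matrix(1)), class = "stitchflat_argument")
  expect_error(mosaic_image(matrix(NaN, 3, 3)), class = "stitchflat_empty_image")
})

test_that("withholding takes exactly the top fraction when nothing saturates", {
  set.seed(1)
  vals <- sample(seq_len(1000 * 1000))  # distinct values
  m <- mosaic_image(matrix(as.numeric(vals), 1000, 1000))
  s <- sanitize_mosaic(m, pipeline_config())
  expect_equal(nrow(s$record$withheld), 10000L)   # exactly 1%
  expect_equal(sort(s$record$withheld$value), as.numeric(990001:1000000))
  expect_equal(s$record$withheld_fraction, 0.01)
  # withheld positions now hold the replacement value
  idx <- cbind(s$record$withheld$row, s$record$withheld$col)
  expect_true(all(s$image$pixels[idx] == s$record$replacement_value))
})

test_that("saturated pixels are all withheld when more numerous than 1%", {
  set.seed(2)
  x <- matrix(runif(200 * 200, 0, 100), 200, 200)
  sat_idx <- sample(length(x), 2000)  # 5% saturated
  x[sat_idx] <- 255
  m <- mosaic_image(x, saturation_level = 255)
  s <- sanitize_mosaic(m, pipeline_config())
  expect_gte(nrow(s$record$withheld), 2000L)
  expect_true(all(x[sat_idx] %in% s$record$withheld$value))
})

test_that("constant image withholds ceil(f*N) pixels in scan order", {
  m <- mosaic_image(matrix(5, 30, 30))
  s <- sanitize_mosaic(m, pipeline_config())
  expect_equal(nrow(s$record$withheld), ceiling(0.01 * 900))
  # scan order: first column-major indices win the tie
  first <- arrayInd(seq_len(ceiling(0.01 * 900)), c(30L, 30L))
  expect_equal(s$record$withheld$row, first[, 1])
  expect_equal(s$record$withheld$col, first[, 2])
})

test_that("Inf pixels are replaced by the max finite value and counted", {
  x <- matrix(c(1, 2, Inf, 4, 5, 6), 2, 3)
  s <- sanitize_mosaic(mosaic_image(x), pipeline_config())
  expect_equal(s$record$inf_count, 1L)
  expect_true(all(is.finite(s$image$pixels)))
  expect_lte(max(s$image$pixels), 6)
})

test_that("sanitize validates tissue_mean and rejects all-NaN input", {
  m <- mosaic_image(matrix(1:9 + 0.0, 3, 3))
  expect_error(sanitize_mosaic(m, pipeline_config(), tissue_mean = Inf),
               class = "stitchflat_argument")
})

test_that("restore_rescale is the identity on an unchanged image", {
  set.seed(3)
  orig <- mosaic_image(matrix(runif(50 * 50, 10, 250), 50, 50))
  s <- sanitize_mosaic(orig, pipeline_config())
  out <- restore_rescale(s$image, s$record, orig)
  expect_identical(out$pixels, orig$pixels)
})

test_that("restore_rescale with an empty record forces the affine map", {
  orig <- mosaic_image(matrix(c(10, 30, 100, 250), 2, 2))
  rec <- stitchflat:::empty_sanitization_record(c(10, 250))
  corr <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  out <- restore_rescale(mosaic_image(corr), rec, orig)
  expect_equal(range(out$pixels), c(10, 250))
  expect_equal(out$pixels[1, 1], 10)
  expect_equal(out$pixels[2, 2], 250)
})

test_that("withheld pixels are restored bit-exactly and NaN preserved", {
  set.seed(4)
  x <- matrix(runif(60 * 60, 0, 4095), 60, 60)
  x[1:3, 1:3] <- NaN
  x[10, 10] <- 4095  # known bright pixel, will be withheld
  orig <- mosaic_image(x)
  s <- sanitize_mosaic(orig, pipeline_config())
  corrected <- s$image$pixels * 1.7 + 3  # arbitrary affine distortion
  out <- restore_rescale(mosaic_image(corrected), s$record, orig)
  expect_identical(out$pixels[10, 10], 4095)
  idx <- cbind(s$record$withheld$row, s$record$withheld$col)
  expect_identical(out$pixels[idx], s$record$withheld$value)
  expect_true(all(is.nan(out$pixels[1:3, 1:3])))
  expect_equal(range(out$pixels[is.finite(out$pixels)]),
               range(x[is.finite(x)]))
  expect_error(restore_rescale(mosaic_image(matrix(1, 3, 3)), s$record, orig),
               class = "stitchflat_argument")
})

test_that("pipeline_config validates its numeric contracts", {
  expect_error(pipeline_config(withhold_fraction = 0.7), class = "stitchflat_argument")
  expect_error(pipeline_config(multiplier_cap = 1), class = "stitchflat_argument")
  expect_error(pipeline_config(disk_radius_texture = 0), class = "stitchflat_argument")
})
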