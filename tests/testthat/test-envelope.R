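test_that("moving_average has the filter-definition impulse response", {
  x <- rep(0, 201); x[101] <- 1
  sm <- moving_average(x, 51)
  expect_equal(sm[76:126], rep(1 / 51, 51))
  expect_equal(sm[74], 0)
  expect_equal(moving_average(rep(3, 10), 5), rep(3, 10))
})

test_that("find_extrema locates cosine extrema at the tile scale", {
  P <- 128; n <- 4 * P
  x <- 100 + 10 * cos(2 * pi * (0:(n - 1)) / P)  # maxima at 1, P+1, 2P+1, 3P+1
  ext <- find_extrema(as_profile(x), P)
  expect_true(all(c(1, P + 1, 2 * P + 1, 3 * P + 1) %in% ext$maxima))
  true_min <- P / 2 + 1 + P * (0:3)
  expect_true(all(vapply(true_min,
                         function(m) min(abs(ext$minima - m)) <= 1, logical(1))))
  # spacing of interior extrema is the period
  expect_true(all(abs(diff(setdiff(ext$maxima, c(1, n))) - P) <= 1))
})

test_that("the separation rule rejects high-frequency ripple", {
  P <- 128; n <- 4 * P
  clean <- 100 + 10 * cos(2 * pi * (0:(n - 1)) / P)
  rippled <- clean + 0.8 * cos(2 * pi * (0:(n - 1)) / 16)
  e1 <- find_extrema(as_profile(clean), P)
  e2 <- find_extrema(as_profile(rippled), P)
  expect_equal(length(e2$maxima), length(e1$maxima))
  expect_true(all(abs(sort(e2$maxima) - sort(e1$maxima)) <= 8))
})

test_that("monotone profiles have no tile structure", {
  expect_error(find_extrema(as_profile(seq(1, 100, length.out = 512)), 64),
               class = "stitchflat_degenerate_profile")
})

test_that("envelope brackets a cosine with its closed form", {
  P <- 500; n <- 1e4
  a <- 50; b <- 8
  x <- a + b * cos(2 * pi * (0:(n - 1)) / P)
  prof <- as_profile(x)
  ext <- find_extrema(prof, P)
  env <- build_envelope(prof, ext, P)
  interior <- (P):(n - P)
  expect_lt(max(abs(env$upper[interior] - (a + b))), 0.5)
  expect_lt(max(abs(env$lower[interior] - (a - b))), 0.5)
  expect_lt(max(abs(env$midline[interior] - a)), 0.5)
  expect_equal(env$midline, (env$upper + env$lower) / 2)
})

test_that("envelope through hand-picked knots of a constant profile is constant", {
  prof <- as_profile(rep(42, 400))
  env <- build_envelope(prof, list(minima = c(50, 350), maxima = c(100, 300)), 200)
  expect_equal(env$upper, rep(42, 400))
  expect_equal(env$lower, rep(42, 400))
  expect_equal(env$midline, rep(42, 400))
})

test_that("multiplier is unity on a flat profile and lifts troughs by midline/trough", {
  prof <- as_profile(rep(100, 512))
  env <- build_envelope(prof, list(minima = c(100, 400), maxima = c(200, 300)), 256)
  mult <- envelope_multiplier(prof, env)
  expect_equal(mult$values, rep(1, 512), tolerance = 1e-12)

  # cosine between 80 and 120: midline 100, troughs at 80 -> peak 100/80
  P <- 256; n <- 4 * P
  x <- 100 + 20 * cos(2 * pi * (0:(n - 1)) / P)
  prof2 <- as_profile(x)
  env2 <- build_envelope(prof2, find_extrema(prof2, P), P)
  mult2 <- envelope_multiplier(prof2, env2, smooth_window = 5)
  troughs <- P / 2 + 1 + P * (0:3)
  expect_equal(max(mult2$values[troughs]), 100 / 80, tolerance = 0.05)
  expect_true(all(mult2$values > 0))
})

test_that("no multiplier peak exceeds the mean peak height", {
  n <- 1024
  vals <- rep(1, n)
  bump <- function(c0, h) {
    idx <- (c0 - 40):(c0 + 40)
    vals[idx] <<- pmax(vals[idx], 1 + (h - 1) * cos(pi * (-40:40) / 160)^2)
  }
  bump(256, 2.5); bump(768, 1.25)   # unequal per-tile peaks, mean 1.875
  out <- stitchflat:::constrain_peaks(vals, 512)
  expect_equal(max(out), 1.875, tolerance = 1e-9)       # deep peak capped at the mean
  expect_equal(out[768], 1.25, tolerance = 1e-9)        # sub-mean peak untouched
  expect_true(all(out <= vals + 1e-12))                 # the constraint never amplifies
  # equal peaks: constraint is a no-op
  vals2 <- rep(1, n); v <- vals2
  vals2[200:312] <- 1 + 0.5 * cos(pi * (-56:56) / 112)^2
  vals2[712:824] <- 1 + 0.5 * cos(pi * (-56:56) / 112)^2
  expect_equal(stitchflat:::constrain_peaks(vals2, 512), vals2)
})

test_that("multiplier caps and excluded positions behave by contract", {
  n <- 512
  x <- c(rep(0.001, 50), rep(100, n - 50))   # near-zero stretch forces the cap
  prof <- as_profile(x)
  env <- build_envelope(prof, list(minima = c(25, 400), maxima = c(200, 300)), 256)
  mult <- envelope_multiplier(prof, env, cap = 5, smooth_window = 3)
  expect_lte(max(mult$values), 5)
  expect_gte(min(mult$values), 1 / 5)
  # excluded positions get exactly 1
  vals <- rep(100, n); vals[10] <- NaN
  cnts <- rep(1L, n); cnts[10] <- 0L
  prof2 <- as_profile(vals, counts = cnts)
  env2 <- build_envelope(prof2, list(minima = c(100, 400), maxima = c(200, 300)), 256)
  mult2 <- envelope_multiplier(prof2, env2)
  expect_equal(mult2$values[10], 1)
})

test_that("axis multipliers scale rows/columns and commute", {
  img <- matrix(c(2, 4, 2, 4), 2, 2)
  out <- apply_axis_multiplier(img, c(2, 1), axis = "rows")
  expect_equal(out, matrix(c(4, 4, 4, 4), 2, 2))
  set.seed(12)
  img2 <- matrix(runif(20 * 30), 20, 30)
  mr <- runif(20, 0.5, 2); mc <- runif(30, 0.5, 2)
  a <- apply_axis_multiplier(apply_axis_multiplier(img2, mr, "rows"), mc, "cols")
  b <- apply_axis_multiplier(apply_axis_multiplier(img2, mc, "cols"), mr, "rows")
  expect_equal(a, b)
  img3 <- img2; img3[1, 1] <- NaN
  expect_true(is.nan(apply_axis_multiplier(img3, mr, "rows")[1, 1]))
  expect_error(apply_axis_multiplier(img2, mr[-1], "rows"), class = "stitchflat_argument")
})

test_that("separable periodic gain is flattened by the two envelope passes", {
  n <- 1024; P <- 256
  img <- separable_gain_image(n, P, 0.2)
  flatten_axis <- function(image, axis) {
    prof <- axis_profiles(image)[[axis]]
    ext <- find_extrema(prof, P)
    env <- build_envelope(prof, ext, P)
    apply_axis_multiplier(image, envelope_multiplier(prof, env))
  }
  corrected <- flatten_axis(flatten_axis(img, "rows"), "cols")
  interior <- (P / 2):(n - P / 2)
  ripple <- function(v) diff(range(v[interior]))
  r_before <- ripple(rowMeans(img))
  r_after <- ripple(rowMeans(corrected))
  expect_gte(r_before / r_after, 5)
  c_before <- ripple(colMeans(img))
  c_after <- ripple(colMeans(corrected))
  expect_gte(c_before / c_after, 5)
})

test_that("repeating the correction has diminishing returns", {
  n <- 1024; P <- 256
  img <- separable_gain_image(n, P, 0.2)
  pass <- function(image) {
    for (axis in c("rows", "cols")) {
      prof <- axis_profiles(image)[[axis]]
      ext <- tryCatch(find_extrema(prof, P), stitchflat_error = function(e) NULL)
      if (is.null(ext)) return(image)
      env <- build_envelope(prof, ext, P)
      image <- apply_axis_multiplier(image, envelope_multiplier(prof, env))
    }
    image
  }
  once <- pass(img); twice <- pass(once)
  interior <- (P / 2):(n - P / 2)
  ripple <- function(im) diff(range(rowMeans(im)[interior]))
  gain1 <- ripple(img) - ripple(once)
  gain2 <- abs(ripple(once) - ripple(twice))
  expect_lt(gain2, gain1)
})
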