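test_that("degradation constructor validates its fields", {
  expect_s3_class(degradation("blur", sigma_ref = 4), "degradation")
  expect_error(degradation("blur"), "sigma_ref")
  expect_error(degradation("blur", sigma_ref = -1), "non-negative")
  expect_error(degradation("none", sigma_ref = 2), "only meaningful")
  expect_error(degradation("hue_rotation"), "angle")
  expect_equal(degradation("hue_rotation", angle = 390)$angle, 30)
  rt <- degradation_from_json(degradation_to_json(degradation("blur", sigma_ref = 4)))
  expect_equal(rt, degradation("blur", sigma_ref = 4))
})

test_that("blur at sigma 0 is the identity and sigma scales with resolution", {
  x <- random_raster(32, seed = 3)
  expect_identical(gaussian_blur(x, 0), x)
  # sigma_ref 4 on a 64-px image means effective sigma 1: same result as
  # stating sigma 1 at the image's own width
  y <- random_raster(64, seed = 4)
  expect_equal(gaussian_blur(y, 4, ref_size = 256),
               gaussian_blur(y, 1, ref_size = 64), tolerance = 1e-12)
})

test_that("blur of a centered impulse matches direct convolution", {
  img <- array(0, dim = c(33, 33, 3))
  img[17, 17, ] <- 1
  got <- gaussian_blur(img, 2, ref_size = 33)
  want <- direct_blur(img, 2)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("blur with boundary interaction matches the brute-force oracle", {
  x <- random_raster(17, seed = 9)
  got <- gaussian_blur(x, 1.5, ref_size = 17)
  want <- direct_blur(x, 1.5)
  expect_lt(max(abs(got - want)), 1e-6)
})

test_that("blur monotonically removes supra-cutoff spectral power", {
  x <- random_raster(32, seed = 5)  # mid-range values, no clipping
  for (f0 in c(0.05, 0.1, 0.25)) {
    pw <- vapply(c(0, 1, 2, 4),
                 function(s) power_above(gaussian_blur(x, s, ref_size = 32), f0),
                 numeric(1))
    expect_true(all(diff(pw) <= 1e-8))
  }
})

test_that("grayscale uses BT.601 luminance, replicates channels, idempotent", {
  x <- random_raster(8, seed = 6)
  g <- to_grayscale(x)
  expect_equal(g[, , 1], g[, , 2])
  expect_equal(g[, , 2], g[, , 3])
  expect_identical(to_grayscale(g), g)
  achro <- array(rep(x[, , 1], 3), dim = dim(x))
  expect_equal(to_grayscale(achro), achro)
  red <- array(c(1, 0, 0), dim = c(1, 1, 3))
  expect_equal(as.vector(to_grayscale(red)), rep(0.299, 3))
  expect_error(to_grayscale(x[, , 1]), "H x W x 3")
})

test_that("hue rotation: identity, closure, primary rotation, composition", {
  x <- random_raster(8, seed = 8)
  expect_lt(max(abs(hue_rotate(x, 0) - x)), 1e-6)
  expect_lt(max(abs(hue_rotate(x, 360) - x)), 1e-6)
  red <- array(c(1, 0, 0), dim = c(1, 1, 3))
  green <- array(c(0, 1, 0), dim = c(1, 1, 3))
  expect_lt(max(abs(hue_rotate(red, 120) - green)), 1e-6)
  # composition over several angle pairs
  for (ab in list(c(30, 45), c(120, 300), c(17, 200))) {
    lhs <- hue_rotate(hue_rotate(x, ab[1]), ab[2])
    rhs <- hue_rotate(x, sum(ab))
    expect_lt(max(abs(lhs - rhs)), 1e-5)
  }
  # saturation and value preserved
  hsv0 <- rgb2hsv(t(matrix(x, ncol = 3)), maxColorValue = 1)
  hsv1 <- rgb2hsv(t(matrix(hue_rotate(x, 77), ncol = 3)), maxColorValue = 1)
  expect_lt(max(abs(hsv0[2:3, ] - hsv1[2:3, ])), 1e-6)
})

test_that("grayscale output carries zero chromatic energy", {
  x <- random_raster(5, seed = 11)
  expect_equal(color_tuning_score(to_grayscale(x) - 0.5), 0)
})

test_that("apply_degradation dispatches and 'none' is bitwise identity", {
  x <- random_raster(16, seed = 10)
  expect_identical(apply_degradation(degradation("none"), x), x)
  expect_identical(apply_degradation(degradation("blur", sigma_ref = 4), x),
                   gaussian_blur(x, 4, 256))
  expect_identical(apply_degradation(degradation("grayscale"), x),
                   to_grayscale(x))
  expect_identical(apply_degradation(degradation("hue_rotation", angle = 90), x),
                   hue_rotate(x, 90))
})

test_that("preprocessing rescales to [-1, 1] and is deterministic per mode", {
  imgs <- list(array(0, c(8, 8, 3)), array(1, c(8, 8, 3)))
  X <- preprocess_batch(imgs, train_mode = FALSE, crop_size = 6)
  expect_equal(unique(as.vector(X[, , , 1])), -1)
  expect_equal(unique(as.vector(X[, , , 2])), 1)
  imgs2 <- lapply(1:3, function(i) random_raster(12, seed = 20 + i))
  e1 <- preprocess_batch(imgs2, FALSE, 10)
  e2 <- preprocess_batch(imgs2, FALSE, 10)
  expect_identical(e1, e2)
  set.seed(99); t1 <- preprocess_batch(imgs2, TRUE, 10)
  set.seed(99); t2 <- preprocess_batch(imgs2, TRUE, 10)
  expect_identical(t1, t2)
  expect_error(preprocess_batch(imgs2, FALSE, 13), "crop_size")
})
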