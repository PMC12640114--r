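test_that("spec validation names the offending field", {
  expect_error(imageset_spec(n_classes = 0), "n_classes")
  expect_error(imageset_spec(train_per_class = -1), "train_per_class")
  expect_error(imageset_spec(image_size = 16), "image_size")
  expect_error(imageset_spec(noise_sd = -0.1), "noise_sd")
  expect_error(imageset_spec(n_classes = 2,
    texture_freq_bands = list(c(0.1, 0.6), c(0.2, 0.3))), "0, 0.5")
  expect_error(imageset_spec(n_classes = 3,
    texture_freq_bands = list(c(0.1, 0.2))), "per class")
})

test_that("generation yields the forced counts, labels and invariants", {
  spec <- imageset_spec(n_classes = 2, train_per_class = 4,
                        test_per_class = 2, image_size = 64, seed = 7)
  sets <- generate_dataset(spec)
  expect_length(sets$train$images, 8)
  expect_length(sets$test$images, 4)
  expect_setequal(unique(sets$train$labels), 0:1)
  expect_setequal(unique(sets$test$labels), 0:1)
  expect_equal(dim(sets$train$images[[1]]), c(64L, 64L, 3L))
  # validate_imageset passes (range, shapes, coverage)
  expect_s3_class(validate_imageset(sets$train), "imageset")
  rng <- range(unlist(lapply(sets$train$images, range)))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
})

test_that("equal specs generate bitwise-identical sets", {
  spec <- imageset_spec(n_classes = 2, train_per_class = 3,
                        test_per_class = 2, image_size = 48, seed = 11)
  a <- generate_dataset(spec)
  b <- generate_dataset(spec)
  expect_identical(a$train$images, b$train$images)
  expect_identical(a$test$images, b$test$images)
  c <- generate_dataset(imageset_spec(n_classes = 2, train_per_class = 3,
                                      test_per_class = 2, image_size = 48,
                                      seed = 12))
  expect_false(identical(a$train$images[[1]], c$train$images[[1]]))
})

test_that("opposite hue centers are reported 180 degrees apart", {
  sets <- generate_dataset(imageset_spec(
    n_classes = 2, train_per_class = 6, test_per_class = 2,
    image_size = 64, hue_separation = 180, hue_jitter_sd = 0, seed = 3))
  cd <- cue_diagnostics(sets$train)
  dh <- abs(cd$per_class$hue_angle[1] - cd$per_class$hue_angle[2])
  dh <- min(dh, 360 - dh)
  expect_equal(dh, 180, tolerance = 0.05)
})

test_that("grayscale removes the chromatic cue but not the texture cue", {
  sets <- tiny_sets()
  cd0 <- cue_diagnostics(sets$train)
  gray <- sets$train
  gray$images <- lapply(gray$images, to_grayscale)
  cdg <- cue_diagnostics(gray)
  expect_lt(cdg$chromatic_separation, 1e-10)
  expect_lt(abs(cdg$texture_separation - cd0$texture_separation) /
              cd0$texture_separation, 0.05)
})

test_that("strong blur collapses texture separation but not hue separation", {
  sets <- tiny_sets()
  cd0 <- cue_diagnostics(sets$train)
  blur <- sets$train
  # sigma 3 px at the native 64-px resolution: at least half the longest
  # texture wavelength (1/0.18 ~ 5.6 px) used by the generator
  blur$images <- lapply(blur$images, gaussian_blur, sigma_ref = 3,
                        ref_size = 64)
  cdb <- cue_diagnostics(blur)
  expect_lt(cdb$texture_separation, 0.5 * cd0$texture_separation)
  expect_lt(abs(cdb$chromatic_separation - cd0$chromatic_separation) /
              cd0$chromatic_separation, 0.05)
})

test_that("single-class diagnostics are flagged undefined", {
  sets <- tiny_sets()
  one <- sets$train
  keep <- which(one$labels == 0)
  one$images <- one$images[keep]
  one$labels <- one$labels[keep]
  one$n_classes <- 1L
  cd <- cue_diagnostics(one)
  expect_false(cd$separation_defined)
  expect_true(is.na(cd$chromatic_separation))
})

test_that("PNG + manifest round trip preserves labels and pixels to 8 bits", {
  sets <- generate_dataset(imageset_spec(
    n_classes = 2, train_per_class = 3, test_per_class = 2,
    image_size = 32, seed = 5))
  dir <- withr::local_tempdir()
  write_imageset(sets$train, dir)
  write_imageset(sets$test, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  expect_true(file.exists(file.path(dir, "spec.json")))
  back <- read_imageset(dir, "train")
  expect_equal(back$labels, sets$train$labels)
  expect_length(back$images, 6)
  expect_lt(max(abs(back$images[[1]] - sets$train$images[[1]])), 1 / 255)
  test_back <- read_imageset(dir, "test")
  expect_equal(test_back$labels, sets$test$labels)
})
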