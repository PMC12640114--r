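random_filter <- function(k = 5, seed = 1) {
  set.seed(seed)
  array(rnorm(k * k * 3), dim = c(k, k, 3))
}

test_that("color tuning score matches a brute-force per-pixel oracle", {
  brute <- function(f) {
    k <- dim(f)[1]
    num <- 0; den <- 0
    u <- rep(1, 3) / sqrt(3)
    for (i in seq_len(k)) for (j in seq_len(dim(f)[2])) {
      v <- f[i, j, ]
      a <- sum(v * u) * u     # achromatic projection
      num <- num + sum((v - a)^2)
      den <- den + sum(v^2)
    }
    if (den == 0) 0 else num / den
  }
  for (s in 1:5) {
    f <- random_filter(5, s)
    expect_lt(abs(color_tuning_score(f) - brute(f)), 1e-10)
  }
})

test_that("color tuning score: analytic cases and scale invariance", {
  f <- random_filter(4, 9)
  achro <- array(rep(f[, , 1], 3), dim = dim(f))
  expect_equal(color_tuning_score(achro), 0)
  # channel triplets summing to zero have no achromatic component
  opp <- array(0, c(3, 3, 3))
  opp[, , 1] <- 1; opp[, , 2] <- -1
  expect_equal(color_tuning_score(opp), 1)
  expect_equal(color_tuning_score(array(0, c(3, 3, 3))), 0)
  expect_equal(color_tuning_score(f * 17), color_tuning_score(f))
  s <- color_tuning_score(f)
  expect_gte(s, 0); expect_lte(s, 1)
  bad <- f; bad[1] <- NaN
  expect_error(color_tuning_score(bad), "finite")
})

test_that("spatial-frequency centroid hits analytic cases", {
  expect_equal(sf_centroid(array(0.7, c(5, 5, 3))), 0)
  # pure sinusoid aligned to a DFT bin on a 16-px filter
  n <- 16
  wave <- matrix(cos(2 * pi * 0.25 * (0:(n - 1))), n, n)
  expect_equal(sf_centroid(array(rep(wave, 3), c(n, n, 3))), 0.25,
               tolerance = 1e-10)
  f <- random_filter(8, 2)
  expect_equal(sf_centroid(f * 3), sf_centroid(f))
  expect_equal(sf_centroid(f + 2), sf_centroid(f), tolerance = 1e-8)
  expect_lte(sf_centroid(f), 0.5 * sqrt(2))
})

test_that("blurring a filter lowers its spatial-frequency centroid", {
  for (s in 1:3) {
    f <- random_filter(9, 10 + s)
    # map to [0,1] (centroid is affine-invariant) and blur at native size
    g <- (f - min(f)) / diff(range(f))
    gb <- gaussian_blur(g, 1.5, ref_size = 9)
    expect_lte(sf_centroid(gb), sf_centroid(g) + 1e-10)
  }
})

test_that("below-diagonal count uses strict inequality", {
  expect_equal(below_diagonal_count(cbind(c(1, 2), c(1, 2))),
               list(count_below = 0L, total = 2L))
  ex <- rbind(c(0.1, 0.2), c(0.3, 0.3), c(0.5, 0.4))
  expect_equal(below_diagonal_count(ex)$count_below, 1L)
  set.seed(4)
  pr <- cbind(runif(50), runif(50))
  loop <- sum(vapply(1:50, function(i) pr[i, 1] < pr[i, 2], logical(1)))
  expect_equal(below_diagonal_count(pr)$count_below, loop)
  expect_error(below_diagonal_count(pr[0, , drop = FALSE]), "non-empty")
})

test_that("weight change magnitude matches an elementwise oracle", {
  run <- micro_train(epochs = 2)
  c0 <- run$checkpoints[[1]]; c1 <- run$checkpoints[[2]]
  expect_equal(weight_change_magnitude(c0, c0, "conv1"), 0)
  for (ly in names(c0$layers)) {
    brute <- mean(abs(c1$layers[[ly]]$W - c0$layers[[ly]]$W))
    expect_lt(abs(weight_change_magnitude(c0, c1, ly) - brute), 1e-12)
  }
  # a uniform +c shift has magnitude exactly c
  shifted <- c0
  shifted$layers$conv1$W <- c0$layers$conv1$W + 0.25
  expect_equal(weight_change_magnitude(c0, shifted, "conv1"), 0.25)
  expect_error(weight_change_magnitude(c0, c1, "conv9"), "conv9")
})

test_that("adjacent-epoch correlation: identity, scaling, negation, affine", {
  run <- micro_train(epochs = 2)
  c0 <- run$checkpoints[[1]]
  expect_equal(adjacent_epoch_correlation(c0, c0, "conv1"), 1.0)
  scaled <- c0; scaled$layers$conv1$W <- c0$layers$conv1$W * 2
  expect_equal(adjacent_epoch_correlation(c0, scaled, "conv1"), 1.0)
  neg <- c0; neg$layers$conv1$W <- -c0$layers$conv1$W
  expect_equal(adjacent_epoch_correlation(c0, neg, "conv1"), -1.0)
  aff <- c0; aff$layers$fc1$W <- 3 * c0$layers$fc1$W + 5
  expect_equal(adjacent_epoch_correlation(c0, aff, "fc1"), 1.0)
  flat <- c0; flat$layers$conv1$W <- c0$layers$conv1$W * 0
  expect_true(is.na(adjacent_epoch_correlation(c0, flat, "conv1")))
})

test_that("first-layer extraction returns indexed rasters and a tile image", {
  run <- micro_train(epochs = 2)
  fl <- extract_first_layer(run)
  expect_length(fl$filters, 8)
  expect_equal(dim(fl$filters[[1]]), c(5L, 5L, 3L))
  fl2 <- extract_first_layer(final_checkpoint <- run$checkpoints[[length(run$checkpoints)]])
  expect_identical(fl$filters, fl2$filters)
  # filter rasters reproduce the stored weight rows
  ck <- run$checkpoints[[length(run$checkpoints)]]
  expect_equal(as.vector(fl$filters[[3]]), as.vector(ck$layers$conv1$W[3, ]))
  expect_equal(dim(fl$tile)[3], 3)
  expect_true(all(fl$tile >= 0 & fl$tile <= 1))
})

test_that("dynamics profile has L x (E-1) records and sane summaries", {
  run <- micro_train(epochs = 3)
  dp <- dynamics_profile(run)
  n_layers <- length(run$checkpoints[[1]]$layers)
  expect_equal(nrow(dp$records), n_layers * (length(run$checkpoints) - 1))
  expect_true(all(dp$records$change_magnitude >= 0))
  expect_true(all(abs(dp$records$correlation) <= 1, na.rm = TRUE))
  expect_setequal(dp$summary$layer, names(run$checkpoints[[1]]$layers))
  td <- tidy(dp)
  expect_true(all(c("layer", "correlation", "regimen") %in% names(td)))
})

test_that("a zero learning-rate run leaves weights frozen", {
  sched <- make_lr_schedule("const1", 2)
  sched$initial_lr <- 0
  run <- micro_train(epochs = 2, sched = sched)
  c0 <- run$checkpoints[[1]]
  cF <- run$checkpoints[[length(run$checkpoints)]]
  for (ly in names(c0$layers)) {
    expect_identical(c0$layers[[ly]]$W, cF$layers[[ly]]$W)
    expect_identical(c0$layers[[ly]]$b, cF$layers[[ly]]$b)
  }
  dp <- dynamics_profile(run)
  expect_true(all(dp$records$correlation == 1))
  expect_true(all(dp$records$change_magnitude == 0))
})

test_that("rf_scatter pairs filters by index and counts below-diagonal", {
  r1 <- micro_train("D2F", "dec1", epochs = 2, seed = 1, domain = "grayscale")
  r2 <- micro_train("D2F", "const1", epochs = 2, seed = 1,
                    domain = "grayscale")
  sc <- rf_scatter(r1, r2, metric = "color")
  expect_equal(nrow(sc), 8)
  expect_equal(attr(sc, "total"), 8)
  bd <- below_diagonal_count(cbind(sc$score_decreasing, sc$score_constant))
  expect_equal(attr(sc, "count_below"), bd$count_below)
})
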