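test_that("a constant-output model scores exactly chance on a balanced set", {
  sets <- micro_sets()
  ck <- build_model(micro_arch(), 1)
  # zero the output layer: logits identical across classes for every input
  nfc <- length(ck$model$fc)
  ck$model$fc[[nfc]]$W <- ck$model$fc[[nfc]]$W * 0
  ck$model$fc[[nfc]]$b <- ck$model$fc[[nfc]]$b * 0
  rec <- evaluate(ck, sets$test, degradation("none"))
  expect_equal(rec$top1_accuracy, 0.5)  # 2 balanced classes
})

test_that("evaluation is deterministic and order-invariant", {
  sets <- micro_sets()
  run <- micro_train(epochs = 2)
  a <- evaluate(run, sets$test, degradation("blur", sigma_ref = 2))
  b <- evaluate(run, sets$test, degradation("blur", sigma_ref = 2))
  expect_identical(a$top1_accuracy, b$top1_accuracy)
  perm <- sets$test
  ord <- rev(seq_along(perm$images))
  perm$images <- perm$images[ord]
  perm$labels <- perm$labels[ord]
  c <- evaluate(run, perm, degradation("blur", sigma_ref = 2))
  expect_equal(a$top1_accuracy, c$top1_accuracy)
})

test_that("a model trained to memorize a tiny set classifies it perfectly", {
  sets <- micro_sets()
  tiny <- sets$train
  keep <- c(which(tiny$labels == 0)[1:6], which(tiny$labels == 1)[1:6])
  tiny$images <- tiny$images[keep]
  tiny$labels <- tiny$labels[keep]
  cfg <- train_config(batch_size = 12L, epochs = 30L, seed = 1,
                      checkpoint_every = 30L)
  run <- train(micro_arch(), tiny, tiny, make_regimen("F2F", 30),
               make_lr_schedule("const1", 30), cfg)
  expect_lt(run$per_epoch$train_loss[30], 0.05)
  rec <- evaluate(run, tiny, degradation("none"))
  expect_equal(rec$top1_accuracy, 1.0)
})

test_that("sweeps are consistent with single evaluations", {
  sets <- micro_sets()
  run <- micro_train(epochs = 2)
  bs <- blur_sweep(run, sets$test, sigmas = c(0, 2, 4))
  expect_equal(nrow(bs), 3)
  base <- evaluate(run, sets$test, degradation("none"))
  expect_equal(bs$top1_accuracy[bs$sigma_ref == 0], base$top1_accuracy)
  hs <- hue_sweep(run, sets$test, angles = c(0, 90, 180))
  expect_equal(nrow(hs), 3)
  expect_equal(hs$top1_accuracy[hs$angle == 0], base$top1_accuracy)
  expect_error(blur_sweep(run, sets$test, sigmas = c(-1)), "non-negative")
  expect_error(hue_sweep(run, sets$test, angles = 400), "360")
})

test_that("seed aggregation reports mean and standard error conventions", {
  recs <- tibble::tibble(
    regimen_name = "D2F", lr_schedule_name = "dec1", seed = 1:3,
    test_condition = "none", top1_accuracy = c(0.4, 0.5, 0.6))
  agg <- aggregate_seeds(recs)
  expect_equal(agg$mean_accuracy, 0.5)
  expect_equal(agg$se, 0.1 / sqrt(3), tolerance = 1e-12)
  expect_true(agg$se_defined)
  same <- recs; same$top1_accuracy <- rep(0.5, 3)
  expect_equal(aggregate_seeds(same)$se, 0)
  one <- recs[1, ]
  agg1 <- aggregate_seeds(one)
  expect_equal(agg1$mean_accuracy, 0.4)
  expect_true(is.na(agg1$se))
  expect_false(agg1$se_defined)
})

test_that("matched comparison computes per-seed deltas and their SE", {
  mk <- function(sched, accs) tibble::tibble(
    regimen_name = "D2F", lr_schedule_name = sched, seed = 1:3,
    test_condition = "degraded", top1_accuracy = accs)
  recs <- dplyr::bind_rows(mk("dec1", c(0.50, 0.52, 0.54)),
                           mk("const1", c(0.50, 0.50, 0.50)))
  cmp <- compare_matched(recs, "initial")
  expect_equal(cmp$delta_accuracy, 0.02, tolerance = 1e-12)
  expect_equal(cmp$se, sd(c(0, 0.02, 0.04)) / sqrt(3), tolerance = 1e-12)
  expect_equal(cmp$decreasing, "dec1")
  expect_equal(cmp$constant, "const1")
  # identical arms give exactly zero
  recs0 <- dplyr::bind_rows(mk("dec1", rep(0.5, 3)), mk("const1", rep(0.5, 3)))
  expect_equal(compare_matched(recs0, "initial")$delta_accuracy, 0)
  # final-value basis pairs dec1 with const2
  recsf <- dplyr::bind_rows(mk("dec1", rep(0.5, 3)), mk("const2", rep(0.4, 3)))
  cmpf <- compare_matched(recsf, "final")
  expect_equal(cmpf$constant, "const2")
  expect_equal(cmpf$delta_accuracy, 0.1)
  expect_error(compare_matched(mk("dec1", rep(0.5, 3)), "initial"),
               "matched")
})

test_that("timing sweep produces rows per switch point and condition", {
  sets <- micro_sets()
  cfg <- train_config(batch_size = 8L, epochs = 4L, seed = 1,
                      checkpoint_every = 4L)
  res <- timing_sweep(sets$train, sets$test, micro_arch(), cfg,
                      domain = "acuity", switch_epochs = c(2, 4),
                      mode = "lr_timing", seeds = 1)
  expect_equal(nrow(res), 2 * 2)
  expect_setequal(unique(res$switch_epoch), c(2, 4))
  expect_error(timing_sweep(sets$train, sets$test, micro_arch(), cfg,
                            domain = "acuity", switch_epochs = 9,
                            mode = "lr_timing"), "range")
})

test_that("the abrupt-vs-gradual factorial trains four cells per seed", {
  sets <- micro_sets()
  cfg <- train_config(batch_size = 8L, epochs = 5L, seed = 1,
                      checkpoint_every = 5L)
  res <- gradual_factorial(sets$train, sets$test, micro_arch(), cfg,
                           seeds = 1, sigmas = c(0, 4))
  cells <- dplyr::distinct(res[, c("blur_decay", "lr_decay")])
  expect_equal(nrow(cells), 4)
  expect_equal(nrow(res), 4 * 2)  # 2 sweep points per cell
})
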