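test_that("regimen presets reproduce the printed phase structures", {
  d2f <- make_regimen("D2F", 100, degraded = "blur")
  expect_equal(d2f$phases$kind, c("blur", "none"))
  expect_equal(d2f$phases$n_epochs, c(50L, 50L))
  expect_equal(d2f$phases$sigma_ref[1], 4)

  gb <- make_regimen("gradual_blur", 100)
  expect_equal(gb$phases$n_epochs, rep(20L, 5))
  expect_equal(gb$phases$sigma_ref, c(4, 3, 2, 1, NA))
  expect_equal(gb$phases$kind, c(rep("blur", 4), "none"))

  f2f <- make_regimen("F2F", 100)
  expect_true(all(f2f$phases$kind == "none"))
  expect_equal(nrow(f2f$phases), 2)  # two identical phases by convention

  d2d <- make_regimen("D2D", 100, degraded = "grayscale")
  expect_true(all(d2d$phases$kind == "grayscale"))

  for (k in c(10, 20, 30, 40)) {
    p <- make_regimen("D2F_partial", 100, degraded = "blur",
                      partial_degraded_epochs = k)
    expect_equal(p$phases$n_epochs, c(k, 100L - k))
  }
  expect_error(make_regimen("D2F_partial", 100, partial_degraded_epochs = 15),
               "10, 20, 30, 40")
  expect_error(make_regimen("nope", 100), "unknown")
})

test_that("degradation_at_epoch is total and honors phase boundaries", {
  d2f <- make_regimen("D2F", 100, degraded = "blur")
  expect_equal(degradation_at_epoch(d2f, 50),
               degradation("blur", sigma_ref = 4))
  expect_equal(degradation_at_epoch(d2f, 51), degradation("none"))
  gb <- make_regimen("gradual_blur", 100)
  expect_equal(degradation_at_epoch(gb, 70),
               degradation("blur", sigma_ref = 1))
  expect_equal(degradation_at_epoch(gb, 100), degradation("none"))
  # totality: every epoch of every preset maps to a spec, counts sum exactly
  for (nm in c("F2F", "D2D", "D2F", "F2D", "gradual_blur")) {
    r <- make_regimen(nm, 20)
    expect_equal(sum(r$phases$n_epochs), 20L)
    for (e in 1:20) expect_s3_class(degradation_at_epoch(r, e), "degradation")
  }
  expect_error(degradation_at_epoch(d2f, 0), "epoch")
  expect_error(degradation_at_epoch(d2f, 101), "epoch")
})

test_that("learning-rate presets emit the printed values", {
  dec1 <- make_lr_schedule("dec1", 100)
  expect_equal(lr_at_epoch(dec1, 50), 0.01)
  expect_equal(lr_at_epoch(dec1, 51), 0.001)
  expect_equal(lr_at_epoch(make_lr_schedule("dec2", 100), 51), 0.0001)
  d3 <- make_lr_schedule("dec3", 100)
  expect_equal(lr_at_epoch(d3, 1), 0.001)
  expect_equal(lr_at_epoch(d3, 100), 0.0001)
  for (e in c(1, 50, 100))
    expect_equal(lr_at_epoch(make_lr_schedule("const2", 100), e), 0.001)

  g <- make_lr_schedule("gradual", 100)
  expect_equal(vapply(c(10, 30, 50, 70, 90),
                      function(e) lr_at_epoch(g, e), numeric(1)),
               c(0.01, 0.0075, 0.005, 0.0025, 0.001))
  expect_equal(lr_at_epoch(g, 50), 0.005)  # third 20-epoch block, 41-60

  p <- make_lr_schedule("plateau", 100)
  expect_equal(p$plateau,
               list(factor = 0.5, patience = 5L, min_delta = 0,
                    cooldown = 0L, min_lr = 0))
  expect_error(lr_at_epoch(p, 1), "plateau_state")
})

test_that("every preset schedule is non-increasing over epochs", {
  for (nm in c("const1", "const2", "const3", "dec1", "dec2", "dec3",
               "gradual")) {
    s <- make_lr_schedule(nm, 100)
    lrs <- vapply(1:100, function(e) lr_at_epoch(s, e), numeric(1))
    expect_true(all(diff(lrs) <= 0), info = nm)
  }
})

test_that("switch points scale proportionally with total epochs", {
  d2f <- make_regimen("D2F", 20, degraded = "blur")
  expect_equal(d2f$phases$n_epochs, c(10L, 10L))
  expect_equal(degradation_at_epoch(d2f, 10)$kind, "blur")
  expect_equal(degradation_at_epoch(d2f, 11)$kind, "none")
  dec1 <- make_lr_schedule("dec1", 20)
  expect_equal(lr_at_epoch(dec1, 10), 0.01)
  expect_equal(lr_at_epoch(dec1, 11), 0.001)
})

test_that("plateau state machine reduces on sustained flatness only", {
  params <- make_lr_schedule("plateau", 100)$plateau
  st <- plateau_state(0.01)
  # improving metric: never reduces
  for (m in seq(0.1, 0.9, by = 0.1)) st <- plateau_update(st, params, m)
  expect_equal(st$current_lr, 0.01)
  # flat for patience + 1 epochs: exactly one halving
  for (i in 1:6) st <- plateau_update(st, params, 0.9)
  expect_equal(st$current_lr, 0.005)
  expect_equal(st$epochs_since_improvement, 0L)
  # floor at min_lr
  params2 <- params; params2$min_lr <- 0.005
  for (i in 1:20) st <- plateau_update(st, params2, 0.9)
  expect_equal(st$current_lr, 0.005)
  # LR sequence non-increasing under arbitrary monitored values
  set.seed(1)
  st <- plateau_state(0.01); prev <- 0.01
  for (i in 1:50) {
    st <- plateau_update(st, params, runif(1))
    expect_lte(st$current_lr, prev)
    expect_gte(st$current_lr, params$min_lr)
    prev <- st$current_lr
  }
  expect_error(plateau_update(st, modifyList(params, list(factor = 1.5)), 1),
               "factor")
})

test_that("matched pairs follow the initial- and final-value conventions", {
  mi <- matched_pairs("initial")
  expect_equal(mi$constant[mi$decreasing == "dec1"], "const1")
  expect_equal(mi$constant[mi$decreasing == "dec2"], "const1")
  expect_equal(mi$constant[mi$decreasing == "dec3"], "const2")
  mf <- matched_pairs("final")
  expect_equal(mf$constant[mf$decreasing == "dec1"], "const2")
  expect_equal(mf$constant[mf$decreasing == "dec2"], "const3")
  expect_equal(mf$constant[mf$decreasing == "dec3"], "const3")
})

test_that("schedules and regimens serialize to JSON", {
  j <- jsonlite::fromJSON(schedule_to_json(make_lr_schedule("dec1", 100)))
  expect_equal(j$initial_lr, 0.01)
  expect_equal(j$steps$after_epoch, 50)
  r <- jsonlite::fromJSON(schedule_to_json(make_regimen("D2F", 100)))
  expect_equal(r$phases$kind, c("blur", "none"))
})
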