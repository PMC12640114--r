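# Shared fixtures, built in code and memoised per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env))
    assign(key, force(expr), envir = .fixture_env)
  get(key, envir = .fixture_env)
}

# small 3-class set used by deterministic image/cue tests
tiny_sets <- function() memo("tiny_sets", {
  generate_dataset(imageset_spec(
    n_classes = 3, train_per_class = 6, test_per_class = 3,
    image_size = 64, seed = 42))
})

# 2-class micro set + architecture for fast training-loop tests
micro_sets <- function() memo("micro_sets", {
  generate_dataset(imageset_spec(
    n_classes = 2, train_per_class = 12, test_per_class = 4,
    image_size = 32, seed = 7))
})

micro_arch <- function() arch_config(
  conv_layers = list(list(n_filters = 8L, kernel = 5L),
                     list(n_filters = 8L, kernel = 3L)),
  fc_hidden = 16L, n_classes = 2L, input_size = 28L)

micro_train <- function(regimen_name = "F2F", sched_name = "const1",
                        epochs = 2L, seed = 1L, sched = NULL,
                        domain = "blur") {
  sets <- micro_sets()
  if (is.null(sched)) sched <- make_lr_schedule(sched_name, epochs)
  train(micro_arch(), sets$train, sets$test,
        make_regimen(regimen_name, epochs, degraded = domain), sched,
        train_config(batch_size = 8L, epochs = epochs, seed = seed))
}

# deterministic pseudo-random raster in [lo, hi]
random_raster <- function(n = 16, seed = 1, lo = 0.2, hi = 0.8) {
  set.seed(seed)
  array(runif(n * n * 3, lo, hi), dim = c(n, n, 3))
}

# brute-force direct 2-D convolution with symmetric-reflection padding
direct_blur <- function(image, sigma) {
  r <- ceiling(4 * sigma)
  x <- (-r):r
  k1 <- exp(-x^2 / (2 * sigma^2)); k1 <- k1 / sum(k1)
  k2 <- outer(k1, k1)
  d <- dim(image)
  reflect <- function(i, n) {
    i <- ifelse(i < 1, 1 - i, i)
    ifelse(i > n, 2 * n + 1 - i, i)
  }
  out <- image
  for (ch in 1:3)
    for (i in seq_len(d[1]))
      for (j in seq_len(d[2])) {
        acc <- 0
        for (a in seq_along(x))
          for (b in seq_along(x)) {
            ii <- reflect(i + x[a], d[1])
            jj <- reflect(j + x[b], d[2])
            acc <- acc + k2[a, b] * image[ii, jj, ch]
          }
        out[i, j, ch] <- acc
      }
  pmin(pmax(out, 0), 1)
}

# spectral power above a radial frequency cutoff, per channel sum
power_above <- function(image, f0) {
  n <- dim(image)[1]
  fr <- sqrt(outer(blurriculum:::fft_freqs(n)^2,
                   blurriculum:::fft_freqs(dim(image)[2])^2, "+"))
  tot <- 0
  for (ch in 1:3) {
    P <- Mod(fft(image[, , ch]))^2
    tot <- tot + sum(P[fr > f0])
  }
  tot
}
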