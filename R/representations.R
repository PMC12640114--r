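#' Extract first-layer receptive fields from a checkpoint
#'
#' Returns the first convolutional layer's filters as k x k x 3 rasters in
#' index order, plus a tiled visualization raster in which each filter is
#' min-max normalized independently.
#'
#' @param checkpoint A `model_checkpoint` or `run_record` (final checkpoint).
#' @param ncol_tiles Tiles per row of the visualization (default: near
#'   square).
#' @return A list of class `first_layer_filters`: `filters` (list of
#'   k x k x 3 arrays), `tile` (H x W x 3 array in [0, 1]), `kernel`.
#' @export
extract_first_layer <- function(checkpoint, ncol_tiles = NULL) {
  if (inherits(checkpoint, "run_record"))
    checkpoint <- final_checkpoint(checkpoint)
  stopifnot(inherits(checkpoint, "model_checkpoint"))
  conv <- checkpoint$model$conv
  if (length(conv) < 1) abort("checkpoint has no conv layer")
  W <- conv[[1]]$W
  K <- conv[[1]]$kernel
  filters <- lapply(seq_len(nrow(W)), function(f) array(W[f, ], c(K, K, 3L)))
  nf <- length(filters)
  if (is.null(ncol_tiles)) ncol_tiles <- ceiling(sqrt(nf))
  nrow_tiles <- ceiling(nf / ncol_tiles)
  pad <- 1L
  th <- nrow_tiles * (K + pad) + pad
  tw <- ncol_tiles * (K + pad) + pad
  tile <- array(0.5, c(th, tw, 3))
  for (f in seq_len(nf)) {
    fr <- filters[[f]]
    rng <- range(fr)
    fr <- if (diff(rng) > 0) (fr - rng[1]) / diff(rng) else fr * 0 + 0.5
    r0 <- ((f - 1) %/% ncol_tiles) * (K + pad) + pad + 1L
    c0 <- ((f - 1) %% ncol_tiles) * (K + pad) + pad + 1L
    tile[r0:(r0 + K - 1L), c0:(c0 + K - 1L), ] <- fr
  }
  structure(list(filters = filters, tile = tile, kernel = K),
            class = "first_layer_filters")
}

#' @export
print.first_layer_filters <- function(x, ...) {
  cat(sprintf("<first_layer_filters> %d filters of %dx%dx3\n",
              length(x$filters), x$kernel, x$kernel))
  invisible(x)
}

#' Chromatic tuning score of a filter
#'
#' Decomposes every spatial position's channel triplet into its achromatic
#' component (projection onto the unit vector (1,1,1)/sqrt(3)) and the
#' chromatic residual, and returns the fraction of total energy carried by
#' the residuals. The score lies in [0, 1]: 0 for grayscale-equivalent
#' filters (all channels equal), 1 for filters whose channel triplets sum to
#' zero everywhere. Invariant to global rescaling of the filter; defined as
#' 0 for an all-zero filter.
#'
#' @param f A k x k x 3 array (a first-layer filter raster).
#' @return A number in [0, 1].
#' @export
color_tuning_score <- function(f) {
  if (!is.array(f) || length(dim(f)) != 3 || dim(f)[3] != 3)
    abort("`f` must be a k x k x 3 array")
  if (any(!is.finite(f))) abort("filter contains non-finite weights")
  m <- matrix(f, ncol = 3)
  total <- sum(m^2)
  if (total == 0) return(0)
  resid <- m - rowMeans(m)
  sum(resid^2) / total
}

#' Spatial-frequency centroid of a filter
#'
#' Converts the filter to its achromatic component (channel mean), subtracts
#' the mean, and returns the power-weighted mean radial frequency of its 2-D
#' discrete Fourier spectrum over non-DC bins, in cycles/pixel. Invariant to
#' amplitude scaling and constant offsets; defined as 0 for a constant
#' filter.
#'
#' @param f A k x k x 3 array (or k x k matrix, treated as achromatic).
#' @return A non-negative number, at most `0.5 * sqrt(2)`.
#' @export
sf_centroid <- function(f) {
  if (is.matrix(f)) f <- array(rep(f, 3), c(dim(f), 3))
  if (!is.array(f) || length(dim(f)) != 3 || dim(f)[3] != 3)
    abort("`f` must be a k x k x 3 array")
  if (any(!is.finite(f))) abort("filter contains non-finite weights")
  a <- (f[, , 1] + f[, , 2] + f[, , 3]) / 3
  a <- a - mean(a)
  P <- Mod(fft(a))^2
  fr <- sqrt(outer(fft_freqs(nrow(a))^2, fft_freqs(ncol(a))^2, "+"))
  nondc <- fr > 0
  tot <- sum(P[nondc])
  if (tot == 0) return(0)
  sum(P[nondc] * fr[nondc]) / tot
}

#' Count scatter points strictly below the diagonal
#'
#' Convention: the first score of each pair sits on the vertical axis (the
#' decreasing-rate model), the second on the horizontal (the constant-rate
#' model); a point is below the diagonal iff `score_A < score_B` strictly —
#' ties are not below.
#'
#' @param pairs A two-column matrix / data frame of `(score_A, score_B)`
#'   pairs, or a list of length-2 vectors.
#' @return A list with `count_below` and `total`.
#' @export
below_diagonal_count <- function(pairs) {
  if (is.list(pairs) && !is.data.frame(pairs))
    pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (nrow(pairs) == 0) abort("`pairs` must be non-empty")
  if (ncol(pairs) != 2 || any(!is.finite(pairs)))
    abort("`pairs` must be finite (score_A, score_B) rows")
  list(count_below = sum(pairs[, 1] < pairs[, 2]), total = nrow(pairs))
}

#' Score every first-layer filter of a checkpoint
#'
#' @param checkpoint A `model_checkpoint` or `run_record`.
#' @return A tibble: `filter_index`, `color_score`, `sf_centroid`.
#' @export
tuning_scores <- function(checkpoint) {
  fl <- extract_first_layer(checkpoint)
  tibble(filter_index = seq_along(fl$filters),
         color_score = map_dbl(fl$filters, color_tuning_score),
         sf_centroid = map_dbl(fl$filters, sf_centroid))
}

get_layer_W <- function(checkpoint, layer_name) {
  l <- checkpoint$layers[[layer_name]]
  if (is.null(l)) abort(sprintf("no layer named '%s'", layer_name))
  l$W
}

#' Epoch-to-epoch weight change magnitude of one layer
#'
#' Mean absolute elementwise difference of the layer's kernel weights
#' between two checkpoints (biases excluded).
#'
#' @param ckpt_t,ckpt_t1 `model_checkpoint`s with identical layer shapes.
#' @param layer_name A name from the checkpoint's `layers` list.
#' @return A non-negative number.
#' @export
weight_change_magnitude <- function(ckpt_t, ckpt_t1, layer_name) {
  W0 <- get_layer_W(ckpt_t, layer_name)
  W1 <- get_layer_W(ckpt_t1, layer_name)
  if (!identical(dim(W0), dim(W1))) abort("layer shapes differ")
  mean(abs(W1 - W0))
}

#' Correlation of one layer's weights between adjacent epochs
#'
#' Pearson correlation between the flattened kernel weight vectors of the
#' layer at the two checkpoints (biases excluded). Scale- and
#' offset-invariant, so it disregards changes in the absolute strength of
#' filters. Returns `NA` (flagged by a warning-free attribute in summaries)
#' when either layer has zero variance.
#'
#' @inheritParams weight_change_magnitude
#' @return A number in [-1, 1], or `NA` for a zero-variance layer.
#' @export
adjacent_epoch_correlation <- function(ckpt_t, ckpt_t1, layer_name) {
  W0 <- as.vector(get_layer_W(ckpt_t, layer_name))
  W1 <- as.vector(get_layer_W(ckpt_t1, layer_name))
  if (length(W0) != length(W1)) abort("layer shapes differ")
  if (sd(W0) == 0 || sd(W1) == 0) return(NA_real_)
  cor(W0, W1)
}

#' Layer-wise weight dynamics of a training run
#'
#' For every tracked layer and every adjacent pair of stored checkpoints,
#' computes the weight change magnitude and the adjacent-epoch correlation.
#' The summary reports, per layer, the first epoch at which the correlation
#' reaches the stabilization threshold (default 0.99) — the regime where
#' representations have effectively stopped changing.
#'
#' @param run A `run_record` with at least two checkpoints.
#' @param threshold Stabilization threshold on the correlation.
#' @return A list of class `dynamics_profile`: `records` (tibble with
#'   `layer`, `epoch_from`, `epoch_to`, `change_magnitude`, `correlation`),
#'   `summary` (tibble with `layer`, `stabilization_epoch`), `threshold`.
#' @export
dynamics_profile <- function(run, threshold = 0.99) {
  stopifnot(inherits(run, "run_record"))
  cks <- run$checkpoints
  if (length(cks) < 2) abort("run has fewer than 2 checkpoints")
  layers <- names(cks[[1]]$layers)
  rows <- list()
  for (l in layers) for (i in seq_len(length(cks) - 1L)) {
    rows[[length(rows) + 1L]] <- tibble(
      layer = l, epoch_from = cks[[i]]$epoch, epoch_to = cks[[i + 1L]]$epoch,
      change_magnitude = weight_change_magnitude(cks[[i]], cks[[i + 1L]], l),
      correlation = adjacent_epoch_correlation(cks[[i]], cks[[i + 1L]], l))
  }
  records <- bind_rows(rows)
  summary <- records |>
    filter(!is.na(.data$correlation)) |>
    group_by(layer = .data$layer) |>
    summarise(stabilization_epoch = {
      hit <- .data$epoch_to[.data$correlation >= threshold]
      if (length(hit) > 0) min(hit) else NA_integer_
    }, .groups = "drop")
  summary <- summary[match(layers, summary$layer), ]
  structure(list(records = records, summary = summary,
                 threshold = threshold,
                 regimen_name = run$regimen$name,
                 lr_schedule_name = run$lr_schedule$name, seed = run$seed),
            class = "dynamics_profile")
}

#' @export
print.dynamics_profile <- function(x, ...) {
  cat(sprintf("<dynamics_profile> %s x %s seed %d; threshold %.2f\n",
              x$regimen_name, x$lr_schedule_name, x$seed, x$threshold))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.dynamics_profile <- function(x, ...) {
  mutate(x$records, regimen = x$regimen_name,
         lr_schedule = x$lr_schedule_name, seed = x$seed)
}

#' @export
glance.dynamics_profile <- function(x, ...) {
  tibble(regimen = x$regimen_name, lr_schedule = x$lr_schedule_name,
         seed = x$seed, n_layers = length(unique(x$records$layer)),
         n_pairs = nrow(x$records),
         mean_correlation = mean(x$records$correlation, na.rm = TRUE))
}

#' Per-filter tuning scatter between two matched runs
#'
#' Pairs first-layer filters by index between two runs trained from the same
#' initialization seed (so indices correspond), scoring each filter with
#' `metric`. By the plotting convention the first run (decreasing rate) is
#' the vertical axis.
#'
#' @param run_dec,run_con `run_record`s (or checkpoints) sharing an
#'   initialization seed.
#' @param metric `"color"` or `"sf"`.
#' @return A tibble `filter_index`, `score_decreasing`, `score_constant`,
#'   with the below-diagonal count in attributes `count_below` / `total`.
#' @export
rf_scatter <- function(run_dec, run_con, metric = c("color", "sf")) {
  metric <- match.arg(metric)
  score <- if (metric == "color") color_tuning_score else sf_centroid
  fd <- extract_first_layer(run_dec)$filters
  fc <- extract_first_layer(run_con)$filters
  if (length(fd) != length(fc)) abort("runs have different filter counts")
  out <- tibble(filter_index = seq_along(fd),
                score_decreasing = map_dbl(fd, score),
                score_constant = map_dbl(fc, score))
  bd <- below_diagonal_count(cbind(out$score_decreasing, out$score_constant))
  attr(out, "count_below") <- bd$count_below
  attr(out, "total") <- bd$total
  out
}
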