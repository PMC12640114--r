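#' Plot the training trajectory of a run
#'
#' Train loss and test accuracies (full and domain-degraded) against epoch,
#' with the learning rate on a companion strip.
#'
#' @param object A `run_record`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.run_record <- function(object, ...) {
  pe <- tidy(object)
  long <- tidyr::pivot_longer(
    pe, c("train_loss", "test_acc_full", "test_acc_degraded"),
    names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$epoch, y = .data$value,
                   colour = .data$metric)) +
    geom_line() +
    facet_wrap(~ ifelse(.data$metric == "train_loss", "loss", "accuracy"),
               scales = "free_y") +
    labs(title = sprintf("%s x %s (seed %d)", object$regimen$name,
                         object$lr_schedule$name, object$seed),
         x = "epoch", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Plot a test-degradation sweep
#'
#' Accuracy curves against test blur sigma or hue-rotation angle, one line
#' per regimen x schedule, mean over seeds with a ±1 SE ribbon when several
#' seeds are present.
#'
#' @param records Sweep rows from [blur_sweep()] or [hue_sweep()].
#' @return A ggplot.
#' @export
plot_sweep <- function(records) {
  xvar <- if (all(is.na(records$angle))) "sigma_ref" else "angle"
  agg <- records |>
    group_by(.data$regimen_name, .data$lr_schedule_name,
             across(all_of(xvar))) |>
    summarise(mean_accuracy = mean(.data$top1_accuracy),
              se = if (n() > 1) sd(.data$top1_accuracy) / sqrt(n())
                   else NA_real_, .groups = "drop") |>
    mutate(condition = paste(.data$regimen_name, .data$lr_schedule_name))
  p <- ggplot(agg, aes(x = .data[[xvar]], y = .data$mean_accuracy,
                       colour = .data$condition, group = .data$condition))
  if (any(!is.na(agg$se)))
    p <- p + geom_ribbon(aes(ymin = .data$mean_accuracy - .data$se,
                             ymax = .data$mean_accuracy + .data$se,
                             fill = .data$condition),
                         alpha = 0.15, colour = NA)
  p + geom_line() + geom_point() +
    labs(x = if (xvar == "sigma_ref") "test blur (reference sigma)"
             else "hue rotation (degrees)",
         y = "top-1 accuracy", colour = NULL, fill = NULL) +
    theme_minimal()
}

#' Plot the per-filter tuning scatter of two matched runs
#'
#' One point per first-layer filter; the decreasing-rate score on the
#' vertical axis, the constant-rate score on the horizontal; points below
#' the identity line mark filters tuned more to the degraded stimulus
#' statistics under the decreasing rate.
#'
#' @param scatter A tibble from [rf_scatter()].
#' @return A ggplot.
#' @export
plot_rf_scatter <- function(scatter) {
  bd <- attr(scatter, "count_below")
  tot <- attr(scatter, "total")
  ggplot(scatter, aes(x = .data$score_constant,
                      y = .data$score_decreasing)) +
    geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.7) +
    coord_equal() +
    labs(x = "constant LR score", y = "decreasing LR score",
         subtitle = if (!is.null(bd))
           sprintf("%d of %d below the diagonal", bd, tot) else NULL) +
    theme_minimal()
}

#' Plot layer-wise weight dynamics
#'
#' Heat-map-style tiles of epoch-by-epoch weight change magnitude and
#' adjacent-epoch correlation per layer.
#'
#' @param x A `dynamics_profile`.
#' @param metric `"correlation"` or `"change_magnitude"`.
#' @return A ggplot.
#' @export
plot_dynamics <- function(x, metric = c("correlation", "change_magnitude")) {
  metric <- match.arg(metric)
  rec <- x$records
  rec$layer <- factor(rec$layer, levels = unique(rec$layer))
  ggplot(rec, aes(x = .data$epoch_to, y = .data$layer,
                  fill = .data[[metric]])) +
    geom_tile() +
    scale_fill_viridis_c() +
    labs(x = "epoch", y = NULL, fill = metric,
         title = sprintf("%s x %s (seed %d)", x$regimen_name,
                         x$lr_schedule_name, x$seed)) +
    theme_minimal()
}

#' @rdname plot_dynamics
#' @param object A `dynamics_profile`.
#' @param ... Unused.
#' @export
autoplot.dynamics_profile <- function(object, ...) plot_dynamics(object)

#' Display a labeled image set or a filter tile raster
#'
#' @param object An `imageset` (a sample grid is drawn) or
#'   `first_layer_filters` (the tile raster).
#' @param n Number of sample images for an `imageset`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.imageset <- function(object, n = 12, ...) {
  idx <- seq(1, length(object$images), length.out = min(n, length(object$images)))
  idx <- unique(round(idx))
  df <- bind_rows(lapply(idx, function(i) {
    im <- object$images[[i]]
    d <- dim(im)
    tibble(img = i, label = object$labels[i],
           y = rep(seq_len(d[1]), d[2]),
           x = rep(seq_len(d[2]), each = d[1]),
           col = grDevices::rgb(as.vector(im[, , 1]), as.vector(im[, , 2]),
                                as.vector(im[, , 3])))
  }))
  ggplot(df, aes(.data$x, -.data$y, fill = .data$col)) +
    geom_raster() + scale_fill_identity() +
    facet_wrap(~ paste0("img ", .data$img, " / class ", .data$label)) +
    coord_equal() + theme_void()
}

#' @rdname autoplot.imageset
#' @export
autoplot.first_layer_filters <- function(object, ...) {
  im <- object$tile
  d <- dim(im)
  df <- tibble(y = rep(seq_len(d[1]), d[2]),
               x = rep(seq_len(d[2]), each = d[1]),
               col = grDevices::rgb(as.vector(im[, , 1]),
                                    as.vector(im[, , 2]),
                                    as.vector(im[, , 3])))
  ggplot(df, aes(.data$x, -.data$y, fill = .data$col)) +
    geom_raster() + scale_fill_identity() + coord_equal() + theme_void()
}
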