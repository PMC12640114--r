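#' Evaluate a checkpoint on a test set under one degradation condition
#'
#' Every test image is degraded per `condition`, preprocessed in eval mode
#' (deterministic center crop, no flip, rescale to [-1, 1]) and classified;
#' top-1 accuracy is the fraction of correct predictions. Deterministic given
#' the checkpoint and set, and invariant to test-set order.
#'
#' @param checkpoint A `model_checkpoint` (e.g. the final checkpoint of a
#'   [train()] run) or a `run_record`, whose final checkpoint is used.
#' @param test_set An `imageset` with matching `n_classes`.
#' @param condition A [degradation()] applied to every test image.
#' @param regimen_name,lr_schedule_name,seed Optional metadata carried into
#'   the record (filled automatically when a `run_record` is passed).
#' @return A one-row tibble: `regimen_name`, `lr_schedule_name`, `seed`,
#'   `test_condition`, `sigma_ref`, `angle`, `top1_accuracy`, `n_test`.
#' @export
evaluate <- function(checkpoint, test_set, condition = degradation("none"),
                     regimen_name = NA_character_,
                     lr_schedule_name = NA_character_, seed = NA_integer_) {
  if (inherits(checkpoint, "run_record")) {
    run <- checkpoint
    regimen_name <- run$regimen$name
    lr_schedule_name <- run$lr_schedule$name
    seed <- run$seed
    checkpoint <- final_checkpoint(run)
  }
  stopifnot(inherits(checkpoint, "model_checkpoint"),
            inherits(test_set, "imageset"), inherits(condition, "degradation"))
  if (length(test_set$images) == 0) abort("empty test set")
  if (test_set$n_classes != checkpoint$arch$n_classes)
    abort("class-count mismatch between checkpoint and test set")
  imgs <- degrade_images(test_set$images, condition)
  acc <- model_accuracy(checkpoint$model, imgs, test_set$labels,
                        checkpoint$arch$input_size)
  tibble(regimen_name = regimen_name, lr_schedule_name = lr_schedule_name,
         seed = seed, test_condition = format(condition),
         sigma_ref = if (condition$kind == "blur") condition$sigma_ref
                     else NA_real_,
         angle = if (condition$kind == "hue_rotation") condition$angle
                 else NA_real_,
         top1_accuracy = acc, n_test = length(test_set$images))
}

#' Test-blur and hue-rotation evaluation sweeps
#'
#' `blur_sweep()` evaluates the checkpoint across a grid of test-time blur
#' reference sigmas (sigma 0 is the unmodified condition); `hue_sweep()`
#' across a grid of hue-rotation angles (angle 0 likewise).
#'
#' @inheritParams evaluate
#' @param sigmas Non-negative blur reference sigmas (default 0:4).
#' @param angles Hue angles in degrees, within [0, 360)
#'   (default 0 to 180 in 30-degree steps).
#' @return A tibble with one [evaluate()] row per grid point.
#' @export
blur_sweep <- function(checkpoint, test_set, sigmas = 0:4, ...) {
  if (any(sigmas < 0)) abort("`sigmas` must be non-negative")
  bind_rows(lapply(sigmas, function(s) {
    cond <- if (s == 0) degradation("none") else degradation("blur", sigma_ref = s)
    mutate(evaluate(checkpoint, test_set, cond, ...), sigma_ref = s)
  }))
}

#' @rdname blur_sweep
#' @export
hue_sweep <- function(checkpoint, test_set, angles = seq(0, 180, by = 30), ...) {
  if (any(angles < 0 | angles >= 360)) abort("`angles` must lie in [0, 360)")
  bind_rows(lapply(angles, function(a) {
    cond <- if (a == 0) degradation("none")
            else degradation("hue_rotation", angle = a)
    mutate(evaluate(checkpoint, test_set, cond, ...), angle = a)
  }))
}

#' Matched decreasing-vs-constant learning-rate comparison
#'
#' For each matched pair of schedules (see [matched_pairs()]) and each
#' regimen x test-condition cell, computes the per-seed accuracy difference
#' (decreasing minus constant), its mean over seeds, and the standard error
#' of the per-seed differences.
#'
#' @param records A tibble of [evaluate()] rows covering both members of
#'   each pair for at least one common seed.
#' @param matching_basis `"initial"` or `"final"`.
#' @return A tibble: `regimen_name`, `decreasing`, `constant`,
#'   `matching_basis`, `test_condition`, `delta_accuracy`, `se`, `n_seeds`.
#' @export
compare_matched <- function(records, matching_basis = c("initial", "final")) {
  matching_basis <- match.arg(matching_basis)
  pairs <- matched_pairs(matching_basis)
  pairs <- pairs[pairs$decreasing %in% records$lr_schedule_name &
                 pairs$constant %in% records$lr_schedule_name, ]
  if (nrow(pairs) == 0)
    abort("records contain no complete matched schedule pair")
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    dec <- records[records$lr_schedule_name == pairs$decreasing[i], ]
    con <- records[records$lr_schedule_name == pairs$constant[i], ]
    joined <- inner_join(
      distinct(dec[, c("regimen_name", "seed", "test_condition",
                       "top1_accuracy")]),
      distinct(con[, c("regimen_name", "seed", "test_condition",
                       "top1_accuracy")]),
      by = c("regimen_name", "seed", "test_condition"),
      suffix = c("_dec", "_con"), relationship = "one-to-one")
    if (nrow(joined) == 0)
      abort(sprintf("no overlapping runs for pair (%s, %s)",
                    pairs$decreasing[i], pairs$constant[i]))
    out[[i]] <- joined |>
      mutate(delta = .data$top1_accuracy_dec - .data$top1_accuracy_con) |>
      group_by(.data$regimen_name, .data$test_condition) |>
      summarise(delta_accuracy = mean(.data$delta),
                se = if (n() > 1) sd(.data$delta) / sqrt(n()) else NA_real_,
                n_seeds = n(), .groups = "drop") |>
      mutate(decreasing = pairs$decreasing[i], constant = pairs$constant[i],
             matching_basis = matching_basis)
  }
  bind_rows(out)[, c("regimen_name", "decreasing", "constant",
                     "matching_basis", "test_condition", "delta_accuracy",
                     "se", "n_seeds")]
}

#' Aggregate evaluation records over seeds
#'
#' Means and standard errors (sample standard deviation over sqrt(n)) per
#' cell, following the three-seed reporting convention. With a single seed
#' the SE is reported as `NA` and flagged.
#'
#' @param records A tibble of [evaluate()] rows.
#' @return A tibble grouped by regimen, schedule and test condition with
#'   `mean_accuracy`, `se`, `n_seeds`, `se_defined`.
#' @export
aggregate_seeds <- function(records) {
  records |>
    group_by(.data$regimen_name, .data$lr_schedule_name,
             .data$test_condition) |>
    summarise(mean_accuracy = mean(.data$top1_accuracy),
              se = if (n() > 1) sd(.data$top1_accuracy) / sqrt(n())
                   else NA_real_,
              n_seeds = n(), .groups = "drop") |>
    mutate(se_defined = !is.na(.data$se))
}

#' Timing sweeps over the degraded phase and the learning-rate switch
#'
#' Two companion sweeps around the degraded-to-full regimen:
#' \describe{
#'   \item{`mode = "lr_timing"`}{holds the stimulus phases fixed at the
#'     half/half split and varies only the epoch after which the rate drops
#'     from 0.01 to 0.001 (`switch_epochs`).}
#'   \item{`mode = "phase_length"`}{varies the degraded-phase length `k`
#'     (epochs on the current scale) with the rate switch co-timed at `k`.}
#' }
#' Each grid point trains one run per seed and evaluates full and
#' domain-degraded accuracy at the final epoch.
#'
#' @param train_set,test_set `imageset` objects.
#' @param arch An [arch_config()].
#' @param config A [train_config()]; its `epochs` set the run length.
#' @param domain `"acuity"` (blur) or `"color"` (grayscale).
#' @param switch_epochs Integer epochs within `[1, epochs]`.
#' @param mode See Details.
#' @param seeds Integer seeds (one run each per switch epoch).
#' @return A tibble with one row per (switch epoch, seed, condition).
#' @export
timing_sweep <- function(train_set, test_set, arch, config,
                         domain = c("acuity", "color"), switch_epochs,
                         mode = c("lr_timing", "phase_length"),
                         seeds = config$seed) {
  domain <- match.arg(domain)
  mode <- match.arg(mode)
  epochs <- config$epochs
  if (any(switch_epochs < 1 | switch_epochs > epochs))
    abort("`switch_epochs` out of range")
  degraded <- if (domain == "acuity") "blur" else "grayscale"
  out <- list()
  for (k in switch_epochs) for (s in seeds) {
    cfg <- config; cfg$seed <- as.integer(s)
    if (mode == "lr_timing") {
      reg <- make_regimen("D2F", epochs, degraded = degraded)
    } else {
      reg <- make_regimen("D2F", epochs, degraded = degraded)
      # rebuild with a k-epoch degraded phase
      reg$phases$n_epochs <- c(as.integer(k), as.integer(epochs - k))
    }
    sched <- make_lr_schedule("dec1", epochs)
    if (k >= epochs) {
      sched <- make_lr_schedule("const1", epochs)
      sched$name <- "dec1"
    } else {
      sched$steps$after_epoch <- as.integer(k)
    }
    run <- train(arch, train_set, test_set, reg, sched, cfg)
    cond_deg <- domain_degradation(reg)
    out[[length(out) + 1L]] <- bind_rows(
      evaluate(run, test_set, degradation("none")),
      evaluate(run, test_set, cond_deg)) |>
      mutate(switch_epoch = k, mode = mode, domain = domain)
  }
  bind_rows(out)
}

#' Abrupt-versus-gradual factorial around the degraded-to-full regimen
#'
#' Crosses blur decay (abrupt half/half D2F versus the five-level gradual
#' blur ladder) with learning-rate decay (abrupt `dec1` versus the
#' five-block `gradual` schedule): four runs per seed, each ending in a
#' test-blur sweep.
#'
#' @inheritParams timing_sweep
#' @param sigmas Test-blur grid passed to [blur_sweep()].
#' @return A tibble of sweep rows with `blur_decay` and `lr_decay` columns.
#' @export
gradual_factorial <- function(train_set, test_set, arch, config,
                              seeds = config$seed, sigmas = 0:4) {
  epochs <- config$epochs
  cells <- expand.grid(blur_decay = c("abrupt", "gradual"),
                       lr_decay = c("abrupt", "gradual"),
                       stringsAsFactors = FALSE)
  out <- list()
  for (i in seq_len(nrow(cells))) for (s in seeds) {
    cfg <- config; cfg$seed <- as.integer(s)
    reg <- if (cells$blur_decay[i] == "abrupt")
      make_regimen("D2F", epochs, degraded = "blur")
    else make_regimen("gradual_blur", epochs)
    sched <- make_lr_schedule(
      if (cells$lr_decay[i] == "abrupt") "dec1" else "gradual", epochs)
    run <- train(arch, train_set, test_set, reg, sched, cfg)
    out[[length(out) + 1L]] <-
      blur_sweep(run, test_set, sigmas = sigmas) |>
      mutate(blur_decay = cells$blur_decay[i], lr_decay = cells$lr_decay[i])
  }
  bind_rows(out)
}

# completeness check used before factorial comparisons
assert_complete_factorial <- function(records) {
  cells <- expand.grid(regimen_name = unique(records$regimen_name),
                       lr_schedule_name = unique(records$lr_schedule_name),
                       seed = unique(records$seed),
                       test_condition = unique(records$test_condition),
                       stringsAsFactors = FALSE)
  have <- paste(records$regimen_name, records$lr_schedule_name,
                records$seed, records$test_condition)
  want <- paste(cells$regimen_name, cells$lr_schedule_name, cells$seed,
                cells$test_condition)
  missing <- setdiff(want, have)
  if (length(missing) > 0)
    abort(paste0("incomplete factorial; missing cells:\n  ",
                 paste(head(missing, 10), collapse = "\n  ")))
  invisible(records)
}
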