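#' Training regimens: epoch-indexed stimulus trajectories
#'
#' A regimen orders degraded and full-fidelity inputs over training epochs.
#' Presets follow the four canonical stimulus trajectories plus their
#' variants:
#' \describe{
#'   \item{F2F}{full-fidelity inputs for all epochs (two identical phases).}
#'   \item{D2D}{degraded inputs (blur or grayscale) for all epochs.}
#'   \item{D2F}{the developmentally inspired order: the first half degraded,
#'     the second half full-fidelity.}
#'   \item{F2D}{the inverse: full first, degraded last.}
#'   \item{D2F_partial}{D2F with a shorter degraded opening phase
#'     (`partial_degraded_epochs` of 10, 20, 30 or 40 on a 100-epoch scale,
#'     rescaled proportionally for other lengths).}
#'   \item{gradual_blur}{five equal phases at blur reference sigmas
#'     4, 3, 2, 1, 0.}
#' }
#' Switch points scale proportionally with `total_epochs` (rounded to the
#' nearest epoch), so a 20-epoch run switches after epoch 10 where a
#' 100-epoch run switches after epoch 50.
#'
#' @param name Preset name: `"F2F"`, `"D2D"`, `"D2F"`, `"F2D"`,
#'   `"D2F_partial"` or `"gradual_blur"`.
#' @param total_epochs Total training epochs.
#' @param degraded Degraded-input kind for the two-phase presets: `"blur"`
#'   (acuity domain) or `"grayscale"` (color domain).
#' @param sigma_ref Blur reference sigma for `degraded = "blur"` (default 4).
#' @param partial_degraded_epochs Degraded-phase length on the 100-epoch
#'   scale for `D2F_partial` (one of 10, 20, 30, 40).
#' @return An object of class `regimen` with a `phases` tibble
#'   (`kind`, `sigma_ref`, `angle`, `n_epochs`) and `total_epochs`.
#' @examples
#' make_regimen("D2F", 100, degraded = "blur")
#' make_regimen("gradual_blur", 100)
#' @export
make_regimen <- function(name, total_epochs = 100L,
                         degraded = c("blur", "grayscale"),
                         sigma_ref = 4, partial_degraded_epochs = NULL) {
  degraded <- match.arg(degraded)
  total_epochs <- as.integer(total_epochs)
  if (total_epochs < 2) abort("`total_epochs` must be at least 2")
  half <- as.integer(round(total_epochs / 2))
  deg_row <- function(n) {
    if (degraded == "blur")
      tibble(kind = "blur", sigma_ref = sigma_ref, angle = NA_real_,
             n_epochs = as.integer(n))
    else
      tibble(kind = "grayscale", sigma_ref = NA_real_, angle = NA_real_,
             n_epochs = as.integer(n))
  }
  none_row <- function(n) tibble(kind = "none", sigma_ref = NA_real_,
                                 angle = NA_real_, n_epochs = as.integer(n))
  phases <- switch(name,
    F2F = bind_rows(none_row(half), none_row(total_epochs - half)),
    D2D = bind_rows(deg_row(half), deg_row(total_epochs - half)),
    D2F = bind_rows(deg_row(half), none_row(total_epochs - half)),
    F2D = bind_rows(none_row(half), deg_row(total_epochs - half)),
    D2F_partial = {
      if (is.null(partial_degraded_epochs) ||
          !partial_degraded_epochs %in% c(10, 20, 30, 40))
        abort("`partial_degraded_epochs` must be one of 10, 20, 30, 40")
      k <- as.integer(round(partial_degraded_epochs * total_epochs / 100))
      if (k < 1 || k >= total_epochs)
        abort("scaled degraded phase is empty or fills the whole run")
      bind_rows(deg_row(k), none_row(total_epochs - k))
    },
    gradual_blur = {
      bounds <- round(seq(0, total_epochs, length.out = 6))
      lens <- diff(bounds)
      if (any(lens < 1)) abort("`total_epochs` too short for 5 blur phases")
      bind_rows(lapply(1:5, function(i) {
        s <- c(4, 3, 2, 1, 0)[i]
        if (s > 0) tibble(kind = "blur", sigma_ref = s, angle = NA_real_,
                          n_epochs = as.integer(lens[i]))
        else none_row(lens[i])
      }))
    },
    abort(sprintf("unknown regimen preset '%s'", name))
  )
  reg <- structure(list(name = name, phases = phases,
                        total_epochs = total_epochs,
                        degraded = degraded),
                   class = "regimen")
  stopifnot(sum(reg$phases$n_epochs) == total_epochs)
  reg
}

#' @export
print.regimen <- function(x, ...) {
  cat(sprintf("<regimen> %s (%d epochs)\n", x$name, x$total_epochs))
  print(x$phases)
  invisible(x)
}

#' Degradation in force at a given training epoch
#'
#' Phase boundaries are inclusive of their last epoch: in a 100-epoch D2F
#' regimen, epoch 50 is still degraded and epoch 51 is the first full
#' fidelity epoch.
#'
#' @param regimen A [make_regimen()] result.
#' @param epoch 1-based epoch within `[1, total_epochs]`.
#' @return A [degradation()].
#' @export
degradation_at_epoch <- function(regimen, epoch) {
  stopifnot(inherits(regimen, "regimen"))
  if (!is.numeric(epoch) || length(epoch) != 1 || epoch < 1 ||
      epoch > regimen$total_epochs || epoch != round(epoch))
    abort(sprintf("`epoch` must be an integer in [1, %d]",
                  regimen$total_epochs))
  ends <- cumsum(regimen$phases$n_epochs)
  i <- which(epoch <= ends)[1]
  row <- regimen$phases[i, ]
  switch(row$kind,
    none = degradation("none"),
    blur = degradation("blur", sigma_ref = row$sigma_ref),
    grayscale = degradation("grayscale"),
    hue_rotation = degradation("hue_rotation", angle = row$angle)
  )
}

#' Learning-rate schedules
#'
#' Presets reproduce the schedule battery used to model declining plasticity:
#' three constant rates, three midway step decreases, one gradual decrease,
#' and a data-driven reduce-on-plateau rule.
#' \describe{
#'   \item{const1, const2, const3}{constant 0.01 / 0.001 / 0.0001.}
#'   \item{dec1}{0.01 dropping to 0.001 after the (scaled) epoch 50.}
#'   \item{dec2}{0.01 dropping to 0.0001 after the (scaled) epoch 50.}
#'   \item{dec3}{0.001 dropping to 0.0001 after the (scaled) epoch 50.}
#'   \item{gradual}{0.01, 0.0075, 0.005, 0.0025, 0.001 in five equal blocks.}
#'   \item{plateau}{reduce-on-plateau: initial 0.01, factor 0.5, patience 5,
#'     min_delta 0, cooldown 0, min_lr 0.}
#' }
#' "After epoch k" means epochs `<= k` keep the old value and epoch `k + 1`
#' onward uses the new one. Switch epochs scale proportionally with
#' `total_epochs`.
#'
#' @param name Preset identifier (see Details).
#' @param total_epochs Total training epochs (switch points scale with it).
#' @return An object of class `lr_schedule`.
#' @examples
#' lr_at_epoch(make_lr_schedule("dec1", 100), 51)  # 0.001
#' @export
make_lr_schedule <- function(name, total_epochs = 100L) {
  total_epochs <- as.integer(total_epochs)
  half <- as.integer(round(total_epochs / 2))
  step_sched <- function(init, steps) {
    structure(list(name = name, kind = if (nrow(steps) > 1) "multi_step"
                                       else "step",
                   initial_lr = init, steps = steps, plateau = NULL,
                   total_epochs = total_epochs),
              class = "lr_schedule")
  }
  const_sched <- function(init) {
    structure(list(name = name, kind = "constant", initial_lr = init,
                   steps = NULL, plateau = NULL, total_epochs = total_epochs),
              class = "lr_schedule")
  }
  sched <- switch(name,
    const1 = const_sched(0.01),
    const2 = const_sched(0.001),
    const3 = const_sched(0.0001),
    dec1 = step_sched(0.01, tibble(after_epoch = half, lr = 0.001)),
    dec2 = step_sched(0.01, tibble(after_epoch = half, lr = 0.0001)),
    dec3 = step_sched(0.001, tibble(after_epoch = half, lr = 0.0001)),
    gradual = {
      bounds <- round(seq(0, total_epochs, length.out = 6))
      step_sched(0.01, tibble(after_epoch = as.integer(bounds[2:5]),
                              lr = c(0.0075, 0.005, 0.0025, 0.001)))
    },
    plateau = structure(
      list(name = name, kind = "reduce_on_plateau", initial_lr = 0.01,
           steps = NULL,
           plateau = list(factor = 0.5, patience = 5L, min_delta = 0,
                          cooldown = 0L, min_lr = 0),
           total_epochs = total_epochs),
      class = "lr_schedule"),
    abort(sprintf("unknown LR schedule preset '%s'", name))
  )
  validate_lr_schedule(sched)
}

validate_lr_schedule <- function(s) {
  if (!is.null(s$steps) && nrow(s$steps) > 0) {
    if (any(diff(c(0L, s$steps$after_epoch)) <= 0))
      abort("step epochs must be strictly increasing")
    if (any(diff(c(s$initial_lr, s$steps$lr)) >= 0))
      abort("step LR values must be strictly decreasing")
  }
  if (!is.null(s$plateau)) {
    p <- s$plateau
    if (p$factor <= 0 || p$factor >= 1) abort("plateau factor must be in (0,1)")
    if (p$patience < 0 || p$min_delta < 0 || p$cooldown < 0 || p$min_lr < 0)
      abort("plateau parameters must be non-negative")
  }
  s
}

#' @export
print.lr_schedule <- function(x, ...) {
  cat(sprintf("<lr_schedule> %s (%s), initial %g\n", x$name, x$kind,
              x$initial_lr))
  if (!is.null(x$steps)) print(x$steps)
  if (!is.null(x$plateau)) utils::str(x$plateau)
  invisible(x)
}

#' Reduce-on-plateau state machine
#'
#' `plateau_state()` initializes the state; `plateau_update()` consumes one
#' monitored value per epoch. An observation improves when it beats the best
#' seen so far by strictly more than `min_delta`; otherwise the
#' no-improvement counter increments, and once it exceeds `patience` (with no
#' cooldown pending) the rate is multiplied by `factor`, floored at
#' `min_lr`.
#'
#' @param initial_lr Starting learning rate.
#' @param state A `plateau_state`.
#' @param params The `plateau` parameter list of a `plateau` schedule
#'   (`factor`, `patience`, `min_delta`, `cooldown`, `min_lr`).
#' @param monitored The monitored metric for the epoch just finished.
#' @param higher_is_better Direction of improvement (default `TRUE`,
#'   e.g. test accuracy).
#' @return A `plateau_state` list: `current_lr`, `best_metric`,
#'   `epochs_since_improvement`, `cooldown_remaining`.
#' @export
plateau_state <- function(initial_lr) {
  structure(list(current_lr = initial_lr, best_metric = NA_real_,
                 epochs_since_improvement = 0L, cooldown_remaining = 0L),
            class = "plateau_state")
}

#' @rdname plateau_state
#' @export
plateau_update <- function(state, params, monitored, higher_is_better = TRUE) {
  stopifnot(inherits(state, "plateau_state"))
  if (params$factor <= 0 || params$factor >= 1)
    abort("plateau factor must be in (0,1)")
  improved <- is.na(state$best_metric) ||
    (if (higher_is_better) monitored > state$best_metric + params$min_delta
     else monitored < state$best_metric - params$min_delta)
  if (improved) {
    state$best_metric <- monitored
    state$epochs_since_improvement <- 0L
  } else {
    state$epochs_since_improvement <- state$epochs_since_improvement + 1L
  }
  if (state$cooldown_remaining > 0L) {
    state$cooldown_remaining <- state$cooldown_remaining - 1L
  } else if (state$epochs_since_improvement > params$patience) {
    state$current_lr <- max(state$current_lr * params$factor, params$min_lr)
    state$epochs_since_improvement <- 0L
    state$cooldown_remaining <- as.integer(params$cooldown)
  }
  state
}

#' Learning rate in force at a given epoch
#'
#' @param schedule An [make_lr_schedule()] result.
#' @param epoch 1-based epoch.
#' @param state For `reduce_on_plateau` schedules, the current
#'   [plateau_state()]; an error to omit.
#' @return The positive learning rate for that epoch.
#' @export
lr_at_epoch <- function(schedule, epoch, state = NULL) {
  stopifnot(inherits(schedule, "lr_schedule"))
  if (epoch < 1 || epoch != round(epoch))
    abort("`epoch` must be a positive integer")
  if (schedule$kind == "reduce_on_plateau") {
    if (is.null(state))
      abort("plateau schedules require a `plateau_state`")
    return(state$current_lr)
  }
  lr <- schedule$initial_lr
  if (!is.null(schedule$steps))
    for (i in seq_len(nrow(schedule$steps)))
      if (epoch > schedule$steps$after_epoch[i]) lr <- schedule$steps$lr[i]
  lr
}

#' Matched decreasing-vs-constant schedule pairs
#'
#' Each decreasing schedule is compared against the constant schedule sharing
#' its initial value (`basis = "initial"`: dec1 and dec2 against const1, dec3
#' against const2) or its final value (`basis = "final"`: dec1 against
#' const2, dec2 and dec3 against const3).
#'
#' @param basis `"initial"` or `"final"`.
#' @return A tibble with columns `decreasing`, `constant`, `matching_basis`.
#' @export
matched_pairs <- function(basis = c("initial", "final")) {
  basis <- match.arg(basis)
  if (basis == "initial")
    tibble(decreasing = c("dec1", "dec2", "dec3"),
           constant = c("const1", "const1", "const2"),
           matching_basis = basis)
  else
    tibble(decreasing = c("dec1", "dec2", "dec3"),
           constant = c("const2", "const3", "const3"),
           matching_basis = basis)
}

#' Serialize schedules and regimens to JSON
#'
#' @param x A `regimen` or `lr_schedule`.
#' @return A JSON string.
#' @export
schedule_to_json <- function(x) {
  if (inherits(x, "regimen"))
    jsonlite::toJSON(list(type = "regimen", name = x$name,
                          total_epochs = x$total_epochs,
                          degraded = x$degraded,
                          phases = x$phases),
                     auto_unbox = TRUE, dataframe = "rows", na = "null")
  else if (inherits(x, "lr_schedule"))
    jsonlite::toJSON(list(type = "lr_schedule", name = x$name, kind = x$kind,
                          initial_lr = x$initial_lr, steps = x$steps,
                          plateau = x$plateau,
                          total_epochs = x$total_epochs),
                     auto_unbox = TRUE, dataframe = "rows", na = "null")
  else abort("not a regimen or lr_schedule")
}
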