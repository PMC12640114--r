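#' Architecture of the scaled-down convolutional classifier
#'
#' A conv-then-fc classifier preserving, at desk scale, the structure of the
#' large networks used to study visual development: a stack of convolutional
#' layers (ReLU, optional 2x2 max pooling) followed by fully-connected layers
#' ending in a softmax over classes. The default — three conv layers of
#' 32, 64 and 64 filters (5x5 then 3x3 kernels, pooling after each) and one
#' hidden fc layer of 128 units on 56x56 crops — keeps a visualizable first
#' layer and trains on one CPU. At least two conv layers and one hidden fc
#' layer are required so layer-wise dynamics remain analyzable.
#'
#' @param conv_layers List of conv layer descriptors, each a list with
#'   `n_filters`, `kernel`, and optional `stride` (default 1) and `pool`
#'   (default `TRUE`).
#' @param fc_hidden Integer vector of hidden fully-connected widths.
#' @param n_classes Number of output classes.
#' @param input_size Side of the square input crop fed to the network.
#' @return An object of class `arch_config`.
#' @export
arch_config <- function(conv_layers = list(
                          list(n_filters = 32L, kernel = 5L),
                          list(n_filters = 64L, kernel = 3L),
                          list(n_filters = 64L, kernel = 3L)),
                        fc_hidden = 128L, n_classes = 10L,
                        input_size = 56L) {
  if (length(conv_layers) < 2) abort("need at least 2 conv layers")
  if (length(fc_hidden) < 1) abort("need at least 1 hidden fc layer")
  conv_layers <- lapply(conv_layers, function(l) {
    modifyList(list(stride = 1L, pool = TRUE), l)
  })
  arch <- structure(list(conv_layers = conv_layers,
                         fc_hidden = as.integer(fc_hidden),
                         n_classes = as.integer(n_classes),
                         input_size = as.integer(input_size)),
                    class = "arch_config")
  arch_shapes(arch)  # errors if the stack collapses below 1x1
  arch
}

# spatial sizes through the conv stack; returns flattened feature dimension
arch_shapes <- function(arch) {
  s <- arch$input_size
  c_in <- 3L
  shapes <- list()
  for (i in seq_along(arch$conv_layers)) {
    l <- arch$conv_layers[[i]]
    if (l$kernel > s) abort(sprintf("conv layer %d kernel exceeds its input", i))
    s <- (s - l$kernel) %/% l$stride + 1L
    if (isTRUE(l$pool)) s <- s %/% 2L
    if (s < 1) abort(sprintf("feature map vanishes at conv layer %d", i))
    shapes[[i]] <- list(c_in = c_in, side = s)
    c_in <- as.integer(l$n_filters)
  }
  list(shapes = shapes, flat_dim = as.integer(c_in * s * s))
}

#' @export
print.arch_config <- function(x, ...) {
  conv <- paste(vapply(x$conv_layers, function(l)
    sprintf("%dx%dx%d", l$n_filters, l$kernel, l$kernel), character(1)),
    collapse = " -> ")
  cat(sprintf("<arch_config> input %dx%d | conv %s | fc %s -> %d classes\n",
              x$input_size, x$input_size, conv,
              paste(x$fc_hidden, collapse = ","), x$n_classes))
  invisible(x)
}

#' Training configuration
#'
#' SGD with Nesterov momentum 0.9 and restricted augmentation (random crop,
#' horizontal flip, rescale to [-1, 1]) mirror the reference training
#' procedure; batch size and epoch count are scaled down for desk use. All
#' run randomness (initialization, shuffling, crops, flips) flows from
#' `seed` through one RNG stream, so identical configurations reproduce runs
#' bitwise.
#'
#' @param batch_size Minibatch size.
#' @param momentum Nesterov momentum coefficient in [0, 1).
#' @param epochs Total training epochs.
#' @param seed Integer run seed.
#' @param crop_size Square crop side (defaults to the architecture's
#'   `input_size` at train time).
#' @param checkpoint_every Checkpoint cadence in epochs; the final epoch is
#'   always checkpointed, and epoch 0 (initialization) always kept.
#' @param eval_every Test-evaluation cadence in epochs (the final epoch is
#'   always evaluated; plateau schedules force every epoch since they
#'   consume the monitor). Skipped epochs log `NA` accuracies.
#' @param monitor Metric consumed by reduce-on-plateau schedules:
#'   `"test_acc_full"`, `"test_acc_degraded"` or `"train_loss"`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, momentum = 0.9, epochs = 20L,
                         seed = 1L, crop_size = NULL, checkpoint_every = 1L,
                         eval_every = 1L, monitor = "test_acc_full") {
  if (momentum < 0 || momentum >= 1) abort("`momentum` must be in [0, 1)")
  if (epochs < 1) abort("`epochs` must be positive")
  structure(list(batch_size = as.integer(batch_size), momentum = momentum,
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 crop_size = if (is.null(crop_size)) NULL
                             else as.integer(crop_size),
                 checkpoint_every = as.integer(checkpoint_every),
                 eval_every = as.integer(eval_every),
                 monitor = monitor),
            class = "train_config")
}

# internal model representation consumed by the C++ kernels
new_model <- function(arch) {
  info <- arch_shapes(arch)
  conv <- list()
  c_in <- 3L
  for (i in seq_along(arch$conv_layers)) {
    l <- arch$conv_layers[[i]]
    fan_in <- l$kernel^2 * c_in
    conv[[i]] <- list(
      W = matrix(rnorm(l$n_filters * fan_in, 0, sqrt(2 / fan_in)),
                 nrow = l$n_filters),
      b = numeric(l$n_filters),
      kernel = as.integer(l$kernel), stride = as.integer(l$stride),
      pool = isTRUE(l$pool))
    c_in <- as.integer(l$n_filters)
  }
  widths <- c(info$flat_dim, arch$fc_hidden, arch$n_classes)
  fc <- lapply(seq_len(length(widths) - 1L), function(i) {
    list(W = matrix(rnorm(widths[i + 1] * widths[i], 0, sqrt(2 / widths[i])),
                    nrow = widths[i + 1]),
         b = numeric(widths[i + 1]))
  })
  list(conv = conv, fc = fc, input_size = arch$input_size)
}

zero_like_model <- function(model) {
  model$conv <- lapply(model$conv, function(l) {
    l$W <- l$W * 0; l$b <- l$b * 0; l
  })
  model$fc <- lapply(model$fc, function(l) {
    l$W <- l$W * 0; l$b <- l$b * 0; l
  })
  model
}

# deep copy (the C++ step mutates weight memory in place)
copy_model <- function(model) {
  model$conv <- lapply(model$conv, function(l) { l$W <- l$W + 0; l$b <- l$b + 0; l })
  model$fc <- lapply(model$fc, function(l) { l$W <- l$W + 0; l$b <- l$b + 0; l })
  model
}

model_layer_names <- function(model) {
  c(paste0("conv", seq_along(model$conv)), paste0("fc", seq_along(model$fc)))
}

# named list layer_name -> weight matrix (biases kept separately)
model_layers <- function(model) {
  layers <- c(lapply(model$conv, function(l) list(W = l$W, b = l$b)),
              lapply(model$fc, function(l) list(W = l$W, b = l$b)))
  names(layers) <- model_layer_names(model)
  layers
}

new_checkpoint <- function(model, arch, epoch) {
  m <- copy_model(model)  # the C++ step mutates live weights in place
  structure(list(epoch = as.integer(epoch), layers = model_layers(m),
                 arch = arch, model = m),
            class = "model_checkpoint")
}

#' @export
print.model_checkpoint <- function(x, ...) {
  cat(sprintf("<model_checkpoint> epoch %d, layers: %s\n", x$epoch,
              paste(names(x$layers), collapse = ", ")))
  invisible(x)
}

#' Initialize a model checkpoint (epoch 0)
#'
#' Weights are drawn from a fan-in-scaled normal initialization (He), biases
#' start at zero; the draw is deterministic per `seed`.
#'
#' @param arch An [arch_config()].
#' @param seed Integer seed for the weight draw.
#' @return A `model_checkpoint` with `epoch = 0`.
#' @export
build_model <- function(arch, seed) {
  stopifnot(inherits(arch, "arch_config"))
  set.seed(seed)
  new_checkpoint(new_model(arch), arch, 0L)
}

# accuracy of a model on a degraded, eval-mode-preprocessed test set
model_accuracy <- function(model, images, labels, crop_size,
                           batch_size = 256L) {
  n <- length(images)
  correct <- 0L
  for (start in seq(1L, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, n)
    X <- preprocess_batch(images[idx], train_mode = FALSE,
                          crop_size = crop_size)
    logits <- cpp_logits(model, X)
    pred <- max.col(t(logits), ties.method = "first") - 1L
    correct <- correct + sum(pred == labels[idx])
  }
  correct / n
}

#' Train the classifier under a regimen and a learning-rate schedule
#'
#' Runs the full training loop: each epoch, every training image is degraded
#' according to [degradation_at_epoch()], preprocessed in train mode (random
#' crop, random horizontal flip, rescale to [-1, 1]), shuffled into
#' minibatches, and used for one SGD + Nesterov pass at the epoch's
#' [lr_at_epoch()] rate. Degraded versions of the training set are computed
#' once per distinct phase and cached. Weights are checkpointed at the
#' configured cadence (plus initialization and the final epoch); per-epoch
#' train loss and test accuracies on full-fidelity and domain-degraded
#' images are logged. Plateau schedules are updated from the configured
#' monitor after every epoch.
#'
#' @param arch An [arch_config()] (its `n_classes` must match the data).
#' @param train_set,test_set `imageset` objects sharing `n_classes`.
#' @param regimen A [make_regimen()] result with
#'   `total_epochs == config$epochs`.
#' @param lr_schedule A [make_lr_schedule()] result.
#' @param config A [train_config()].
#' @return A `run_record`: regimen, schedule, seed, the list of checkpoints,
#'   and a `per_epoch` tibble (`epoch`, `lr`, `degradation_kind`, `sigma`,
#'   `train_loss`, `test_acc_full`, `test_acc_degraded`).
#' @export
train <- function(arch, train_set, test_set, regimen, lr_schedule, config) {
  stopifnot(inherits(arch, "arch_config"), inherits(train_set, "imageset"),
            inherits(test_set, "imageset"), inherits(regimen, "regimen"),
            inherits(lr_schedule, "lr_schedule"),
            inherits(config, "train_config"))
  if (regimen$total_epochs != config$epochs)
    abort("`regimen$total_epochs` must equal `config$epochs`")
  if (train_set$n_classes != arch$n_classes ||
      test_set$n_classes != arch$n_classes)
    abort("class-count mismatch between data and architecture")
  crop <- if (is.null(config$crop_size)) arch$input_size else config$crop_size
  if (crop != arch$input_size)
    abort("`crop_size` must match the architecture input size")

  set.seed(config$seed)
  model <- new_model(arch)
  velocity <- zero_like_model(model)
  checkpoints <- list(new_checkpoint(model, arch, 0L))

  # cache degraded train / test images per distinct phase degradation
  img_w <- dim(train_set$images[[1]])[2]
  specs <- lapply(seq_len(config$epochs),
                  function(e) degradation_at_epoch(regimen, e))
  cache <- list()
  for (sp in specs) {
    k <- degradation_key(sp)
    if (is.null(cache[[k]])) cache[[k]] <- degrade_images(train_set$images, sp)
  }
  # domain-degraded test condition: strongest degradation of the regimen (or
  # the regimen's domain default for F2F so the log stays comparable)
  test_degr <- domain_degradation(regimen)
  test_full <- test_set$images
  test_deg_imgs <- degrade_images(test_set$images, test_degr)

  pstate <- if (lr_schedule$kind == "reduce_on_plateau")
    plateau_state(lr_schedule$initial_lr) else NULL

  n <- length(train_set$images)
  per_epoch <- vector("list", config$epochs)
  for (epoch in seq_len(config$epochs)) {
    sp <- specs[[epoch]]
    imgs <- cache[[degradation_key(sp)]]
    lr <- lr_at_epoch(lr_schedule, epoch, pstate)
    ord <- sample.int(n)
    losses <- c()
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      X <- preprocess_batch(imgs[idx], train_mode = TRUE, crop_size = crop)
      loss <- cpp_train_batch(model, velocity, X,
                              train_set$labels[idx], lr, config$momentum)
      if (!is.finite(loss))
        abort(sprintf("non-finite loss at epoch %d (lr = %g)", epoch, lr))
      losses <- c(losses, loss)
    }
    eval_every <- if (is.null(config$eval_every)) 1L else config$eval_every
    do_eval <- !is.null(pstate) || epoch %% eval_every == 0L ||
      epoch == config$epochs
    acc_full <- if (do_eval)
      model_accuracy(model, test_full, test_set$labels, crop) else NA_real_
    acc_deg <- if (do_eval)
      model_accuracy(model, test_deg_imgs, test_set$labels, crop)
      else NA_real_
    per_epoch[[epoch]] <- tibble(
      epoch = epoch, lr = lr, degradation_kind = sp$kind,
      sigma = if (sp$kind == "blur") sp$sigma_ref else NA_real_,
      train_loss = mean(losses), test_acc_full = acc_full,
      test_acc_degraded = acc_deg)
    if (!is.null(pstate)) {
      monitored <- switch(config$monitor,
        test_acc_full = acc_full,
        test_acc_degraded = acc_deg,
        train_loss = mean(losses),
        abort(sprintf("unknown monitor '%s'", config$monitor)))
      pstate <- plateau_update(pstate, lr_schedule$plateau, monitored,
                               higher_is_better = config$monitor != "train_loss")
    }
    if (epoch %% config$checkpoint_every == 0L || epoch == config$epochs)
      checkpoints[[length(checkpoints) + 1L]] <-
        new_checkpoint(model, arch, epoch)
  }

  structure(list(regimen = regimen, lr_schedule = lr_schedule,
                 seed = config$seed, arch = arch, config = config,
                 checkpoints = checkpoints,
                 per_epoch = bind_rows(per_epoch)),
            class = "run_record")
}

# the degraded test condition canonically associated with a regimen
domain_degradation <- function(regimen) {
  deg <- regimen$phases[regimen$phases$kind != "none", ]
  if (nrow(deg) == 0) {
    if (identical(regimen$degraded, "grayscale")) degradation("grayscale")
    else degradation("blur", sigma_ref = 4)
  } else if (deg$kind[1] == "grayscale") {
    degradation("grayscale")
  } else {
    degradation("blur", sigma_ref = max(deg$sigma_ref, na.rm = TRUE))
  }
}

#' @export
print.run_record <- function(x, ...) {
  cat(sprintf("<run_record> %s x %s, seed %d, %d epochs, %d checkpoints\n",
              x$regimen$name, x$lr_schedule$name, x$seed,
              nrow(x$per_epoch), length(x$checkpoints)))
  last <- x$per_epoch[nrow(x$per_epoch), ]
  cat(sprintf("  final: loss %.4f | acc full %.3f | acc degraded %.3f\n",
              last$train_loss, last$test_acc_full, last$test_acc_degraded))
  invisible(x)
}

#' @describeIn train Per-epoch log of a run as a tibble.
#' @param x A `run_record`.
#' @param ... Unused.
#' @export
tidy.run_record <- function(x, ...) {
  mutate(x$per_epoch, regimen = x$regimen$name,
         lr_schedule = x$lr_schedule$name, seed = x$seed)
}

#' @describeIn train One-row summary of a run.
#' @export
glance.run_record <- function(x, ...) {
  last <- x$per_epoch[nrow(x$per_epoch), ]
  tibble(regimen = x$regimen$name, lr_schedule = x$lr_schedule$name,
         seed = x$seed, epochs = nrow(x$per_epoch),
         final_train_loss = last$train_loss,
         final_test_acc_full = last$test_acc_full,
         final_test_acc_degraded = last$test_acc_degraded)
}

final_checkpoint <- function(run) run$checkpoints[[length(run$checkpoints)]]
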