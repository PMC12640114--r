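#' Experiment configuration
#'
#' Describes one full experiment grid: the dataset (a generator spec or a
#' manifest directory), the domain (acuity = blur, color = grayscale), the
#' regimen and learning-rate schedule presets, the seeds, the architecture
#' and run length, and the evaluation grids.
#'
#' @param dataset An [imageset_spec()] or a directory containing a
#'   `manifest.csv` (see [read_imageset()]).
#' @param domain `"acuity"` or `"color"`; selects the degraded-input kind.
#' @param regimens Character vector of [make_regimen()] preset names.
#' @param lr_schedules Character vector of [make_lr_schedule()] preset names.
#' @param seeds Integer seeds; one training run per grid cell per seed.
#' @param total_epochs Training epochs per run.
#' @param arch An [arch_config()].
#' @param out_dir Output directory for the results bundle.
#' @param sigmas,angles Evaluation sweep grids (test blur sigmas; hue
#'   angles).
#' @param batch_size Minibatch size.
#' @param checkpoint_every Checkpoint cadence in epochs.
#' @param mode `"grid"` (regimen x schedule factorial), `"timing_sweep"` or
#'   `"gradual_factorial"`.
#' @param switch_epochs Switch-epoch grid for `mode = "timing_sweep"`.
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(dataset, domain = c("acuity", "color"),
                              regimens = c("F2F", "D2D", "D2F", "F2D"),
                              lr_schedules = c("const1", "dec1"),
                              seeds = 1:3, total_epochs = 20L,
                              arch = NULL, out_dir,
                              sigmas = 0:4, angles = seq(0, 180, by = 30),
                              batch_size = 64L, checkpoint_every = 1L,
                              mode = c("grid", "timing_sweep",
                                       "gradual_factorial"),
                              switch_epochs = NULL) {
  domain <- match.arg(domain)
  mode <- match.arg(mode)
  if (length(regimens) == 0 || length(lr_schedules) == 0 ||
      length(seeds) == 0)
    abort("regimens, lr_schedules and seeds must be non-empty")
  structure(list(dataset = dataset, domain = domain, regimens = regimens,
                 lr_schedules = lr_schedules, seeds = as.integer(seeds),
                 total_epochs = as.integer(total_epochs), arch = arch,
                 out_dir = out_dir, sigmas = sigmas, angles = angles,
                 batch_size = as.integer(batch_size),
                 checkpoint_every = as.integer(checkpoint_every),
                 mode = mode, switch_epochs = switch_epochs),
            class = "experiment_config")
}

#' Shipped experiment presets
#'
#' `"paper-desk-acuity"` and `"paper-desk-color"` run the four-regimen grid
#' against matched constant/decreasing schedules in the blur and grayscale
#' domains; `"timing-sweep"` varies the learning-rate switch epoch around
#' the half/half degraded-to-full regimen; `"gradual-factorial"` crosses
#' abrupt/gradual blur decay with abrupt/gradual rate decay.
#'
#' @param name Preset name.
#' @param out_dir Output directory.
#' @param dataset Optional [imageset_spec()] override.
#' @param ... Further overrides passed to [experiment_config()].
#' @return An `experiment_config`.
#' @export
preset_config <- function(name, out_dir, dataset = imageset_spec(), ...) {
  base <- switch(name,
    "paper-desk-acuity" = list(domain = "acuity"),
    "paper-desk-color" = list(domain = "color"),
    "timing-sweep" = list(domain = "acuity", mode = "timing_sweep",
                          regimens = "D2F", lr_schedules = "dec1"),
    "gradual-factorial" = list(domain = "acuity", mode = "gradual_factorial",
                               regimens = c("D2F", "gradual_blur"),
                               lr_schedules = c("dec1", "gradual")),
    abort(sprintf("unknown preset '%s'", name))
  )
  do.call(experiment_config,
          modifyList(c(list(dataset = dataset, out_dir = out_dir), base),
                     list(...)))
}

#' Compact desk evaluation profile
#'
#' The fixed configuration used by the package's replication suite and by
#' `scripts/acceptance.R`: a 10-class synthetic set (60 train + 20 test
#' images per class at 48 x 48 pixels, generator seed 100), a
#' 32/64/64-filter three-conv architecture on 40-pixel crops, 12 training
#' epochs with proportionally scaled switch points, and three run seeds.
#' Sizes are chosen once so the full regimen-by-schedule grid trains on a
#' single CPU in minutes while both cue families remain informative; the
#' methods vignette discusses the choice.
#'
#' @param seeds Run seeds (default 1:3).
#' @return A list: `spec`, `arch`, `epochs`, `batch_size`, `seeds`.
#' @export
desk_profile <- function(seeds = 1:3) {
  list(spec = imageset_spec(n_classes = 10L, train_per_class = 60L,
                            test_per_class = 20L, image_size = 48L,
                            seed = 100L),
       arch = arch_config(n_classes = 10L, input_size = 40L),
       epochs = 20L, batch_size = 64L, seeds = as.integer(seeds))
}

config_hash <- function(config) {
  c2 <- unclass(config)
  c2$out_dir <- NULL
  c2$arch <- if (!is.null(c2$arch)) unclass(c2$arch) else NULL
  c2$dataset <- if (inherits(c2$dataset, "imageset_spec"))
    unclass(c2$dataset) else as.character(c2$dataset)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(c2, auto_unbox = TRUE,
                                           digits = NA, force = TRUE)), tmp)
  unname(tools::md5sum(tmp))
}

read_manifest <- function(out_dir) {
  p <- file.path(out_dir, "manifest.json")
  if (file.exists(p)) jsonlite::fromJSON(p, simplifyVector = FALSE) else NULL
}

write_manifest <- function(out_dir, hash, files) {
  hashes <- tools::md5sum(file.path(out_dir, files))
  jsonlite::write_json(
    list(config_hash = hash,
         files = lapply(seq_along(files), function(i)
           list(path = files[i], md5 = unname(hashes[i])))),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
}

#' Run a full experiment and write the results bundle
#'
#' Generates (or loads) the dataset, trains the full factorial of regimens,
#' learning-rate schedules and seeds, evaluates every run on the
#' full-fidelity and domain-degraded conditions plus the configured sweep,
#' and writes: per-run records (`runs/*.rds`), `eval_records.csv`,
#' matched-comparison tables, first-layer `tuning_scores.csv`,
#' `dynamics.csv`, and a `manifest.json` listing every output with an md5
#' content hash and the configuration hash. Re-running over a completed
#' directory is idempotent: completed runs are skipped; a directory holding
#' results from a different configuration is refused.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with `out_dir`, `eval_records`, `runs` (named
#'   list of `run_record`s for grid mode), and `n_trained` (runs trained in
#'   this call).
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  out_dir <- config$out_dir
  dir.create(file.path(out_dir, "runs"), recursive = TRUE,
             showWarnings = FALSE)
  hash <- config_hash(config)
  man <- read_manifest(out_dir)
  if (!is.null(man) && !identical(man$config_hash, hash))
    abort(paste("output directory contains results from a different",
                "configuration (hash mismatch); use a fresh directory"))

  if (inherits(config$dataset, "imageset_spec")) {
    sets <- generate_dataset(config$dataset)
  } else {
    sets <- list(train = read_imageset(config$dataset, "train"),
                 test = read_imageset(config$dataset, "test"))
  }
  arch <- config$arch
  if (is.null(arch)) arch <- arch_config(n_classes = sets$train$n_classes)
  degraded <- if (config$domain == "acuity") "blur" else "grayscale"

  if (config$mode == "timing_sweep") {
    cfg <- train_config(batch_size = config$batch_size,
                        epochs = config$total_epochs,
                        checkpoint_every = config$checkpoint_every)
    switches <- config$switch_epochs
    if (is.null(switches))
      switches <- unique(round(config$total_epochs * c(.1, .3, .5, .7, .9)))
    res <- timing_sweep(sets$train, sets$test, arch, cfg,
                        domain = config$domain, switch_epochs = switches,
                        mode = "lr_timing", seeds = config$seeds)
    write.csv(res, file.path(out_dir, "timing_sweep.csv"), row.names = FALSE)
    write_manifest(out_dir, hash, "timing_sweep.csv")
    return(invisible(list(out_dir = out_dir, eval_records = res,
                          runs = NULL, n_trained = NA_integer_)))
  }
  if (config$mode == "gradual_factorial") {
    cfg <- train_config(batch_size = config$batch_size,
                        epochs = config$total_epochs,
                        checkpoint_every = config$checkpoint_every)
    res <- gradual_factorial(sets$train, sets$test, arch, cfg,
                             seeds = config$seeds, sigmas = config$sigmas)
    write.csv(res, file.path(out_dir, "gradual_factorial.csv"),
              row.names = FALSE)
    write_manifest(out_dir, hash, "gradual_factorial.csv")
    return(invisible(list(out_dir = out_dir, eval_records = res,
                          runs = NULL, n_trained = NA_integer_)))
  }

  runs <- list()
  n_trained <- 0L
  eval_rows <- list()
  tune_rows <- list()
  dyn_rows <- list()
  for (rname in config$regimens) for (sname in config$lr_schedules)
    for (seed in config$seeds) {
      key <- sprintf("%s_%s_seed%d", rname, sname, seed)
      run_path <- file.path(out_dir, "runs", paste0(key, ".rds"))
      if (file.exists(run_path)) {
        run <- readRDS(run_path)
      } else {
        if (!quiet) message("training ", key)
        reg <- make_regimen(rname, config$total_epochs, degraded = degraded)
        sched <- make_lr_schedule(sname, config$total_epochs)
        cfg <- train_config(batch_size = config$batch_size,
                            epochs = config$total_epochs, seed = seed,
                            checkpoint_every = config$checkpoint_every)
        run <- train(arch, sets$train, sets$test, reg, sched, cfg)
        saveRDS(run, run_path)
        n_trained <- n_trained + 1L
      }
      runs[[key]] <- run
      conds <- list(degradation("none"),
                    if (degraded == "blur") degradation("blur", sigma_ref = 4)
                    else degradation("grayscale"))
      eval_rows[[key]] <- bind_rows(lapply(conds, function(cd)
        evaluate(run, sets$test, cd)))
      sweep <- if (config$domain == "acuity")
        blur_sweep(run, sets$test, sigmas = config$sigmas)
      else hue_sweep(run, sets$test, angles = config$angles)
      eval_rows[[paste0(key, "_sweep")]] <- sweep
      tune_rows[[key]] <- mutate(tuning_scores(run), regimen_name = rname,
                                 lr_schedule_name = sname, seed = seed)
      if (length(run$checkpoints) >= 2)
        dyn_rows[[key]] <- tidy(dynamics_profile(run))
    }

  eval_records <- bind_rows(eval_rows)
  write.csv(eval_records, file.path(out_dir, "eval_records.csv"),
            row.names = FALSE)
  files <- "eval_records.csv"
  base <- distinct(
    eval_records[!grepl("hue_rotation|blur\\(sigma_ref=[123]\\)",
                        eval_records$test_condition), ])
  for (basis in c("initial", "final")) {
    pairs <- matched_pairs(basis)
    ok <- any(pairs$decreasing %in% config$lr_schedules &
              pairs$constant %in% config$lr_schedules)
    if (ok) {
      cmp <- compare_matched(base, basis)
      fn <- sprintf("comparison_%s.csv", basis)
      write.csv(cmp, file.path(out_dir, fn), row.names = FALSE)
      files <- c(files, fn)
    }
  }
  write.csv(bind_rows(tune_rows), file.path(out_dir, "tuning_scores.csv"),
            row.names = FALSE)
  files <- c(files, "tuning_scores.csv")
  if (length(dyn_rows) > 0) {
    write.csv(bind_rows(dyn_rows), file.path(out_dir, "dynamics.csv"),
              row.names = FALSE)
    files <- c(files, "dynamics.csv")
  }
  files <- c(files, file.path("runs", paste0(names(runs), ".rds")))
  write_manifest(out_dir, hash, files)
  invisible(list(out_dir = out_dir, eval_records = eval_records,
                 runs = runs, n_trained = n_trained))
}

#' Figure-style tables from a results bundle
#'
#' Re-shapes the CSV outputs of [run_experiment()] into the panel layouts of
#' the result figures: per-regimen accuracy under one schedule
#' (`"accuracy"`, panels like 1B/2B), matched decreasing-minus-constant
#' deltas (`"delta"`, 1D-F/2D-F), test-degradation sweep curves (`"sweep"`,
#' 1G-J/2G-J), the per-filter tuning scatter (`"rf_scatter"`, 4C/F), and the
#' layer-wise dynamics table (`"dynamics"`, 4G-J).
#'
#' @param results_dir A directory written by [run_experiment()].
#' @param figure_id One of `"accuracy"`, `"delta"`, `"sweep"`,
#'   `"rf_scatter"`, `"dynamics"` (panel aliases `"1B"`, `"1D"`, `"1G"`,
#'   `"4C"`, `"4G"` and siblings are accepted).
#' @return A tibble in the panel's layout.
#' @export
figure_tables <- function(results_dir, figure_id) {
  alias <- c("1B" = "accuracy", "1C" = "accuracy", "2B" = "accuracy",
             "2C" = "accuracy", "1D" = "delta", "1E" = "delta",
             "1F" = "delta", "2D" = "delta", "2E" = "delta", "2F" = "delta",
             "1G" = "sweep", "1H" = "sweep", "1I" = "sweep", "1J" = "sweep",
             "2G" = "sweep", "2H" = "sweep", "2I" = "sweep", "2J" = "sweep",
             "4C" = "rf_scatter", "4F" = "rf_scatter",
             "4G" = "dynamics", "4H" = "dynamics", "4I" = "dynamics",
             "4J" = "dynamics")
  if (figure_id %in% names(alias)) figure_id <- alias[[figure_id]]
  get_csv <- function(fn) {
    p <- file.path(results_dir, fn)
    if (!file.exists(p)) abort(sprintf("%s not found in results dir", fn))
    as_tibble(read.csv(p, stringsAsFactors = FALSE))
  }
  switch(figure_id,
    accuracy = {
      ev <- get_csv("eval_records.csv")
      ev <- distinct(ev[ev$test_condition %in%
                          c("none", "blur(sigma_ref=4)", "grayscale"), ])
      aggregate_seeds(ev) |>
        mutate(condition = ifelse(.data$test_condition == "none",
                                  "full", "degraded"),
               mean_accuracy_pct = 100 * .data$mean_accuracy)
    },
    delta = {
      cmp <- get_csv("comparison_initial.csv")
      mutate(cmp, delta_pct = 100 * .data$delta_accuracy)
    },
    sweep = {
      ev <- get_csv("eval_records.csv")
      ev |> group_by(.data$regimen_name, .data$lr_schedule_name,
                     .data$test_condition, .data$sigma_ref, .data$angle) |>
        summarise(mean_accuracy = mean(.data$top1_accuracy),
                  se = if (n() > 1) sd(.data$top1_accuracy) / sqrt(n())
                       else NA_real_, .groups = "drop")
    },
    rf_scatter = {
      ts <- get_csv("tuning_scores.csv")
      scheds <- unique(ts$lr_schedule_name)
      dec <- scheds[grepl("^dec|^gradual|^plateau", scheds)][1]
      con <- scheds[grepl("^const", scheds)][1]
      if (is.na(dec) || is.na(con))
        abort("need one decreasing and one constant schedule for the scatter")
      inner_join(
        ts[ts$lr_schedule_name == dec,
           c("regimen_name", "seed", "filter_index", "color_score",
             "sf_centroid")],
        ts[ts$lr_schedule_name == con,
           c("regimen_name", "seed", "filter_index", "color_score",
             "sf_centroid")],
        by = c("regimen_name", "seed", "filter_index"),
        suffix = c("_decreasing", "_constant"))
    },
    dynamics = get_csv("dynamics.csv"),
    abort(sprintf("unknown figure id '%s'", figure_id))
  )
}

#' Read / write an experiment configuration as YAML or JSON
#'
#' @param path File path ending in `.yaml`, `.yml` or `.json`.
#' @param config An `experiment_config`.
#' @return `read_experiment_config()` an `experiment_config`.
#' @export
write_experiment_config <- function(config, path) {
  l <- unclass(config)
  l$arch <- if (!is.null(l$arch)) unclass(l$arch) else NULL
  if (inherits(l$dataset, "imageset_spec")) l$dataset <- unclass(l$dataset)
  if (grepl("\\.ya?ml$", path)) yaml::write_yaml(l, path)
  else jsonlite::write_json(l, path, auto_unbox = TRUE, digits = NA,
                            force = TRUE)
  invisible(path)
}

#' @rdname write_experiment_config
#' @export
read_experiment_config <- function(path) {
  l <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
       else jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.list(l$dataset) || is.character(l$dataset) && length(l$dataset) > 1) {
    ds <- l$dataset
    bands <- ds$texture_freq_bands
    if (is.matrix(bands)) bands <- asplit(bands, 1)  # fromJSON simplification
    l$dataset <- imageset_spec(
      n_classes = ds$n_classes, train_per_class = ds$train_per_class,
      test_per_class = ds$test_per_class, image_size = ds$image_size,
      hue_separation = ds$hue_separation,
      hue_jitter_sd = ds$hue_jitter_sd,
      texture_freq_bands = lapply(bands, as.numeric),
      shape_families = unlist(ds$shape_families),
      noise_sd = ds$noise_sd, seed = ds$seed)
  }
  arch <- NULL
  if (!is.null(l$arch)) {
    cl <- l$arch$conv_layers
    if (is.data.frame(cl))  # fromJSON record simplification
      cl <- lapply(seq_len(nrow(cl)), function(i) as.list(cl[i, ]))
    l$arch$conv_layers <- cl
    arch <- arch_config(conv_layers = l$arch$conv_layers,
                        fc_hidden = unlist(l$arch$fc_hidden),
                        n_classes = l$arch$n_classes,
                        input_size = l$arch$input_size)
  }
  experiment_config(dataset = l$dataset, domain = l$domain,
                    regimens = unlist(l$regimens),
                    lr_schedules = unlist(l$lr_schedules),
                    seeds = unlist(l$seeds), total_epochs = l$total_epochs,
                    arch = arch, out_dir = l$out_dir,
                    sigmas = unlist(l$sigmas), angles = unlist(l$angles),
                    batch_size = l$batch_size,
                    checkpoint_every = l$checkpoint_every,
                    mode = l$mode, switch_epochs = l$switch_epochs)
}
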