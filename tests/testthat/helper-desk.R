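# Desk-profile replication grid, trained once per test session and shared by
# the directional pattern checks. Keeps only what those checks consume:
# evaluation rows, below-diagonal counts for the color D2F pairs, and
# dynamics summaries for the dec1 color D2F runs. The all-clear F2F runs are
# domain-independent and trained once, then evaluated under both domains'
# degradations.

desk_grid <- function() memo("desk_grid", {
  prof <- desk_profile()
  sets <- generate_dataset(prof$spec)
  half <- as.integer(round(prof$epochs / 2))
  cond_for <- function(domain)
    if (domain == "blur") degradation("blur", sigma_ref = 4)
    else degradation("grayscale")
  eval_rows <- list()
  scatter_counts <- list()
  dyn <- list()

  run_one <- function(rname, sname, seed, domain, keep_ckpts = FALSE) {
    reg <- make_regimen(rname, prof$epochs, degraded = domain)
    sch <- make_lr_schedule(sname, prof$epochs)
    cfg <- train_config(batch_size = prof$batch_size, epochs = prof$epochs,
                        seed = seed, eval_every = prof$epochs,
                        checkpoint_every = if (keep_ckpts) 1L
                                           else prof$epochs)
    train(prof$arch, sets$train, sets$test, reg, sch, cfg)
  }
  eval_pair <- function(run, domain) {
    ev <- dplyr::bind_rows(
      evaluate(run, sets$test, degradation("none")),
      evaluate(run, sets$test, cond_for(domain)))
    ev$domain <- domain
    ev
  }

  # F2F is all-clear regardless of domain: train once, evaluate under both
  for (seed in prof$seeds) {
    run <- run_one("F2F", "const1", seed, "blur")
    for (domain in c("blur", "grayscale"))
      eval_rows[[paste("F2F", domain, seed)]] <- eval_pair(run, domain)
  }

  for (domain in c("blur", "grayscale")) {
    color_d2f <- list()
    cells <- rbind(
      expand.grid(regimen = c("D2D", "D2F", "F2D"), sched = "const1",
                  stringsAsFactors = FALSE),
      data.frame(regimen = "D2F", sched = "dec1"))
    for (i in seq_len(nrow(cells))) for (seed in prof$seeds) {
      rname <- cells$regimen[i]; sname <- cells$sched[i]
      need_ckpts <- domain == "grayscale" && rname == "D2F"
      run <- run_one(rname, sname, seed, domain, keep_ckpts = need_ckpts)
      eval_rows[[paste(domain, rname, sname, seed)]] <- eval_pair(run, domain)
      if (need_ckpts) {
        color_d2f[[paste(sname, seed)]] <- run
        if (sname == "dec1") {
          recs <- dynamics_profile(run)$records
          dyn[[paste(seed)]] <- list(
            pre = mean(recs$correlation[recs$epoch_to <= half], na.rm = TRUE),
            post = mean(recs$correlation[recs$epoch_to > half], na.rm = TRUE),
            stab = dynamics_profile(run)$summary)
        }
      }
    }
    if (domain == "grayscale") {
      for (seed in prof$seeds) {
        sc <- rf_scatter(color_d2f[[paste("dec1", seed)]],
                         color_d2f[[paste("const1", seed)]],
                         metric = "color")
        scatter_counts[[paste(seed)]] <-
          list(below = attr(sc, "count_below"), total = attr(sc, "total"))
      }
    }
  }
  list(records = dplyr::bind_rows(eval_rows),
       scatter = scatter_counts, dynamics = dyn, profile = prof)
})

# seed-averaged accuracy for one grid cell
cell_mean <- function(records, domain, regimen, sched, condition) {
  sel <- records$domain == domain & records$regimen_name == regimen &
    records$lr_schedule_name == sched &
    (if (condition == "full") records$test_condition == "none"
     else records$test_condition != "none")
  mean(records$top1_accuracy[sel])
}
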