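#' Run the full simulation-to-evaluation pipeline
#'
#' Executes the complete workflow on synthetic data: phantom generation ->
#' forward acoustic simulation on a sparse ring -> sensor noise -> time
#' reversal -> dataset assembly -> network training -> evaluation ->
#' profiling. All artifacts (dataset, metrics JSON, previews, config) are
#' written under `config$out_dir`; reruns with the same configuration
#' reproduce identical outputs.
#'
#' @param config List as produced by [default_run_config()] /
#'   [read_run_config()].
#' @param verbose Log one line per stage.
#' @return Invisibly, a list with the dataset, the fit, the evaluation
#'   report and the profile.
#' @export
run_pipeline <- function(config = default_run_config(), verbose = TRUE) {
  cfg <- modifyList(default_run_config(), config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(stage, ...) {
    if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
  }

  say("simulate", "generating %d scenes (seed %d)", cfg$n_scenes, cfg$seed)
  scenes <- generate_scenes(cfg$n_scenes, seed = cfg$seed, vessels = cfg$vessels)

  say("reconstruct", "forward + TR at %d sensors, SNR %g-%g dB",
      cfg$n_sensors, cfg$snr_db[1], cfg$snr_db[2])
  grid <- pat_grid()
  medium <- pat_medium()
  ds <- make_paired_dataset(scenes, n_sensors = cfg$n_sensors,
                            snr_db_range = cfg$snr_db, grid = grid,
                            medium = medium, seed = cfg$seed + 1L)
  write_pat_dataset(ds, file.path(cfg$out_dir, "dataset.rds"), config = cfg)

  say("train", "stage %s, width factor %d, %d epochs", cfg$stage,
      cfg$width_factor, cfg$epochs)
  mcfg <- msdnet_config_small(cfg$width_factor, stage = cfg$stage,
                              seed = cfg$seed + 2L)
  model <- build_msdnet(mcfg)
  tr <- dataset_subset(ds, "train")
  va <- dataset_subset(ds, "val")
  has_val <- dim(va$inputs)[3] > 0
  tcfg <- train_config(learning_rate = cfg$learning_rate,
                       batch_size = cfg$batch_size, epochs = cfg$epochs,
                       seed = cfg$seed + 3L)
  fit <- train_network(model, tr$inputs, tr$targets, tcfg,
                       val_inputs = if (has_val) va$inputs,
                       val_targets = if (has_val) va$targets,
                       verbose = verbose)

  say("eval", "scoring the held-out test split")
  te <- dataset_subset(ds, "test")
  report <- evaluate_network(model, te$inputs, te$targets)
  base <- metrics_report(te$inputs, te$targets)

  say("profile", "counting parameters and FLOPs")
  prof <- profile_network(model)

  metrics <- list(
    test = as.list(stats::setNames(report$summary$mean, report$summary$metric)),
    test_sd = as.list(stats::setNames(report$summary$sd, report$summary$metric)),
    tr_input = as.list(stats::setNames(base$summary$mean, base$summary$metric)),
    n_params = prof$n_params, flops = prof$flops,
    config = cfg
  )
  jsonlite::write_json(metrics, file.path(cfg$out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_png_image(ds$targets[, , 1], file.path(cfg$out_dir, "preview_truth.png"))
  write_png_image(ds$inputs[, , 1], file.path(cfg$out_dir, "preview_tr.png"))
  write_png_image(predict(model, ds$inputs[, , 1]),
                  file.path(cfg$out_dir, "preview_net.png"))
  write_run_config(cfg, file.path(cfg$out_dir, "config.yaml"))
  say("done", "artifacts in %s", cfg$out_dir)
  invisible(list(dataset = ds, fit = fit, report = report, profile = prof,
                 metrics = metrics))
}
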