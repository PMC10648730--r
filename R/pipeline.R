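# Desk-scale end-to-end study: generate phantom cohorts, assemble per-side
# datasets, (optionally) run the hyperparameter search, train both side
# models, segment an application set, compute volumes by all three methods,
# and produce the agreement reports.

#' Configuration of an end-to-end run
#'
#' Defaults define the desk-scale study: 20 training phantoms and a
#' 22-phantom application set (the clinical application-set size) built from
#' the small 128 x 128 phantom preset, 128 x 64 model inputs with 8 starting
#' feature maps, and a fixed seed from which all stage seeds derive.
#'
#' @param n_train_phantoms Training-cohort size.
#' @param n_application Application-set size (default 22).
#' @param base_spec Base [phantom_spec()] the cohorts are sampled around.
#' @param target_shape Model input shape `c(height, width)`.
#' @param hp [hyperparameters()] for training. The desk-scale default uses a
#'   lower learning rate and smaller batch/feature counts than the full-scale
#'   optimum, matched to the small inputs.
#' @param sampling_interval_mm Training-slice extraction interval.
#' @param negative_fraction Negative-control fraction of each dataset.
#' @param max_epochs,patience Training schedule.
#' @param augment_prob Training-time augmentation probability.
#' @param use_ga Run the genetic hyperparameter search before training.
#' @param ga_generations,ga_epoch_budget Search budget when `use_ga = TRUE`.
#' @param min_area_mm2 Area floor of the slice-profile post-processing in
#'   mm2. The clinical 200-pixel floor on a 0.7 x 0.7 mm grid corresponds to
#'   98 mm2; expressing it as an area keeps its meaning on the coarser
#'   phantom grid.
#' @param seed Master seed.
#' @param out_dir Optional output directory; when given, every stage persists
#'   its artifacts there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n_train_phantoms = 20, n_application = 22,
                       base_spec = phantom_spec_small(),
                       target_shape = c(128, 64),
                       hp = hyperparameters(learning_rate = 2e-3,
                                            dropout_rate = 0.1,
                                            start_feature_maps = 8,
                                            batch_size = 8),
                       sampling_interval_mm = 10,
                       negative_fraction = 0.28,
                       max_epochs = 12, patience = 30,
                       augment_prob = 0.5,
                       use_ga = FALSE, ga_generations = 3,
                       ga_epoch_budget = 2,
                       min_area_mm2 = 98,
                       seed = 1L, out_dir = NULL) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

stage_seed <- function(cfg, stage) {
  offsets <- c(train_phantoms = 101L, app_phantoms = 202L, dataset = 303L,
               train_left = 404L, train_right = 505L, ga = 606L)
  (cfg$seed * 1000L + offsets[[stage]]) %% .Machine$integer.max
}

#' Run the full study end to end
#'
#' Executes the linear workflow: phantom generation, per-side dataset
#' assembly, optional genetic hyperparameter search, independent training of
#' the left and right models, segmentation of the application set,
#' volumetry by the CNN method, the 3 mm semi-automated reference on the
#' ground-truth masks, and full-resolution ground-truth volumetry, and the
#' agreement statistics of CNN vs reference and CNN vs analytic truth.
#' Re-running with the same configuration reproduces all volumes exactly.
#'
#' @param cfg A [run_config()].
#' @param verbose Print stage progress.
#' @return A list of class `study_result` with the trained models, per-kidney
#'   volume table, per-slice Dice scores, pixel profiles, agreement reports,
#'   training histories, and a manifest of all seeds.
#' @export
run_end_to_end <- function(cfg = run_config(), verbose = interactive()) {
  stopifnot(inherits(cfg, "run_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t_start <- proc.time()[3]

  say("[1/6] generating %d training + %d application phantoms",
      cfg$n_train_phantoms, cfg$n_application)
  train_specs <- sample_phantom_specs(cfg$n_train_phantoms, cfg$base_spec,
                                      seed = stage_seed(cfg, "train_phantoms"))
  app_specs <- sample_phantom_specs(cfg$n_application, cfg$base_spec,
                                    seed = stage_seed(cfg, "app_phantoms"))
  train_ph <- lapply(train_specs, generate_phantom)
  app_ph <- lapply(app_specs, generate_phantom)

  say("[2/6] building side datasets")
  ds <- list()
  for (side in c("left", "right")) {
    ds[[side]] <- build_training_set(
      train_ph, side = side, target_shape = cfg$target_shape,
      sampling_interval_mm = cfg$sampling_interval_mm,
      negative_fraction = cfg$negative_fraction,
      seed = stage_seed(cfg, "dataset"))
  }

  hp <- cfg$hp
  ga_state <- NULL
  if (isTRUE(cfg$use_ga)) {
    say("[3/6] genetic hyperparameter search (%d generations)",
        cfg$ga_generations)
    fit_fn <- cnn_fitness(ds$right, input_shape = cfg$target_shape,
                          epoch_budget = cfg$ga_epoch_budget,
                          seed = stage_seed(cfg, "ga"))
    ga_state <- init_population(seed = stage_seed(cfg, "ga"))
    ga_state <- evolve(ga_state, fit_fn, generations = cfg$ga_generations)
    hp <- best_hyperparameters(ga_state)
  } else {
    say("[3/6] hyperparameter search skipped (configured hyperparameters)")
  }

  models <- list(); histories <- list()
  for (side in c("left", "right")) {
    say("[4/6] training %s-kidney model (%d slices)", side,
        length(ds[[side]]$slices))
    net <- build_unet(hp, cfg$target_shape,
                      seed = stage_seed(cfg, paste0("train_", side)))
    net$side <- side
    tr <- train_unet(net, ds[[side]], patience = cfg$patience,
                     max_epochs = cfg$max_epochs,
                     augment_prob = cfg$augment_prob,
                     seed = stage_seed(cfg, paste0("train_", side)))
    models[[side]] <- tr$net
    histories[[side]] <- tr$history
  }

  say("[5/6] segmenting %d application phantoms", cfg$n_application)
  vol_rows <- list(); dsc_rows <- list(); profiles <- list()
  for (i in seq_along(app_ph)) {
    ph <- app_ph[[i]]
    seg <- segment_series(ph$volume, models$left, models$right)
    profiles[[i]] <- list()
    for (side in c("left", "right")) {
      prof <- select_kidney_region(seg[[side]],
                                   min_area_mm2 = cfg$min_area_mm2)
      profiles[[i]][[side]] <- prof
      v_cnn <- compute_volume(seg[[side]], prof, method = "cnn")
      ts <- truth_mask_series(ph, side)
      v_semi <- semi_automated_volume(ts, sampling_interval_mm = 3)
      v_gt <- compute_volume(ts, select_kidney_region(ts, min_pixel_count = 1),
                             method = "ground_truth")
      vol_rows[[length(vol_rows) + 1L]] <- data.frame(
        phantom = i, side = side,
        cnn_ml = v_cnn$volume_ml, semi_automated_ml = v_semi$volume_ml,
        ground_truth_ml = v_gt$volume_ml,
        analytic_ml = ph$truth[[paste0("analytic_volume_", side)]])
      # per-slice Dice on the kidney-bearing slices, at original grid
      truth_masks <- ph$truth[[paste0("masks_", side)]]
      half_w <- dim(truth_masks)[2] %/% 2
      cols <- if (side == "right") 1:half_w else (half_w + 1):dim(truth_masks)[2]
      pos <- which(apply(truth_masks, 3, sum) > 0)
      for (k in pos) {
        dsc_rows[[length(dsc_rows) + 1L]] <- data.frame(
          phantom = i, side = side, slice = k,
          dsc = dice(seg[[side]]$masks[[k]], truth_masks[, cols, k]))
      }
    }
  }
  volumes <- do.call(rbind, vol_rows)
  dsc <- do.call(rbind, dsc_rows)

  say("[6/6] agreement statistics")
  reports <- list()
  for (side in c("left", "right")) {
    v <- volumes[volumes$side == side, ]
    reports[[side]] <- list(
      cnn_vs_reference = agreement_report(
        paired_measurements(v$semi_automated_ml, v$cnn_ml, v$phantom),
        dsc = dsc$dsc[dsc$side == side]),
      cnn_vs_ground_truth = agreement_report(
        paired_measurements(v$ground_truth_ml, v$cnn_ml, v$phantom)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("renalvol")),
    seed = cfg$seed,
    stage_seeds = sapply(c("train_phantoms", "app_phantoms", "dataset",
                           "train_left", "train_right", "ga"),
                         function(s) stage_seed(cfg, s)),
    hyperparameters = unclass(hp),
    n_train_phantoms = cfg$n_train_phantoms,
    n_application = cfg$n_application,
    target_shape = cfg$target_shape,
    elapsed_s = unname(proc.time()[3] - t_start))

  result <- structure(list(models = models, histories = histories,
                           volumes = volumes, dsc = dsc, profiles = profiles,
                           reports = reports, ga = ga_state, config = cfg,
                           manifest = manifest),
                      class = "study_result")
  if (!is.null(cfg$out_dir)) write_study_result(result, cfg$out_dir)
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("End-to-end study: %d application phantoms, %.1f s\n",
              x$config$n_application, x$manifest$elapsed_s))
  for (side in c("left", "right")) {
    rep <- x$reports[[side]]$cnn_vs_reference
    cat(sprintf(
      "  %s: mean DSC %.3f, ICC(absolute) %.3f, MAE %.1f ml, MdAPE %.1f%%\n",
      side, mean(x$dsc$dsc[x$dsc$side == side]),
      rep$icc_absolute$value, rep$errors$mae, rep$errors$mdape))
  }
  invisible(x)
}

#' Persist a study result
#'
#' Writes the configuration echo, volume and Dice tables, loss histories,
#' pixel profiles, agreement reports, the manifest, and the trained models
#' into a directory.
#'
#' @param result A `study_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- result$config
  cfg_echo <- unclass(cfg)
  cfg_echo$base_spec <- unclass(cfg$base_spec)
  cfg_echo$hp <- unclass(cfg$hp)
  jsonlite::write_json(cfg_echo, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  write.csv(result$volumes, file.path(dir, "volumes.csv"), row.names = FALSE)
  write.csv(result$dsc, file.path(dir, "dsc.csv"), row.names = FALSE)
  for (side in names(result$histories)) {
    write.csv(result$histories[[side]],
              file.path(dir, paste0("loss_history_", side, ".csv")),
              row.names = FALSE)
  }
  prof_rows <- list()
  for (i in seq_along(result$profiles)) {
    for (side in names(result$profiles[[i]])) {
      p <- result$profiles[[i]][[side]]
      prof_rows[[length(prof_rows) + 1L]] <- data.frame(
        phantom = i, side = side, slice = seq_along(p$counts),
        pixel_count = p$counts,
        in_run = if (is.null(p$run)) FALSE else
          seq_along(p$counts) >= p$run[1] & seq_along(p$counts) <= p$run[2])
    }
  }
  write.csv(do.call(rbind, prof_rows), file.path(dir, "pixel_profiles.csv"),
            row.names = FALSE)
  reports <- lapply(result$reports, function(side_reps)
    lapply(side_reps, tidy))
  jsonlite::write_json(reports, file.path(dir, "agreement_reports.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  saveRDS(result$models, file.path(dir, "models.rds"))
  invisible(dir)
}
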