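# End-to-end orchestration: simulate -> score sleep -> photometry -> maze ->
# cluster -> link, with a reproducibility manifest.

#' Validate and normalize a run configuration
#'
#' Reads a JSON run configuration (or takes a list), fills defaults for every
#' section and enforces cross-field invariants (e.g. port-zone radii inside
#' the arena).  An empty file or `NULL` yields the all-defaults
#' configuration.
#'
#' @param config path to a JSON file, a list, or `NULL` for defaults.
#' @return list of class `run_config` with sections `sim` ([sim_config()]),
#'   `geometry` ([maze_geometry()]), `cluster` ([cluster_config()]),
#'   `photometry` (detrend degree, quiet length, detection thresholds),
#'   `seed`, `desk_scale`.
#' @export
validate_config <- function(config = NULL) {
  raw <- if (is.character(config)) {
    txt <- paste(readLines(config, warn = FALSE), collapse = "\n")
    if (nchar(trimws(txt)) == 0) list() else
      jsonlite::fromJSON(txt, simplifyVector = TRUE)
  } else config %||% list()
  seed <- as.integer(raw$seed %||% 1L)
  desk <- isTRUE(raw$desk_scale %||% TRUE)
  sim_args <- as.list(raw$sim %||% list())
  sim_args$seed <- sim_args$seed %||% seed
  sim <- do.call(if (desk) sim_config_desk else sim_config, sim_args)
  geom_args <- as.list(raw$geometry %||% list())
  if (is.null(geom_args$arena_diameter)) {
    geom_args$arena_diameter <- sim$arena_diameter
  }
  if (is.null(geom_args$n_ports)) geom_args$n_ports <- sim$n_ports
  geom <- do.call(maze_geometry, geom_args)   # enforces zone/arena invariants
  cl_args <- as.list(raw$cluster %||% list())
  cl_args$seed <- cl_args$seed %||% seed
  cl <- do.call(cluster_config, cl_args)
  ph <- list(degree = 2, quiet_length = 250, prominence_mult = 3,
             min_halfwidth = 1.5)
  ph[names(raw$photometry %||% list())] <- raw$photometry
  if (desk) ph$quiet_length <- min(ph$quiet_length, sim$rest_duration / 6)
  structure(list(sim = sim, geometry = geom, cluster = cl, photometry = ph,
                 seed = seed, desk_scale = desk),
            class = "run_config")
}

#' Serialize a run configuration to JSON
#'
#' @param config a `run_config` from [validate_config()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  out <- list(seed = config$seed, desk_scale = config$desk_scale,
              sim = unclass(config$sim), geometry = unclass(config$geometry),
              cluster = unclass(config$cluster),
              photometry = config$photometry)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

stage_log <- function(log, stage, msg) {
  message(sprintf("[%s] %s", stage, msg))
  c(log, sprintf("[%s] %s", stage, msg))
}

#' Run the full pipeline on a synthetic experiment
#'
#' Executes the stages in dependency order: simulate the multi-day
#' experiment; score sleep from the synthetic EEG/EMG; detrend, normalize
#' and detect photometry transients per rest, summarize per state and
#' standardize NREM amplitudes across animals; compute maze visit statistics
#' and the speed mixture; train the cluster model and assign per-trial
#' occupancy; join sleep to next-day behavior and compute the correlation
#' and quartile statistics.  Every output is written under `out_dir` along
#' with a manifest of checksums and seeds.
#'
#' @param config a `run_config` ([validate_config()]).
#' @param out_dir output directory (created if needed).
#' @return list: `report` (link-layer statistics and stage summaries),
#'   `manifest` (file checksums, seed, config hash), paths of outputs.
#' @export
run_pipeline <- function(config, out_dir) {
  nl_assert(inherits(config, "run_config"), "config must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character(0)
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      nl_stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
              "stage_failure")
    })
  }
  sim <- config$sim; geom <- config$geometry

  log <- stage_log(log, "simulate", sprintf(
    "generating %d mice x %d days (seed %d)", sim$n_mice, sim$n_days, sim$seed))
  ds <- run_stage("simulate", synth_multiday_experiment(sim))
  jsonlite::write_json(ds$ground_truth,
                       file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")

  log <- stage_log(log, "score-sleep", "scoring vigilance states")
  scored <- run_stage("score-sleep", lapply(ds$rests, function(r) {
    hyp <- score_sleep(r$eeg, r$emg, epoch_len = sim$epoch_len)
    write_hypnogram(hyp, file.path(out_dir, sprintf(
      "hypnogram_m%d_d%d.csv", r$mouse, r$day)))
    hyp
  }))

  log <- stage_log(log, "photometry", "detecting transients per rest")
  summaries <- run_stage("photometry", {
    rows <- lapply(seq_along(ds$rests), function(i) {
      r <- ds$rests[[i]]
      detr <- detrend_baseline(r$photometry, degree = config$photometry$degree)
      dff <- smooth_trace(compute_dff(detr))
      qp <- find_quiet_period(dff, scored[[i]],
                              length = config$photometry$quiet_length)
      tr <- detect_transients(dff, qp$sd,
                              prominence_mult = config$photometry$prominence_mult,
                              min_halfwidth = config$photometry$min_halfwidth)
      utils::write.csv(tr, file.path(out_dir, sprintf(
        "transients_m%d_d%d.csv", r$mouse, r$day)), row.names = FALSE)
      summ <- state_activity_summary(tr, dff, scored[[i]])
      data.frame(mouse = r$mouse, day = r$day,
                 nrem_amp = summ$mean_amplitude[summ$state == "NREM"],
                 rem_amp = summ$mean_amplitude[summ$state == "REM"],
                 nrem_integral = summ$cumulative_integral[summ$state == "NREM"])
    })
    tab <- do.call(rbind, rows)
    tab$nrem_amp[is.na(tab$nrem_amp)] <- 0
    tab$rem_amp[is.na(tab$rem_amp)] <- 0
    tab$nrem_activity <- standardize_values(tab$mouse, tab$day, tab$nrem_amp)
    tab$rem_activity <- standardize_values(tab$mouse, tab$day, tab$rem_amp)
    tab
  })
  utils::write.csv(summaries, file.path(out_dir, "sleep_summaries.csv"),
                   row.names = FALSE)

  log <- stage_log(log, "maze", "port visits and speed mixture")
  behavior <- run_stage("maze", {
    rows <- lapply(ds$trials, function(tr) {
      g <- attr(tr, "geometry") %||% geom
      vis <- detect_port_entries(tr, g)
      sp <- vis$visit_speed[!is.na(vis$visit_speed)]
      data.frame(mouse = tr$mouse, day = tr$day, trial = tr$trial,
                 n_visits = nrow(vis),
                 mean_visit_speed = if (length(sp)) mean(sp) else NA_real_,
                 visit_speeds = I(list(sp)))
    })
    do.call(rbind, rows)
  })
  all_speeds <- unlist(behavior$visit_speeds)
  mixture <- if (length(all_speeds) >= 20) fit_speed_mixture(all_speeds) else NULL

  log <- stage_log(log, "cluster", "training VAE+SOM and assigning occupancy")
  cl <- run_stage("cluster", {
    dset <- build_window_dataset(ds$trials)
    model <- train_cluster_model(dset, config$cluster)
    map <- assign_clusters(model, dset)
    utils::write.csv(cbind(map$meta, label = map$labels),
                     file.path(out_dir, "cluster_map.csv"), row.names = FALSE)
    occ_df <- as.data.frame(map$occupancy)
    names(occ_df) <- paste0("occ_", seq_len(ncol(occ_df)))
    utils::write.csv(cbind(map$occupancy_meta, occ_df),
                     file.path(out_dir, "occupancy.csv"), row.names = FALSE)
    list(model = model, map = map, occ_df = cbind(map$occupancy_meta, occ_df))
  })

  log <- stage_log(log, "link", "correlating sleep with next-day behavior")
  report <- run_stage("link", {
    behav <- merge(behavior, cl$occ_df, by = c("mouse", "day", "trial"))
    tab <- build_link_table(
      summaries[, c("mouse", "day", "nrem_activity", "rem_activity")], behav)
    corr_n <- correlate_occupancy_activity(tab, "NREM")
    corr_r <- correlate_occupancy_activity(tab, "REM")
    quart <- tryCatch(quartile_speed_comparison(tab, "NREM", n_comparisons = 2),
                      error = function(e) NULL)
    utils::write.csv(corr_n, file.path(out_dir, "cluster_correlations_nrem.csv"),
                     row.names = FALSE)
    utils::write.csv(corr_r, file.path(out_dir, "cluster_correlations_rem.csv"),
                     row.names = FALSE)
    list(
      n_rests = length(ds$rests), n_trials = length(ds$trials),
      mixture = if (!is.null(mixture)) {
        list(selected_k = mixture$selected_k, means = mixture$means)
      },
      val_mse = cl$model$val_mse,
      nrem_significant = corr_n$cluster[!is.na(corr_n$p_bonferroni) &
                                          corr_n$p_bonferroni < 0.05],
      rem_significant = corr_r$cluster[!is.na(corr_r$p_bonferroni) &
                                         corr_r$p_bonferroni < 0.05],
      quartile = if (!is.null(quart)) {
        list(U = quart$U, p = quart$p, p_adjusted = quart$p_adjusted)
      })
  })
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  files <- list.files(out_dir, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("nremlink")),
    seed = config$seed,
    config_hash = unname(tools::md5sum(write_config(
      config, file.path(out_dir, "config_used.json")))),
    checksums = as.list(tools::md5sum(sort(files))),
    log = log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, manifest = manifest, out_dir = out_dir))
}
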