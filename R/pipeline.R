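#' Pipeline configuration
#'
#' A fully serializable description of one end-to-end run: which circuit
#' and stimulus to simulate, which kinetic parameters to use, geometry and
#' optics overrides, the seeds for every source of randomness, and
#' analysis options. The resolved configuration is written next to every
#' run's outputs.
#'
#' @param circuit A [circuit_preset()] name or a list of [circuit_spec()]
#'   arguments.
#' @param stimulus A [stimulus_preset()] name or a list of
#'   [stimulus_program()] arguments.
#' @param params `"default"` or a named list of [kinetic_params()]
#'   overrides.
#' @param geometry Named list of [cell_geometry()] overrides.
#' @param optics Named list of [optics_noise()] overrides.
#' @param seeds Named list: `simulation` (stochastic transcription; `NULL`
#'   keeps the deterministic mode), `render`, `jitter`.
#' @param analysis Named list: `fold_method` (`"final"`/`"max"`), `tau`,
#'   `welch`, `snr_threshold`, `min_frames`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(circuit = "fos_btg2", stimulus = "serum10",
                            params = "default", geometry = list(),
                            optics = list(),
                            seeds = list(simulation = NULL, render = 1,
                                         jitter = 1),
                            analysis = list(fold_method = "final", tau = 1.5,
                                            welch = FALSE, snr_threshold = 5,
                                            min_frames = 5)) {
  structure(list(circuit = circuit, stimulus = stimulus, params = params,
                 geometry = geometry, optics = optics, seeds = seeds,
                 analysis = analysis),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#' @param path A `.yaml`/`.yml` or `.json` file with `pipeline_config`
#'   fields.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort_validation("config file not found: %s", path)
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
  else yaml::read_yaml(path)
  do.call(pipeline_config, cfg[intersect(names(cfg),
                                         names(formals(pipeline_config)))])
}

#' Write the resolved configuration next to a run's outputs
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

resolve_circuit <- function(config) {
  if (is.character(config$circuit)) circuit_preset(config$circuit)
  else do.call(circuit_spec, config$circuit)
}

resolve_stimulus <- function(config) {
  if (is.character(config$stimulus)) stimulus_preset(config$stimulus)
  else do.call(stimulus_program, config$stimulus)
}

resolve_params <- function(config) {
  if (identical(config$params, "default")) default_kinetic_params()
  else do.call(kinetic_params,
               utils::modifyList(as.list(unclass(default_kinetic_params())),
                                 config$params))
}

resolve_geometry <- function(config, spec) {
  do.call(cell_geometry,
          utils::modifyList(list(n_sites = spec$n_sites), config$geometry))
}

resolve_optics <- function(config) {
  do.call(optics_noise, config$optics)
}

run_log <- function(outdir, config, inputs = character(0)) {
  lines <- c(sprintf("synieg %s", as.character(utils::packageVersion("synieg"))),
             sprintf("seeds: simulation=%s render=%s jitter=%s",
                     config$seeds$simulation %||% "none",
                     config$seeds$render %||% "none",
                     config$seeds$jitter %||% "none"))
  if (length(inputs)) {
    sums <- tools::md5sum(inputs)
    lines <- c(lines, sprintf("input %s md5 %s", names(sums), sums))
  }
  writeLines(lines, file.path(outdir, "run_log.txt"))
  write_pipeline_config(config, file.path(outdir, "resolved_config.yaml"))
}

#' Pipeline stages
#'
#' Each stage writes its outputs (plus the resolved configuration and a
#' small run log) into `outdir` and returns its main result invisibly:
#'
#' * `pipeline_simulate()`: trajectory CSV.
#' * `pipeline_render()`: movie TIFF + JSON sidecar + ground-truth CSV.
#' * `pipeline_quantify()`: burst-trace CSV and nuclear-trace CSV.
#' * `pipeline_analyze()`: per-trace and summary CSVs plus a JSON report
#'   with AUC, fold and kinetic metrics of the mean burst trace.
#' * `pipeline_run()`: all of the above in sequence.
#'
#' Outputs are deterministic for fixed seeds.
#'
#' @param config A [pipeline_config()].
#' @param outdir Output directory (created if needed).
#' @return See above.
#' @name pipeline
NULL

#' @rdname pipeline
#' @export
pipeline_simulate <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- resolve_circuit(config)
  params <- resolve_params(config)
  sig <- make_stimulus(resolve_stimulus(config), params)
  traj <- simulate_circuit(spec, params, sig,
                           seed = config$seeds$simulation)
  write_trajectory_csv(traj, file.path(outdir, "trajectory.csv"))
  run_log(outdir, config)
  invisible(traj)
}

#' @rdname pipeline
#' @param traj A trajectory (defaults to running [pipeline_simulate()]).
#' @export
pipeline_render <- function(config, outdir, traj = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(traj)) traj <- pipeline_simulate(config, outdir)
  spec <- attr(traj, "spec") %||% resolve_circuit(config)
  geom <- resolve_geometry(config, spec)
  optics <- resolve_optics(config)
  movie <- render_movie(traj, geom, optics,
                        seed = config$seeds$render %||% 1)
  write_movie_tiff(movie, file.path(outdir, "movie.tif"))
  invisible(movie)
}

#' @rdname pipeline
#' @param movie A `movie_stack` or a path to a movie TIFF.
#' @export
pipeline_quantify <- function(config, outdir, movie) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(movie)) movie <- read_movie_tiff(movie)
  an <- config$analysis
  dt <- detect_and_track(movie,
                         snr_threshold = an$snr_threshold %||% 5,
                         min_frames = an$min_frames %||% 5)
  bursts <- burst_traces(movie, dt$tracks)
  write_burst_csv(bursts, file.path(outdir, "burst_traces.csv"))
  nuc <- nuclear_mean_trace(movie, "YFP")
  write_traces_csv(list(nuc), file.path(outdir, "nuclear_trace.csv"))
  invisible(list(tracks = dt$tracks, bursts = bursts, nuclear = nuc))
}

#' @rdname pipeline
#' @param quant Result of [pipeline_quantify()].
#' @export
pipeline_analyze <- function(config, outdir, quant) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  traces <- quant$bursts$traces
  agg <- aggregate_traces(c(traces, list(quant$nuclear)),
                          condition = c(rep("burst", length(traces)),
                                        "nuclear"))
  utils::write.csv(agg$per_trace, file.path(outdir, "per_trace.csv"),
                   row.names = FALSE)
  utils::write.csv(agg$summary, file.path(outdir, "summary.csv"),
                   row.names = FALSE)
  mb <- mean_trace(traces)
  km <- tryCatch(
    kinetic_metrics(mb, noise_sd = tryCatch(prestim_noise_sd(mb),
                                            synieg_validation =
                                              function(e) 0)),
    synieg_validation = function(e)
      list(time_to_peak_min = NA_real_, adaptation_time_min = NA_real_))
  nuc_fc <- fold_change(quant$nuclear,
                        method = config$analysis$fold_method %||% "final")
  report <- list(n_tracks = length(traces),
                 burst_time_to_peak_min = km$time_to_peak_min,
                 burst_adaptation_time_min = km$adaptation_time_min,
                 nuclear_fold = nuc_fc$fold,
                 nuclear_percent = nuc_fc$percent,
                 nuclear_auc = compute_auc(quant$nuclear)$auc)
  jsonlite::write_json(report, file.path(outdir, "analysis.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' @rdname pipeline
#' @export
pipeline_run <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  traj <- pipeline_simulate(config, outdir)
  movie <- pipeline_render(config, outdir, traj)
  quant <- pipeline_quantify(config, outdir, movie)
  report <- pipeline_analyze(config, outdir, quant)
  invisible(list(trajectory = traj, movie = movie, quant = quant,
                 report = report))
}

#' Simulate a jittered population and score the AND gate
#'
#' Trajectory-level population experiment for gate characterization:
#' simulates `n_cells` jittered cells ([jitter_population()]) under the
#' four AND-gate conditions (starve, serum, doxorubicin, both), computes
#' per-cell AUC and fold of the protein trace, and runs [gate_analysis()].
#'
#' @param spec Circuit to test (default the AND-gate SynIEG).
#' @param params Base [kinetic_params()].
#' @param n_cells Cells per condition.
#' @param cv Cell-to-cell parameter CV.
#' @param seed Population seed.
#' @param tau,welch Passed to [gate_analysis()].
#' @return A `gate_report` with the per-cell table attached as attribute
#'   `data`.
#' @export
simulate_gate_experiment <- function(spec = circuit_preset("and_gate"),
                                     params = default_kinetic_params(),
                                     n_cells = 20, cv = 0.2, seed = 1,
                                     tau = 1.5, welch = FALSE) {
  conds <- c(starve = "starve", A = "serum1", B = "dox", AB = "serum1_dox")
  pop <- jitter_population(cell_geometry(n_sites = spec$n_sites), params,
                           n_cells, cv, seed)
  rows <- list()
  for (ci in names(conds)) {
    sigs <- NULL
    for (j in seq_len(n_cells)) {
      p <- pop[[j]]$params
      sig <- make_stimulus(stimulus_preset(conds[[ci]]), p)
      tr <- protein_trace(simulate_circuit(spec, p, sig))
      rows[[length(rows) + 1L]] <-
        data.frame(condition = ci, cell = j,
                   auc = compute_auc(tr)$auc,
                   fold = fold_change(tr)$fold)
    }
  }
  df <- do.call(rbind, rows)
  rep <- gate_analysis(df$auc, df$condition, fold = df$fold, tau = tau,
                       welch = welch)
  attr(rep, "data") <- df
  rep
}

#' Simulate a jittered population and score the duration filter
#'
#' Simulates `n_cells` jittered cells under sustained and transient light
#' and computes the [duration_filter_index()] from the per-cell protein
#' fold-changes.
#'
#' @param spec Circuit to test.
#' @param params Base [kinetic_params()].
#' @param n_cells,cv,seed Population settings.
#' @param welch Use Welch's t-test.
#' @return A list with `index` (the [duration_filter_index()] result) and
#'   `folds` (per-cell folds by condition).
#' @export
simulate_filter_experiment <- function(spec = circuit_preset("fos_fra1deg_fos"),
                                       params = default_kinetic_params(),
                                       n_cells = 20, cv = 0.2, seed = 1,
                                       welch = FALSE) {
  pop <- jitter_population(cell_geometry(n_sites = spec$n_sites), params,
                           n_cells, cv, seed)
  fold_for <- function(preset) {
    vapply(pop, function(cell) {
      sig <- make_stimulus(stimulus_preset(preset), cell$params)
      fold_change(protein_trace(simulate_circuit(spec, cell$params,
                                                 sig)))$fold
    }, numeric(1))
  }
  fs <- fold_for("sustained"); ft <- fold_for("transient20")
  list(index = duration_filter_index(fs, ft, welch = welch),
       folds = data.frame(sustained = fs, transient = ft))
}

#' Generate the canonical fixture set
#'
#' Writes a small deterministic fixture collection: one simulated
#' trajectory CSV per named circuit under its characteristic stimulus, and
#' one compact rendered movie (TIFF + sidecar + ground truth) for the
#' default transcription-imaging circuit. A manifest with MD5 checksums is
#' returned and written as `manifest.json`.
#'
#' @param outdir Output directory.
#' @param seed Master seed.
#' @return Invisibly, the manifest data frame (file, md5).
#' @export
make_fixtures <- function(outdir, seed = 1) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  combos <- list(
    fos_tubulin = "sustained", fos_btg2 = "serum10", fos_fos = "serum10",
    btg2_fos = "serum10", btg2_btg2 = "serum10",
    fos_fra1deg_fos = "sustained", and_gate = "serum1_dox")
  params <- default_kinetic_params()
  for (nm in names(combos)) {
    sig <- make_stimulus(stimulus_preset(combos[[nm]]), params)
    traj <- simulate_circuit(circuit_preset(nm), params, sig)
    write_trajectory_csv(traj, file.path(outdir,
                                         sprintf("traj_%s.csv", nm)))
  }
  # compact movie fixture: small field, few sites, short timecourse
  spec <- circuit_preset("fos_btg2", n_sites = 4)
  sig <- make_stimulus(stimulus_preset("serum10"), params)
  traj <- simulate_circuit(spec, params, sig)
  sub <- traj[traj$time_min <= 60, ]
  attr(sub, "spec") <- spec
  attr(sub, "stim_onset_min") <- attr(traj, "stim_onset_min")
  attr(sub, "dt_min") <- attr(traj, "dt_min")
  class(sub) <- class(traj)
  geom <- cell_geometry(image_shape = c(64, 64), nucleus_axes = c(18, 14),
                        n_sites = 4, seed = seed)
  movie <- render_movie(sub, geom, optics_noise(), seed = seed)
  write_movie_tiff(movie, file.path(outdir, "movie_fos_btg2.tif"))

  files <- sort(list.files(outdir, full.names = TRUE))
  files <- files[!grepl("manifest\\.json$", files)]
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
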