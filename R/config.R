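# Run configuration and experiment orchestration: chains the pipeline stages
# into the two study experiments (gesture classification, force regression)
# plus the sensor benchmark.

default_run_config <- function() {
  list(
    experiment = "gesture",
    subjects = 1L,
    seed = 42L,
    rest_s = 15, gesture_s = 15, ramp_s = 15,
    n_reps = 6L, n_ramps = 10L,
    gestures = DEFAULT_GESTURES,
    sample_rate_lmg = 400, sample_rate_emg = 1200, led_toggle_ms = 125,
    noise_frac = 0.05, drift_amp = 0, tau_ms = 150,
    window_ms = 200, stride_ms = 20, label_policy = "strict",
    families = c("RF", "CNN", "TMC-ViT"),
    modalities = c("LMG", "EMG"),
    k_folds = 5L,
    epochs = 10L, batch_size = 128L, lr = 1e-3,
    max_train_windows = 1800,
    luminosity = 1, responsivity = 1,
    out_dir = "."
  )
}

#' Read and validate a run configuration
#'
#' Flat key/value YAML; unknown keys raise a configuration error, missing
#' keys take the documented defaults. All referenced parameters are
#' validated against their module's constraints before any stage runs.
#'
#' @param path YAML file path, or `NULL` for the defaults.
#' @param overrides named list applied on top.
#' @return validated configuration list.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  cfg <- default_run_config()
  user <- if (!is.null(path)) {
    if (!file.exists(path)) stop_config(sprintf("config file %s not found", path))
    yaml::read_yaml(path)
  } else list()
  user <- utils::modifyList(user, overrides)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    stop_config(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(cfg, user)
  if (!cfg$experiment %in% c("gesture", "force", "sensor-bench")) {
    stop_config("experiment must be gesture, force or sensor-bench")
  }
  if (!all(cfg$families %in% c("RF", "CNN", "TMC-ViT"))) {
    stop_config("families must be among RF, CNN, TMC-ViT")
  }
  if (!all(cfg$modalities %in% c("LMG", "EMG"))) {
    stop_config("modalities must be among LMG, EMG")
  }
  if (cfg$subjects < 1) stop_config("subjects must be >= 1")
  # constructing the protocol validates durations/repetitions/toggle
  if (cfg$experiment == "force") {
    makeForceProtocol(cfg$rest_s, cfg$ramp_s, cfg$n_ramps,
                      cfg$sample_rate_lmg, cfg$sample_rate_emg,
                      cfg$led_toggle_ms)
  } else {
    makeGestureProtocol(cfg$rest_s, cfg$gesture_s, cfg$n_reps, cfg$gestures,
                        cfg$sample_rate_lmg, cfg$sample_rate_emg,
                        cfg$led_toggle_ms)
  }
  cfg
}

subject_params_for <- function(cfg, s) {
  defaultSubjectParams(gestures = cfg$gestures, seed = cfg$seed + 1000L * s,
                       noise_frac = cfg$noise_frac, tau_deform_ms = cfg$tau_ms,
                       drift_amp = cfg$drift_amp)
}

train_config_for <- function(cfg, task, seed_offset = 0L) {
  trainConfig(loss = if (task == "regression") "MSE" else NULL,
              lr = cfg$lr, epochs = cfg$epochs, batch_size = cfg$batch_size,
              max_train_windows = cfg$max_train_windows,
              seed = cfg$seed + seed_offset)
}

# Balanced strict-labelled LMG window set of one simulated gesture session.
gesture_lmg_windows <- function(protocol, params, seed, cfg,
                                subject_id = "S1") {
  ses <- simulateGestureSession(protocol, params, seed, subject_id)
  rec <- demultiplex(ses$lmg)
  ws <- slideWindows(rec, cfg$window_ms, cfg$stride_ms,
                     label_policy = cfg$label_policy)
  balanceClasses(ws, seed = seed)
}

# Balanced EMG feature table of the same session.
gesture_emg_features <- function(protocol, params, seed, cfg,
                                 subject_id = "S1") {
  ses <- simulateGestureSession(protocol, params, seed, subject_id)
  emg <- bandpassFilter(ses$emg, low_hz = 5, high_hz = 500, order = 4)
  ws <- slideWindows(emg, cfg$window_ms, cfg$stride_ms,
                     label_policy = cfg$label_policy)
  ws <- balanceClasses(ws, seed = seed)
  featureTable(ws)
}

# Force-active LMG window set (windows fully inside ramp phases) with
# mean-force targets.
force_lmg_windows <- function(protocol, params, seed, cfg,
                              subject_id = "S1") {
  ses <- simulateForceSession(protocol, params, seed, subject_id)
  rec <- demultiplex(ses$lmg)
  ws <- slideWindows(rec, cfg$window_ms, cfg$stride_ms,
                     label_policy = "strict", target = forceValues(ses$force))
  subsetWindows(ws, which(windowLabels(ws) == "ramp"))
}

#' Reference gesture-classification benchmark on synthetic data
#'
#' The package's default synthetic benchmark: one subject (published seed-42
#' parameter draw, 5% noise, no drift), five gestures (rest + four grasps)
#' x six repetitions of 15 s rest / 15 s gesture, strict window labelling,
#' and repetition-blocked 5-fold cross-validation per decoder family on raw
#' demultiplexed LMG windows.
#'
#' @param families decoder families to run.
#' @param seed benchmark seed.
#' @param cfg_overrides named list of run-config overrides.
#' @return named list of [CVReport-class], one per family.
#' @export
gestureBenchmark <- function(families = c("RF", "CNN", "TMC-ViT"), seed = 42,
                             cfg_overrides = list()) {
  cfg <- readRunConfig(overrides = utils::modifyList(
    list(seed = as.integer(seed)), cfg_overrides))
  protocol <- makeGestureProtocol(cfg$rest_s, cfg$gesture_s, cfg$n_reps,
                                  cfg$gestures, cfg$sample_rate_lmg,
                                  cfg$sample_rate_emg, cfg$led_toggle_ms)
  params <- defaultSubjectParams(gestures = cfg$gestures, seed = seed,
                                 noise_frac = cfg$noise_frac,
                                 tau_deform_ms = cfg$tau_ms,
                                 drift_amp = cfg$drift_amp)
  ws <- gesture_lmg_windows(protocol, params, seed, cfg)
  out <- list()
  for (fam in families) {
    spec <- modelSpec(fam, "classification",
                      n_classes = length(cfg$gestures) + 1L, seed = seed)
    out[[fam]] <- crossvalClassification(
      ws, spec, k = cfg$k_folds, seed = seed,
      cfg = train_config_for(cfg, "classification"))
  }
  out
}

#' Reference force-regression benchmark on synthetic data
#'
#' One subject, ten 15 s rest / 15 s triangular force-ramp repetitions,
#' windows restricted to force-active periods, leave-one-repetition-out
#' 10-fold cross-validation. Metrics per fold: Pearson correlation and the
#' NMSE fit score of the reconstructed force trajectory.
#'
#' @param family decoder family.
#' @param seed benchmark seed.
#' @param cfg_overrides named list of run-config overrides.
#' @return a [CVReport-class]
#' @export
forceBenchmark <- function(family = "TMC-ViT", seed = 42,
                           cfg_overrides = list()) {
  # the near-linear force mapping converges in a few epochs; 6 keeps the
  # 10-fold benchmark in CPU minutes
  cfg <- readRunConfig(overrides = utils::modifyList(
    list(seed = as.integer(seed), experiment = "force", epochs = 6L),
    cfg_overrides))
  protocol <- makeForceProtocol(cfg$rest_s, cfg$ramp_s, cfg$n_ramps,
                                cfg$sample_rate_lmg, cfg$sample_rate_emg,
                                cfg$led_toggle_ms)
  params <- defaultSubjectParams(gestures = cfg$gestures, seed = seed,
                                 noise_frac = cfg$noise_frac,
                                 tau_deform_ms = cfg$tau_ms,
                                 drift_amp = cfg$drift_amp)
  ws <- force_lmg_windows(protocol, params, seed, cfg)
  spec <- modelSpec(family, "regression", seed = seed)
  crossvalRegression(ws, spec, folds = cfg$n_ramps,
                     cfg = train_config_for(cfg, "regression"))
}

#' Run a configured experiment end to end
#'
#' `gesture`: per subject, simulates an LMG + EMG session, preprocesses both
#' modalities, runs repetition-blocked cross-validation for every configured
#' family, aggregates a per-subject results table, and compares the two
#' modalities with one-way ANOVA over the subject x family accuracy means.
#' `force`: per subject, leave-one-repetition-out force regression per
#' family. `sensor-bench`: per-channel performance index of the simulated
#' armband. Artifacts (CSV/JSON) are written under `cfg$out_dir`.
#'
#' @param cfg configuration list from [readRunConfig()].
#' @return list with the results table (or bench values) and paths of the
#'   written artifacts.
#' @export
runExperiment <- function(cfg) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  switch(cfg$experiment,
         "gesture" = run_gesture_experiment(cfg),
         "force" = run_force_experiment(cfg),
         "sensor-bench" = run_sensor_bench(cfg))
}

run_gesture_experiment <- function(cfg) {
  protocol <- makeGestureProtocol(cfg$rest_s, cfg$gesture_s, cfg$n_reps,
                                  cfg$gestures, cfg$sample_rate_lmg,
                                  cfg$sample_rate_emg, cfg$led_toggle_ms)
  rows <- list()
  for (s in seq_len(cfg$subjects)) {
    params <- subject_params_for(cfg, s)
    sid <- sprintf("S%02d", s)
    seed_s <- cfg$seed + s
    inputs <- list()
    if ("LMG" %in% cfg$modalities) {
      inputs$LMG <- gesture_lmg_windows(protocol, params, seed_s, cfg, sid)
    }
    if ("EMG" %in% cfg$modalities) {
      inputs$EMG <- gesture_emg_features(protocol, params, seed_s, cfg, sid)
    }
    row <- list(subject = sid)
    for (mo in names(inputs)) {
      for (fam in cfg$families) {
        spec <- modelSpec(fam, "classification",
                          n_classes = length(cfg$gestures) + 1L,
                          seed = seed_s)
        rep_ <- crossvalClassification(
          inputs[[mo]], spec, k = cfg$k_folds, seed = seed_s,
          cfg = train_config_for(cfg, "classification", s))
        row[[paste0(mo, "_", fam)]] <- 100 * cvMeans(rep_)[["accuracy"]]
        row[[paste0(mo, "_", fam, "_sd")]] <- 100 * cvStds(rep_)[["accuracy"]]
        msg_log(sprintf("%s %s %s: %.2f +/- %.2f %%", sid, mo, fam,
                        row[[paste0(mo, "_", fam)]],
                        row[[paste0(mo, "_", fam, "_sd")]]))
      }
    }
    rows[[s]] <- as.data.frame(row, check.names = FALSE)
  }
  df <- do.call(rbind, rows)
  mean_cols <- grep("_sd$", setdiff(names(df), "subject"),
                    invert = TRUE, value = TRUE)
  compare <- NULL
  if (all(c("LMG", "EMG") %in% cfg$modalities)) {
    compare <- stats::setNames(
      lapply(cfg$families, function(f) c(paste0("LMG_", f), paste0("EMG_", f))),
      cfg$families)
  }
  rt <- aggregateResults(df, compare = compare)
  an <- NULL
  if (!is.null(compare) && cfg$subjects * length(cfg$families) >= 2) {
    lmg_acc <- unlist(df[paste0("LMG_", cfg$families)])
    emg_acc <- unlist(df[paste0("EMG_", cfg$families)])
    an <- anovaOneWay(lmg_acc, emg_acc)
  }
  prefix <- file.path(cfg$out_dir, "gesture_results")
  writeResultsTable(rt, prefix, anova = an)
  list(results = rt, anova = an, artifacts = session_files(prefix))
}

run_force_experiment <- function(cfg) {
  protocol <- makeForceProtocol(cfg$rest_s, cfg$ramp_s, cfg$n_ramps,
                                cfg$sample_rate_lmg, cfg$sample_rate_emg,
                                cfg$led_toggle_ms)
  rows <- list()
  for (s in seq_len(cfg$subjects)) {
    params <- subject_params_for(cfg, s)
    sid <- sprintf("S%02d", s)
    seed_s <- cfg$seed + s
    ws <- force_lmg_windows(protocol, params, seed_s, cfg, sid)
    row <- list(subject = sid)
    for (fam in cfg$families) {
      spec <- modelSpec(fam, "regression", seed = seed_s)
      rep_ <- crossvalRegression(ws, spec, folds = cfg$n_ramps,
                                 cfg = train_config_for(cfg, "regression", s))
      row[[paste0(fam, "_corr")]] <- 100 * cvMeans(rep_)[["pearson"]]
      row[[paste0(fam, "_nmse")]] <- cvMeans(rep_)[["nmse"]]
      msg_log(sprintf("%s %s: corr %.2f%%, NMSE %.2f%%", sid, fam,
                      row[[paste0(fam, "_corr")]],
                      row[[paste0(fam, "_nmse")]]))
    }
    rows[[s]] <- as.data.frame(row, check.names = FALSE)
  }
  rt <- aggregateResults(do.call(rbind, rows))
  prefix <- file.path(cfg$out_dir, "force_results")
  writeResultsTable(rt, prefix)
  list(results = rt, artifacts = session_files(prefix))
}

run_sensor_bench <- function(cfg) {
  protocol <- makeGestureProtocol(cfg$rest_s, cfg$gesture_s,
                                  max(2L, cfg$n_reps), cfg$gestures,
                                  cfg$sample_rate_lmg, cfg$sample_rate_emg,
                                  cfg$led_toggle_ms)
  params <- subject_params_for(cfg, 1L)
  ses <- simulateGestureSession(protocol, params, cfg$seed, "S01")
  rec <- demultiplex(ses$lmg)
  sig <- signalMatrix(rec)
  trig <- triggerTrack(rec)
  idx <- list(gesture = trig != "rest", rest = trig == "rest")
  vals <- lapply(1:5, function(c_) {
    b <- sensorBench(mean(sig[idx$gesture, c_]), mean(sig[idx$rest, c_]),
                     cfg$luminosity, cfg$responsivity)
    performanceIndex(b)
  })
  out <- list(per_channel = unlist(vals), mean = mean(unlist(vals)),
              luminosity = cfg$luminosity, responsivity = cfg$responsivity)
  path <- file.path(cfg$out_dir, "sensor_bench.json")
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  list(bench = out, artifacts = path)
}
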