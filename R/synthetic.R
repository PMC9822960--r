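# Synthetic session generator. Emulates the 5-module optical (LMG) armband
# with time-multiplexed green/IR LEDs, 5-channel bipolar EMG, and grip-force
# ramp sessions, with the temporal structure the downstream analysis assumes:
# block-designed rest/active phases, first-order tissue deformation dynamics,
# slow drift, and sensor noise.

DEFAULT_GESTURES <- c("pinch", "tripod", "power", "extension")

#' Build a block-design gesture protocol
#'
#' Each gesture repetition is one (rest, gesture) phase pair; the schedule is
#' ordered gesture-by-gesture, repetition-by-repetition, so it alternates rest
#' and active phases throughout.
#'
#' @param rest_s rest phase duration in seconds.
#' @param gesture_s active phase duration in seconds.
#' @param n_reps repetitions per gesture.
#' @param gestures character vector of active gesture labels.
#' @param sample_rate_lmg LMG (photodiode) sampling rate in Hz.
#' @param sample_rate_emg EMG sampling rate in Hz.
#' @param led_toggle_ms LED alternation interval in ms.
#' @return a [Protocol-class] with `2 * n_reps * length(gestures)` phases.
#' @examples
#' p <- makeGestureProtocol(15, 15, 6, c("pinch", "tripod", "power", "extension"))
#' nrow(protocolPhases(p))  # 48
#' @export
makeGestureProtocol <- function(rest_s = 15, gesture_s = 15, n_reps = 6,
                                gestures = DEFAULT_GESTURES,
                                sample_rate_lmg = 400,
                                sample_rate_emg = 1200,
                                led_toggle_ms = 125) {
  if (length(gestures) == 0) stop_config("gesture list must be non-empty")
  if (rest_s <= 0 || gesture_s <= 0) stop_config("phase durations must be > 0")
  if (n_reps < 1) stop_config("n_reps must be >= 1")
  gestures <- as.character(gestures)
  rows <- do.call(rbind, lapply(gestures, function(g) {
    do.call(rbind, lapply(seq_len(n_reps), function(r) {
      data.frame(label = c("rest", g), duration_s = c(rest_s, gesture_s),
                 repetition = r, active = c(FALSE, TRUE),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  new("Protocol", phases = rows, gestures = gestures,
      nRepetitions = as.integer(n_reps), sampleRateLMG = sample_rate_lmg,
      sampleRateEMG = sample_rate_emg, ledToggleMs = led_toggle_ms)
}

#' Build a force-ramp protocol
#'
#' Alternates rest phases with triangular force-ramp phases (ramp to half of
#' maximum clench and back), repeated `n_reps` times.
#'
#' @param rest_s rest duration (s).
#' @param ramp_s ramp duration (s).
#' @param n_reps number of ramps.
#' @inheritParams makeGestureProtocol
#' @return a [Protocol-class] whose single active label is `"ramp"`.
#' @export
makeForceProtocol <- function(rest_s = 15, ramp_s = 15, n_reps = 10,
                              sample_rate_lmg = 400,
                              sample_rate_emg = 1200,
                              led_toggle_ms = 125) {
  if (rest_s <= 0 || ramp_s <= 0) stop_config("phase durations must be > 0")
  if (n_reps < 1) stop_config("n_reps must be >= 1")
  rows <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    data.frame(label = c("rest", "ramp"), duration_s = c(rest_s, ramp_s),
               repetition = r, active = c(FALSE, TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  new("Protocol", phases = rows, gestures = "ramp",
      nRepetitions = as.integer(n_reps), sampleRateLMG = sample_rate_lmg,
      sampleRateEMG = sample_rate_emg, ledToggleMs = led_toggle_ms)
}

#' Phase schedule of a protocol
#' @param protocol a [Protocol-class]
#' @return data.frame with columns label, duration_s, repetition, active
#' @export
protocolPhases <- function(protocol) protocol@phases

#' Gesture vocabulary of a protocol (active labels, excluding rest)
#' @param protocol a [Protocol-class]
#' @return character vector
#' @export
protocolGestures <- function(protocol) protocol@gestures

# Per-sample label / repetition tracks on a given sample grid.
phase_tracks <- function(protocol, sample_rate) {
  ph <- protocol@phases
  n <- round(ph$duration_s * sample_rate)
  list(trigger = rep(ph$label, times = n),
       repetition = rep(ph$repetition, times = n),
       phase_index = rep(seq_len(nrow(ph)), times = n),
       n_per_phase = n)
}

#' Default subject parameters (published seed-42 draw)
#'
#' Gesture gain columns are drawn uniformly and redrawn (rejection) until the
#' minimum pairwise Euclidean column distance exceeds `min_col_dist`, so no
#' two gestures produce the same deflection pattern. The LMG noise SD defaults
#' to `noise_frac` of the mean active optical gain.
#'
#' @param gestures active gesture labels.
#' @param seed integer seed of the draw.
#' @param noise_frac LMG/EMG noise SD as a fraction of the mean active gain.
#' @param tau_deform_ms tissue time constant (ms).
#' @param drift_amp drift amplitude (a.u.); `NULL` = 2% of the gain scale.
#' @param drift_period_s drift period (s).
#' @param n_channels number of armband modules.
#' @param min_col_dist minimum pairwise gain-column distance enforced by
#'   rejection.
#' @return a [SubjectParams-class]
#' @export
defaultSubjectParams <- function(gestures = DEFAULT_GESTURES, seed = 42,
                                 noise_frac = 0.05, tau_deform_ms = 150,
                                 drift_amp = NULL, drift_period_s = 60,
                                 n_channels = 5, min_col_dist = 0.5) {
  gestures <- as.character(gestures)
  draw_gains <- function(lo, hi) {
    repeat {
      m <- matrix(stats::runif(n_channels * length(gestures), lo, hi),
                  nrow = n_channels, dimnames = list(NULL, gestures))
      if (length(gestures) < 2) return(m)
      d <- as.matrix(stats::dist(t(m)))
      if (min(d[upper.tri(d)]) >= min_col_dist) return(m)
    }
  }
  with_seed(seed, {
    gg <- draw_gains(0.6, 1.6)
    gi <- draw_gains(0.3, 1.0)
    ge <- draw_gains(0.5, 1.5)
    baseline <- stats::runif(n_channels, 1.8, 2.2)
  })
  add_rest <- function(m) {
    cbind(rest = rep(0, n_channels), m)
  }
  gscale <- mean(c(gg, gi))
  new("SubjectParams",
      gainGreen = add_rest(gg), gainIR = add_rest(gi),
      baseline = baseline, tauDeformMs = tau_deform_ms,
      driftAmp = drift_amp %||% (0.02 * gscale),
      driftPeriodS = drift_period_s,
      noiseSdLMG = noise_frac * gscale,
      emgGain = add_rest(ge),
      noiseSdEMG = noise_frac * mean(ge),
      emgBandHz = c(20, 450),
      seed = as.integer(seed))
}

#' First-order activation envelopes from a trigger track
#'
#' One envelope per gesture: the first-order lag response
#' `e(t + dt) = e(t) + (target - e(t)) * (1 - exp(-dt / tau))` to the 0/1
#' indicator of that gesture being active, computed exactly with a recursive
#' filter. Values are bounded in \[0, 1\] and monotone toward the target
#' within each phase.
#'
#' @param trigger character label track.
#' @param tau_deform_ms time constant in ms.
#' @param sample_rate sampling rate in Hz.
#' @param gestures envelope columns to produce; default all non-rest labels
#'   present in `trigger`.
#' @return T x G numeric matrix with gesture column names.
#' @export
activationEnvelope <- function(trigger, tau_deform_ms, sample_rate,
                               gestures = NULL) {
  if (tau_deform_ms <= 0) stop_config("tau_deform_ms must be > 0")
  gestures <- gestures %||% setdiff(unique(trigger), "rest")
  alpha <- 1 - exp(-1000 / (tau_deform_ms * sample_rate))
  env <- matrix(0, nrow = length(trigger), ncol = length(gestures),
                dimnames = list(NULL, gestures))
  for (g in gestures) {
    target <- as.numeric(trigger == g)
    e <- stats::filter(alpha * target, filter = 1 - alpha,
                       method = "recursive")
    env[, g] <- pmin(pmax(as.numeric(e), 0), 1)
  }
  env
}

# Deflection common to both LED colours: per-channel gesture gain times the
# per-gesture envelope, summed over gestures (at most one is non-negligible
# at a time under a block design).
lmg_deflection <- function(env, gains) {
  # env: T x G (active gestures); gains: 5 x (rest + gestures)
  act <- gains[, colnames(env), drop = FALSE]  # 5 x G
  env %*% t(act)                               # T x 5
}

led_state_track <- function(T_, sample_rate, toggle_ms) {
  nrun <- round(toggle_ms * sample_rate / 1000)
  n_runs <- ceiling(T_ / nrun)
  states <- rep(c("green", "ir"), length.out = n_runs)
  rep(states, each = nrun)[seq_len(T_)]
}

drift_track <- function(T_, sample_rate, amp, period_s) {
  if (amp == 0) return(numeric(T_))
  t <- (seq_len(T_) - 1) / sample_rate
  amp * sin(2 * pi * t / period_s)
}

# Band-limited unit-variance noise carrier for EMG synthesis.
emg_carrier <- function(T_, sample_rate, band) {
  ny <- sample_rate / 2
  w <- pmin(band / ny, 0.99)
  bf <- signal::butter(4, w, type = "pass")
  x <- stats::rnorm(T_)
  y <- as.numeric(signal::filter(bf, x))
  y / stats::sd(y)
}

#' Simulate one gesture session (LMG + EMG)
#'
#' The multiplexed photodiode sample at time t on channel c is
#' `baseline_c + gain[c, g(t)] * e(t)` for the currently lit LED colour,
#' plus drift and Gaussian sensor noise. EMG channels are band-limited
#' standard noise amplitude-modulated by `emg_gain[c, g(t)] * e(t)` plus
#' measurement noise. Identical `(protocol, params, seed)` give bit-identical
#' output.
#'
#' @param protocol a [Protocol-class] from [makeGestureProtocol()].
#' @param params a [SubjectParams-class].
#' @param seed integer seed.
#' @param subject_id subject identifier stored in the outputs.
#' @return list with elements `lmg` ([MultiplexedLMG-class]),
#'   `emg` ([SessionRecording-class]) and `trigger` (the LMG-grid label
#'   track).
#' @export
simulateGestureSession <- function(protocol, params, seed = 1,
                                   subject_id = "S1") {
  validObject(protocol); validObject(params)
  fs_l <- protocol@sampleRateLMG
  fs_e <- protocol@sampleRateEMG
  tr_l <- phase_tracks(protocol, fs_l)
  tr_e <- phase_tracks(protocol, fs_e)
  T_l <- length(tr_l$trigger)
  T_e <- length(tr_e$trigger)
  gset <- protocol@gestures

  env_l <- activationEnvelope(tr_l$trigger, params@tauDeformMs, fs_l, gset)
  env_e <- activationEnvelope(tr_e$trigger, params@tauDeformMs, fs_e, gset)
  defl_g <- lmg_deflection(env_l, params@gainGreen)
  defl_i <- lmg_deflection(env_l, params@gainIR)
  led <- led_state_track(T_l, fs_l, protocol@ledToggleMs)
  green_lit <- led == "green"
  defl <- defl_i
  defl[green_lit, ] <- defl_g[green_lit, ]
  drift <- drift_track(T_l, fs_l, params@driftAmp, params@driftPeriodS)

  with_seed(seed, {
    noise_l <- matrix(stats::rnorm(T_l * 5, sd = params@noiseSdLMG), T_l, 5)
    carriers <- vapply(1:5, function(c_)
      emg_carrier(T_e, fs_e, params@emgBandHz), numeric(T_e))
    noise_e <- matrix(stats::rnorm(T_e * 5, sd = params@noiseSdEMG), T_e, 5)
  })

  samples <- sweep(defl, 2, params@baseline, "+") + drift + noise_l
  colnames(samples) <- paste0("pd", 1:5)

  amp_e <- lmg_deflection(env_e, params@emgGain)  # T_e x 5 activation amplitude
  emg_sig <- amp_e * carriers + noise_e
  colnames(emg_sig) <- paste0("emg", 1:5)

  lmg <- new("MultiplexedLMG", samples = samples, ledState = led,
             trigger = tr_l$trigger, repetitionId = as.integer(tr_l$repetition),
             sampleRate = fs_l, toggleMs = protocol@ledToggleMs,
             subjectId = subject_id)
  emg <- new("SessionRecording", signal = emg_sig, trigger = tr_e$trigger,
             repetitionId = as.integer(tr_e$repetition), sampleRate = fs_e,
             modality = "EMG", subjectId = subject_id)
  list(lmg = lmg, emg = emg, trigger = tr_l$trigger)
}

# Triangular ramp 0 -> peak -> 0 over one phase, evaluated on the sample grid.
triangle_ramp <- function(n, duration_s, sample_rate, peak = 0.5) {
  t_off <- (seq_len(n) - 1) / sample_rate
  peak * (1 - abs(1 - 2 * t_off / duration_s))
}

#' Simulate one force-ramp session (LMG + force trace)
#'
#' Force is a triangular ramp 0 -> 0.5 -> 0 of the normalized maximum clench
#' per active phase. The optical deflection is `gain * (force / 0.5)` passed
#' through the same first-order tissue dynamics; the `"power"` gesture gain
#' column drives the armband (a clench is a power grasp). Force and LMG are
#' time-aligned on the LMG sample grid.
#'
#' @param protocol a [Protocol-class] from [makeForceProtocol()].
#' @param params a [SubjectParams-class]; must contain a `"power"` gain
#'   column.
#' @param seed integer seed.
#' @param subject_id subject identifier.
#' @return list with elements `lmg` ([MultiplexedLMG-class]) and
#'   `force` ([ForceTrace-class]).
#' @export
simulateForceSession <- function(protocol, params, seed = 1,
                                 subject_id = "S1") {
  validObject(protocol); validObject(params)
  if (!"power" %in% colnames(params@gainGreen)) {
    stop_config("params must provide a 'power' gain column for clench force")
  }
  fs <- protocol@sampleRateLMG
  tr <- phase_tracks(protocol, fs)
  T_ <- length(tr$trigger)
  ph <- protocol@phases

  force <- numeric(T_)
  offs <- c(0, cumsum(tr$n_per_phase))
  for (i in seq_len(nrow(ph))) {
    if (!ph$active[i]) next
    idx <- (offs[i] + 1):offs[i + 1]
    force[idx] <- triangle_ramp(length(idx), ph$duration_s[i], fs)
  }

  # First-order tissue response to the continuous drive force / 0.5.
  alpha <- 1 - exp(-1000 / (params@tauDeformMs * fs))
  drive <- force / 0.5
  e <- as.numeric(stats::filter(alpha * drive, filter = 1 - alpha,
                                method = "recursive"))
  defl_g <- outer(e, params@gainGreen[, "power"])
  defl_i <- outer(e, params@gainIR[, "power"])
  led <- led_state_track(T_, fs, protocol@ledToggleMs)
  green_lit <- led == "green"
  defl <- defl_i
  defl[green_lit, ] <- defl_g[green_lit, ]
  drift <- drift_track(T_, fs, params@driftAmp, params@driftPeriodS)

  with_seed(seed, {
    noise <- matrix(stats::rnorm(T_ * 5, sd = params@noiseSdLMG), T_, 5)
  })
  samples <- sweep(defl, 2, params@baseline, "+") + drift + noise
  colnames(samples) <- paste0("pd", 1:5)

  lmg <- new("MultiplexedLMG", samples = samples, ledState = led,
             trigger = tr$trigger, repetitionId = as.integer(tr$repetition),
             sampleRate = fs, toggleMs = protocol@ledToggleMs,
             subjectId = subject_id)
  list(lmg = lmg, force = new("ForceTrace", force = force, sampleRate = fs))
}
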