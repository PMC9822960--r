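#' @import methods
NULL

#' Recording protocol for a data-collection session
#'
#' A `Protocol` holds the phase schedule of one session: an ordered table of
#' phases alternating rest and active periods, the gesture vocabulary, the
#' per-modality sampling rates and the LED multiplexing interval of the
#' optical armband.
#'
#' @slot phases data.frame with columns `label`, `duration_s`, `repetition`,
#'   `active`; rows are executed in order.
#' @slot gestures ordered character vector of active gesture labels
#'   (excluding `"rest"`).
#' @slot nRepetitions integer, repetitions per gesture.
#' @slot sampleRateLMG numeric, photodiode sampling rate (Hz).
#' @slot sampleRateEMG numeric, EMG sampling rate (Hz).
#' @slot ledToggleMs numeric, green/IR LED alternation interval (ms).
#' @export
setClass("Protocol", representation(
  phases = "data.frame",
  gestures = "character",
  nRepetitions = "integer",
  sampleRateLMG = "numeric",
  sampleRateEMG = "numeric",
  ledToggleMs = "numeric"
))

setValidity("Protocol", function(object) {
  ph <- object@phases
  msgs <- character()
  need <- c("label", "duration_s", "repetition", "active")
  if (!all(need %in% names(ph))) {
    return(sprintf("phases must have columns %s", paste(need, collapse = ", ")))
  }
  if (nrow(ph) == 0) msgs <- c(msgs, "empty phase schedule")
  if (any(ph$duration_s <= 0)) msgs <- c(msgs, "phase durations must be > 0")
  if (object@nRepetitions < 1L) msgs <- c(msgs, "nRepetitions must be >= 1")
  if (object@ledToggleMs <= 0) msgs <- c(msgs, "ledToggleMs must be > 0")
  if (object@sampleRateLMG <= 0 || object@sampleRateEMG <= 0) {
    msgs <- c(msgs, "sample rates must be > 0")
  }
  if (nrow(ph) > 1 && any(ph$active[-1] == ph$active[-nrow(ph)])) {
    msgs <- c(msgs, "schedule must alternate rest and active phases")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Phenomenological per-subject simulation parameters
#'
#' Gain matrices map (channel, gesture) to the luminosity deflection seen by
#' the photodiode under each LED colour, or to the EMG activation amplitude.
#' Columns are named by gesture; the `"rest"` column is identically zero.
#'
#' @slot gainGreen 5 x G matrix of green-LED luminosity deflections (a.u.).
#' @slot gainIR 5 x G matrix of infrared-LED deflections (a.u.).
#' @slot baseline per-channel photodiode offset (a.u.).
#' @slot tauDeformMs first-order tissue deformation time constant (ms).
#' @slot driftAmp slow baseline drift amplitude (a.u.).
#' @slot driftPeriodS drift sinusoid period (s).
#' @slot noiseSdLMG photodiode noise standard deviation (a.u.).
#' @slot emgGain 5 x G matrix of EMG activation amplitudes (mV).
#' @slot noiseSdEMG EMG measurement noise standard deviation (mV).
#' @slot emgBandHz length-2 synthesis band of the EMG carrier noise (Hz).
#' @slot seed integer seed the parameter draw is published under.
#' @export
setClass("SubjectParams", representation(
  gainGreen = "matrix",
  gainIR = "matrix",
  baseline = "numeric",
  tauDeformMs = "numeric",
  driftAmp = "numeric",
  driftPeriodS = "numeric",
  noiseSdLMG = "numeric",
  emgGain = "matrix",
  noiseSdEMG = "numeric",
  emgBandHz = "numeric",
  seed = "integer"
))

setValidity("SubjectParams", function(object) {
  msgs <- character()
  mats <- list(gainGreen = object@gainGreen, gainIR = object@gainIR,
               emgGain = object@emgGain)
  for (nm in names(mats)) {
    m <- mats[[nm]]
    if (is.null(colnames(m))) {
      msgs <- c(msgs, sprintf("%s must have gesture column names", nm))
      next
    }
    if (!"rest" %in% colnames(m)) {
      msgs <- c(msgs, sprintf("%s must include a 'rest' column", nm))
    } else if (any(m[, "rest"] != 0)) {
      msgs <- c(msgs, sprintf("%s rest column must be all zero", nm))
    }
    act <- m[, setdiff(colnames(m), "rest"), drop = FALSE]
    if (ncol(act) >= 2) {
      for (i in seq_len(ncol(act) - 1)) {
        for (j in (i + 1):ncol(act)) {
          if (isTRUE(all(act[, i] == act[, j]))) {
            msgs <- c(msgs, sprintf("%s has identical columns '%s' and '%s'",
                                    nm, colnames(act)[i], colnames(act)[j]))
          }
        }
      }
    }
  }
  if (object@tauDeformMs <= 0) msgs <- c(msgs, "tauDeformMs must be > 0")
  if (object@noiseSdLMG < 0 || object@noiseSdEMG < 0) {
    msgs <- c(msgs, "noise standard deviations must be >= 0")
  }
  if (length(object@emgBandHz) != 2 || object@emgBandHz[1] >= object@emgBandHz[2]) {
    msgs <- c(msgs, "emgBandHz must be (low, high) with low < high")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Raw time-multiplexed photodiode recording
#'
#' Photodiode samples before green/IR separation, together with the LED-state
#' track and the supervision tracks (trigger, repetition) recorded alongside.
#'
#' @slot samples T x 5 matrix of photodiode readings (a.u.).
#' @slot ledState length-T character track, values `"green"` or `"ir"`.
#' @slot trigger length-T gesture/rest label track.
#' @slot repetitionId length-T integer repetition track.
#' @slot sampleRate sampling rate (Hz).
#' @slot toggleMs LED alternation interval (ms).
#' @slot subjectId subject identifier.
#' @export
setClass("MultiplexedLMG", representation(
  samples = "matrix",
  ledState = "character",
  trigger = "character",
  repetitionId = "integer",
  sampleRate = "numeric",
  toggleMs = "numeric",
  subjectId = "character"
))

setValidity("MultiplexedLMG", function(object) {
  msgs <- character()
  T_ <- nrow(object@samples)
  if (T_ < 1) msgs <- c(msgs, "need at least one sample")
  if (!all(object@ledState %in% c("green", "ir"))) {
    msgs <- c(msgs, "ledState values must be 'green' or 'ir'")
  }
  if (length(object@ledState) != T_ || length(object@trigger) != T_ ||
      length(object@repetitionId) != T_) {
    msgs <- c(msgs, "samples, ledState, trigger, repetitionId must share length")
  }
  nrun <- round(object@toggleMs * object@sampleRate / 1000)
  r <- rle(object@ledState)
  if (length(r$lengths) > 1 && !all(r$lengths[-length(r$lengths)] == nrun)) {
    msgs <- c(msgs, sprintf("ledState must alternate in runs of %d samples", nrun))
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Demultiplexed or EMG session recording
#'
#' The uniformly sampled multichannel block every pipeline stage consumes:
#' 10 demultiplexed LMG channels (5 green + 5 IR) or 5 bipolar EMG channels,
#' plus the per-sample trigger and repetition tracks.
#'
#' @slot signal T x C numeric matrix, channels in columns.
#' @slot trigger length-T gesture/rest label track.
#' @slot repetitionId length-T integer repetition track.
#' @slot sampleRate sampling rate (Hz).
#' @slot modality `"LMG"` or `"EMG"`.
#' @slot subjectId subject identifier.
#' @export
setClass("SessionRecording", representation(
  signal = "matrix",
  trigger = "character",
  repetitionId = "integer",
  sampleRate = "numeric",
  modality = "character",
  subjectId = "character"
))

setValidity("SessionRecording", function(object) {
  msgs <- character()
  T_ <- nrow(object@signal)
  if (length(object@trigger) != T_ || length(object@repetitionId) != T_) {
    msgs <- c(msgs, "signal, trigger and repetitionId must share length")
  }
  if (!object@modality %in% c("LMG", "EMG")) {
    msgs <- c(msgs, "modality must be 'LMG' or 'EMG'")
  }
  if (object@sampleRate <= 0) msgs <- c(msgs, "sampleRate must be > 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Normalized grip-force trace
#'
#' Force normalized to the subject's maximum clench, aligned on the LMG
#' sample grid.
#'
#' @slot force length-T numeric in \[0, 1\].
#' @slot sampleRate sampling rate (Hz).
#' @export
setClass("ForceTrace", representation(
  force = "numeric",
  sampleRate = "numeric"
))

setValidity("ForceTrace", function(object) {
  if (any(object@force < 0 | object@force > 1)) {
    "force must lie in [0, 1]"
  } else if (object@sampleRate <= 0) {
    "sampleRate must be > 0"
  } else TRUE
})

#' Set of fixed-length labelled windows
#'
#' The N x L x C tensor of sliding windows cut from one session, with
#' per-window label, repetition id and (for force sessions) regression target.
#'
#' @slot windows numeric array `[N, L, C]`.
#' @slot labels length-N character labels.
#' @slot repetitionIds length-N integer repetition ids.
#' @slot targets length-N numeric regression targets, or length 0.
#' @slot windowMs window length (ms).
#' @slot strideMs stride (ms).
#' @slot modality `"LMG"` or `"EMG"`.
#' @slot sampleRate source sampling rate (Hz).
#' @slot channelNames channel names (length C).
#' @export
setClass("WindowSet", representation(
  windows = "array",
  labels = "character",
  repetitionIds = "integer",
  targets = "numeric",
  windowMs = "numeric",
  strideMs = "numeric",
  modality = "character",
  sampleRate = "numeric",
  channelNames = "character"
))

setValidity("WindowSet", function(object) {
  d <- dim(object@windows)
  msgs <- character()
  if (length(d) != 3) return("windows must be a 3-d array [N, L, C]")
  if (length(object@labels) != d[1] || length(object@repetitionIds) != d[1]) {
    msgs <- c(msgs, "labels and repetitionIds must have one entry per window")
  }
  if (length(object@targets) && length(object@targets) != d[1]) {
    msgs <- c(msgs, "targets must be empty or one per window")
  }
  if (length(object@channelNames) && length(object@channelNames) != d[3]) {
    msgs <- c(msgs, "channelNames must match the channel dimension")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Per-window EMG time-domain feature table
#'
#' One row per window; columns are channel x feature with the fixed feature
#' order RMS, WL, ZC, MAV, iEMG, WAMP, VAR, LOG.
#'
#' @slot values N x (8 C) numeric matrix with named columns.
#' @slot thresholds list with `eps_zc`, `eps_wamp`, `delta_log`.
#' @slot labels length-N window labels.
#' @slot repetitionIds length-N repetition ids.
#' @export
setClass("FeatureTable", representation(
  values = "matrix",
  thresholds = "list",
  labels = "character",
  repetitionIds = "integer"
))

setValidity("FeatureTable", function(object) {
  msgs <- character()
  if (ncol(object@values) %% 8 != 0) {
    msgs <- c(msgs, "column count must be 8 per channel")
  }
  if (nrow(object@values) && !all(is.finite(object@values))) {
    msgs <- c(msgs, "all feature values must be finite")
  }
  if (length(object@labels) != nrow(object@values) ||
      length(object@repetitionIds) != nrow(object@values)) {
    msgs <- c(msgs, "labels/repetitionIds must have one entry per row")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Decoder architecture specification
#'
#' Declarative description of one decoder: the model family, the task, and
#' every size hyperparameter. Construction is seed-deterministic.
#'
#' @slot family `"RF"`, `"CNN"` or `"TMC-ViT"`.
#' @slot task `"classification"` or `"regression"`.
#' @slot rfTrees number of trees for the random forest.
#' @slot cnnFilters filters of the three convolutional blocks.
#' @slot cnnKernel temporal kernel size.
#' @slot cnnDropout dropout rate inside each conv block.
#' @slot cnnFcWidths widths of the four fully-connected layers.
#' @slot cnnStride temporal stride of each conv block.
#' @slot vitConvFilters filters of the two embedding conv layers.
#' @slot patchSize patch size, default `c(2, 2)`.
#' @slot nAttentionLayers transformer encoder depth.
#' @slot nHeads attention heads per layer.
#' @slot embedDim token embedding dimension.
#' @slot mlpDim hidden width of the encoder MLP.
#' @slot nClasses classification output size.
#' @slot seed integer seed for weight initialization.
#' @export
setClass("ModelSpec", representation(
  family = "character",
  task = "character",
  rfTrees = "integer",
  cnnFilters = "integer",
  cnnKernel = "integer",
  cnnDropout = "numeric",
  cnnFcWidths = "integer",
  cnnStride = "integer",
  vitConvFilters = "integer",
  patchSize = "integer",
  nAttentionLayers = "integer",
  nHeads = "integer",
  embedDim = "integer",
  mlpDim = "integer",
  nClasses = "integer",
  seed = "integer"
))

setValidity("ModelSpec", function(object) {
  msgs <- character()
  if (!object@family %in% c("RF", "CNN", "TMC-ViT")) {
    msgs <- c(msgs, "family must be RF, CNN or TMC-ViT")
  }
  if (!object@task %in% c("classification", "regression")) {
    msgs <- c(msgs, "task must be classification or regression")
  }
  if (object@rfTrees < 1L) msgs <- c(msgs, "rfTrees must be >= 1")
  if (object@embedDim %% object@nHeads != 0L) {
    msgs <- c(msgs, "embedDim must be divisible by nHeads")
  }
  if (object@task == "classification" && object@nClasses < 2L) {
    msgs <- c(msgs, "classification needs >= 2 classes")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Training configuration
#'
#' @slot loss `"sparse-categorical-cross-entropy"` or `"MSE"`.
#' @slot lr Adam learning rate.
#' @slot beta1,beta2 Adam moment decays.
#' @slot epochs maximum training epochs.
#' @slot batchSize minibatch size.
#' @slot patience early-stop patience (epochs without loss improvement).
#' @slot maxTrainWindows seeded subsample cap on the training set (Inf = all).
#' @slot seed integer seed for shuffling/dropout.
#' @export
setClass("TrainConfig", representation(
  loss = "character",
  lr = "numeric",
  beta1 = "numeric",
  beta2 = "numeric",
  epochs = "integer",
  batchSize = "integer",
  patience = "integer",
  maxTrainWindows = "numeric",
  seed = "integer"
))

setValidity("TrainConfig", function(object) {
  msgs <- character()
  if (!object@loss %in% c("sparse-categorical-cross-entropy", "MSE")) {
    msgs <- c(msgs, "unknown loss")
  }
  if (object@epochs < 1L || object@batchSize < 1L) {
    msgs <- c(msgs, "epochs and batchSize must be >= 1")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Untrained decoder
#'
#' A built (seed-deterministically initialized) but unfitted decoder.
#'
#' @slot spec the [ModelSpec-class].
#' @slot inputShape integer `c(L, C)` window shape.
#' @slot net list holding geometry and initial parameters (deep families).
#' @export
setClass("Decoder", representation(
  spec = "ModelSpec",
  inputShape = "integer",
  net = "list"
))

#' Fitted decoder
#'
#' @slot spec the [ModelSpec-class].
#' @slot inputShape integer `c(L, C)`.
#' @slot model fitted ranger forest or native network parameter list.
#' @slot classes class labels (classification) or `character(0)`.
#' @slot history training history (per-epoch losses).
#' @export
setClass("FittedDecoder", representation(
  spec = "ModelSpec",
  inputShape = "integer",
  model = "ANY",
  classes = "character",
  history = "list"
))

#' Photodiode/LED sensing benchmark quadruple
#'
#' Holds the quantities of the sensor figure of merit: mean signal during
#' gesture and rest, LED luminous intensity and photodiode responsivity at
#' the LED's dominant wavelength.
#'
#' @slot sGestureMean mean signal during gesture (a.u.).
#' @slot sRestMean mean signal during rest (a.u.).
#' @slot luminosity LED luminous intensity (datasheet units).
#' @slot responsivity photodiode responsivity (datasheet units).
#' @export
setClass("SensorBench", representation(
  sGestureMean = "numeric",
  sRestMean = "numeric",
  luminosity = "numeric",
  responsivity = "numeric"
))

setValidity("SensorBench", function(object) {
  if (object@luminosity <= 0) return("luminosity must be > 0")
  if (object@responsivity <= 0) return("responsivity must be > 0")
  TRUE
})

#' Cross-validation report
#'
#' @slot perFold data.frame: one row per fold with its metrics.
#' @slot means named numeric, per-metric mean over folds.
#' @slot stds named numeric, per-metric standard deviation over folds.
#' @slot k number of folds.
#' @slot grouping `"repetition-blocked"` or `"window-random"`.
#' @slot metricNames metric column names.
#' @slot leakageChecked TRUE once the train/test repetition-disjointness
#'   assertion has run.
#' @export
setClass("CVReport", representation(
  perFold = "data.frame",
  means = "numeric",
  stds = "numeric",
  k = "integer",
  grouping = "character",
  metricNames = "character",
  leakageChecked = "logical"
))

setValidity("CVReport", function(object) {
  msgs <- character()
  if (object@k < 2L) msgs <- c(msgs, "k must be >= 2")
  if (nrow(object@perFold) != object@k) {
    msgs <- c(msgs, "perFold must have exactly k rows")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Aggregated per-subject results table
#'
#' Mirrors the per-subject x model (x modality) layout of the study's results
#' table: subject rows, an AVG row equal to the arithmetic mean of the subject
#' rows, per-column maxima, and optional better-modality flags.
#'
#' @slot table data.frame of subject rows plus the `AVG` row.
#' @slot maxima named numeric per-column maxima (over subject rows).
#' @slot better data.frame of per-subject better-modality flags (or empty).
#' @export
setClass("ResultsTable", representation(
  table = "data.frame",
  maxima = "numeric",
  better = "data.frame"
))
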