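# Generics, accessors and show methods. Slots are never reached into from
# user code; these accessors are the supported surface.

#' Sampling rate of a recording object
#' @param x a recording, trace or window-set object
#' @return sampling rate in Hz
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname sampleRate
#' @export
setMethod("sampleRate", "SessionRecording", function(x) x@sampleRate)
#' @rdname sampleRate
#' @export
setMethod("sampleRate", "MultiplexedLMG", function(x) x@sampleRate)
#' @rdname sampleRate
#' @export
setMethod("sampleRate", "ForceTrace", function(x) x@sampleRate)
#' @rdname sampleRate
#' @export
setMethod("sampleRate", "WindowSet", function(x) x@sampleRate)

#' Modality of a recording or window set
#' @param x a `SessionRecording` or `WindowSet`
#' @return `"LMG"` or `"EMG"`
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname modality
#' @export
setMethod("modality", "SessionRecording", function(x) x@modality)
#' @rdname modality
#' @export
setMethod("modality", "WindowSet", function(x) x@modality)

#' Per-sample trigger (label) track
#' @param x a recording object
#' @return character vector, one label per sample
#' @export
setGeneric("triggerTrack", function(x) standardGeneric("triggerTrack"))

#' @rdname triggerTrack
#' @export
setMethod("triggerTrack", "SessionRecording", function(x) x@trigger)
#' @rdname triggerTrack
#' @export
setMethod("triggerTrack", "MultiplexedLMG", function(x) x@trigger)

#' Per-sample repetition track
#' @param x a recording object
#' @return integer vector, one repetition id per sample
#' @export
setGeneric("repetitionTrack", function(x) standardGeneric("repetitionTrack"))

#' @rdname repetitionTrack
#' @export
setMethod("repetitionTrack", "SessionRecording", function(x) x@repetitionId)
#' @rdname repetitionTrack
#' @export
setMethod("repetitionTrack", "MultiplexedLMG", function(x) x@repetitionId)

#' Signal matrix of a recording
#' @param x a `SessionRecording` or `MultiplexedLMG`
#' @return T x C numeric matrix
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "SessionRecording", function(x) x@signal)
#' @rdname signalMatrix
#' @export
setMethod("signalMatrix", "MultiplexedLMG", function(x) x@samples)

#' LED state track of a multiplexed recording
#' @param x a `MultiplexedLMG`
#' @return character vector of `"green"`/`"ir"`
#' @export
setGeneric("ledState", function(x) standardGeneric("ledState"))

#' @rdname ledState
#' @export
setMethod("ledState", "MultiplexedLMG", function(x) x@ledState)

#' Force values of a force trace
#' @param x a `ForceTrace`
#' @return numeric vector in \[0, 1\]
#' @export
setGeneric("forceValues", function(x) standardGeneric("forceValues"))

#' @rdname forceValues
#' @export
setMethod("forceValues", "ForceTrace", function(x) x@force)

#' Number of windows in a window set or feature table
#' @param x a `WindowSet` or `FeatureTable`
#' @return integer count
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname nWindows
#' @export
setMethod("nWindows", "WindowSet", function(x) dim(x@windows)[1])
#' @rdname nWindows
#' @export
setMethod("nWindows", "FeatureTable", function(x) nrow(x@values))

#' Window tensor of a window set
#' @param x a `WindowSet`
#' @return numeric array `[N, L, C]`
#' @export
setGeneric("windowArray", function(x) standardGeneric("windowArray"))

#' @rdname windowArray
#' @export
setMethod("windowArray", "WindowSet", function(x) x@windows)

#' Per-window labels
#' @param x a `WindowSet` or `FeatureTable`
#' @return character vector
#' @export
setGeneric("windowLabels", function(x) standardGeneric("windowLabels"))

#' @rdname windowLabels
#' @export
setMethod("windowLabels", "WindowSet", function(x) x@labels)
#' @rdname windowLabels
#' @export
setMethod("windowLabels", "FeatureTable", function(x) x@labels)

#' Per-window repetition ids
#' @param x a `WindowSet` or `FeatureTable`
#' @return integer vector
#' @export
setGeneric("windowRepetitions", function(x) standardGeneric("windowRepetitions"))

#' @rdname windowRepetitions
#' @export
setMethod("windowRepetitions", "WindowSet", function(x) x@repetitionIds)
#' @rdname windowRepetitions
#' @export
setMethod("windowRepetitions", "FeatureTable", function(x) x@repetitionIds)

#' Per-window regression targets
#' @param x a `WindowSet`
#' @return numeric vector (length 0 when unset)
#' @export
setGeneric("windowTargets", function(x) standardGeneric("windowTargets"))

#' @rdname windowTargets
#' @export
setMethod("windowTargets", "WindowSet", function(x) x@targets)

#' Feature value matrix
#' @param x a `FeatureTable`
#' @return N x (8 C) numeric matrix with named columns
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname featureMatrix
#' @export
setMethod("featureMatrix", "FeatureTable", function(x) x@values)

#' Per-fold cross-validation metrics
#' @param x a `CVReport`
#' @return data.frame with one row per fold
#' @export
setGeneric("foldMetrics", function(x) standardGeneric("foldMetrics"))

#' @rdname foldMetrics
#' @export
setMethod("foldMetrics", "CVReport", function(x) x@perFold)

#' Fold-mean metrics of a cross-validation report
#' @param x a `CVReport`
#' @return named numeric vector of metric means
#' @export
setGeneric("cvMeans", function(x) standardGeneric("cvMeans"))

#' @rdname cvMeans
#' @export
setMethod("cvMeans", "CVReport", function(x) x@means)

#' Fold standard deviations of a cross-validation report
#' @param x a `CVReport`
#' @return named numeric vector of metric standard deviations
#' @export
setGeneric("cvStds", function(x) standardGeneric("cvStds"))

#' @rdname cvStds
#' @export
setMethod("cvStds", "CVReport", function(x) x@stds)

#' Results table data frame (subject rows plus AVG row)
#' @param x a `ResultsTable`
#' @return data.frame
#' @export
setGeneric("resultsFrame", function(x) standardGeneric("resultsFrame"))

#' @rdname resultsFrame
#' @export
setMethod("resultsFrame", "ResultsTable", function(x) x@table)

#' Per-column maxima of a results table
#' @param x a `ResultsTable`
#' @return named numeric vector
#' @export
setGeneric("resultsMaxima", function(x) standardGeneric("resultsMaxima"))

#' @rdname resultsMaxima
#' @export
setMethod("resultsMaxima", "ResultsTable", function(x) x@maxima)

setMethod("show", "Protocol", function(object) {
  cat(sprintf("Protocol: %d phases, %d repetitions x %d gestures, %.0f s total\n",
              nrow(object@phases), object@nRepetitions, length(object@gestures),
              sum(object@phases$duration_s)))
  cat(sprintf("  rates: LMG %g Hz, EMG %g Hz; LED toggle %g ms\n",
              object@sampleRateLMG, object@sampleRateEMG, object@ledToggleMs))
})

setMethod("show", "SubjectParams", function(object) {
  cat(sprintf("SubjectParams: %d channels x %d gestures (seed %d)\n",
              nrow(object@gainGreen), ncol(object@gainGreen) - 1L, object@seed))
  cat(sprintf("  tau %g ms, LMG noise sd %.4g, EMG noise sd %.4g, drift %.4g\n",
              object@tauDeformMs, object@noiseSdLMG, object@noiseSdEMG,
              object@driftAmp))
})

setMethod("show", "MultiplexedLMG", function(object) {
  cat(sprintf("MultiplexedLMG: %d samples x %d photodiodes at %g Hz (toggle %g ms)\n",
              nrow(object@samples), ncol(object@samples), object@sampleRate,
              object@toggleMs))
})

setMethod("show", "SessionRecording", function(object) {
  cat(sprintf("SessionRecording [%s]: %d samples x %d channels at %g Hz, subject '%s'\n",
              object@modality, nrow(object@signal), ncol(object@signal),
              object@sampleRate, object@subjectId))
  tab <- table(object@trigger)
  cat("  labels:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "WindowSet", function(object) {
  d <- dim(object@windows)
  cat(sprintf("WindowSet [%s]: %d windows of %d samples x %d channels (%g/%g ms)\n",
              object@modality, d[1], d[2], d[3], object@windowMs, object@strideMs))
})

setMethod("show", "FeatureTable", function(object) {
  cat(sprintf("FeatureTable: %d windows x %d features (%d channels x 8)\n",
              nrow(object@values), ncol(object@values), ncol(object@values) %/% 8L))
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s (%s)\n", object@family, object@task))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %d-fold, %s grouping\n", object@k, object@grouping))
  for (m in object@metricNames) {
    cat(sprintf("  %s = %.4f +/- %.4f\n", m, object@means[m], object@stds[m]))
  }
})

setMethod("show", "ResultsTable", function(object) {
  cat("ResultsTable:\n")
  print(object@table, digits = 4)
})
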