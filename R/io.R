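# Session and results IO: CSV with a JSON metadata sidecar, lossless for
# round-trips (full-precision numerics via data.table).

session_files <- function(prefix) {
  list(csv = paste0(prefix, ".csv"), json = paste0(prefix, ".json"))
}

# Render doubles with 17 significant digits so a write/read cycle restores
# them bit for bit (the default 15-digit CSV rendering can lose the last ulp).
fwrite_exact <- function(dt, path) {
  num <- names(dt)[vapply(dt, is.double, logical(1))]
  for (cn in num) data.table::set(dt, j = cn,
                                  value = sprintf("%.17g", dt[[cn]]))
  data.table::fwrite(dt, path)
}

#' Write a session to CSV + JSON sidecar
#'
#' Emits `<prefix>.csv` with columns `time_s, ch01..chNN, led_state`
#' (multiplexed LMG only), `trigger, repetition`, and `<prefix>.json` with
#' modality, sample rate, subject, channel names, seed and a content hash.
#'
#' @param x a [MultiplexedLMG-class] or [SessionRecording-class].
#' @param prefix output path without extension.
#' @param seed the generation seed to record (optional).
#' @return the prefix, invisibly.
#' @export
writeSession <- function(x, prefix, seed = NA_integer_) {
  f <- session_files(prefix)
  sig <- signalMatrix(x)
  T_ <- nrow(sig)
  ch <- sprintf("ch%02d", seq_len(ncol(sig)))
  dt <- data.table::as.data.table(sig)
  data.table::setnames(dt, ch)
  dt[, time_s := (seq_len(T_) - 1) / sampleRate(x)]
  if (is(x, "MultiplexedLMG")) dt[, led_state := x@ledState]
  dt[, trigger := triggerTrack(x)]
  dt[, repetition := repetitionTrack(x)]
  data.table::setcolorder(dt, c("time_s", ch))
  meta <- list(
    modality = if (is(x, "MultiplexedLMG")) "LMG-mux" else x@modality,
    sample_rate = sampleRate(x),
    subject_id = x@subjectId,
    channels = colnames(sig),
    n_samples = T_,
    seed = seed,
    params_hash = object_hash(sig)
  )
  if (is(x, "MultiplexedLMG")) meta$toggle_ms <- x@toggleMs
  fwrite_exact(dt, f$csv)
  jsonlite::write_json(meta, f$json, auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a session written by [writeSession()]
#'
#' Validates the writer contract: the sidecar must be present, the trigger
#' column must exist, a multiplexed LMG file must carry `led_state`, and the
#' row spacing must match the sidecar sample rate.
#'
#' @param prefix path prefix used at write time.
#' @return a [MultiplexedLMG-class] or [SessionRecording-class].
#' @export
readSession <- function(prefix) {
  f <- session_files(prefix)
  if (!file.exists(f$json)) stop_format(sprintf("sidecar %s is missing", f$json))
  if (!file.exists(f$csv)) stop_format(sprintf("session file %s is missing", f$csv))
  meta <- jsonlite::read_json(f$json, simplifyVector = TRUE)
  dt <- data.table::fread(f$csv)
  if (!"trigger" %in% names(dt)) stop_format("missing trigger column")
  if (!"repetition" %in% names(dt)) stop_format("missing repetition column")
  if (nrow(dt) > 1) {
    dt_spacing <- (dt$time_s[nrow(dt)] - dt$time_s[1]) / (nrow(dt) - 1)
    if (abs(dt_spacing - 1 / meta$sample_rate) > 1e-9 / meta$sample_rate) {
      stop_format(sprintf("row spacing %.9g s disagrees with sidecar rate %g Hz",
                          dt_spacing, meta$sample_rate))
    }
  }
  ch_cols <- grep("^ch[0-9]+$", names(dt), value = TRUE)
  sig <- as.matrix(dt[, ch_cols, with = FALSE])
  colnames(sig) <- unlist(meta$channels)
  if (identical(meta$modality, "LMG-mux")) {
    if (!"led_state" %in% names(dt)) {
      stop_format("multiplexed LMG session without led_state column")
    }
    return(new("MultiplexedLMG", samples = sig, ledState = dt$led_state,
               trigger = dt$trigger, repetitionId = as.integer(dt$repetition),
               sampleRate = meta$sample_rate, toggleMs = meta$toggle_ms,
               subjectId = meta$subject_id))
  }
  new("SessionRecording", signal = sig, trigger = dt$trigger,
      repetitionId = as.integer(dt$repetition),
      sampleRate = meta$sample_rate, modality = meta$modality,
      subjectId = meta$subject_id)
}

#' Write a window set as flat CSV + JSON manifest
#'
#' Each row is one window: `label, repetition, target?` followed by the
#' window samples flattened channel-major (`ch01_t001 ...`). The manifest
#' records the tensor shape, timing, modality and a provenance hash.
#'
#' @param ws a [WindowSet-class].
#' @param prefix output path without extension.
#' @return the prefix, invisibly.
#' @export
writeWindowSet <- function(ws, prefix) {
  f <- session_files(prefix)
  d <- dim(ws@windows)
  flat <- ws@windows
  dim(flat) <- c(d[1], d[2] * d[3])
  cn <- as.vector(outer(sprintf("t%03d", seq_len(d[2])),
                        sprintf("ch%02d", seq_len(d[3])),
                        function(t, c) paste0(c, "_", t)))
  dt <- data.table::as.data.table(flat)
  data.table::setnames(dt, cn)
  dt[, label := ws@labels]
  dt[, repetition := ws@repetitionIds]
  if (length(ws@targets)) dt[, target := ws@targets]
  data.table::setcolorder(dt, intersect(c("label", "repetition", "target"),
                                        names(dt)))
  manifest <- list(n_windows = d[1], window_len = d[2], n_channels = d[3],
                   window_ms = ws@windowMs, stride_ms = ws@strideMs,
                   modality = ws@modality, sample_rate = ws@sampleRate,
                   channels = ws@channelNames,
                   has_targets = length(ws@targets) > 0,
                   provenance_hash = object_hash(ws@windows))
  fwrite_exact(dt, f$csv)
  jsonlite::write_json(manifest, f$json, auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}

#' Read a window set written by [writeWindowSet()]
#' @param prefix path prefix used at write time.
#' @return a [WindowSet-class]
#' @export
readWindowSet <- function(prefix) {
  f <- session_files(prefix)
  if (!file.exists(f$json)) stop_format(sprintf("manifest %s is missing", f$json))
  m <- jsonlite::read_json(f$json, simplifyVector = TRUE)
  dt <- data.table::fread(f$csv)
  if (!"label" %in% names(dt)) stop_format("missing label column")
  meta_cols <- intersect(c("label", "repetition", "target"), names(dt))
  flat <- as.matrix(dt[, setdiff(names(dt), meta_cols), with = FALSE])
  arr <- array(flat, c(m$n_windows, m$window_len, m$n_channels))
  new("WindowSet", windows = arr, labels = as.character(dt$label),
      repetitionIds = as.integer(dt$repetition),
      targets = if (isTRUE(m$has_targets)) dt$target else numeric(0),
      windowMs = m$window_ms, strideMs = m$stride_ms, modality = m$modality,
      sampleRate = m$sample_rate,
      channelNames = unlist(m$channels) %||% character(0))
}

#' Write a results table as CSV + JSON summary
#'
#' @param rt a [ResultsTable-class].
#' @param prefix output path without extension.
#' @param anova optional list from [anovaOneWay()] to embed in the summary.
#' @return the prefix, invisibly.
#' @export
writeResultsTable <- function(rt, prefix, anova = NULL) {
  f <- session_files(prefix)
  data.table::fwrite(data.table::as.data.table(rt@table), f$csv)
  tab <- rt@table
  avg <- tab[tab$subject == "AVG", setdiff(names(tab), "subject"),
             drop = FALSE]
  summary <- list(avg = as.list(avg), maxima = as.list(rt@maxima))
  if (nrow(rt@better)) summary$lmg_better <- rt@better
  if (!is.null(anova)) summary$anova <- anova
  jsonlite::write_json(summary, f$json, auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
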