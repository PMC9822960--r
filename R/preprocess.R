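# Preprocessing: LED demultiplexing, EMG bandpass filtering, sliding-window
# extraction, transition handling, and class balancing.

#' Demultiplex a raw LMG recording into 10 logical channels
#'
#' Produces 5 green + 5 IR channels on the full sample grid. Each logical
#' channel holds the photodiode value while its LED is lit and carries the
#' last lit value forward (sample-and-hold) while the other LED is lit;
#' samples before a channel's first lit interval are back-filled from its
#' first value. A per-cycle-averaging variant is available behind
#' `method = "cycle-mean"`, which replaces each lit run by its mean before
#' holding.
#'
#' @param mux a [MultiplexedLMG-class].
#' @param method `"sample-hold"` (default) or `"cycle-mean"`.
#' @return a [SessionRecording-class] with channels `grn1..grn5, ir1..ir5`.
#' @export
demultiplex <- function(mux, method = c("sample-hold", "cycle-mean")) {
  method <- match.arg(method)
  led <- mux@ledState
  if (!all(led %in% c("green", "ir"))) {
    stop_format("ledState contains values outside {green, ir}")
  }
  x <- mux@samples
  T_ <- nrow(x)
  out <- matrix(NA_real_, T_, 10)
  colnames(out) <- c(paste0("grn", 1:5), paste0("ir", 1:5))
  for (colour in c("green", "ir")) {
    lit <- led == colour
    cols <- if (colour == "green") 1:5 else 6:10
    vals <- x[lit, , drop = FALSE]
    if (method == "cycle-mean") {
      r <- rle(lit)
      run_id <- rep(seq_along(r$lengths), r$lengths)[lit]
      vals <- apply(vals, 2, function(v) stats::ave(v, run_id))
      vals <- matrix(vals, ncol = 5)
    }
    held <- matrix(NA_real_, T_, 5)
    held[lit, ] <- vals
    # forward-fill held samples, then back-fill the leading gap
    idx <- cummax(ifelse(lit, seq_len(T_), 0L))
    first_lit <- which(lit)[1]
    idx[idx == 0L] <- first_lit
    out[, cols] <- held[idx, , drop = FALSE]
  }
  new("SessionRecording", signal = out, trigger = mux@trigger,
      repetitionId = mux@repetitionId, sampleRate = mux@sampleRate,
      modality = "LMG", subjectId = mux@subjectId)
}

#' Butterworth bandpass filter
#'
#' Causal IIR bandpass applied independently per channel; output length
#' equals input length. If `high_hz` reaches the Nyquist frequency it is
#' clamped to 0.99 x Nyquist with a logged warning. A zero-phase offline
#' variant (forward-backward) is available via `zero_phase = TRUE`.
#'
#' @param x numeric vector, matrix (channels in columns) or
#'   [SessionRecording-class].
#' @param low_hz,high_hz band corner frequencies (Hz).
#' @param order Butterworth prototype order.
#' @param sample_rate sampling rate (Hz); taken from the recording when `x`
#'   is a `SessionRecording`.
#' @param zero_phase apply forward-backward filtering instead of causal.
#' @return same shape/class as the input.
#' @export
bandpassFilter <- function(x, low_hz = 5, high_hz = 500, order = 4,
                           sample_rate = NULL, zero_phase = FALSE) {
  if (is(x, "SessionRecording")) {
    sig <- bandpassFilter(x@signal, low_hz, high_hz, order,
                          sample_rate %||% x@sampleRate, zero_phase)
    return(new("SessionRecording", signal = sig, trigger = x@trigger,
               repetitionId = x@repetitionId, sampleRate = x@sampleRate,
               modality = x@modality, subjectId = x@subjectId))
  }
  if (is.null(sample_rate)) stop_config("sample_rate is required")
  if (low_hz <= 0 || low_hz >= high_hz) {
    stop_config("need 0 < low_hz < high_hz")
  }
  if (sample_rate <= 2 * low_hz) {
    stop_config("sample_rate must exceed 2 * low_hz")
  }
  ny <- sample_rate / 2
  if (high_hz >= ny) {
    msg_log(sprintf("high cutoff %g Hz >= Nyquist %g Hz; clamping to %g Hz",
                    high_hz, ny, 0.99 * ny))
    high_hz <- 0.99 * ny
  }
  bf <- signal::butter(order, c(low_hz, high_hz) / ny, type = "pass")
  apply_one <- function(v) {
    if (zero_phase) as.numeric(signal::filtfilt(bf, v))
    else as.numeric(signal::filter(bf, v))
  }
  if (is.matrix(x)) {
    out <- apply(x, 2, apply_one)
    dimnames(out) <- dimnames(x)
    out
  } else {
    apply_one(x)
  }
}

# Number of complete windows of length L with stride S over T samples.
window_count <- function(T_, L, S) {
  if (T_ < L) 0L else as.integer((T_ - L) %/% S + 1L)
}

#' Cut a session into fixed-length sliding windows
#'
#' Windows of `window_ms` every `stride_ms`. Labels follow `label_policy`:
#' `"majority"` (default) labels a window with the most frequent trigger
#' value across its samples; `"strict"` drops windows whose trigger is not
#' single-valued. The repetition id of a window is the repetition of its
#' majority label samples. With `target` given (e.g. a force trace), each
#' window also records the mean target over its span.
#'
#' @param session a [SessionRecording-class].
#' @param window_ms window length (ms).
#' @param stride_ms stride (ms).
#' @param label_policy `"majority"` or `"strict"`.
#' @param target optional per-sample numeric target aligned with the session.
#' @return a [WindowSet-class]; zero windows (with a logged warning) when the
#'   window is longer than the session.
#' @export
slideWindows <- function(session, window_ms = 200, stride_ms = 20,
                         label_policy = c("majority", "strict"),
                         target = NULL) {
  label_policy <- match.arg(label_policy)
  if (stride_ms <= 0) stop_config("stride_ms must be > 0")
  fs <- session@sampleRate
  L <- round(window_ms * fs / 1000)
  S <- round(stride_ms * fs / 1000)
  if (S < 1) stop_config("stride shorter than one sample")
  sig <- session@signal
  T_ <- nrow(sig)
  C <- ncol(sig)
  if (!is.null(target) && length(target) != T_) {
    stop_contract("target length must match the session length")
  }
  N <- window_count(T_, L, S)
  if (N == 0L) {
    msg_log(sprintf("window (%d samples) longer than session (%d); no windows",
                    L, T_))
    return(new("WindowSet",
               windows = array(numeric(0), c(0L, L, C)),
               labels = character(0), repetitionIds = integer(0),
               targets = if (is.null(target)) numeric(0) else numeric(0),
               windowMs = window_ms, strideMs = stride_ms,
               modality = session@modality, sampleRate = fs,
               channelNames = colnames(sig) %||% character(0)))
  }
  starts <- (seq_len(N) - 1L) * S + 1L

  # Per-window label bookkeeping without materializing dropped windows.
  # The trigger is piecewise constant, so a window is single-valued iff its
  # first and last sample fall in the same run; only the few windows that
  # straddle a phase boundary need a per-sample look.
  trig <- session@trigger
  reps <- session@repetitionId
  run_id <- cumsum(c(1L, trig[-1L] != trig[-T_]))
  ends <- starts + L - 1L
  pure <- run_id[starts] == run_id[ends]
  lab <- trig[starts]
  rep_id <- reps[starts]
  keep <- rep(TRUE, N)
  mixed <- which(!pure)
  if (length(mixed)) {
    if (label_policy == "strict") {
      keep[mixed] <- FALSE
    } else {
      for (w in mixed) {
        span <- starts[w]:ends[w]
        tab <- table(trig[span])
        lab[w] <- names(tab)[which.max(tab)]
        rep_id[w] <- reps[span[trig[span] == lab[w]][1L]]
      }
    }
  }
  starts <- starts[keep]
  lab <- lab[keep]
  rep_id <- rep_id[keep]
  N <- length(starts)

  win <- array(0, c(N, L, C))
  for (l in seq_len(L)) {
    win[, l, ] <- sig[starts + l - 1L, , drop = FALSE]
  }
  tg <- numeric(0)
  if (!is.null(target) && N > 0) {
    csum <- c(0, cumsum(target))
    tg <- (csum[starts + L] - csum[starts]) / L
  }
  new("WindowSet", windows = win, labels = lab,
      repetitionIds = as.integer(rep_id), targets = tg,
      windowMs = window_ms, strideMs = stride_ms,
      modality = session@modality, sampleRate = fs,
      channelNames = colnames(sig) %||% character(0))
}

#' Balance window classes by seeded down-sampling
#'
#' Every class is down-sampled uniformly at random (seeded) to the minimum
#' class count; relative window order is preserved and no window is ever
#' invented. Already-balanced input passes through unchanged.
#'
#' @param ws a [WindowSet-class].
#' @param seed integer seed for the selection.
#' @param classes classes that must be present; defaults to the classes in
#'   `ws`. A named class with zero windows raises a balancing error.
#' @return a balanced [WindowSet-class].
#' @export
balanceClasses <- function(ws, seed = 1, classes = NULL) {
  lab <- ws@labels
  classes <- classes %||% sort(unique(lab))
  counts <- table(factor(lab, levels = classes))
  if (any(counts == 0)) {
    stop_config(sprintf("class '%s' has zero windows; cannot balance",
                        names(counts)[counts == 0][1]))
  }
  m <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(lab == cl)
      if (length(idx) > m) sort(sample(idx, m)) else idx
    }))
  })
  keep <- sort(keep)
  subsetWindows(ws, keep)
}

#' Subset a window set by window index
#' @param ws a [WindowSet-class]
#' @param idx integer index vector
#' @return a [WindowSet-class] with the selected windows, in `idx` order
#' @export
subsetWindows <- function(ws, idx) {
  new("WindowSet", windows = ws@windows[idx, , , drop = FALSE],
      labels = ws@labels[idx], repetitionIds = ws@repetitionIds[idx],
      targets = if (length(ws@targets)) ws@targets[idx] else numeric(0),
      windowMs = ws@windowMs, strideMs = ws@strideMs,
      modality = ws@modality, sampleRate = ws@sampleRate,
      channelNames = ws@channelNames)
}
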