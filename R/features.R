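# The eight classical EMG time-domain features, per window per channel,
# in the Phinyomark convention:
#   MAV  = mean(|x|)                    iEMG = sum(|x|)
#   RMS  = sqrt(mean(x^2))              VAR  = sample variance about the mean
#   WL   = sum(|x[i+1] - x[i]|)         LOG  = exp(mean(log(|x| + delta)))
#   ZC   = #{i : x[i] x[i+1] < 0 and |x[i] - x[i+1]| >= eps_zc}
#   WAMP = #{i : |x[i] - x[i+1]| >= eps_wamp}

FEATURE_NAMES <- c("RMS", "WL", "ZC", "MAV", "iEMG", "WAMP", "VAR", "LOG")

#' Default feature thresholds
#'
#' @param eps_zc zero-crossing amplitude threshold (signal units).
#' @param eps_wamp Willison amplitude threshold (signal units).
#' @param delta_log additive offset inside the log detector, avoiding
#'   `log(0)`.
#' @return named list of the three thresholds.
#' @export
featureThresholds <- function(eps_zc = 0, eps_wamp = 0.005,
                              delta_log = 1e-12) {
  list(eps_zc = eps_zc, eps_wamp = eps_wamp, delta_log = delta_log)
}

#' Eight time-domain features of one window
#'
#' @param x numeric vector of at least 2 samples.
#' @param thresholds list from [featureThresholds()].
#' @param var_about_mean compute VAR about the window mean (default); set
#'   `FALSE` for the zero-mean shortcut `sum(x^2) / (L - 1)`.
#' @return named numeric vector in the order RMS, WL, ZC, MAV, iEMG, WAMP,
#'   VAR, LOG.
#' @examples
#' windowFeatures(c(1, -1, 1, -1), featureThresholds(eps_wamp = 1))
#' @export
windowFeatures <- function(x, thresholds = featureThresholds(),
                           var_about_mean = TRUE) {
  L <- length(x)
  if (L < 2) stop_domain("window features need at least 2 samples")
  dx <- diff(x)
  adx <- abs(dx)
  v <- c(
    RMS = sqrt(mean(x^2)),
    WL = sum(adx),
    ZC = sum(x[-L] * x[-1] < 0 & adx >= thresholds$eps_zc),
    MAV = mean(abs(x)),
    iEMG = sum(abs(x)),
    WAMP = sum(adx >= thresholds$eps_wamp),
    VAR = if (var_about_mean) stats::var(x) else sum(x^2) / (L - 1),
    LOG = exp(mean(log(abs(x) + thresholds$delta_log)))
  )
  v[FEATURE_NAMES]
}

#' Feature table of a window set
#'
#' Row n is the concatenation over channels of [windowFeatures()] applied to
#' that channel's slice of window n; row order matches the window order.
#' Windows containing non-finite samples are flagged, excluded, and their
#' count logged. Column names are `chXX_FEAT`.
#'
#' @param ws a [WindowSet-class] with windows of length >= 2.
#' @param thresholds list from [featureThresholds()].
#' @param var_about_mean see [windowFeatures()].
#' @return a [FeatureTable-class] with `8 * C` named columns.
#' @export
featureTable <- function(ws, thresholds = featureThresholds(),
                         var_about_mean = TRUE) {
  d <- dim(ws@windows)
  N <- d[1]; L <- d[2]; C <- d[3]
  if (L < 2) stop_domain("windows must have at least 2 samples")
  cn <- as.vector(vapply(seq_len(C), function(c_)
    paste0(sprintf("ch%02d", c_), "_", FEATURE_NAMES), character(8)))
  if (N == 0) {
    return(new("FeatureTable",
               values = matrix(numeric(0), 0, 8 * C, dimnames = list(NULL, cn)),
               thresholds = thresholds, labels = character(0),
               repetitionIds = integer(0)))
  }
  vals <- matrix(NA_real_, N, 8 * C, dimnames = list(NULL, cn))
  for (c_ in seq_len(C)) {
    W <- t(ws@windows[, , c_])            # L x N, windows in columns
    aW <- abs(W)
    dW <- W[-1, , drop = FALSE] - W[-L, , drop = FALSE]
    adW <- abs(dW)
    sgn <- W[-L, , drop = FALSE] * W[-1, , drop = FALSE] < 0
    mav <- colMeans(aW)
    block <- cbind(
      RMS = sqrt(colMeans(W^2)),
      WL = colSums(adW),
      ZC = colSums(sgn & adW >= thresholds$eps_zc),
      MAV = mav,
      iEMG = colSums(aW),
      WAMP = colSums(adW >= thresholds$eps_wamp),
      VAR = if (var_about_mean) {
        colSums((W - rep(colMeans(W), each = L))^2) / (L - 1)
      } else colSums(W^2) / (L - 1),
      LOG = exp(colMeans(log(aW + thresholds$delta_log)))
    )
    vals[, (c_ - 1L) * 8L + seq_len(8L)] <- block
  }
  ok <- rowSums(!is.finite(vals)) == 0
  if (any(!ok)) {
    msg_log(sprintf("excluding %d window(s) with non-finite features",
                    sum(!ok)))
  }
  new("FeatureTable", values = vals[ok, , drop = FALSE],
      thresholds = thresholds, labels = ws@labels[ok],
      repetitionIds = ws@repetitionIds[ok])
}
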