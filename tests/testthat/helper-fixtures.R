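# Shared fixtures and a per-session cache for the expensive benchmark runs.

.lmg_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.lmg_cache[[key]])) .lmg_cache[[key]] <- force(expr)
  .lmg_cache[[key]]
}

# Small gesture session shared by several files (1 s phases, 2 gestures).
tiny_session <- function(seed = 7, noise_frac = 0.05, drift_amp = 0) {
  protocol <- makeGestureProtocol(1, 1, 2, c("power", "pinch"))
  params <- defaultSubjectParams(gestures = c("power", "pinch"), seed = 42,
                                 noise_frac = noise_frac,
                                 drift_amp = drift_amp)
  list(protocol = protocol, params = params,
       session = simulateGestureSession(protocol, params, seed = seed))
}

# Hand-built WindowSet: `per` windows for every (class, repetition) pair,
# with class-dependent mean levels so the data are separable.
toy_windowset <- function(classes = c("rest", "pinch", "tripod", "power",
                                      "extension"),
                          reps = 1:6, per = 4, L = 8, C = 3, sd = 0.01,
                          seed = 99) {
  n <- length(classes) * length(reps) * per
  labels <- rep(classes, each = length(reps) * per)
  rep_id <- rep(rep(reps, each = per), times = length(classes))
  mu <- stats::setNames(seq_along(classes) - 1, classes)
  win <- with_seed_test(seed, {
    arr <- array(stats::rnorm(n * L * C, sd = sd), c(n, L, C))
    arr + array(rep(mu[labels], L * C), c(n, L, C))
  })
  new("WindowSet", windows = win, labels = labels,
      repetitionIds = as.integer(rep_id), targets = numeric(0),
      windowMs = L, strideMs = 1, modality = "LMG", sampleRate = 1000,
      channelNames = paste0("ch", seq_len(C)))
}

# Regression WindowSet whose target pattern is identical across repetitions
# (so a train-mean predictor hits the test mean exactly).
toy_force_windowset <- function(reps = 10, per = 12, L = 8, C = 3,
                                seed = 123) {
  n <- reps * per
  pattern <- seq(0, 0.5, length.out = per)
  targets <- rep(pattern, times = reps)
  rep_id <- rep(seq_len(reps), each = per)
  win <- with_seed_test(seed, {
    arr <- array(stats::rnorm(n * L * C, sd = 0.01), c(n, L, C))
    arr + array(rep(targets, L * C), c(n, L, C))
  })
  new("WindowSet", windows = win, labels = rep("ramp", n),
      repetitionIds = as.integer(rep_id), targets = targets,
      windowMs = L, strideMs = 1, modality = "LMG", sampleRate = 1000,
      channelNames = paste0("ch", seq_len(C)))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Direct-summation oracle for the eight time-domain features (independent of
# the vectorized implementation).
feature_oracle <- function(x, eps_zc = 0, eps_wamp = 0.005,
                           delta_log = 1e-12) {
  L <- length(x)
  mav <- 0; iemg <- 0; ss <- 0; wl <- 0; zc <- 0; wamp <- 0; lg <- 0
  for (i in seq_len(L)) {
    mav <- mav + abs(x[i]) / L
    iemg <- iemg + abs(x[i])
    ss <- ss + x[i]^2
    lg <- lg + log(abs(x[i]) + delta_log) / L
  }
  m <- sum(x) / L
  vr <- 0
  for (i in seq_len(L)) vr <- vr + (x[i] - m)^2 / (L - 1)
  for (i in seq_len(L - 1)) {
    d <- x[i + 1] - x[i]
    wl <- wl + abs(d)
    if (x[i] * x[i + 1] < 0 && abs(d) >= eps_zc) zc <- zc + 1
    if (abs(d) >= eps_wamp) wamp <- wamp + 1
  }
  c(RMS = sqrt(ss / L), WL = wl, ZC = zc, MAV = mav, iEMG = iemg,
    WAMP = wamp, VAR = vr, LOG = exp(lg))
}

# Brute-force window-count oracle: enumerate valid start indices.
window_count_oracle <- function(T_, L, S) {
  n <- 0L
  s <- 1L
  while (s + L - 1L <= T_) {
    n <- n + 1L
    s <- s + S
  }
  n
}

# Sum-of-squares one-way ANOVA oracle for two groups.
anova_oracle <- function(a, b) {
  g <- c(mean(a), mean(b))
  gm <- mean(c(a, b))
  ssb <- length(a) * (g[1] - gm)^2 + length(b) * (g[2] - gm)^2
  ssw <- sum((a - g[1])^2) + sum((b - g[2])^2)
  df1 <- 1
  df2 <- length(a) + length(b) - 2
  F_ <- (ssb / df1) / (ssw / df2)
  list(F = F_, p = stats::pf(F_, df1, df2, lower.tail = FALSE))
}
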