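test_that("gesture protocol schedule has the expected shape and totals", {
  p <- makeGestureProtocol(15, 15, 6, c("pinch", "tripod", "power", "extension"))
  ph <- protocolPhases(p)
  expect_equal(nrow(ph), 48)
  expect_equal(sum(ph$duration_s), 720)

  p1 <- makeGestureProtocol(15, 15, 1, "pinch")
  expect_equal(nrow(protocolPhases(p1)), 2)
  expect_equal(sum(protocolPhases(p1)$duration_s), 30)

  # hand-enumerated schedule for (1, 1, 2, {power, pinch})
  p2 <- makeGestureProtocol(1, 1, 2, c("power", "pinch"))
  ph2 <- protocolPhases(p2)
  expect_equal(nrow(ph2), 8)
  expect_equal(sum(ph2$duration_s), 8)
  expect_equal(ph2$label,
               c("rest", "power", "rest", "power", "rest", "pinch",
                 "rest", "pinch"))
  expect_equal(ph2$repetition, c(1, 1, 2, 2, 1, 1, 2, 2))
  expect_true(all(ph2$active == rep(c(FALSE, TRUE), 4)))
})

test_that("invalid protocols are rejected", {
  expect_error(makeGestureProtocol(15, 15, 6, character(0)),
               class = "lmg_config_error")
  expect_error(makeGestureProtocol(-1, 15, 6, "pinch"),
               class = "lmg_config_error")
  expect_error(makeGestureProtocol(15, 15, 0, "pinch"),
               class = "lmg_config_error")
})

test_that("activation envelope follows the first-order closed form", {
  # constant rest -> identically zero
  e0 <- activationEnvelope(rep("rest", 500), 150, 400, gestures = "power")
  expect_true(all(e0 == 0))

  # step response: e(t0 + tau) = 1 - exp(-1)
  tr <- c(rep("rest", 100), rep("power", 300))
  e <- activationEnvelope(tr, 150, 400)
  n_tau <- 150e-3 * 400                       # samples per time constant
  expect_equal(unname(e[100 + n_tau, "power"]), 1 - exp(-1),
               tolerance = 1e-12)

  # envelope is bounded and monotone within each phase
  expect_true(all(e >= 0 & e <= 1))
  expect_true(all(diff(e[101:400, "power"]) >= 0))

  # symmetry of the recursion: rise from 0 and decay from 1 are mirror
  # images, e_up(n) + e_down(n) = 1
  up <- activationEnvelope(rep("power", 200), 150, 400)[, 1]
  down_tr <- c(rep("power", 4000), rep("rest", 200))  # saturate, then release
  down <- activationEnvelope(down_tr, 150, 400)[4000 + (1:200), 1]
  expect_lt(max(abs(up + down - 1)), 1e-9)
})

test_that("simulator is bit-reproducible and respects the signal model", {
  fx <- tiny_session(seed = 11)
  fx2 <- tiny_session(seed = 11)
  expect_identical(signalMatrix(fx$session$lmg), signalMatrix(fx2$session$lmg))
  expect_identical(signalMatrix(fx$session$emg), signalMatrix(fx2$session$emg))

  # different seed changes the noise
  fx3 <- tiny_session(seed = 12)
  expect_false(identical(signalMatrix(fx$session$lmg),
                         signalMatrix(fx3$session$lmg)))
})

test_that("noise-free samples hit baseline and saturated gains exactly", {
  params <- defaultSubjectParams(gestures = "power", seed = 42,
                                 noise_frac = 0, drift_amp = 0)
  protocol <- makeGestureProtocol(1, 5, 1, "power")
  ses <- simulateGestureSession(protocol, params, seed = 1)
  x <- signalMatrix(ses$lmg)
  led <- ledState(ses$lmg)
  trig <- triggerTrack(ses$lmg)
  baseline <- x[1, ]                           # first rest sample

  # first rest phase: envelope is identically zero -> baseline exactly
  rest_idx <- which(trig == "rest")
  expect_equal(max(abs(sweep(x[rest_idx, ], 2, baseline))), 0)

  # deep into the gesture (t >> tau), green-lit samples saturate to
  # baseline + gain_green[, "power"]
  late <- which(trig == "power" & led == "green")
  late <- late[late > 0.9 * max(late)]
  gain <- params@gainGreen[, "power"]
  expected <- baseline + gain
  err <- sweep(x[late, , drop = FALSE], 2, expected)
  expect_lt(max(abs(err)), 1e-6)

  # IR-lit samples saturate to the IR gain instead
  late_ir <- which(trig == "power" & led == "ir")
  late_ir <- late_ir[late_ir > 0.9 * max(late_ir)]
  err_ir <- sweep(x[late_ir, , drop = FALSE], 2, baseline + params@gainIR[, "power"])
  expect_lt(max(abs(err_ir)), 1e-6)
})

test_that("label counts match the protocol (label conservation)", {
  protocol <- makeGestureProtocol(2, 3, 4, c("pinch", "power"))
  params <- defaultSubjectParams(gestures = c("pinch", "power"), seed = 42)
  ses <- simulateGestureSession(protocol, params, seed = 3)
  for (obj in list(ses$lmg, ses$emg)) {
    fs <- sampleRate(obj)
    counts <- table(triggerTrack(obj))
    expect_equal(unname(counts[["pinch"]]), 3 * fs * 4)
    expect_equal(unname(counts[["power"]]), 3 * fs * 4)
    expect_equal(unname(counts[["rest"]]), 2 * fs * 8)
  }
})

test_that("LED state alternates in toggle-length runs", {
  fx <- tiny_session()
  led <- ledState(fx$session$lmg)
  r <- rle(led)
  nrun <- round(125 * 400 / 1000)
  expect_true(all(r$lengths[-length(r$lengths)] == nrun))
  expect_true(all(r$values[seq(1, length(r$values), 2)] == "green"))
})

test_that("force session ramps are exact triangles with 0.5 apexes", {
  protocol <- makeForceProtocol(1, 1, 10)
  params <- defaultSubjectParams(seed = 42, noise_frac = 0, drift_amp = 0)
  ses <- simulateForceSession(protocol, params, seed = 5)
  f <- forceValues(ses$force)
  fs <- sampleRate(ses$force)

  # ten apexes of exactly 0.5
  expect_equal(sum(f == 0.5), 10)
  # quarter point of each ramp is exactly 0.25
  n_phase <- fs                                # 1 s phases
  ramp_starts <- seq(n_phase, by = 2 * n_phase, length.out = 10)
  quarter <- f[ramp_starts + n_phase / 4 + 1]  # t_off = 0.25 s into the ramp
  expect_equal(quarter, rep(0.25, 10))
  expect_true(all(f >= 0 & f <= 0.5))

  # zero-gain params: LMG equals baseline despite nonzero force (a single
  # gesture column may be zero without violating column distinctness)
  zp <- defaultSubjectParams(gestures = "power", seed = 42, noise_frac = 0,
                             drift_amp = 0)
  zg <- zp@gainGreen; zg[] <- 0
  zi <- zp@gainIR; zi[] <- 0
  slot(zp, "gainGreen") <- zg
  slot(zp, "gainIR") <- zi
  ses0 <- simulateForceSession(makeForceProtocol(1, 1, 2), zp, seed = 5)
  x <- signalMatrix(ses0$lmg)
  expect_equal(max(abs(sweep(x, 2, zp@baseline))), 0)
})

test_that("synthetic EMG power stays inside the synthesis band", {
  protocol <- makeGestureProtocol(1, 2, 1, "power")
  params <- defaultSubjectParams(gestures = "power", seed = 42,
                                 noise_frac = 0, drift_amp = 0)
  ses <- simulateGestureSession(protocol, params, seed = 9)
  x <- signalMatrix(ses$emg)
  trig <- triggerTrack(ses$emg)
  v <- x[trig == "power", 1]
  pg <- stats::spec.pgram(v, taper = 0, plot = FALSE, detrend = FALSE)
  freq_hz <- pg$freq * sampleRate(ses$emg)
  band <- params@emgBandHz
  frac <- sum(pg$spec[freq_hz >= band[1] & freq_hz <= band[2]]) / sum(pg$spec)
  expect_gte(frac, 0.95)
})

test_that("subject parameter draws are reproducible with separated columns", {
  p1 <- defaultSubjectParams(seed = 42)
  p2 <- defaultSubjectParams(seed = 42)
  expect_identical(p1@gainGreen, p2@gainGreen)
  expect_true(all(p1@gainGreen[, "rest"] == 0))
  act <- p1@gainGreen[, -1]
  d <- as.matrix(dist(t(act)))
  expect_gte(min(d[upper.tri(d)]), 0.5)

  # identical gesture columns are rejected by the validity method
  bad <- p1@gainGreen
  bad[, "tripod"] <- bad[, "pinch"]
  expect_error(new("SubjectParams", gainGreen = bad, gainIR = p1@gainIR,
                   baseline = p1@baseline, tauDeformMs = 150, driftAmp = 0,
                   driftPeriodS = 60, noiseSdLMG = 0.05, emgGain = p1@emgGain,
                   noiseSdEMG = 0.05, emgBandHz = c(20, 450), seed = 1L),
               "identical columns")
})
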