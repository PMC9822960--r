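make_mux <- function(samples, states, rate = 1000, toggle_ms = 2) {
  T_ <- nrow(samples)
  new("MultiplexedLMG", samples = samples, ledState = states,
      trigger = rep("rest", T_), repetitionId = rep(1L, T_),
      sampleRate = rate, toggleMs = toggle_ms, subjectId = "T")
}

test_that("demultiplexing sample-and-hold matches the hand trace", {
  # toggle every 2 samples; photodiode [1,1,9,9,1,1]; states g,g,i,i,g,g
  samples <- matrix(rep(c(1, 1, 9, 9, 1, 1), 5), ncol = 5)
  mux <- make_mux(samples, c("green", "green", "ir", "ir", "green", "green"))
  rec <- demultiplex(mux)
  sig <- signalMatrix(rec)
  expect_equal(unname(sig[, "grn1"]), rep(1, 6))
  expect_equal(unname(sig[, "ir1"]), rep(9, 6))   # leading gap back-filled
  expect_equal(ncol(sig), 10)
  expect_equal(modality(rec), "LMG")
})

test_that("constant photodiode input demultiplexes to constant channels", {
  samples <- matrix(4.2, 8, 5)
  mux <- make_mux(samples, rep(c("green", "green", "ir", "ir"), 2))
  sig <- signalMatrix(demultiplex(mux))
  expect_true(all(sig == 4.2))
})

test_that("demultiplexing is lossless on fresh (lit) samples", {
  fx <- tiny_session()
  rec <- demultiplex(fx$session$lmg)
  raw <- signalMatrix(fx$session$lmg)
  led <- ledState(fx$session$lmg)
  sig <- signalMatrix(rec)
  expect_identical(unname(sig[led == "green", 1:5]),
                   unname(raw[led == "green", ]))
  expect_identical(unname(sig[led == "ir", 6:10]),
                   unname(raw[led == "ir", ]))
  # roughly half the grid is fresh per colour (plus/minus one toggle run)
  nrun <- round(125 * 400 / 1000)
  expect_lte(abs(sum(led == "green") - nrow(raw) / 2), nrun)
})

test_that("invalid LED states are rejected", {
  samples <- matrix(1, 4, 5)
  mux <- make_mux(samples, rep(c("green", "green", "ir", "ir"), 1))
  slot(mux, "ledState", check = FALSE) <- c("green", "green", "red", "ir")
  expect_error(demultiplex(mux), class = "lmg_format_error")
})

test_that("bandpass filter preserves the passband and rejects the stopband", {
  fs <- 1200
  t <- seq(0, 4, by = 1 / fs)
  steady <- seq_along(t) > length(t) / 2

  x100 <- sin(2 * pi * 100 * t)
  y100 <- bandpassFilter(x100, 5, 500, order = 4, sample_rate = fs)
  amp <- sqrt(2) * sd(y100[steady])
  expect_lt(abs(amp - 1), 0.05)

  x1 <- sin(2 * pi * 1 * t)
  y1 <- bandpassFilter(x1, 5, 500, order = 4, sample_rate = fs)
  atten_db <- 20 * log10(sqrt(2) * sd(y1[steady]))
  expect_lt(atten_db, -20)

  expect_equal(bandpassFilter(numeric(100) , 5, 500, order = 4,
                              sample_rate = fs), numeric(100))
  expect_message(bandpassFilter(x100, 5, 700, order = 4, sample_rate = fs),
                 "clamping")
  expect_error(bandpassFilter(x100, 500, 5, sample_rate = fs),
               class = "lmg_config_error")
})

test_that("window counts follow floor((T - L)/S) + 1", {
  # 15 s single-label session at 400 Hz: T = 6000, L = 80, S = 8 -> 741
  T_ <- 6000
  ses <- new("SessionRecording", signal = matrix(rnorm(T_ * 2), T_, 2),
             trigger = rep("power", T_), repetitionId = rep(1L, T_),
             sampleRate = 400, modality = "LMG", subjectId = "T")
  ws <- slideWindows(ses, 200, 20)
  expect_equal(nWindows(ws), 741)

  # T = L -> exactly one window
  ses1 <- new("SessionRecording", signal = matrix(1, 80, 1),
              trigger = rep("rest", 80), repetitionId = rep(1L, 80),
              sampleRate = 400, modality = "LMG", subjectId = "T")
  expect_equal(nWindows(slideWindows(ses1, 200, 20)), 1)

  # window longer than session -> zero windows with a logged warning
  ses2 <- new("SessionRecording", signal = matrix(1, 40, 1),
              trigger = rep("rest", 40), repetitionId = rep(1L, 40),
              sampleRate = 400, modality = "LMG", subjectId = "T")
  expect_message(ws0 <- slideWindows(ses2, 200, 20), "no windows")
  expect_equal(nWindows(ws0), 0)
})

test_that("window count formula agrees with brute-force enumeration", {
  set.seed(21)
  for (i in 1:60) {
    T_ <- sample(5:400, 1)
    L <- sample(2:T_, 1)
    S <- sample(1:40, 1)
    ses <- new("SessionRecording", signal = matrix(0, T_, 1),
               trigger = rep("x", T_), repetitionId = rep(1L, T_),
               sampleRate = 1000, modality = "LMG", subjectId = "T")
    ws <- suppressMessages(
      slideWindows(ses, window_ms = L, stride_ms = S))  # 1 ms = 1 sample
    expect_equal(nWindows(ws), window_count_oracle(T_, L, S))
  }
})

test_that("windows are exact slices of the source signal", {
  fx <- tiny_session()
  rec <- demultiplex(fx$session$lmg)
  ws <- slideWindows(rec, 200, 20)
  sig <- signalMatrix(rec)
  L <- dim(windowArray(ws))[2]
  S <- round(20 * 400 / 1000)
  for (w in c(1, 5, nWindows(ws))) {
    start <- (w - 1) * S + 1
    expect_identical(windowArray(ws)[w, , ],
                     unname(sig[start:(start + L - 1), ]))
  }
})

test_that("strict labelling drops transition windows, majority keeps them", {
  T_ <- 300
  trig <- c(rep("rest", 150), rep("pinch", 150))
  ses <- new("SessionRecording", signal = matrix(0, T_, 1),
             trigger = trig, repetitionId = rep(1L, T_),
             sampleRate = 1000, modality = "LMG", subjectId = "T")
  ws_strict <- slideWindows(ses, 50, 10, "strict")
  ws_major <- slideWindows(ses, 50, 10, "majority")
  # strict: exactly the windows with a single-valued trigger span survive
  L <- 50; S <- 10
  starts <- seq(1, T_ - L + 1, by = S)
  pure <- vapply(starts, function(s)
    length(unique(trig[s:(s + L - 1)])) == 1L, logical(1))
  expect_equal(nWindows(ws_strict), sum(pure))
  expect_equal(windowLabels(ws_strict), trig[starts[pure]])
  expect_equal(nWindows(ws_major) - nWindows(ws_strict), (L - S) / S)
  expect_setequal(unique(windowLabels(ws_strict)), c("rest", "pinch"))
  # majority labels the mid-transition windows by the dominant phase
  expect_gte(sum(windowLabels(ws_major) == "pinch"),
             sum(windowLabels(ws_strict) == "pinch"))
})

test_that("class balancing down-samples to the minimum count, seeded", {
  ws <- toy_windowset(classes = c("rest", "pinch", "tripod", "power",
                                  "extension"), reps = 1:2, per = 40)
  # inflate rest from 80 to 100 windows by duplication
  unbal <- subsetWindows(ws, c(seq_len(nWindows(ws)),
                               which(windowLabels(ws) == "rest")[1:20]))
  counts <- table(windowLabels(unbal))
  expect_equal(unname(counts[["rest"]]), 100)

  bal <- balanceClasses(unbal, seed = 4)
  expect_true(all(table(windowLabels(bal)) == 80))
  expect_equal(nWindows(bal), 400)

  # determinism and no-invention (output windows are a subset of the input)
  bal2 <- balanceClasses(unbal, seed = 4)
  expect_identical(windowArray(bal), windowArray(bal2))
  src_levels <- unique(as.vector(windowArray(unbal)))
  expect_true(all(as.vector(windowArray(bal)) %in% src_levels))

  # already balanced input passes through unchanged
  bal3 <- balanceClasses(ws, seed = 4)
  expect_identical(windowArray(bal3), windowArray(ws))

  # a named class with zero windows raises an error naming it
  expect_error(balanceClasses(ws, classes = c("rest", "pinch", "lateral")),
               "lateral")
})
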