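test_that("performance index normalizes the rest-to-gesture deflection", {
  expect_equal(performanceIndex(sensorBench(2, 1, 4, 0.5)), 0.5)
  expect_equal(performanceIndex(sensorBench(3, 3, 2, 1)), 0)
  # absolute value: swapping gesture and rest means changes nothing
  expect_equal(performanceIndex(sensorBench(1, 2, 4, 0.5)),
               performanceIndex(sensorBench(2, 1, 4, 0.5)))
  # common offset invariance and 1/(phi * R) scaling
  expect_equal(performanceIndex(sensorBench(12, 11, 4, 0.5)),
               performanceIndex(sensorBench(2, 1, 4, 0.5)))
  expect_equal(performanceIndex(sensorBench(2, 1, 8, 0.5)),
               performanceIndex(sensorBench(2, 1, 4, 0.5)) / 2)
  expect_error(sensorBench(2, 1, 0, 0.5), class = "lmg_domain_error")
})

test_that("NMSE hits its analytic anchors", {
  x <- seq(0, 1, length.out = 100)
  expect_equal(nmsePercent(x, x), 100)
  expect_equal(nmsePercent(x, rep(mean(x), 100)), 0, tolerance = 1e-10)
  expect_equal(nmsePercent(c(1, 2, 3), c(1, 2, 4)), 50)
  expect_error(nmsePercent(rep(2, 5), rnorm(5)), class = "lmg_domain_error")
  expect_error(nmsePercent(1:3, 1:4), class = "lmg_contract_error")

  # NMSE <= 100 always, with equality only at exact equality
  set.seed(41)
  for (i in 1:50) {
    r <- rnorm(20)
    p <- r + rnorm(20, sd = runif(1, 0, 2))
    v <- nmsePercent(r, p)
    expect_lte(v, 100)
    if (v == 100) expect_identical(r, p)
  }
})

test_that("Pearson correlation matches hand computation", {
  x <- c(1, 2, 3)
  expect_equal(pearsonR(x, x), 1)
  expect_equal(pearsonR(x, -x), -1)
  expect_equal(pearsonR(x, c(1, 2, 2)), sqrt(3) / 2)
  expect_error(pearsonR(x, rep(1, 3)), class = "lmg_domain_error")
  expect_error(pearsonR(1:3, 1:4), class = "lmg_contract_error")
})

test_that("two-group one-way ANOVA matches the sum-of-squares oracle", {
  r <- anovaOneWay(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$F, 1.5)

  same <- anovaOneWay(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$F, 0)
  expect_equal(same$p, 1)

  # equal means, nonzero variance
  em <- anovaOneWay(c(-1, 1), c(-2, 2))
  expect_equal(em$F, 0)

  # degenerate: no variance anywhere, equal means -> p = 1 convention
  deg <- anovaOneWay(c(2, 2), c(2, 2))
  expect_equal(deg$p, 1)
  expect_equal(deg$F, 0)

  set.seed(42)
  for (i in 1:30) {
    a <- rnorm(sample(3:10, 1))
    b <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    got <- anovaOneWay(a, b)
    want <- anova_oracle(a, b)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  expect_error(anovaOneWay(1, c(1, 2)), class = "lmg_contract_error")
})

test_that("classification CV partitions repetitions without leakage", {
  ws <- toy_windowset()                       # 5 classes x 6 reps x 4
  # fold bookkeeping probe: record what each trainer call sees
  seen <- list()
  probe_trainer <- function(xtrain, ytrain) {
    tr_reps <- unique(windowRepetitions(xtrain))
    function(xtest) {
      seen[[length(seen) + 1]] <<- list(train = tr_reps,
                                        test = unique(windowRepetitions(xtest)),
                                        test_idx = windowRepetitions(xtest))
      rep("rest", nWindows(xtest))             # majority-class stub
    }
  }
  rep_ <- crossvalClassification(ws, k = 5, seed = 2, trainer = probe_trainer)
  expect_s4_class(rep_, "CVReport")
  # balanced data: the constant-class stub scores exactly chance (0.20)
  expect_equal(unname(cvMeans(rep_)["accuracy"]), 0.2)
  expect_equal(foldMetrics(rep_)$accuracy, rep(0.2, 5))

  # fold sizes differ by at most one repetition; disjoint and exhaustive
  test_reps <- lapply(seen, `[[`, "test")
  sizes <- lengths(test_reps)
  expect_lte(diff(range(sizes)), 1)
  expect_setequal(unlist(test_reps), 1:6)
  expect_equal(sum(lengths(test_reps)), 6)     # each rep tested exactly once
  for (s in seen) expect_length(intersect(s$train, s$test), 0)

  # a perfect oracle scores 1.0 with zero variance
  oracle <- function(xtrain, ytrain) function(xtest) windowLabels(xtest)
  ro <- crossvalClassification(ws, k = 5, seed = 2, trainer = oracle)
  expect_equal(unname(cvMeans(ro)["accuracy"]), 1)
  expect_equal(unname(cvStds(ro)["accuracy"]), 0)

  # fewer repetitions than folds is a configuration error
  expect_error(crossvalClassification(toy_windowset(reps = 1:3), k = 5,
                                      trainer = oracle),
               class = "lmg_config_error")
})

test_that("regression CV holds out one repetition per fold", {
  ws <- toy_force_windowset(reps = 10)
  tested <- integer(0)
  identity_oracle <- function(xtrain, ytrain) {
    function(xtest) {
      tested <<- c(tested, which(windowRepetitions(ws) %in%
                                   unique(windowRepetitions(xtest))))
      windowTargets(xtest)
    }
  }
  r <- crossvalRegression(ws, folds = 10, trainer = identity_oracle)
  expect_equal(unname(cvMeans(r)["nmse"]), 100)
  expect_equal(unname(cvMeans(r)["pearson"]), 1)
  # every window appears in exactly one test fold
  expect_equal(sort(tested), seq_len(nWindows(ws)))

  # train-mean predictor: targets repeat across repetitions, so the
  # prediction equals the test mean and NMSE is exactly 0
  mean_stub <- function(xtrain, ytrain) {
    m <- mean(ytrain)
    function(xtest) rep(m, nWindows(xtest))
  }
  r0 <- crossvalRegression(ws, folds = 10, trainer = mean_stub)
  expect_equal(unname(cvMeans(r0)["nmse"]), 0, tolerance = 1e-9)
  expect_true(all(is.na(foldMetrics(r0)$pearson)))  # correlation undefined

  expect_error(crossvalRegression(ws, folds = 8, trainer = mean_stub),
               class = "lmg_config_error")
})

test_that("results aggregation produces AVG rows, maxima and flags", {
  df <- data.frame(subject = c("S1", "S2"),
                   LMG_RF = c(96, 98), EMG_RF = c(95, 99))
  rt <- aggregateResults(df, compare = list(RF = c("LMG_RF", "EMG_RF")))
  tab <- resultsFrame(rt)
  expect_equal(tab$LMG_RF[tab$subject == "AVG"], 97)
  expect_equal(unname(resultsMaxima(rt)["EMG_RF"]), 99)
  expect_equal(rt@better$RF_lmg_better, c(TRUE, FALSE))

  # single subject: AVG equals that subject's row
  rt1 <- aggregateResults(df[1, ])
  tab1 <- resultsFrame(rt1)
  expect_equal(tab1$LMG_RF[tab1$subject == "AVG"], tab1$LMG_RF[1])

  # missing cell names subject and column
  df$LMG_RF[2] <- NA
  expect_error(aggregateResults(df), "S2.*LMG_RF")
})
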