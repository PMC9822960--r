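test_that("window features match hand-computed values", {
  th <- featureThresholds(eps_zc = 0, eps_wamp = 1)
  f <- windowFeatures(c(1, -1, 1, -1), th)
  expect_equal(unname(f[c("MAV", "iEMG", "RMS", "WL", "ZC", "WAMP")]),
               c(1, 4, 1, 6, 3, 3))
  expect_equal(unname(f["VAR"]), 4 / 3)

  # zero signal: everything zero, LOG collapses to delta_log
  f0 <- windowFeatures(c(0, 0, 0), featureThresholds())
  expect_equal(unname(f0[c("MAV", "RMS", "WL", "ZC", "WAMP", "iEMG", "VAR")]),
               rep(0, 7))
  expect_equal(unname(f0["LOG"]), 1e-12)

  # two-sample closed forms
  f2 <- windowFeatures(c(3, 4), featureThresholds())
  expect_equal(unname(f2["RMS"]), sqrt(12.5))
  expect_equal(unname(f2[c("MAV", "iEMG", "WL", "VAR")]), c(3.5, 7, 1, 0.5))

  expect_error(windowFeatures(5), class = "lmg_domain_error")
})

test_that("vectorized features agree with the direct-summation oracle", {
  set.seed(31)
  for (i in 1:25) {
    x <- rnorm(sample(3:50, 1))
    got <- windowFeatures(x)
    expect_equal(got, feature_oracle(x), tolerance = 1e-12)
  }
})

test_that("feature inequalities and identities hold on random windows", {
  set.seed(32)
  for (i in 1:30) {
    L <- sample(4:60, 1)
    x <- rnorm(L, sd = runif(1, 0.1, 5))
    f <- windowFeatures(x)
    expect_gte(f[["RMS"]], f[["MAV"]])                 # power-mean inequality
    expect_equal(f[["iEMG"]], L * f[["MAV"]])          # exact identity
    expect_lte(f[["ZC"]], L - 1)
    # with both thresholds zero and no zero samples, ZC <= WAMP
    th0 <- featureThresholds(eps_zc = 0, eps_wamp = 0)
    f0 <- windowFeatures(x, th0)
    expect_lte(f0[["ZC"]], f0[["WAMP"]])

    # scale equivariance
    k <- runif(1, 0.5, 3)
    fk <- windowFeatures(k * x, featureThresholds(delta_log = 0))
    fd <- windowFeatures(x, featureThresholds(delta_log = 0))
    for (nm in c("MAV", "iEMG", "RMS", "WL", "LOG")) {
      expect_equal(fk[[nm]], k * fd[[nm]], tolerance = 1e-9)
    }
    expect_equal(fk[["VAR"]], k^2 * fd[["VAR"]], tolerance = 1e-9)
    expect_equal(fk[["ZC"]], fd[["ZC"]])
  }
})

test_that("feature tables concatenate channels in window order", {
  ws <- toy_windowset(classes = c("a", "b"), reps = 1:2, per = 3, L = 10,
                      C = 5)
  ft <- featureTable(ws)
  expect_equal(ncol(featureMatrix(ft)), 40)            # 5 channels x 8
  expect_equal(nWindows(ft), nWindows(ws))
  expect_equal(windowLabels(ft), windowLabels(ws))
  expect_equal(colnames(featureMatrix(ft))[1:8],
               paste0("ch01_", c("RMS", "WL", "ZC", "MAV", "iEMG", "WAMP",
                                 "VAR", "LOG")))

  # row n equals the per-channel features of window n
  w <- 4
  for (c_ in 1:5) {
    expect_equal(unname(featureMatrix(ft)[w, (c_ - 1) * 8 + 1:8]),
                 unname(windowFeatures(windowArray(ws)[w, , c_])))
  }

  # permuting windows permutes rows identically
  perm <- c(3, 1, 2, 6, 5, 4, 7:nWindows(ws))
  ftp <- featureTable(subsetWindows(ws, perm))
  expect_equal(featureMatrix(ftp), featureMatrix(ft)[perm, ])

  # empty input keeps the 40 named columns
  ft0 <- featureTable(subsetWindows(ws, integer(0)))
  expect_equal(nWindows(ft0), 0)
  expect_equal(ncol(featureMatrix(ft0)), 40)

  # non-finite samples flag and exclude the window, with a logged count
  bad <- windowArray(ws)
  bad[2, 1, 1] <- NA_real_
  ws_bad <- ws
  slot(ws_bad, "windows", check = FALSE) <- bad
  expect_message(ft_bad <- featureTable(ws_bad), "1 window")
  expect_equal(nWindows(ft_bad), nWindows(ws) - 1)
})
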