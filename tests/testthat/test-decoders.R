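test_that("decoder construction is introspectable and matches the topology", {
  spec <- modelSpec("TMC-ViT", "classification", n_classes = 5)
  dec <- buildDecoder(spec, c(80L, 10L))
  s <- decoderSummary(dec)
  expect_equal(s$n_attention_layers, 4)
  expect_equal(s$built_attention_layers, 4)       # counted from the weights
  expect_equal(s$n_heads, 4)
  expect_equal(s$output_dim, 5)

  cnn <- decoderSummary(buildDecoder(modelSpec("CNN", "classification"),
                                     c(80L, 10L)))
  expect_equal(cnn$conv_blocks, 3)
  expect_equal(cnn$fc_layers, 4)

  # regression head: one output, no softmax
  reg <- buildDecoder(modelSpec("CNN", "regression"), c(16L, 4L))
  expect_equal(decoderSummary(reg)$output_dim, 1)
  expect_equal(length(reg@net$params$head_b), 1)

  # seed-deterministic construction
  d1 <- buildDecoder(modelSpec("CNN", "classification", seed = 9), c(16L, 4L))
  d2 <- buildDecoder(modelSpec("CNN", "classification", seed = 9), c(16L, 4L))
  expect_identical(d1@net$params, d2@net$params)

  # inputs too small for the patch reductions fail with the minimum stated
  expect_error(buildDecoder(modelSpec("TMC-ViT", "classification"),
                            c(4L, 1L)),
               "L = 8")
})

test_that("a fitted RF reports its tree count and memorizes separable data", {
  ws <- toy_windowset(classes = c("a", "b"), reps = 1:2, per = 4)
  spec <- modelSpec("RF", "classification", n_classes = 2)
  fit <- trainDecoder(spec, ws, cfg = trainConfig(seed = 3))
  expect_equal(decoderSummary(fit)$n_trees, 150)
  pr <- predictDecoder(fit, ws)
  expect_equal(pr$labels, windowLabels(ws))       # pure leaves on toy data
})

test_that("all three families fit linearly separable toy data perfectly", {
  set.seed(1)
  N <- 60; L <- 16; C <- 4
  y <- rep(c("a", "b"), each = N / 2)
  x <- array(rnorm(N * L * C, sd = 0.05), c(N, L, C)) +
    array(rep(ifelse(y == "a", 0, 1), L * C), c(N, L, C))
  cfg <- trainConfig(epochs = 60, batch_size = 16, seed = 5,
                     max_train_windows = Inf)
  for (fam in c("RF", "CNN", "TMC-ViT")) {
    spec <- modelSpec(fam, "classification", n_classes = 2, seed = 2)
    fit <- trainDecoder(buildDecoder(spec, c(L, C)), x, y, cfg)
    pr <- predictDecoder(fit, x)
    expect_equal(mean(pr$labels == y), 1, info = fam)
    expect_equal(rowSums(pr$prob), rep(1, N), tolerance = 1e-6)
    expect_true(all(pr$prob >= 0))
  }
})

test_that("constant-target regression converges to the constant", {
  N <- 40; L <- 16; C <- 4
  x <- array(0.5, c(N, L, C))
  yt <- rep(0.37, N)
  cfg <- trainConfig(loss = "MSE", epochs = 150, batch_size = 32, lr = 3e-3,
                     patience = 30, seed = 5, max_train_windows = Inf)
  for (fam in c("RF", "CNN", "TMC-ViT")) {
    spec <- modelSpec(fam, "regression", seed = 2, cnn_dropout = 0)
    fit <- trainDecoder(buildDecoder(spec, c(L, C)), x, yt, cfg)
    pr <- predictDecoder(fit, x)
    expect_lt(max(abs(pr - 0.37)), 1e-3)
  }
})

test_that("training is reproducible under a fixed seed", {
  ws <- toy_windowset(classes = c("a", "b"), reps = 1:2, per = 4, L = 12,
                      C = 3)
  cfg <- trainConfig(epochs = 5, batch_size = 8, seed = 11,
                     max_train_windows = Inf)
  for (fam in c("RF", "CNN", "TMC-ViT")) {
    spec <- modelSpec(fam, "classification", n_classes = 2, seed = 7,
                      cnn_filters = c(4, 5, 6), cnn_fc_widths = c(8, 6, 5, 4),
                      vit_conv_filters = c(3, 4), embed_dim = 8, mlp_dim = 12,
                      n_attention_layers = 2, n_heads = 2)
    f1 <- trainDecoder(spec, ws, cfg = cfg)
    f2 <- trainDecoder(spec, ws, cfg = cfg)
    p1 <- predictDecoder(f1, ws)
    p2 <- predictDecoder(f2, ws)
    expect_identical(p1$prob, p2$prob, info = fam)
  }
})

test_that("prediction contracts: empty input, shape mismatch, mixed loss", {
  ws <- toy_windowset(classes = c("a", "b"), reps = 1:2, per = 4, L = 12,
                      C = 3)
  spec <- modelSpec("RF", "classification", n_classes = 2)
  fit <- trainDecoder(spec, ws, cfg = trainConfig(seed = 1))

  empty <- subsetWindows(ws, integer(0))
  pr <- predictDecoder(fit, empty)
  expect_equal(length(pr$labels), 0)
  expect_equal(nrow(pr$prob), 0)

  wrong <- toy_windowset(classes = c("a", "b"), reps = 1:2, per = 2, L = 6,
                         C = 2)
  expect_error(predictDecoder(fit, wrong), class = "lmg_contract_error")

  # target/window count mismatch
  expect_error(trainDecoder(spec, ws, y = c("a", "b")),
               class = "lmg_contract_error")

  # classification must pair with cross-entropy
  expect_error(trainDecoder(spec, ws, cfg = trainConfig(loss = "MSE")),
               class = "lmg_config_error")
})
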