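# Decoder families: random forest (via ranger), CNN and TMC-ViT (native).
# LMG decoders consume raw windows; EMG decoders consume the feature table.

#' Construct a decoder specification
#'
#' Defaults follow the study topology: RF with 150 trees; CNN with three
#' convolutional blocks (conv + batch norm + dropout), four fully-connected
#' layers and a softmax head; TMC-ViT with two convolutional layers, 2x2
#' patch extraction, and four transformer encoder layers with four heads
#' each. Size hyperparameters not fixed by the topology are explicit,
#' config-visible defaults.
#'
#' @param family `"RF"`, `"CNN"` or `"TMC-ViT"`.
#' @param task `"classification"` or `"regression"`.
#' @param n_classes number of classes (classification).
#' @param rf_trees number of random-forest trees.
#' @param cnn_filters,cnn_kernel,cnn_dropout,cnn_fc_widths,cnn_stride CNN
#'   sizes.
#' @param vit_conv_filters,patch_size,n_attention_layers,n_heads,embed_dim,mlp_dim
#'   TMC-ViT sizes.
#' @param seed integer seed for weight initialization.
#' @return a [ModelSpec-class]
#' @export
modelSpec <- function(family = c("RF", "CNN", "TMC-ViT"),
                      task = c("classification", "regression"),
                      n_classes = 5L,
                      rf_trees = 150L,
                      cnn_filters = c(32L, 64L, 128L),
                      cnn_kernel = 3L,
                      cnn_dropout = 0.3,
                      cnn_fc_widths = c(256L, 128L, 64L, 32L),
                      cnn_stride = 2L,
                      vit_conv_filters = c(8L, 16L),
                      patch_size = c(2L, 2L),
                      n_attention_layers = 4L,
                      n_heads = 4L,
                      embed_dim = 64L,
                      mlp_dim = 128L,
                      seed = 1L) {
  family <- match.arg(family)
  task <- match.arg(task)
  new("ModelSpec", family = family, task = task,
      rfTrees = as.integer(rf_trees),
      cnnFilters = as.integer(cnn_filters),
      cnnKernel = as.integer(cnn_kernel),
      cnnDropout = cnn_dropout,
      cnnFcWidths = as.integer(cnn_fc_widths),
      cnnStride = as.integer(cnn_stride),
      vitConvFilters = as.integer(vit_conv_filters),
      patchSize = as.integer(patch_size),
      nAttentionLayers = as.integer(n_attention_layers),
      nHeads = as.integer(n_heads),
      embedDim = as.integer(embed_dim),
      mlpDim = as.integer(mlp_dim),
      nClasses = as.integer(n_classes),
      seed = as.integer(seed))
}

#' Construct a training configuration
#'
#' The loss is paired with the task: sparse categorical cross-entropy for
#' classification, MSE for regression; passing a mismatched loss raises a
#' configuration error at training time. `max_train_windows` caps the
#' training set by a seeded class-stratified subsample, keeping CPU training
#' times bounded; `Inf` disables the cap.
#'
#' @param loss `NULL` (paired with the task at training time),
#'   `"sparse-categorical-cross-entropy"` or `"MSE"`.
#' @param lr,beta1,beta2 Adam hyperparameters.
#' @param epochs maximum epochs.
#' @param batch_size minibatch size.
#' @param patience early-stop patience in epochs.
#' @param max_train_windows training-set cap.
#' @param seed integer seed for shuffling/dropout/subsampling.
#' @return a [TrainConfig-class]
#' @export
trainConfig <- function(loss = NULL, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                        epochs = 10L, batch_size = 128L, patience = 10L,
                        max_train_windows = 1800, seed = 1L) {
  new("TrainConfig",
      loss = loss %||% "sparse-categorical-cross-entropy",
      lr = lr, beta1 = beta1, beta2 = beta2,
      epochs = as.integer(epochs), batchSize = as.integer(batch_size),
      patience = as.integer(patience), maxTrainWindows = max_train_windows,
      seed = as.integer(seed))
}

# Coerce decoder input to [N, L, C]: a WindowSet stays a window tensor, a
# FeatureTable (or plain matrix) becomes windows of shape (8, C) /
# (ncol, 1) so the same model machinery applies.
decoder_input <- function(x) {
  if (is(x, "WindowSet")) {
    return(list(arr = x@windows, shape = dim(x@windows)[2:3]))
  }
  if (is(x, "FeatureTable")) {
    m <- x@values
    C <- ncol(m) %/% 8L
    arr <- array(0, c(nrow(m), 8L, C))
    for (c_ in seq_len(C)) arr[, , c_] <- m[, (c_ - 1L) * 8L + 1:8]
    return(list(arr = arr, shape = c(8L, C)))
  }
  if (is.matrix(x)) {
    return(list(arr = array(x, c(nrow(x), ncol(x), 1L)),
                shape = c(ncol(x), 1L)))
  }
  if (is.array(x) && length(dim(x)) == 3) {
    return(list(arr = x, shape = dim(x)[2:3]))
  }
  stop_contract("decoder input must be a WindowSet, FeatureTable, matrix or [N,L,C] array")
}

flatten_windows <- function(arr) {
  d <- dim(arr)
  m <- arr
  dim(m) <- c(d[1], d[2] * d[3])
  m
}

#' Build an (untrained) decoder for a given input shape
#'
#' Deep families are initialized seed-deterministically from `spec@@seed`;
#' inputs too small for the TMC-ViT pooling/patch reductions raise a shape
#' error stating the minimum usable size.
#'
#' @param spec a [ModelSpec-class].
#' @param input_shape integer `c(L, C)` window shape.
#' @return a [Decoder-class]
#' @export
buildDecoder <- function(spec, input_shape) {
  validObject(spec)
  input_shape <- as.integer(input_shape)
  n_out <- if (spec@task == "classification") spec@nClasses else 1L
  net <- if (spec@family == "RF") list() else
    net_init(spec@family, input_shape, spec, n_out)
  new("Decoder", spec = spec, inputShape = input_shape, net = net)
}

#' Architecture summary of a decoder
#'
#' @param decoder a [Decoder-class] or [FittedDecoder-class].
#' @return list with family, task, output dimension and family-specific
#'   introspection fields (`n_trees`; `conv_blocks`, `fc_layers`;
#'   `n_attention_layers`, `n_heads`, `n_tokens`).
#' @export
decoderSummary <- function(decoder) {
  spec <- decoder@spec
  out <- list(family = spec@family, task = spec@task,
              output_dim = if (spec@task == "classification") spec@nClasses else 1L)
  if (spec@family == "RF") {
    out$n_trees <- spec@rfTrees
    if (is(decoder, "FittedDecoder")) out$n_trees <- decoder@model$num.trees
  } else if (spec@family == "CNN") {
    out$conv_blocks <- length(spec@cnnFilters)
    out$fc_layers <- length(spec@cnnFcWidths)
  } else {
    out$n_attention_layers <- spec@nAttentionLayers
    out$n_heads <- spec@nHeads
    net <- if (is(decoder, "FittedDecoder")) decoder@model else decoder@net
    prefixes <- unique(sub("_(Wq|Wk|Wv|Wo|bq|bk|bv|bo|ln1_g|ln1_b|ln2_g|ln2_b|m1_W|m1_b|m2_W|m2_b)$",
                           "", grep("^l[0-9]+_", names(net$params), value = TRUE)))
    out$built_attention_layers <- length(prefixes)
    out$n_tokens <- net$geom$n_tokens
  }
  out
}

#' Train a decoder
#'
#' @param decoder a [Decoder-class] from [buildDecoder()], or a
#'   [ModelSpec-class] (the decoder is built for the input shape).
#' @param x training input: [WindowSet-class] (raw windows; the LMG
#'   contract), [FeatureTable-class] (the EMG contract), matrix or
#'   `[N, L, C]` array.
#' @param y targets: labels (classification) or numeric (regression);
#'   defaults to the labels/targets stored in `x`.
#' @param cfg a [TrainConfig-class].
#' @return a [FittedDecoder-class]
#' @export
trainDecoder <- function(decoder, x, y = NULL, cfg = trainConfig()) {
  inp <- decoder_input(x)
  if (is(decoder, "ModelSpec")) decoder <- buildDecoder(decoder, inp$shape)
  spec <- decoder@spec
  if (is.null(y)) {
    y <- if (spec@task == "classification") {
      if (is(x, "WindowSet") || is(x, "FeatureTable")) windowLabels(x) else
        stop_contract("labels required for classification")
    } else {
      if (is(x, "WindowSet") && length(windowTargets(x))) windowTargets(x) else
        stop_contract("numeric targets required for regression")
    }
  }
  N <- dim(inp$arr)[1]
  if (length(y) != N) {
    stop_contract(sprintf("target count (%d) does not match window count (%d)",
                          length(y), N))
  }
  expected_loss <- if (spec@task == "classification")
    "sparse-categorical-cross-entropy" else "MSE"
  if (cfg@loss != expected_loss) {
    if (identical(cfg@loss, "sparse-categorical-cross-entropy") &&
        spec@task == "regression") {
      cfg@loss <- "MSE"   # default pairing
    } else {
      stop_config(sprintf("loss '%s' does not pair with task '%s'",
                          cfg@loss, spec@task))
    }
  }

  classes <- character(0)
  if (spec@task == "classification") {
    classes <- sort(unique(as.character(y)))
    y_idx <- match(as.character(y), classes)
  } else {
    y_idx <- as.numeric(y)
  }

  # seeded, class-stratified training-set cap
  keep <- seq_len(N)
  if (is.finite(cfg@maxTrainWindows) && N > cfg@maxTrainWindows) {
    keep <- with_seed(cfg@seed, {
      if (spec@task == "classification") {
        per <- ceiling(cfg@maxTrainWindows / length(classes))
        sort(unlist(lapply(seq_along(classes), function(k) {
          idx <- which(y_idx == k)
          if (length(idx) > per) sample(idx, per) else idx
        })))
      } else {
        sort(sample.int(N, cfg@maxTrainWindows))
      }
    })
  }
  xtr <- inp$arr[keep, , , drop = FALSE]
  ytr <- y_idx[keep]

  if (spec@family == "RF") {
    xm <- flatten_windows(xtr)
    colnames(xm) <- paste0("x", seq_len(ncol(xm)))
    yr <- if (spec@task == "classification") factor(classes[ytr], levels = classes)
          else ytr
    fit <- ranger::ranger(x = xm, y = yr, num.trees = spec@rfTrees,
                          probability = spec@task == "classification",
                          seed = cfg@seed, num.threads = 1L)
    return(new("FittedDecoder", spec = spec, inputShape = decoder@inputShape,
               model = fit, classes = classes,
               history = list(oob_error = fit$prediction.error)))
  }

  net <- decoder@net
  if (!length(net)) {
    net <- net_init(spec@family, decoder@inputShape,
                    spec, if (spec@task == "classification") spec@nClasses else 1L)
  }
  fitted <- net_fit(spec@family, net, xtr, ytr, spec, cfg, spec@task)
  new("FittedDecoder", spec = spec, inputShape = decoder@inputShape,
      model = fitted$net, classes = classes, history = fitted$history)
}

#' Predict with a fitted decoder
#'
#' @param fitted a [FittedDecoder-class].
#' @param x input windows/features matching the training shape.
#' @return classification: list with `labels` (character) and `prob`
#'   (N x K matrix; rows are non-negative and sum to 1). Regression:
#'   numeric vector of unbounded force estimates.
#' @export
predictDecoder <- function(fitted, x) {
  inp <- decoder_input(x)
  if (!all(inp$shape == fitted@inputShape)) {
    stop_contract(sprintf("input shape (%s) does not match training shape (%s)",
                          paste(inp$shape, collapse = "x"),
                          paste(fitted@inputShape, collapse = "x")))
  }
  spec <- fitted@spec
  N <- dim(inp$arr)[1]
  if (spec@family == "RF") {
    if (N == 0L) {
      if (spec@task == "classification") {
        return(list(labels = character(0),
                    prob = matrix(numeric(0), 0, length(fitted@classes),
                                  dimnames = list(NULL, fitted@classes))))
      }
      return(numeric(0))
    }
    xm <- flatten_windows(inp$arr)
    colnames(xm) <- paste0("x", seq_len(ncol(xm)))
    pr <- stats::predict(fitted@model, data = xm, num.threads = 1L)
    if (spec@task == "classification") {
      prob <- pr$predictions[, fitted@classes, drop = FALSE]
      return(list(labels = fitted@classes[max.col(prob, ties.method = "first")],
                  prob = prob))
    }
    return(as.numeric(pr$predictions))
  }
  out <- net_predict(spec@family, fitted@model, inp$arr, spec)
  if (spec@task == "classification") {
    prob <- if (nrow(out)) softmax_rows(out) else out
    colnames(prob) <- fitted@classes
    list(labels = fitted@classes[if (nrow(prob)) max.col(prob, ties.method = "first") else integer(0)],
         prob = prob)
  } else {
    as.numeric(out)
  }
}
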