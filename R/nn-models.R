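# The two deep decoder families, assembled from the primitives in
# nn-layers.R with hand-chained backpropagation:
#
#  * CNN: 3 x (temporal conv + batch norm + ReLU + dropout), flatten,
#    4 fully-connected ReLU layers, linear head (softmax applied by the
#    loss / at prediction time).
#  * TMC-ViT: 2 x (2-D conv + ReLU + max-pool) over the (time x channel)
#    window image, 2x2 patch extraction, linear patch projection with a
#    learned positional embedding, N pre-LN transformer encoder layers
#    (multi-head self-attention + MLP, residual), final layer norm,
#    mean-pooled tokens, linear head.

## ---------------------------------------------------------------- CNN -----

cnn_geometry <- function(input_shape, spec) {
  L <- input_shape[1]
  sizes <- integer(3)
  for (i in 1:3) {
    L <- as.integer(ceiling(L / spec@cnnStride))
    sizes[i] <- L
  }
  list(conv_len = sizes, flat = sizes[3] * spec@cnnFilters[3])
}

cnn_init <- function(input_shape, spec, n_out) {
  geom <- cnn_geometry(input_shape, spec)
  k <- spec@cnnKernel
  f <- spec@cnnFilters
  cin <- c(input_shape[2], f[1], f[2])
  p <- list()
  s <- list()
  with_seed(spec@seed, {
    for (i in 1:3) {
      p[[paste0("c", i, "_W")]] <- he_init(k * cin[i], c(k, cin[i], f[i]))
      p[[paste0("c", i, "_b")]] <- numeric(f[i])
      p[[paste0("bn", i, "_g")]] <- rep(1, f[i])
      p[[paste0("bn", i, "_b")]] <- numeric(f[i])
      s[[paste0("bn", i, "_mean")]] <- numeric(f[i])
      s[[paste0("bn", i, "_var")]] <- rep(1, f[i])
    }
    widths <- c(geom$flat, spec@cnnFcWidths)
    for (i in seq_along(spec@cnnFcWidths)) {
      p[[paste0("f", i, "_W")]] <- he_init(widths[i], c(widths[i], widths[i + 1]))
      p[[paste0("f", i, "_b")]] <- numeric(widths[i + 1])
    }
    p$head_W <- xavier_init(widths[length(widths)],
                            c(widths[length(widths)], n_out))
    p$head_b <- numeric(n_out)
  })
  list(params = p, state = s, geom = geom)
}

cnn_fwd <- function(p, s, x, spec, train) {
  B <- dim(x)[1]
  caches <- list()
  h <- x
  for (i in 1:3) {
    cv <- conv1d_fwd(h, p[[paste0("c", i, "_W")]], p[[paste0("c", i, "_b")]],
                     stride = spec@cnnStride)
    d3 <- dim(cv$y)
    h2 <- cv$y; dim(h2) <- c(d3[1] * d3[2], d3[3])
    bn <- bn_fwd(h2, p[[paste0("bn", i, "_g")]], p[[paste0("bn", i, "_b")]],
                 s[[paste0("bn", i, "_mean")]], s[[paste0("bn", i, "_var")]],
                 train)
    s[[paste0("bn", i, "_mean")]] <- bn$run_mean
    s[[paste0("bn", i, "_var")]] <- bn$run_var
    rl <- relu_fwd(bn$y)
    dp <- dropout_fwd(rl$y, spec@cnnDropout, train)
    h <- dp$y; dim(h) <- d3
    caches[[i]] <- list(cv = cv$cache, bn = bn$cache, rl = rl$cache,
                        dp = dp$cache, d3 = d3)
  }
  d3 <- dim(h)
  h2 <- h; dim(h2) <- c(B, d3[2] * d3[3])
  fc_caches <- list()
  for (i in seq_along(spec@cnnFcWidths)) {
    dn <- dense_fwd(h2, p[[paste0("f", i, "_W")]], p[[paste0("f", i, "_b")]])
    rl <- relu_fwd(dn$y)
    h2 <- rl$y
    fc_caches[[i]] <- list(dn = dn$cache, rl = rl$cache)
  }
  hd <- dense_fwd(h2, p$head_W, p$head_b)
  list(out = hd$y, state = s,
       cache = list(conv = caches, fc = fc_caches, head = hd$cache,
                    flat_dim = d3))
}

cnn_bwd <- function(p, cache, dout, spec) {
  g <- list()
  bk <- dense_bwd(dout, cache$head)
  g$head_W <- bk$dW; g$head_b <- bk$db
  dh <- bk$dx
  for (i in rev(seq_along(cache$fc))) {
    dh <- relu_bwd(dh, cache$fc[[i]]$rl)
    bk <- dense_bwd(dh, cache$fc[[i]]$dn)
    g[[paste0("f", i, "_W")]] <- bk$dW
    g[[paste0("f", i, "_b")]] <- bk$db
    dh <- bk$dx
  }
  d3 <- cache$flat_dim
  dim(dh) <- d3
  for (i in 3:1) {
    ci <- cache$conv[[i]]
    dh2 <- dh; dim(dh2) <- c(ci$d3[1] * ci$d3[2], ci$d3[3])
    dh2 <- dropout_bwd(dh2, ci$dp)
    dh2 <- relu_bwd(dh2, ci$rl)
    bn <- bn_bwd(dh2, ci$bn)
    g[[paste0("bn", i, "_g")]] <- bn$dg
    g[[paste0("bn", i, "_b")]] <- bn$db
    dcv <- bn$dx; dim(dcv) <- ci$d3
    bk <- conv1d_bwd(dcv, ci$cv)
    g[[paste0("c", i, "_W")]] <- bk$dW
    g[[paste0("c", i, "_b")]] <- bk$db
    dh <- bk$dx
  }
  g
}

## ------------------------------------------------------------- TMC-ViT ----

vit_geometry <- function(input_shape, spec) {
  H <- input_shape[1]; W <- input_shape[2]
  pools <- list()
  for (i in 1:2) {
    pc <- if (W >= 4) 2L else 1L
    H2 <- H %/% 2L; W2 <- W %/% pc
    if (H2 < 1L || W2 < 1L) {
      stop_contract(sprintf(
        "input %d x %d too small for the TMC-ViT embedding; need at least L = 8 and C = 2",
        input_shape[1], input_shape[2]))
    }
    pools[[i]] <- c(2L, pc)
    H <- H2; W <- W2
  }
  ph <- spec@patchSize[1]; pw <- spec@patchSize[2]
  pH <- H %/% ph; pW <- W %/% pw
  if (pH < 1L || pW < 1L) {
    stop_contract(sprintf(
      "pooled map %d x %d cannot host %d x %d patches; need at least L = 8 and C = 2",
      H, W, ph, pw))
  }
  list(pools = pools, n_tokens = pH * pW, patch_dim = ph * pw * spec@vitConvFilters[2])
}

vit_init <- function(input_shape, spec, n_out) {
  geom <- vit_geometry(input_shape, spec)
  f <- spec@vitConvFilters
  D <- spec@embedDim
  p <- list()
  with_seed(spec@seed, {
    p$v1_W <- he_init(9, c(3L, 3L, 1L, f[1]))
    p$v1_b <- numeric(f[1])
    p$v2_W <- he_init(9 * f[1], c(3L, 3L, f[1], f[2]))
    p$v2_b <- numeric(f[2])
    p$proj_W <- xavier_init(geom$patch_dim, c(geom$patch_dim, D))
    p$proj_b <- numeric(D)
    p$pos <- matrix(stats::rnorm(geom$n_tokens * D, sd = 0.02),
                    geom$n_tokens, D)
    for (l in seq_len(spec@nAttentionLayers)) {
      pre <- paste0("l", l, "_")
      p[[paste0(pre, "ln1_g")]] <- rep(1, D)
      p[[paste0(pre, "ln1_b")]] <- numeric(D)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) {
        p[[paste0(pre, nm)]] <- xavier_init(D, c(D, D))
      }
      for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- numeric(D)
      p[[paste0(pre, "ln2_g")]] <- rep(1, D)
      p[[paste0(pre, "ln2_b")]] <- numeric(D)
      p[[paste0(pre, "m1_W")]] <- he_init(D, c(D, spec@mlpDim))
      p[[paste0(pre, "m1_b")]] <- numeric(spec@mlpDim)
      p[[paste0(pre, "m2_W")]] <- xavier_init(spec@mlpDim, c(spec@mlpDim, D))
      p[[paste0(pre, "m2_b")]] <- numeric(D)
    }
    p$lnf_g <- rep(1, D)
    p$lnf_b <- numeric(D)
    p$head_W <- xavier_init(D, c(D, n_out))
    p$head_b <- numeric(n_out)
  })
  list(params = p, state = list(), geom = geom)
}

vit_fwd <- function(p, s, x, spec, train, geom) {
  d <- dim(x); B <- d[1]
  img <- x; dim(img) <- c(B, d[2], d[3], 1L)
  c1 <- conv2d_fwd(img, p$v1_W, p$v1_b)
  r1 <- relu_fwd(c1$y)
  p1 <- maxpool2d_fwd(r1$y, geom$pools[[1]][1], geom$pools[[1]][2])
  c2 <- conv2d_fwd(p1$y, p$v2_W, p$v2_b)
  r2 <- relu_fwd(c2$y)
  p2 <- maxpool2d_fwd(r2$y, geom$pools[[2]][1], geom$pools[[2]][2])
  pt <- patchify_fwd(p2$y, spec@patchSize[1], spec@patchSize[2])
  T_ <- dim(pt$y)[2]
  tk2 <- pt$y; dim(tk2) <- c(B * T_, geom$patch_dim)
  pj <- dense_fwd(tk2, p$proj_W, p$proj_b)
  D <- spec@embedDim
  tok <- pj$y; dim(tok) <- c(B, T_, D)
  pos <- aperm(array(p$pos, c(T_, D, B)), c(3, 1, 2))
  tok <- tok + pos
  layer_caches <- vector("list", spec@nAttentionLayers)
  for (l in seq_len(spec@nAttentionLayers)) {
    pre <- paste0("l", l, "_")
    x2 <- tok; dim(x2) <- c(B * T_, D)
    ln1 <- ln_fwd(x2, p[[paste0(pre, "ln1_g")]], p[[paste0(pre, "ln1_b")]])
    a <- ln1$y; dim(a) <- c(B, T_, D)
    mp <- list(Wq = p[[paste0(pre, "Wq")]], bq = p[[paste0(pre, "bq")]],
               Wk = p[[paste0(pre, "Wk")]], bk = p[[paste0(pre, "bk")]],
               Wv = p[[paste0(pre, "Wv")]], bv = p[[paste0(pre, "bv")]],
               Wo = p[[paste0(pre, "Wo")]], bo = p[[paste0(pre, "bo")]])
    at <- mha_fwd(a, mp, spec@nHeads)
    tok <- tok + at$y
    x2b <- tok; dim(x2b) <- c(B * T_, D)
    ln2 <- ln_fwd(x2b, p[[paste0(pre, "ln2_g")]], p[[paste0(pre, "ln2_b")]])
    m1 <- dense_fwd(ln2$y, p[[paste0(pre, "m1_W")]], p[[paste0(pre, "m1_b")]])
    mr <- relu_fwd(m1$y)
    m2 <- dense_fwd(mr$y, p[[paste0(pre, "m2_W")]], p[[paste0(pre, "m2_b")]])
    dm <- m2$y; dim(dm) <- c(B, T_, D)
    tok <- tok + dm
    layer_caches[[l]] <- list(ln1 = ln1$cache, at = at$cache, ln2 = ln2$cache,
                              m1 = m1$cache, mr = mr$cache, m2 = m2$cache)
  }
  xf <- tok; dim(xf) <- c(B * T_, D)
  lnf <- ln_fwd(xf, p$lnf_g, p$lnf_b)
  yf <- lnf$y; dim(yf) <- c(B, T_, D)
  pooled <- matrix(0, B, D)
  for (t in seq_len(T_)) pooled <- pooled + matrix(yf[, t, ], B)
  pooled <- pooled / T_
  hd <- dense_fwd(pooled, p$head_W, p$head_b)
  list(out = hd$y, state = s,
       cache = list(c1 = c1$cache, r1 = r1$cache, p1 = p1$cache,
                    c2 = c2$cache, r2 = r2$cache, p2 = p2$cache,
                    pt = pt$cache, pj = pj$cache, layers = layer_caches,
                    lnf = lnf$cache, head = hd$cache,
                    B = B, T_ = T_, D = D, in_dims = d))
}

vit_bwd <- function(p, cache, dout, spec) {
  B <- cache$B; T_ <- cache$T_; D <- cache$D
  g <- list()
  bk <- dense_bwd(dout, cache$head)
  g$head_W <- bk$dW; g$head_b <- bk$db
  dyf <- array(0, c(B, T_, D))
  for (t in seq_len(T_)) dyf[, t, ] <- bk$dx / T_
  dyf2 <- dyf; dim(dyf2) <- c(B * T_, D)
  lb <- ln_bwd(dyf2, cache$lnf)
  g$lnf_g <- lb$dg; g$lnf_b <- lb$db
  dtok <- lb$dx; dim(dtok) <- c(B, T_, D)
  for (l in rev(seq_len(spec@nAttentionLayers))) {
    pre <- paste0("l", l, "_")
    lc <- cache$layers[[l]]
    # MLP sub-block (residual)
    dm <- dtok; dim(dm) <- c(B * T_, D)
    b2 <- dense_bwd(dm, lc$m2)
    g[[paste0(pre, "m2_W")]] <- b2$dW; g[[paste0(pre, "m2_b")]] <- b2$db
    dr <- relu_bwd(b2$dx, lc$mr)
    b1 <- dense_bwd(dr, lc$m1)
    g[[paste0(pre, "m1_W")]] <- b1$dW; g[[paste0(pre, "m1_b")]] <- b1$db
    l2 <- ln_bwd(b1$dx, lc$ln2)
    g[[paste0(pre, "ln2_g")]] <- l2$dg; g[[paste0(pre, "ln2_b")]] <- l2$db
    dres <- l2$dx; dim(dres) <- c(B, T_, D)
    dtok <- dtok + dres
    # attention sub-block (residual)
    ab <- mha_bwd(dtok, lc$at)
    for (nm in names(ab$grads)) g[[paste0(pre, nm)]] <- ab$grads[[nm]]
    da2 <- ab$dx; dim(da2) <- c(B * T_, D)
    l1 <- ln_bwd(da2, lc$ln1)
    g[[paste0(pre, "ln1_g")]] <- l1$dg; g[[paste0(pre, "ln1_b")]] <- l1$db
    dres <- l1$dx; dim(dres) <- c(B, T_, D)
    dtok <- dtok + dres
  }
  g$pos <- matrix(0, T_, D)
  for (t in seq_len(T_)) g$pos[t, ] <- colSums(matrix(dtok[, t, ], B))
  dtk2 <- dtok; dim(dtk2) <- c(B * T_, D)
  pjb <- dense_bwd(dtk2, cache$pj)
  g$proj_W <- pjb$dW; g$proj_b <- pjb$db
  dpt <- pjb$dx; dim(dpt) <- c(B, T_, dim(cache$pj$W)[1])
  dp2 <- patchify_bwd(dpt, cache$pt)
  dp2 <- maxpool2d_bwd(dp2, cache$p2)
  dp2 <- relu_bwd(dp2, cache$r2)
  c2b <- conv2d_bwd(dp2, cache$c2)
  g$v2_W <- c2b$dW; g$v2_b <- c2b$db
  dp1 <- maxpool2d_bwd(c2b$dx, cache$p1)
  dp1 <- relu_bwd(dp1, cache$r1)
  c1b <- conv2d_bwd(dp1, cache$c1)
  g$v1_W <- c1b$dW; g$v1_b <- c1b$db
  g
}

## --------------------------------------------------------- fit / predict --

net_init <- function(family, input_shape, spec, n_out) {
  switch(family,
         "CNN" = cnn_init(input_shape, spec, n_out),
         "TMC-ViT" = vit_init(input_shape, spec, n_out),
         stop_config(sprintf("unknown deep family '%s'", family)))
}

net_forward <- function(family, net, x, spec, train) {
  switch(family,
         "CNN" = cnn_fwd(net$params, net$state, x, spec, train),
         "TMC-ViT" = vit_fwd(net$params, net$state, x, spec, train, net$geom))
}

net_backward <- function(family, net, cache, dout, spec) {
  switch(family,
         "CNN" = cnn_bwd(net$params, cache, dout, spec),
         "TMC-ViT" = vit_bwd(net$params, cache, dout, spec))
}

# Train a deep decoder. x: [N, L, C]; y: integer class index (classification)
# or numeric target (regression). Deterministic under (spec seed, cfg seed).
net_fit <- function(family, net, x, y, spec, cfg, task) {
  N <- dim(x)[1]
  losses <- numeric(0)
  opt <- adam_init(net$params)
  best <- Inf
  stall <- 0L
  with_seed(cfg@seed, {
    for (ep in seq_len(cfg@epochs)) {
      idx <- sample.int(N)
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1L, N, by = cfg@batchSize)) {
        bi <- idx[b0:min(b0 + cfg@batchSize - 1L, N)]
        xb <- x[bi, , , drop = FALSE]
        fw <- net_forward(family, net, xb, spec, train = TRUE)
        net$state <- fw$state
        ls <- if (task == "classification") ce_loss(fw$out, y[bi])
              else mse_loss(fw$out, y[bi])
        grads <- net_backward(family, net, fw$cache, ls$dlogits, spec)
        upd <- adam_step(net$params, grads, opt, lr = cfg@lr,
                         beta1 = cfg@beta1, beta2 = cfg@beta2)
        net$params <- upd$params
        opt <- upd$state
        ep_loss <- ep_loss + ls$loss
        nb <- nb + 1L
      }
      ep_loss <- ep_loss / nb
      losses <- c(losses, ep_loss)
      if (ep_loss < best - 1e-5) {
        best <- ep_loss
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= cfg@patience) break
      }
    }
  })
  list(net = net, history = list(loss = losses))
}

net_predict <- function(family, net, x, spec, batch = 512L) {
  N <- dim(x)[1]
  if (N == 0L) {
    n_out <- length(net$params$head_b)
    return(matrix(numeric(0), 0, n_out))
  }
  out <- NULL
  for (b0 in seq(1L, N, by = batch)) {
    bi <- b0:min(b0 + batch - 1L, N)
    fw <- net_forward(family, net, x[bi, , , drop = FALSE], spec,
                      train = FALSE)
    out <- rbind(out, fw$out)
  }
  out
}
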