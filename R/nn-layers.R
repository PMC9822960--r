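# Native neural-network primitives on column-major R arrays, backed by BLAS
# matrix products. Shapes: dense layers use plain matrices; 1-D temporal
# convolutions use [B, L, C] arrays; 2-D convolutions use [B, H, W, F].
# Every *_bwd returns gradients whose shapes match the parameters exactly;
# correctness is pinned by end-to-end finite-difference tests.

he_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

xavier_init <- function(fan_in, dims) {
  array(stats::rnorm(prod(dims), sd = sqrt(1 / fan_in)), dims)
}

## dense ---------------------------------------------------------------------

dense_fwd <- function(x, W, b) {
  y <- x %*% W
  y <- y + rep(b, each = nrow(y))
  list(y = y, cache = list(x = x, W = W))
}

dense_bwd <- function(dy, cache) {
  list(dx = dy %*% t(cache$W),
       dW = crossprod(cache$x, dy),
       db = colSums(dy))
}

## relu ----------------------------------------------------------------------

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, cache = m)
}

relu_bwd <- function(dy, cache) dy * cache

## dropout -------------------------------------------------------------------

dropout_fwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  keep <- 1 - rate
  mask <- (stats::runif(length(x)) < keep) / keep
  dim(mask) <- dim(x)
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(dy, cache) {
  if (is.null(cache)) dy else dy * cache
}

## 1-D temporal convolution ('same' padding) ---------------------------------

conv1d_fwd <- function(x, W, b, stride = 1L) {
  d <- dim(x); B <- d[1]; L <- d[2]; C <- d[3]
  k <- dim(W)[1]; F_ <- dim(W)[3]
  P <- as.integer(ceiling(L / stride))
  pad <- max((P - 1L) * stride + k - L, 0L)
  pl <- pad %/% 2L
  xp <- array(0, c(B, L + pad, C))
  xp[, pl + seq_len(L), ] <- x
  starts <- (seq_len(P) - 1L) * stride + 1L
  M <- array(0, c(B, P, k, C))
  for (u in seq_len(k)) M[, , u, ] <- xp[, starts + u - 1L, ]
  dim(M) <- c(B * P, k * C)
  Wm <- W; dim(Wm) <- c(k * C, F_)
  y <- M %*% Wm
  y <- y + rep(b, each = B * P)
  dim(y) <- c(B, P, F_)
  list(y = y, cache = list(M = M, dims = d, stride = stride, k = k, pl = pl,
                           pad = pad, starts = starts, W = W, P = P))
}

conv1d_bwd <- function(dy, cache) {
  d <- cache$dims; B <- d[1]; L <- d[2]; C <- d[3]
  k <- cache$k; P <- cache$P
  F_ <- dim(dy)[3]
  dim(dy) <- c(B * P, F_)
  Wm <- cache$W; dim(Wm) <- c(k * C, F_)
  dW <- crossprod(cache$M, dy); dim(dW) <- dim(cache$W)
  db <- colSums(dy)
  dM <- dy %*% t(Wm); dim(dM) <- c(B, P, k, C)
  dxp <- array(0, c(B, L + cache$pad, C))
  for (u in seq_len(k)) {
    sl <- cache$starts + u - 1L
    dxp[, sl, ] <- dxp[, sl, ] + dM[, , u, ]
  }
  dx <- dxp[, cache$pl + seq_len(L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

## 2-D convolution (stride 1, 'same' padding) --------------------------------

conv2d_fwd <- function(x, W, b) {
  d <- dim(x); B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  kh <- dim(W)[1]; kw <- dim(W)[2]; F_ <- dim(W)[4]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(B, H + kh - 1L, Wd + kw - 1L, C))
  xp[, ph + seq_len(H), pw + seq_len(Wd), ] <- x
  M <- array(0, c(B, H, Wd, kh, kw, C))
  for (u in seq_len(kh)) for (v in seq_len(kw)) {
    M[, , , u, v, ] <- xp[, u + seq_len(H) - 1L, v + seq_len(Wd) - 1L, ]
  }
  dim(M) <- c(B * H * Wd, kh * kw * C)
  Wm <- W; dim(Wm) <- c(kh * kw * C, F_)
  y <- M %*% Wm
  y <- y + rep(b, each = B * H * Wd)
  dim(y) <- c(B, H, Wd, F_)
  list(y = y, cache = list(M = M, dims = d, kh = kh, kw = kw, ph = ph,
                           pw = pw, W = W))
}

conv2d_bwd <- function(dy, cache) {
  d <- cache$dims; B <- d[1]; H <- d[2]; Wd <- d[3]; C <- d[4]
  kh <- cache$kh; kw <- cache$kw
  F_ <- dim(dy)[4]
  dim(dy) <- c(B * H * Wd, F_)
  Wm <- cache$W; dim(Wm) <- c(kh * kw * C, F_)
  dW <- crossprod(cache$M, dy); dim(dW) <- dim(cache$W)
  db <- colSums(dy)
  dM <- dy %*% t(Wm); dim(dM) <- c(B, H, Wd, kh, kw, C)
  dxp <- array(0, c(B, H + kh - 1L, Wd + kw - 1L, C))
  for (u in seq_len(kh)) for (v in seq_len(kw)) {
    hi <- u + seq_len(H) - 1L; wi <- v + seq_len(Wd) - 1L
    dxp[, hi, wi, ] <- dxp[, hi, wi, ] + dM[, , , u, v, ]
  }
  dx <- dxp[, cache$ph + seq_len(H), cache$pw + seq_len(Wd), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

## 2-D max pooling -----------------------------------------------------------

maxpool2d_fwd <- function(x, ph, pw) {
  d <- dim(x); B <- d[1]; H <- d[2]; Wd <- d[3]; F_ <- d[4]
  H2 <- H %/% ph; W2 <- Wd %/% pw
  y <- array(-Inf, c(B, H2, W2, F_))
  win <- array(0L, c(B, H2, W2, F_))
  hs <- ph * (seq_len(H2) - 1L)
  ws <- pw * (seq_len(W2) - 1L)
  code <- 0L
  for (u in seq_len(ph)) for (v in seq_len(pw)) {
    code <- code + 1L
    s <- x[, hs + u, ws + v, , drop = FALSE]
    upd <- s > y
    y[upd] <- s[upd]
    win[upd] <- code
  }
  list(y = y, cache = list(dims = d, ph = ph, pw = pw, win = win,
                           H2 = H2, W2 = W2))
}

maxpool2d_bwd <- function(dy, cache) {
  d <- cache$dims
  ph <- cache$ph; pw <- cache$pw
  H2 <- cache$H2; W2 <- cache$W2
  dx <- array(0, d)
  hs <- ph * (seq_len(H2) - 1L)
  ws <- pw * (seq_len(W2) - 1L)
  code <- 0L
  for (u in seq_len(ph)) for (v in seq_len(pw)) {
    code <- code + 1L
    dx[, hs + u, ws + v, ] <- dy * (cache$win == code)
  }
  dx
}

## patch extraction ([B,H,W,F] -> [B, T, ph*pw*F] tokens) --------------------

patchify_fwd <- function(x, ph, pw) {
  d <- dim(x); B <- d[1]; H <- d[2]; Wd <- d[3]; F_ <- d[4]
  H2 <- H %/% ph; W2 <- Wd %/% pw
  xc <- x[, seq_len(H2 * ph), seq_len(W2 * pw), , drop = FALSE]
  dim(xc) <- c(B, ph, H2, pw, W2, F_)
  tk <- aperm(xc, c(1L, 3L, 5L, 2L, 4L, 6L))  # B, H2, W2, ph, pw, F
  dim(tk) <- c(B, H2 * W2, ph * pw * F_)
  list(y = tk, cache = list(dims = d, ph = ph, pw = pw, H2 = H2, W2 = W2))
}

patchify_bwd <- function(dy, cache) {
  d <- cache$dims; B <- d[1]; H <- d[2]; Wd <- d[3]; F_ <- d[4]
  ph <- cache$ph; pw <- cache$pw; H2 <- cache$H2; W2 <- cache$W2
  dim(dy) <- c(B, H2, W2, ph, pw, F_)
  dxc <- aperm(dy, c(1L, 4L, 2L, 5L, 3L, 6L))  # B, ph, H2, pw, W2, F
  dim(dxc) <- c(B, H2 * ph, W2 * pw, F_)
  dx <- array(0, d)
  dx[, seq_len(H2 * ph), seq_len(W2 * pw), ] <- dxc
  dx
}

## batch norm (per feature, over all leading positions) ----------------------

bn_fwd <- function(x2, g, b, run_mean, run_var, train, momentum = 0.9,
                   eps = 1e-5) {
  # x2: N x F matrix
  if (train) {
    m <- colMeans(x2)
    xc <- x2 - rep(m, each = nrow(x2))
    v <- colMeans(xc^2)
    run_mean <- momentum * run_mean + (1 - momentum) * m
    run_var <- momentum * run_var + (1 - momentum) * v
  } else {
    m <- run_mean
    v <- run_var
    xc <- x2 - rep(m, each = nrow(x2))
  }
  inv <- 1 / sqrt(v + eps)
  xh <- xc * rep(inv, each = nrow(x2))
  y <- xh * rep(g, each = nrow(x2)) + rep(b, each = nrow(x2))
  list(y = y, cache = list(xh = xh, inv = inv, g = g, train = train),
       run_mean = run_mean, run_var = run_var)
}

bn_bwd <- function(dy, cache) {
  N <- nrow(dy)
  xh <- cache$xh
  dg <- colSums(dy * xh)
  db <- colSums(dy)
  dxh <- dy * rep(cache$g, each = N)
  if (cache$train) {
    dx <- (dxh - rep(colMeans(dxh), each = N) -
             xh * rep(colMeans(dxh * xh), each = N)) *
      rep(cache$inv, each = N)
  } else {
    dx <- dxh * rep(cache$inv, each = N)
  }
  list(dx = dx, dg = dg, db = db)
}

## layer norm (per row, over the embedding dimension) ------------------------

ln_fwd <- function(x2, g, b, eps = 1e-5) {
  D <- ncol(x2)
  m <- rowMeans(x2)
  xc <- x2 - m
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xh <- xc * inv
  y <- xh * rep(g, each = nrow(x2)) + rep(b, each = nrow(x2))
  list(y = y, cache = list(xh = xh, inv = inv, g = g))
}

ln_bwd <- function(dy, cache) {
  N <- nrow(dy)
  xh <- cache$xh
  dg <- colSums(dy * xh)
  db <- colSums(dy)
  dxh <- dy * rep(cache$g, each = N)
  dx <- (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh)) * cache$inv
  list(dx = dx, dg = dg, db = db)
}

## multi-head self-attention on [B, T, D] tokens -----------------------------

# Attention is vectorized over the batch AND the query-token axis: the only
# explicit loop is over the T key tokens. Row layout throughout: (B*T) x D
# matrices whose row index is b + (i - 1) * B (batch fastest), which is the
# natural column-major flattening of [B, T, D].

# slice token j of a [B, T, D] array as a B x D matrix without dropping dims
tok_slice <- function(X, j, B, D) {
  m <- X[, j, , drop = FALSE]
  dim(m) <- c(B, D)
  m
}

mha_fwd <- function(x, p, n_heads) {
  d <- dim(x); B <- d[1]; T_ <- d[2]; D <- d[3]
  dh <- D %/% n_heads
  BT <- B * T_
  X2 <- x; dim(X2) <- c(BT, D)
  Q2 <- X2 %*% p$Wq + rep(p$bq, each = BT)
  K2 <- X2 %*% p$Wk + rep(p$bk, each = BT)
  V2 <- X2 %*% p$Wv + rep(p$bv, each = BT)
  K <- K2; dim(K) <- c(B, T_, D)
  V <- V2; dim(V) <- c(B, T_, D)
  Hmask <- matrix(0, D, n_heads)
  for (h in seq_len(n_heads)) Hmask[(h - 1L) * dh + seq_len(dh), h] <- 1
  hexp <- rep(seq_len(n_heads), each = dh)
  brep <- rep(seq_len(B), T_)
  scale <- 1 / sqrt(dh)
  # scores: S3[(b,i), h, j] = scale * <Q[b,i,head h], K[b,j,head h]>
  S3 <- array(0, c(BT, n_heads, T_))
  for (j in seq_len(T_)) {
    Krep <- tok_slice(K, j, B, D)[brep, , drop = FALSE]
    S3[, , j] <- ((Q2 * Krep) %*% Hmask) * scale
  }
  S2 <- S3; dim(S2) <- c(BT * n_heads, T_)
  mx <- S2[, 1]
  for (j in seq.int(2L, length.out = T_ - 1L)) mx <- pmax(mx, S2[, j])
  E <- exp(S2 - mx)
  A2 <- E / rowSums(E)
  A3 <- A2; dim(A3) <- c(BT, n_heads, T_)
  O2 <- matrix(0, BT, D)
  for (j in seq_len(T_)) {
    Aexp <- matrix(A3[, , j], BT)[, hexp, drop = FALSE]
    Vrep <- tok_slice(V, j, B, D)[brep, , drop = FALSE]
    O2 <- O2 + Aexp * Vrep
  }
  Y2 <- O2 %*% p$Wo + rep(p$bo, each = BT)
  y <- Y2; dim(y) <- c(B, T_, D)
  list(y = y, cache = list(X2 = X2, Q2 = Q2, K = K, V = V, A2 = A2, A3 = A3,
                           O2 = O2, Hmask = Hmask, hexp = hexp, brep = brep,
                           scale = scale, B = B, T_ = T_, D = D,
                           n_heads = n_heads, p = p))
}

mha_bwd <- function(dy, cache) {
  B <- cache$B; T_ <- cache$T_; D <- cache$D
  n_heads <- cache$n_heads
  BT <- B * T_
  p <- cache$p
  hexp <- cache$hexp; Hmask <- cache$Hmask; brep <- cache$brep
  scale <- cache$scale
  K <- cache$K; V <- cache$V; Q2 <- cache$Q2; A3 <- cache$A3
  dy2 <- dy; dim(dy2) <- c(BT, D)
  dWo <- crossprod(cache$O2, dy2)
  dbo <- colSums(dy2)
  dO2 <- dy2 %*% t(p$Wo)
  dV <- array(0, c(B, T_, D))
  dA3 <- array(0, c(BT, n_heads, T_))
  for (j in seq_len(T_)) {
    Vrep <- tok_slice(V, j, B, D)[brep, , drop = FALSE]
    dA3[, , j] <- (dO2 * Vrep) %*% Hmask
    Aexp <- matrix(A3[, , j], BT)[, hexp, drop = FALSE]
    dV[, j, ] <- rowsum(dO2 * Aexp, brep, reorder = TRUE)
  }
  dA2 <- dA3; dim(dA2) <- c(BT * n_heads, T_)
  A2 <- cache$A2
  dS2 <- A2 * (dA2 - rowSums(A2 * dA2))
  dS3 <- dS2; dim(dS3) <- c(BT, n_heads, T_)
  dQ2 <- matrix(0, BT, D)
  dK <- array(0, c(B, T_, D))
  for (j in seq_len(T_)) {
    dSexp <- matrix(dS3[, , j], BT)[, hexp, drop = FALSE] * scale
    Krep <- tok_slice(K, j, B, D)[brep, , drop = FALSE]
    dQ2 <- dQ2 + dSexp * Krep
    dK[, j, ] <- rowsum(dSexp * Q2, brep, reorder = TRUE)
  }
  dK2 <- dK; dim(dK2) <- c(BT, D)
  dV2 <- dV; dim(dV2) <- c(BT, D)
  X2 <- cache$X2
  dX2 <- dQ2 %*% t(p$Wq) + dK2 %*% t(p$Wk) + dV2 %*% t(p$Wv)
  dx <- dX2; dim(dx) <- c(B, T_, D)
  list(dx = dx,
       grads = list(Wq = crossprod(X2, dQ2), bq = colSums(dQ2),
                    Wk = crossprod(X2, dK2), bk = colSums(dK2),
                    Wv = crossprod(X2, dV2), bv = colSums(dV2),
                    Wo = dWo, bo = dbo))
}

## losses --------------------------------------------------------------------

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Sparse categorical cross-entropy; y is an integer class index in 1..K.
ce_loss <- function(logits, y) {
  p <- softmax_rows(logits)
  B <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(B), y)] + eps))
  dlogits <- p
  dlogits[cbind(seq_len(B), y)] <- dlogits[cbind(seq_len(B), y)] - 1
  list(loss = loss, dlogits = dlogits / B)
}

mse_loss <- function(pred, y) {
  B <- length(y)
  r <- as.numeric(pred) - y
  list(loss = mean(r^2), dlogits = matrix(2 * r / B, ncol = 1))
}

## Adam ----------------------------------------------------------------------

adam_init <- function(params) {
  zeros <- lapply(params, function(p) array(0, dim(p) %||% length(p)))
  list(m = zeros, v = zeros, t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, clip = 5) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gn) && gn > clip) grads <- lapply(grads, function(g) g * clip / gn)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
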