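# Neural-network layer primitives: forward and backward passes as BLAS
# matrix operations. Feature maps are kept as matrices with rows indexed by
# (batch, row, col) — batch fastest, then spatial row, then spatial column —
# and one column per feature channel, so a (B, C, H, W) array corresponds to
# aperm(A, c(1, 3, 4, 2)) with dim (B*H*W, C). All layers are checked
# against finite-difference gradients in the test suite.

# --- index plumbing -------------------------------------------------------

# For every output row (b, i, j) and kernel offset (di, dj), the row of the
# padded-source that feeds it: out-of-bounds sources map to the appended
# zero row (n + 1). Injective over valid rows for a fixed offset.
.conv_offset_index <- function(B, H, W, di, dj) {
  i <- rep(rep(seq_len(H), each = B), times = W)
  j <- rep(seq_len(W), each = B * H)
  si <- i + di
  sj <- j + dj
  valid <- si >= 1 & si <= H & sj >= 1 & sj <= W
  idx <- rep(B * H * W + 1L, B * H * W)
  b <- rep_len(seq_len(B), B * H * W)
  idx[valid] <- b[valid] + B * ((si[valid] - 1L) + H * (sj[valid] - 1L))
  idx
}

# --- convolution (same padding, stride 1) ---------------------------------

# W: array (k*k, C, F) — one C x F slab per kernel offset; b: length F.
conv_fwd <- function(X, dims, W, b) {
  B <- dims[1]; H <- dims[2]; Wd <- dims[3]
  k2 <- dim(W)[1]
  k <- as.integer(sqrt(k2))
  p <- (k - 1L) %/% 2L
  nF <- dim(W)[3]
  Xz <- rbind(X, 0)
  Y <- matrix(rep(b, each = nrow(X)), nrow(X), nF)
  idx_list <- vector("list", k2)
  o <- 0L
  for (dj in -p:p) for (di in -p:p) {
    o <- o + 1L
    idx <- .conv_offset_index(B, H, Wd, di, dj)
    idx_list[[o]] <- idx
    Y <- Y + Xz[idx, , drop = FALSE] %*% W[o, , ]
  }
  list(out = Y, cache = list(X = X, dims = dims, W = W, idx = idx_list))
}

conv_bwd <- function(dY, cache) {
  X <- cache$X; W <- cache$W; idx_list <- cache$idx
  n <- nrow(X)
  k2 <- dim(W)[1]
  dW <- array(0, dim(W))
  dX <- matrix(0, n, ncol(X))
  Xz <- rbind(X, 0)
  for (o in seq_len(k2)) {
    idx <- idx_list[[o]]
    dW[o, , ] <- crossprod(Xz[idx, , drop = FALSE], dY)
    tmp <- dY %*% t(W[o, , ])
    v <- idx <= n
    ii <- idx[v]
    dX[ii, ] <- dX[ii, ] + tmp[v, , drop = FALSE]
  }
  list(dX = dX, dW = dW, db = colSums(dY))
}

# --- batch normalization (over batch x spatial rows, per feature) ---------

bn_fwd <- function(X, gamma, beta, state, training, momentum = 0.9,
                   eps = 1e-5) {
  if (training) {
    mu <- colMeans(X)
    xm <- sweep(X, 2, mu)
    v <- colMeans(xm^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
    xm <- sweep(X, 2, mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xm, 2, inv_sd, `*`)
  Y <- sweep(sweep(xhat, 2, gamma, `*`), 2, beta, `+`)
  list(out = Y, state = state,
       cache = list(xhat = xhat, xm = xm, inv_sd = inv_sd, gamma = gamma,
                    training = training))
}

bn_bwd <- function(dY, cache) {
  m <- nrow(dY)
  dxhat <- sweep(dY, 2, cache$gamma, `*`)
  if (cache$training) {
    # full backward through the batch statistics
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dX <- sweep(
      dxhat - matrix(s1 / m, m, ncol(dY), byrow = TRUE) -
        cache$xhat * matrix(s2 / m, m, ncol(dY), byrow = TRUE),
      2, cache$inv_sd, `*`)
  } else {
    dX <- sweep(dxhat, 2, cache$inv_sd, `*`)
  }
  list(dX = dX, dgamma = colSums(dY * cache$xhat), dbeta = colSums(dY))
}

relu_fwd <- function(X) {
  out <- X * (X > 0)
  list(out = out, cache = X > 0)
}

relu_bwd <- function(dY, cache) dY * cache

# --- 2x2 max pooling, stride 2 (floor semantics on odd extents) -----------

pool_fwd <- function(X, dims) {
  B <- dims[1]; H <- dims[2]; W <- dims[3]
  H2 <- H %/% 2L; W2 <- W %/% 2L
  n2 <- B * H2 * W2
  i2 <- rep(rep(seq_len(H2), each = B), times = W2)
  j2 <- rep(seq_len(W2), each = B * H2)
  b <- rep_len(seq_len(B), n2)
  idx <- vector("list", 4L)
  o <- 0L
  for (dj in 0:1) for (di in 0:1) {
    o <- o + 1L
    si <- 2L * i2 - 1L + di
    sj <- 2L * j2 - 1L + dj
    idx[[o]] <- b + B * ((si - 1L) + H * (sj - 1L))
  }
  Y <- X[idx[[1]], , drop = FALSE]
  sel <- matrix(1L, n2, ncol(X))
  for (o in 2:4) {
    cand <- X[idx[[o]], , drop = FALSE]
    better <- cand > Y            # strict: first maximum wins
    Y[better] <- cand[better]
    sel[better] <- o
  }
  list(out = Y, dims_out = c(B, H2, W2),
       cache = list(idx = idx, sel = sel, n_in = nrow(X), n_feat = ncol(X)))
}

pool_bwd <- function(dY, cache) {
  dX <- matrix(0, cache$n_in, cache$n_feat)
  for (o in 1:4) {
    mask <- cache$sel == o
    tmp <- dY * mask
    ii <- cache$idx[[o]]
    dX[ii, ] <- dX[ii, ] + tmp
  }
  dX
}

# --- dense ----------------------------------------------------------------

dense_fwd <- function(X, W, b) {
  list(out = sweep(X %*% W, 2, b, `+`), cache = X)
}

dense_bwd <- function(dY, cache, W) {
  list(dX = dY %*% t(W), dW = crossprod(cache, dY), db = colSums(dY))
}

# --- inverted dropout -----------------------------------------------------

dropout_fwd <- function(X, p, training) {
  if (!training || p <= 0) {
    return(list(out = X, cache = NULL))
  }
  mask <- matrix(stats::runif(length(X)) >= p, nrow(X), ncol(X)) / (1 - p)
  list(out = X * mask, cache = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache)) dY else dY * cache
}

# --- LSTM -----------------------------------------------------------------

.sigmoid <- function(x) 1 / (1 + exp(-x))

# X: array (B, N, M) consumed column-by-column in time order.
# Wx: N x 4H, Wh: H x 4H, b: 4H; gate order [input, forget, cell, output].
# Returns the final hidden state (B x H).
lstm_fwd <- function(X, Wx, Wh, b, keep_cache = TRUE) {
  B <- dim(X)[1]; M <- dim(X)[3]
  Hn <- ncol(Wh) / 4L
  h <- matrix(0, B, Hn)
  cc <- matrix(0, B, Hn)
  gi <- seq_len(Hn); gf <- Hn + gi; gg <- 2L * Hn + gi; go <- 3L * Hn + gi
  cache <- if (keep_cache) vector("list", M) else NULL
  bmat <- matrix(b, B, 4L * Hn, byrow = TRUE)
  for (t in seq_len(M)) {
    xt <- X[, , t, drop = FALSE]
    dim(xt) <- c(B, dim(X)[2])
    Z <- xt %*% Wx + h %*% Wh + bmat
    i <- .sigmoid(Z[, gi, drop = FALSE])
    f <- .sigmoid(Z[, gf, drop = FALSE])
    g <- tanh(Z[, gg, drop = FALSE])
    o <- .sigmoid(Z[, go, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h_prev <- h
    h <- o * tc
    if (keep_cache) {
      cache[[t]] <- list(xt = xt, h_prev = h_prev, c_prev = c_prev,
                         i = i, f = f, g = g, o = o, tc = tc)
    }
  }
  list(out = h, cache = list(steps = cache, Wx = Wx, Wh = Wh, dims = dim(X)))
}

# dH: gradient wrt the final hidden state. Returns dX only when requested
# (needed for the sequential CNN-LSTM wiring, not for raw-input branches).
lstm_bwd <- function(dH, cache, need_dx = FALSE) {
  Wx <- cache$Wx; Wh <- cache$Wh
  dims <- cache$dims
  B <- dims[1]; M <- dims[3]
  Hn <- ncol(Wh) / 4L
  dWx <- matrix(0, nrow(Wx), 4L * Hn)
  dWh <- matrix(0, Hn, 4L * Hn)
  db <- numeric(4L * Hn)
  dX <- if (need_dx) array(0, dims) else NULL
  dh <- dH
  dc <- matrix(0, B, Hn)
  for (t in rev(seq_len(M))) {
    st <- cache$steps[[t]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$c_prev
    dg <- dc * st$i
    dZ <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$xt, dZ)
    dWh <- dWh + crossprod(st$h_prev, dZ)
    db <- db + colSums(dZ)
    dh <- dZ %*% t(Wh)
    dc <- dc * st$f
    if (need_dx) dX[, , t] <- dZ %*% t(Wx)
  }
  list(dWx = dWx, dWh = dWh, db = db, dX = dX)
}

# --- softmax + cross-entropy ----------------------------------------------

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

# y: integer class labels in {0, 1} (column y+1 of the logits is the true
# class). Returns mean loss and the gradient wrt logits.
softmax_ce <- function(logits, y) {
  P <- softmax_rows(logits)
  n <- nrow(P)
  eps <- 1e-12
  idx <- cbind(seq_len(n), y + 1L)
  loss <- -mean(log(pmax(P[idx], eps)))
  dZ <- P
  dZ[idx] <- dZ[idx] - 1
  list(loss = loss, probs = P, dlogits = dZ / n)
}

# --- initialisation -------------------------------------------------------

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}
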