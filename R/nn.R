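# Neural-network primitives. Every layer is a pure function pair:
# forward(x, params) -> list(out, cache); backward(dout, cache) -> gradients
# including dx. The internal array layout is channels x time x batch (CTB):
# with column-major storage this makes im2col, batch/layer normalization and
# the attention slices contiguous reshapes, so all heavy lifting lands in
# BLAS matrix multiplications. Public model functions convert from/to the
# batch-first layout at the boundary. Verified against finite differences in
# the test suite.

# ---- convolution -----------------------------------------------------------

# 1-D convolution, same padding. x: C x T x B; W: F x (C*k) with column
# index (j within kernel, fastest) + (c-1)*k; b: length F. The im2col +
# matrix-multiply kernels live in src/nn_kernels.cpp.
nn_conv1d_forward <- function(x, W, b) {
  if (ncol(W) %% dim(x)[1] != 0)
    stopf("conv weight shape inconsistent with input channels")
  list(out = cpp_conv1d_forward(x, W, b), cache = list(x = x, W = W))
}

nn_conv1d_backward <- function(dout, cache) {
  r <- cpp_conv1d_backward(dout, cache$x, cache$W)
  r$db <- as.numeric(r$db)
  r
}

# ---- pooling ---------------------------------------------------------------

nn_maxpool2_forward <- function(x) {
  d <- dim(x)
  if (d[2] < 2) stopf("max-pool would shrink the time axis below 1 (T=%d)", d[2])
  r <- cpp_maxpool2_forward(x)
  list(out = r$out, cache = list(mask = r$mask, d = d))
}

nn_maxpool2_backward <- function(dout, cache) {
  cpp_maxpool2_backward(dout, cache$mask, cache$d[2])
}

# global average pool over time: C x T x B -> C x B
nn_gap_forward <- function(x) {
  d <- dim(x)
  out <- vapply(seq_len(d[3]),
                function(b) rowMeans(array(x[, , b], d[1:2])), numeric(d[1]))
  list(out = matrix(out, d[1], d[3]), cache = d)
}

nn_gap_backward <- function(dout, cache) {
  d <- cache
  aperm(array(dout / d[2], c(d[1], d[3], d[2])), c(1, 3, 2))
}

# ---- normalization ---------------------------------------------------------

# batch normalization per feature channel over (time, batch)
nn_bn_forward <- function(x, gamma, beta, running, training,
                          momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  xm <- matrix(x, d[1], d[2] * d[3])     # C x (T*B)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm^2) - mu^2
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean; v <- running$var
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- (xm - mu) * istd               # column recycling over rows = C
  ym <- xhat * gamma + beta
  dim(ym) <- d
  list(out = ym, running = running,
       cache = list(xhat = xhat, istd = istd, gamma = gamma, d = d,
                    training = training))
}

nn_bn_backward <- function(dout, cache) {
  d <- cache$d; N <- d[2] * d[3]
  dy <- matrix(dout, d[1], N)
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  if (cache$training) {
    s1 <- rowSums(dxhat)
    s2 <- rowSums(dxhat * cache$xhat)
    dxm <- (dxhat - s1 / N - cache$xhat * (s2 / N)) * cache$istd
  } else {
    dxm <- dxhat * cache$istd
  }
  dim(dxm) <- d
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

# layer normalization over the feature-channel axis, per (time, batch)
nn_ln_forward <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x); C <- d[1]
  xm <- matrix(x, C, d[2] * d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  istd <- 1 / sqrt(v + eps)
  xhat <- t((t(xm) - mu) * istd)
  ym <- xhat * gamma + beta
  dim(ym) <- d
  list(out = ym, cache = list(xhat = xhat, istd = istd, gamma = gamma, d = d))
}

nn_ln_backward <- function(dout, cache) {
  d <- cache$d; C <- d[1]
  dy <- matrix(dout, C, d[2] * d[3])
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dxhat <- dy * cache$gamma
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dxm <- t((t(dxhat) - s1 / C) - t(cache$xhat) * (s2 / C)) *
    rep(cache$istd, each = C)
  dim(dxm) <- d
  list(dx = dxm, dgamma = dgamma, dbeta = dbeta)
}

# ---- activations -----------------------------------------------------------

# GELU, tanh approximation (standard in deep-learning frameworks); the
# cached tanh term is reused by the backward pass (src/nn_kernels.cpp)
nn_gelu_forward <- function(x) {
  r <- cpp_gelu_forward(x)
  list(out = r$out, cache = list(x = x, th = r$th))
}

nn_gelu_backward <- function(dout, cache) {
  cpp_gelu_backward(dout, cache$x, cache$th)
}

nn_relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)
nn_relu_backward <- function(dout, cache) dout * cache

nn_sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- dense -----------------------------------------------------------------

# x: B x D; W: D x H; b: length H
nn_dense_forward <- function(x, W, b) {
  out <- x %*% W
  out <- sweep(out, 2, b, `+`)
  list(out = out, cache = list(x = x, W = W))
}

nn_dense_backward <- function(dout, cache) {
  list(dx = tcrossprod(dout, cache$W), dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# ---- dropout ---------------------------------------------------------------

nn_dropout_forward <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, cache = NULL))
  mask <- array(stats::runif(length(x)) >= rate, dim(x)) / (1 - rate)
  list(out = x * mask, cache = mask)
}

nn_dropout_backward <- function(dout, cache) {
  if (is.null(cache)) dout else dout * cache
}

# ---- softmax / cross-entropy ----------------------------------------------

nn_softmax <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# y: one-hot matrix, same shape as probs; returns loss and dlogits
nn_ce_loss <- function(probs, y) {
  B <- nrow(probs)
  loss <- -mean(log(rowSums(probs * y) + 1e-12))
  list(loss = loss, dlogits = (probs - y) / B)
}

# ---- scaled dot-product self-attention over time ---------------------------

# x: C x T x B. Single head, dimension C. Weights Wq/Wk/Wv/Wo: C x C.
# Per-sample attention maps and projections are computed in C++
# (src/nn_kernels.cpp); attention rows (per query position) sum to 1.
nn_attention_forward <- function(x, Wq, Wk, Wv, Wo) {
  r <- cpp_attention_forward(x, Wq, Wk, Wv, Wo)
  list(out = r$out, attn = r$attn,
       cache = list(x = x, Q = r$Q, K = r$K, V = r$V, O = r$O, attn = r$attn,
                    Wq = Wq, Wk = Wk, Wv = Wv, Wo = Wo))
}

nn_attention_backward <- function(dout, cache) {
  cpp_attention_backward(dout, cache$x, cache$Q, cache$K, cache$V, cache$O,
                         cache$attn, cache$Wq, cache$Wk, cache$Wv, cache$Wo)
}

# ---- LSTM ------------------------------------------------------------------

# x: D x T x B sequence; returns last hidden state (B x H).
# Gate order [i, f, g, o].
nn_lstm_forward <- function(x, Wx, Wh, b) {
  d <- dim(x); D <- d[1]; Tt <- d[2]; B <- d[3]
  H <- nrow(Wh)
  h <- matrix(0, B, H); cst <- matrix(0, B, H)
  steps <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    xt <- t(matrix(x[, t, ], D, B))      # B x D
    a <- xt %*% Wx + h %*% Wh
    a <- sweep(a, 2, b, `+`)
    i <- nn_sigmoid(a[, 1:H, drop = FALSE])
    f <- nn_sigmoid(a[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(a[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- nn_sigmoid(a[, (3 * H + 1):(4 * H), drop = FALSE])
    c_new <- f * cst + i * g
    tc <- tanh(c_new)
    steps[[t]] <- list(xt = xt, hprev = h, cprev = cst, i = i, f = f, g = g,
                       o = o, tc = tc)
    cst <- c_new
    h <- o * tc
  }
  list(out = h, cache = list(steps = steps, Wx = Wx, Wh = Wh, d = d, H = H))
}

nn_lstm_backward <- function(dh_last, cache) {
  d <- cache$d; D <- d[1]; Tt <- d[2]; B <- d[3]; H <- cache$H
  dWx <- matrix(0, D, 4 * H); dWh <- matrix(0, H, 4 * H); db <- numeric(4 * H)
  dx <- array(0, d)
  dh <- dh_last
  dc <- matrix(0, B, H)
  for (t in rev(seq_len(Tt))) {
    st <- cache$steps[[t]]
    do_ <- dh * st$tc
    dc <- dc + dh * st$o * (1 - st$tc^2)
    di <- dc * st$g
    df <- dc * st$cprev
    dg <- dc * st$i
    da <- cbind(di * st$i * (1 - st$i),
                df * st$f * (1 - st$f),
                dg * (1 - st$g^2),
                do_ * st$o * (1 - st$o))
    dWx <- dWx + crossprod(st$xt, da)
    dWh <- dWh + crossprod(st$hprev, da)
    db <- db + colSums(da)
    dx[, t, ] <- t(tcrossprod(da, cache$Wx))
    dh <- tcrossprod(da, cache$Wh)
    dc <- dc * st$f
  }
  list(dx = dx, dWx = dWx, dWh = dWh, db = db)
}

# ---- parameter-tree helpers ------------------------------------------------

# apply f(leaf_a, leaf_b) over two parallel nested lists of numerics
tree_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- mapply(tree_map2, a, b, MoreArgs = list(f = f), SIMPLIFY = FALSE)
    names(out) <- names(a)
    out
  } else f(a, b)
}

tree_map <- function(a, f) {
  if (is.list(a)) {
    out <- lapply(a, tree_map, f = f)
    names(out) <- names(a)
    out
  } else f(a)
}

# flatten leaves into a named list (used by tests/diagnostics)
tree_leaf_apply <- function(a, f, prefix = "") {
  if (is.list(a)) {
    res <- list()
    for (nm in names(a))
      res <- c(res, tree_leaf_apply(a[[nm]], f,
                                    paste0(prefix, if (nzchar(prefix)) "." else "", nm)))
    res
  } else {
    stats::setNames(list(f(a)), prefix)
  }
}

n_params <- function(params)
  sum(unlist(tree_leaf_apply(params, length)))
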