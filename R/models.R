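# The two classifier architectures. Public inputs are batches of
# band-filtered 4-s epochs (batch x channels x samples); outputs are class
# probabilities. Internally arrays are channels x time x batch (see nn.R).
#
# MRCNN-RSE: two parallel convolution branches (kernels 4-3-3 and 10-3-3,
# three conv layers + two max-pools each, batch normalization + GELU),
# channel concatenation, a residual squeeze-and-excitation block, scaled
# dot-product self-attention over time with two add-and-normalize stages,
# global average pooling and a softmax head.
#
# MRCNN-LSTM: three parallel convolution branches with small/medium/large
# kernels (ReLU), concatenation, an LSTM over the pooled time axis, a fully
# connected layer with dropout, and a softmax head.

#' Model specification
#'
#' Hyperparameters of the two architectures. Defaults keep the networks
#' under one million parameters and CPU-trainable; `conv_filters` may be
#' reduced (e.g. `c(8, 8, 8)`) for scaled-down runs.
#'
#' @param architecture `"mrcnn_rse"` or `"mrcnn_lstm"`.
#' @param in_channels input channels (default 6).
#' @param in_samples samples per epoch (default 500 = 4 s at 125 Hz).
#' @param conv_filters filters of the three conv layers per branch.
#' @param rse_branch_kernels kernel sizes of the two MRCNN-RSE branches.
#' @param lstm_branch_kernels first-layer kernel sizes of the three
#'   MRCNN-LSTM branches (each branch continues with a kernel-3 layer).
#' @param se_reduction squeeze-and-excitation bottleneck ratio; must divide
#'   the concatenated feature count.
#' @param lstm_hidden LSTM hidden units.
#' @param dropout_rate dropout probability in `[0, 1)` (MRCNN-LSTM head).
#' @param n_classes number of output classes (2).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(architecture = c("mrcnn_rse", "mrcnn_lstm"),
                       in_channels = 6, in_samples = 500,
                       conv_filters = c(32, 64, 64),
                       rse_branch_kernels = list(c(4, 3, 3), c(10, 3, 3)),
                       lstm_branch_kernels = c(3, 5, 11),
                       se_reduction = 8, lstm_hidden = 64,
                       dropout_rate = 0.5, n_classes = 2) {
  architecture <- match.arg(architecture)
  if (!is_count(in_channels) || !is_count(in_samples))
    stopf("`in_channels` and `in_samples` must be positive integers")
  if (length(conv_filters) != 3 || !all(vapply(conv_filters, is_count, logical(1))))
    stopf("`conv_filters` must be three positive integers")
  if (!is_number(dropout_rate) || dropout_rate < 0 || dropout_rate >= 1)
    stopf("`dropout_rate` must be in [0, 1)")
  kerns <- if (architecture == "mrcnn_rse") unlist(rse_branch_kernels)
           else lstm_branch_kernels
  if (any(kerns < 1) || any(kerns > in_samples))
    stopf("kernel sizes must be in [1, in_samples]")

  # simulate the temporal schedule (two max-pools per branch) and fail at
  # build time if it degenerates
  t_mid <- in_samples %/% 2
  if (t_mid < 1) stopf("first max-pool shrinks the time axis below 1")
  t_final <- t_mid %/% 2
  min_t <- if (architecture == "mrcnn_rse") 4 else 2
  if (t_final < min_t)
    stopf("after the branch pooling schedule the time axis is %d (< %d): in_samples=%d is too short for this architecture",
          t_final, min_t, in_samples)

  c0 <- if (architecture == "mrcnn_rse") 2 * conv_filters[3]
        else 3 * conv_filters[2]
  if (architecture == "mrcnn_rse") {
    if (!is_count(se_reduction) || c0 %% se_reduction != 0)
      stopf("`se_reduction` [%s] must divide the concatenated feature count [%d]",
            se_reduction, c0)
  }
  structure(list(architecture = architecture, in_channels = in_channels,
                 in_samples = in_samples, conv_filters = conv_filters,
                 rse_branch_kernels = rse_branch_kernels,
                 lstm_branch_kernels = lstm_branch_kernels,
                 se_reduction = se_reduction, lstm_hidden = lstm_hidden,
                 dropout_rate = dropout_rate, n_classes = n_classes,
                 t_final = t_final, concat_features = c0),
            class = "model_spec")
}

.init_conv <- function(f, c, k) {
  list(W = matrix(stats::rnorm(f * c * k, 0, sqrt(2 / (c * k))), f, c * k),
       b = numeric(f))
}

.init_dense <- function(d, h, scale = NULL) {
  if (is.null(scale)) scale <- sqrt(2 / d)
  list(W = matrix(stats::rnorm(d * h, 0, scale), d, h), b = numeric(h))
}

.init_params_rse <- function(spec) {
  fs <- spec$conv_filters
  c0 <- spec$concat_features
  branch <- function(ks) list(
    conv1 = .init_conv(fs[1], spec$in_channels, ks[1]),
    bn1 = list(gamma = rep(1, fs[1]), beta = numeric(fs[1])),
    conv2 = .init_conv(fs[2], fs[1], ks[2]),
    bn2 = list(gamma = rep(1, fs[2]), beta = numeric(fs[2])),
    conv3 = .init_conv(fs[3], fs[2], ks[3]),
    bn3 = list(gamma = rep(1, fs[3]), beta = numeric(fs[3])))
  nb <- c0 %/% spec$se_reduction
  list(
    branch1 = branch(spec$rse_branch_kernels[[1]]),
    branch2 = branch(spec$rse_branch_kernels[[2]]),
    rse = list(convA = .init_conv(c0, c0, 1), convB = .init_conv(c0, c0, 1),
               fc1 = .init_dense(c0, nb), fc2 = .init_dense(nb, c0)),
    attn = list(Wq = matrix(stats::rnorm(c0 * c0, 0, sqrt(1 / c0)), c0, c0),
                Wk = matrix(stats::rnorm(c0 * c0, 0, sqrt(1 / c0)), c0, c0),
                Wv = matrix(stats::rnorm(c0 * c0, 0, sqrt(1 / c0)), c0, c0),
                Wo = matrix(stats::rnorm(c0 * c0, 0, sqrt(1 / c0)), c0, c0),
                ln1 = list(gamma = rep(1, c0), beta = numeric(c0)),
                ff1 = .init_conv(c0, c0, 1), ff2 = .init_conv(c0, c0, 1),
                ln2 = list(gamma = rep(1, c0), beta = numeric(c0))),
    head = .init_dense(c0, spec$n_classes, scale = sqrt(1 / c0)))
}

.init_state_rse <- function(spec) {
  fs <- spec$conv_filters
  bn <- function(f) list(mean = numeric(f), var = rep(1, f))
  br <- function() list(bn1 = bn(fs[1]), bn2 = bn(fs[2]), bn3 = bn(fs[3]))
  list(branch1 = br(), branch2 = br())
}

.init_params_lstm <- function(spec) {
  fs <- spec$conv_filters
  c0 <- spec$concat_features
  H <- spec$lstm_hidden
  branch <- function(k) list(
    conv1 = .init_conv(fs[1], spec$in_channels, k),
    conv2 = .init_conv(fs[2], fs[1], 3))
  b_lstm <- numeric(4 * H)
  b_lstm[(H + 1):(2 * H)] <- 1          # forget-gate bias
  list(
    branch1 = branch(spec$lstm_branch_kernels[1]),
    branch2 = branch(spec$lstm_branch_kernels[2]),
    branch3 = branch(spec$lstm_branch_kernels[3]),
    lstm = list(Wx = matrix(stats::rnorm(c0 * 4 * H, 0, sqrt(1 / c0)), c0, 4 * H),
                Wh = matrix(stats::rnorm(H * 4 * H, 0, sqrt(1 / H)), H, 4 * H),
                b = b_lstm),
    fc = .init_dense(H, H),
    head = .init_dense(H, spec$n_classes, scale = sqrt(1 / H)))
}

#' Build a model
#'
#' Instantiates the architecture with seeded random initial parameters;
#' identical spec + seed gives identical parameters.
#'
#' @param spec a [model_spec()].
#' @param seed initialization seed.
#' @return An object of class `eeg_model` with elements `spec`, `params`,
#'   `state` (batch-norm running statistics), `classes` and `scaler`.
#' @export
build_model <- function(spec, seed = 1) {
  if (!inherits(spec, "model_spec")) stopf("`spec` must be a model_spec")
  params <- local_seed(seed, {
    if (spec$architecture == "mrcnn_rse") .init_params_rse(spec)
    else .init_params_lstm(spec)
  })
  state <- if (spec$architecture == "mrcnn_rse") .init_state_rse(spec) else list()
  structure(list(spec = spec, params = params, state = state,
                 classes = c("DD", "HC"), scaler = NULL, seed = seed),
            class = "eeg_model")
}

#' @export
print.eeg_model <- function(x, ...) {
  cat(sprintf("<eeg_model> %s: %d x %d input, %d parameters%s\n",
              x$spec$architecture, x$spec$in_channels, x$spec$in_samples,
              n_params(x$params),
              if (is.null(x$scaler)) " (untrained)" else " (trained)"))
  invisible(x)
}

.check_batch <- function(spec, x) {
  if (!is.array(x) || length(dim(x)) != 3 ||
      dim(x)[2] != spec$in_channels || dim(x)[3] != spec$in_samples)
    stopf("batch shape expected [*, %d, %d], got [%s]",
          spec$in_channels, spec$in_samples, paste(dim(x), collapse = ", "))
}

# batch-first (B,C,T) -> internal (C,T,B) and back
.to_ctb <- function(x) aperm(x, c(2, 3, 1))
.to_bct <- function(x) aperm(x, c(3, 1, 2))

# ---- MRCNN-RSE forward/backward -------------------------------------------

.rse_branch_forward <- function(x, p, s, training) {
  cc <- list()
  c1 <- nn_conv1d_forward(x, p$conv1$W, p$conv1$b); cc$c1 <- c1$cache
  b1 <- nn_bn_forward(c1$out, p$bn1$gamma, p$bn1$beta, s$bn1, training)
  cc$b1 <- b1$cache; s$bn1 <- b1$running
  g1 <- nn_gelu_forward(b1$out); cc$g1 <- g1$cache
  p1 <- nn_maxpool2_forward(g1$out); cc$p1 <- p1$cache
  c2 <- nn_conv1d_forward(p1$out, p$conv2$W, p$conv2$b); cc$c2 <- c2$cache
  b2 <- nn_bn_forward(c2$out, p$bn2$gamma, p$bn2$beta, s$bn2, training)
  cc$b2 <- b2$cache; s$bn2 <- b2$running
  g2 <- nn_gelu_forward(b2$out); cc$g2 <- g2$cache
  c3 <- nn_conv1d_forward(g2$out, p$conv3$W, p$conv3$b); cc$c3 <- c3$cache
  b3 <- nn_bn_forward(c3$out, p$bn3$gamma, p$bn3$beta, s$bn3, training)
  cc$b3 <- b3$cache; s$bn3 <- b3$running
  g3 <- nn_gelu_forward(b3$out); cc$g3 <- g3$cache
  p2 <- nn_maxpool2_forward(g3$out); cc$p2 <- p2$cache
  list(out = p2$out, cache = cc, state = s)
}

.rse_branch_backward <- function(dout, p, cc) {
  d <- nn_maxpool2_backward(dout, cc$p2)
  d <- nn_gelu_backward(d, cc$g3)
  b3 <- nn_bn_backward(d, cc$b3)
  c3 <- nn_conv1d_backward(b3$dx, cc$c3)
  d <- nn_gelu_backward(c3$dx, cc$g2)
  b2 <- nn_bn_backward(d, cc$b2)
  c2 <- nn_conv1d_backward(b2$dx, cc$c2)
  d <- nn_maxpool2_backward(c2$dx, cc$p1)
  d <- nn_gelu_backward(d, cc$g1)
  b1 <- nn_bn_backward(d, cc$b1)
  c1 <- nn_conv1d_backward(b1$dx, cc$c1)
  list(dx = c1$dx,
       grads = list(conv1 = list(W = c1$dW, b = c1$db),
                    bn1 = list(gamma = b1$dgamma, beta = b1$dbeta),
                    conv2 = list(W = c2$dW, b = c2$db),
                    bn2 = list(gamma = b2$dgamma, beta = b2$dbeta),
                    conv3 = list(W = c3$dW, b = c3$db),
                    bn3 = list(gamma = b3$dgamma, beta = b3$dbeta)))
}

# residual squeeze-and-excitation on a feature map z (C x T x B)
.rse_block_forward <- function(z, p) {
  cc <- list()
  a <- nn_conv1d_forward(z, p$convA$W, p$convA$b); cc$a <- a$cache
  ga <- nn_gelu_forward(a$out); cc$ga <- ga$cache
  u <- nn_conv1d_forward(ga$out, p$convB$W, p$convB$b); cc$u <- u$cache
  sq <- nn_gap_forward(u$out); cc$sq <- sq$cache       # C x B
  f1 <- nn_dense_forward(t(sq$out), p$fc1$W, p$fc1$b); cc$f1 <- f1$cache
  r1 <- nn_relu_forward(f1$out); cc$r1 <- r1$cache
  f2 <- nn_dense_forward(r1$out, p$fc2$W, p$fc2$b); cc$f2 <- f2$cache
  g <- nn_sigmoid(f2$out)                              # B x C gates in (0,1)
  d <- dim(u$out)
  gb <- aperm(array(t(g), c(d[1], d[3], d[2])), c(1, 3, 2))
  out <- u$out * gb + z
  cc$g <- g; cc$u_out <- u$out; cc$gb <- gb; cc$d <- d
  list(out = out, gates = g, cache = cc)
}

.rse_block_backward <- function(dout, p, cc) {
  d <- cc$d
  du <- dout * cc$gb
  prod <- dout * cc$u_out
  dg_cb <- vapply(seq_len(d[3]),
                  function(b) rowSums(array(prod[, , b], d[1:2])),
                  numeric(d[1]))                       # C x B
  dg <- t(matrix(dg_cb, d[1], d[3]))                   # B x C
  dpre2 <- dg * cc$g * (1 - cc$g)
  f2 <- nn_dense_backward(dpre2, cc$f2)
  dr1 <- nn_relu_backward(f2$dx, cc$r1)
  f1 <- nn_dense_backward(dr1, cc$f1)
  du <- du + nn_gap_backward(t(f1$dx), cc$sq)
  ub <- nn_conv1d_backward(du, cc$u)
  dga <- nn_gelu_backward(ub$dx, cc$ga)
  ab <- nn_conv1d_backward(dga, cc$a)
  list(dx = ab$dx + dout,
       grads = list(convA = list(W = ab$dW, b = ab$db),
                    convB = list(W = ub$dW, b = ub$db),
                    fc1 = list(W = f1$dW, b = f1$db),
                    fc2 = list(W = f2$dW, b = f2$db)))
}

# self-attention with two add-and-normalize stages
.attn_block_forward <- function(y, p) {
  cc <- list()
  at <- nn_attention_forward(y, p$Wq, p$Wk, p$Wv, p$Wo); cc$at <- at$cache
  l1 <- nn_ln_forward(y + at$out, p$ln1$gamma, p$ln1$beta); cc$l1 <- l1$cache
  h1 <- nn_conv1d_forward(l1$out, p$ff1$W, p$ff1$b); cc$h1 <- h1$cache
  gh <- nn_gelu_forward(h1$out); cc$gh <- gh$cache
  h2 <- nn_conv1d_forward(gh$out, p$ff2$W, p$ff2$b); cc$h2 <- h2$cache
  l2 <- nn_ln_forward(l1$out + h2$out, p$ln2$gamma, p$ln2$beta); cc$l2 <- l2$cache
  list(out = l2$out, attn = at$attn, cache = cc)
}

.attn_block_backward <- function(dout, p, cc) {
  l2 <- nn_ln_backward(dout, cc$l2)
  h2 <- nn_conv1d_backward(l2$dx, cc$h2)
  dgh <- nn_gelu_backward(h2$dx, cc$gh)
  h1 <- nn_conv1d_backward(dgh, cc$h1)
  dl1 <- l2$dx + h1$dx
  l1 <- nn_ln_backward(dl1, cc$l1)
  at <- nn_attention_backward(l1$dx, cc$at)
  list(dx = l1$dx + at$dx,
       grads = list(Wq = at$dWq, Wk = at$dWk, Wv = at$dWv, Wo = at$dWo,
                    ln1 = list(gamma = l1$dgamma, beta = l1$dbeta),
                    ff1 = list(W = h1$dW, b = h1$db),
                    ff2 = list(W = h2$dW, b = h2$db),
                    ln2 = list(gamma = l2$dgamma, beta = l2$dbeta)))
}

.forward_rse <- function(spec, params, state, x, training) {
  br1 <- .rse_branch_forward(x, params$branch1, state$branch1, training)
  br2 <- .rse_branch_forward(x, params$branch2, state$branch2, training)
  state$branch1 <- br1$state; state$branch2 <- br2$state
  d1 <- dim(br1$out)
  z <- array(0, c(2 * d1[1], d1[2], d1[3]))
  z[1:d1[1], , ] <- br1$out
  z[(d1[1] + 1):(2 * d1[1]), , ] <- br2$out
  rse <- .rse_block_forward(z, params$rse)
  att <- .attn_block_forward(rse$out, params$attn)
  gp <- nn_gap_forward(att$out)
  hd <- nn_dense_forward(t(gp$out), params$head$W, params$head$b)
  probs <- nn_softmax(hd$out)
  list(probs = probs, state = state,
       cache = list(br1 = br1$cache, br2 = br2$cache, rse = rse$cache,
                    att = att$cache, gp = gp$cache, hd = hd$cache,
                    nf = d1[1]),
       features = z, rse_out = rse$out, gates = rse$gates, attn = att$attn)
}

.backward_rse <- function(spec, params, cache, dlogits) {
  hd <- nn_dense_backward(dlogits, cache$hd)
  datt <- nn_gap_backward(t(hd$dx), cache$gp)
  att <- .attn_block_backward(datt, params$attn, cache$att)
  rse <- .rse_block_backward(att$dx, params$rse, cache$rse)
  nf <- cache$nf
  d1 <- .rse_branch_backward(rse$dx[1:nf, , , drop = FALSE],
                             params$branch1, cache$br1)
  d2 <- .rse_branch_backward(rse$dx[(nf + 1):(2 * nf), , , drop = FALSE],
                             params$branch2, cache$br2)
  list(branch1 = d1$grads, branch2 = d2$grads, rse = rse$grads,
       attn = att$grads, head = list(W = hd$dW, b = hd$db))
}

# ---- MRCNN-LSTM forward/backward ------------------------------------------

.lstm_branch_forward <- function(x, p) {
  cc <- list()
  c1 <- nn_conv1d_forward(x, p$conv1$W, p$conv1$b); cc$c1 <- c1$cache
  r1 <- nn_relu_forward(c1$out); cc$r1 <- r1$cache
  p1 <- nn_maxpool2_forward(r1$out); cc$p1 <- p1$cache
  c2 <- nn_conv1d_forward(p1$out, p$conv2$W, p$conv2$b); cc$c2 <- c2$cache
  r2 <- nn_relu_forward(c2$out); cc$r2 <- r2$cache
  p2 <- nn_maxpool2_forward(r2$out); cc$p2 <- p2$cache
  list(out = p2$out, cache = cc)
}

.lstm_branch_backward <- function(dout, cc) {
  d <- nn_maxpool2_backward(dout, cc$p2)
  d <- nn_relu_backward(d, cc$r2)
  c2 <- nn_conv1d_backward(d, cc$c2)
  d <- nn_maxpool2_backward(c2$dx, cc$p1)
  d <- nn_relu_backward(d, cc$r1)
  c1 <- nn_conv1d_backward(d, cc$c1)
  list(dx = c1$dx,
       grads = list(conv1 = list(W = c1$dW, b = c1$db),
                    conv2 = list(W = c2$dW, b = c2$db)))
}

.forward_lstm <- function(spec, params, state, x, training) {
  br <- lapply(1:3, function(i)
    .lstm_branch_forward(x, params[[paste0("branch", i)]]))
  d1 <- dim(br[[1]]$out)
  z <- array(0, c(3 * d1[1], d1[2], d1[3]))
  for (i in 1:3) z[((i - 1) * d1[1] + 1):(i * d1[1]), , ] <- br[[i]]$out
  ls <- nn_lstm_forward(z, params$lstm$Wx, params$lstm$Wh, params$lstm$b)
  fc <- nn_dense_forward(ls$out, params$fc$W, params$fc$b)
  rl <- nn_relu_forward(fc$out)
  dp <- nn_dropout_forward(rl$out, spec$dropout_rate, training)
  hd <- nn_dense_forward(dp$out, params$head$W, params$head$b)
  probs <- nn_softmax(hd$out)
  list(probs = probs, state = state,
       cache = list(br = lapply(br, `[[`, "cache"), ls = ls$cache,
                    fc = fc$cache, rl = rl$cache, dp = dp$cache,
                    hd = hd$cache, nf = d1[1]),
       features = z)
}

.backward_lstm <- function(spec, params, cache, dlogits) {
  hd <- nn_dense_backward(dlogits, cache$hd)
  ddp <- nn_dropout_backward(hd$dx, cache$dp)
  drl <- nn_relu_backward(ddp, cache$rl)
  fc <- nn_dense_backward(drl, cache$fc)
  ls <- nn_lstm_backward(fc$dx, cache$ls)
  nf <- cache$nf
  g <- list()
  for (i in 1:3) {
    bb <- .lstm_branch_backward(
      ls$dx[((i - 1) * nf + 1):(i * nf), , , drop = FALSE], cache$br[[i]])
    g[[paste0("branch", i)]] <- bb$grads
  }
  c(g, list(lstm = list(Wx = ls$dWx, Wh = ls$dWh, b = ls$db),
            fc = list(W = fc$dW, b = fc$db),
            head = list(W = hd$dW, b = hd$db)))
}

# ---- public model surface --------------------------------------------------

#' Forward pass: class probabilities
#'
#' Runs the model on a batch in evaluation mode (training mode enables
#' dropout and batch statistics and is used internally by [train_model()]).
#'
#' @param model a [build_model()] result.
#' @param x batch array, batch x in_channels x in_samples. The model's
#'   stored standardization (if trained) is applied.
#' @param training logical; training-mode forward.
#' @return Matrix of class probabilities (rows sum to 1), columns named by
#'   `model$classes`.
#' @export
predict_proba <- function(model, x, training = FALSE) {
  .check_batch(model$spec, x)
  x <- .apply_scaler(model, x)
  fw <- .model_forward(model$spec, model$params, model$state,
                       .to_ctb(x), training)
  colnames(fw$probs) <- model$classes
  fw$probs
}

.model_forward <- function(spec, params, state, x, training) {
  if (spec$architecture == "mrcnn_rse") .forward_rse(spec, params, state, x, training)
  else .forward_lstm(spec, params, state, x, training)
}

.model_backward <- function(spec, params, cache, dlogits) {
  if (spec$architecture == "mrcnn_rse") .backward_rse(spec, params, cache, dlogits)
  else .backward_lstm(spec, params, cache, dlogits)
}

.apply_scaler <- function(model, x) {
  if (is.null(model$scaler)) return(x)
  for (ch in seq_len(dim(x)[2]))
    x[, ch, ] <- (x[, ch, ] - model$scaler$mean[ch]) / model$scaler$sd[ch]
  x
}

#' Multi-resolution CNN feature maps
#'
#' Runs only the parallel convolution branches of either architecture and
#' returns the concatenated feature map (batch x features x time), the
#' representation both heads build on.
#'
#' @param model an `eeg_model`.
#' @param x batch array, batch x channels x samples.
#' @param training training-mode batch statistics.
#' @return Feature array, batch x feature-channels x time.
#' @export
mrcnn_forward <- function(model, x, training = FALSE) {
  .check_batch(model$spec, x)
  x <- .apply_scaler(model, x)
  .to_bct(.model_forward(model$spec, model$params, model$state,
                         .to_ctb(x), training)$features)
}

#' Residual squeeze-and-excitation block
#'
#' Applies the model's RSE block to a feature map: two kernel-1
#' convolutions, global adaptive pooling to one descriptor per feature
#' channel, a ReLU bottleneck and a sigmoid expansion producing per-channel
#' gates in (0, 1) that rescale the features, plus a residual connection to
#' the block input.
#'
#' @param model an `eeg_model` with architecture `mrcnn_rse`.
#' @param fm feature map, batch x features x time.
#' @return List with `out` (same shape) and `gates` (batch x features).
#' @export
rse_block <- function(model, fm) {
  if (model$spec$architecture != "mrcnn_rse")
    stopf("rse_block applies to the mrcnn_rse architecture")
  r <- .rse_block_forward(.to_ctb(fm), model$params$rse)
  list(out = .to_bct(r$out), gates = r$gates)
}

#' Self-attention block
#'
#' Scaled dot-product self-attention over the temporal axis (attention
#' weights per query position sum to 1), followed by residual
#' add-and-normalize, a position-wise transform, and a second
#' add-and-normalize.
#'
#' @param model an `eeg_model` with architecture `mrcnn_rse`.
#' @param fm feature map, batch x features x time.
#' @return List with `out` (same shape) and `attn`
#'   (batch x query-positions x key-positions).
#' @export
self_attention <- function(model, fm) {
  if (model$spec$architecture != "mrcnn_rse")
    stopf("self_attention applies to the mrcnn_rse architecture")
  a <- .attn_block_forward(.to_ctb(fm), model$params$attn)
  list(out = .to_bct(a$out), attn = aperm(a$attn, c(3, 1, 2)))
}

#' MRCNN-LSTM forward pass
#'
#' Convenience wrapper equal to [predict_proba()] for the LSTM architecture:
#' three parallel convolution branches, concatenation, LSTM over time, a
#' fully connected layer with dropout, and softmax.
#'
#' @param model an `eeg_model` with architecture `mrcnn_lstm`.
#' @param x batch array.
#' @param training training-mode forward (enables dropout).
#' @return Class-probability matrix, rows summing to 1.
#' @export
mrcnn_lstm_forward <- function(model, x, training = FALSE) {
  if (model$spec$architecture != "mrcnn_lstm")
    stopf("mrcnn_lstm_forward applies to the mrcnn_lstm architecture")
  predict_proba(model, x, training = training)
}

#' Loss and parameter gradients for one batch
#'
#' Cross-entropy loss and analytic gradients; used by the optimizer and by
#' the finite-difference checks in the test suite.
#'
#' @param model an `eeg_model`.
#' @param x batch array, batch x channels x samples (already standardized if
#'   applicable).
#' @param y one-hot label matrix, batch x n_classes.
#' @param training training-mode forward.
#' @return List with `loss`, `grads` (parameter-tree shaped), `state` and
#'   `probs`.
#' @export
model_loss_grads <- function(model, x, y, training = TRUE) {
  .check_batch(model$spec, x)
  fw <- .model_forward(model$spec, model$params, model$state,
                       .to_ctb(x), training)
  ce <- nn_ce_loss(fw$probs, y)
  grads <- .model_backward(model$spec, model$params, fw$cache, ce$dlogits)
  list(loss = ce$loss, grads = grads, state = fw$state, probs = fw$probs)
}
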