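# Architecture contracts: shapes, degenerate inputs, block semantics,
# analytic gradients, trainability.

test_that("both architectures map a batch to per-class probabilities", {
  set.seed(1)
  x <- array(rnorm(8 * 6 * 500), c(8, 6, 500))
  for (arch in c("mrcnn_rse", "mrcnn_lstm")) {
    m <- build_model(model_spec(arch, conv_filters = c(4, 4, 4),
                                se_reduction = 4), seed = 1)
    p <- predict_proba(m, x)
    expect_equal(dim(p), c(8, 2))
    expect_equal(rowSums(p), rep(1, 8), tolerance = 1e-6)
    expect_equal(colnames(p), c("DD", "HC"))
  }
})

test_that("shape-inconsistent specs fail at build time, before any data", {
  expect_error(model_spec("mrcnn_rse", in_samples = 10), "time axis")
  expect_error(model_spec("mrcnn_rse", conv_filters = c(4, 4, 5)),
               "se_reduction")
  expect_error(model_spec("mrcnn_rse", in_samples = 8,
                          rse_branch_kernels = list(c(10, 3, 3), c(4, 3, 3))),
               "kernel")
  expect_error(model_spec("mrcnn_lstm", dropout_rate = 1), "dropout_rate")
  m <- build_model(micro_spec("mrcnn_rse"), 1)
  expect_error(predict_proba(m, array(0, c(2, 3, 24))), "expected")
})

test_that("zero input stays finite through every normalization layer", {
  for (arch in c("mrcnn_rse", "mrcnn_lstm")) {
    m <- build_model(micro_spec(arch), 1)
    p <- predict_proba(m, array(0, c(4, 2, 24)), training = TRUE)
    expect_true(all(is.finite(p)))
  }
})

test_that("evaluation mode has no cross-sample leakage and is deterministic", {
  set.seed(2)
  x <- array(rnorm(4 * 2 * 24), c(4, 2, 24))
  for (arch in c("mrcnn_rse", "mrcnn_lstm")) {
    m <- build_model(micro_spec(arch, dropout_rate = 0.5), 1)
    p1 <- predict_proba(m, x)
    expect_identical(p1, predict_proba(m, x))      # dropout off in eval
    p2 <- predict_proba(m, x[rep(1:4, 2), , ])     # doubled batch
    expect_equal(p2[1:4, ], p1, tolerance = 1e-12)
  }
})

test_that("the feature extractor concatenates the parallel branches", {
  m <- build_model(micro_spec("mrcnn_rse"), 1)
  set.seed(3)
  x <- array(rnorm(3 * 2 * 24), c(3, 2, 24))
  fm <- mrcnn_forward(m, x)
  expect_equal(dim(fm), c(3, 2 * 4, 6))            # 2 branches x f3, T/4
  m2 <- build_model(micro_spec("mrcnn_lstm"), 1)
  expect_equal(dim(mrcnn_forward(m2, x)), c(3, 3 * 4, 6))
})

test_that("RSE gates lie in (0,1); saturated gates reduce to the residual path", {
  m <- build_model(micro_spec("mrcnn_rse"), 4)
  set.seed(4)
  fm <- array(rnorm(3 * 8 * 6), c(3, 8, 6))
  r <- rse_block(m, fm)
  expect_true(all(r$gates > 0 & r$gates < 1))
  expect_equal(dim(r$out), dim(fm))
  # force gate pre-activations to +inf and silence the conv path: the block
  # must return its input untouched (pure residual)
  m2 <- m
  m2$params$rse$fc2$b[] <- 1e6
  m2$params$rse$convB$W[] <- 0
  m2$params$rse$convB$b[] <- 0
  r2 <- rse_block(m2, fm)
  expect_true(all(r2$gates == 1))
  expect_equal(r2$out, fm, tolerance = 1e-12)
})

test_that("a zeroed feature channel has a zero squeeze descriptor under identity convs", {
  m <- build_model(micro_spec("mrcnn_rse"), 5)
  C <- m$spec$concat_features
  m$params$rse$convA$W <- diag(C); m$params$rse$convA$b[] <- 0
  m$params$rse$convB$W <- diag(C); m$params$rse$convB$b[] <- 0
  set.seed(5)
  fm <- array(abs(rnorm(2 * C * 6)), c(2, C, 6))   # positive: GELU keeps sign
  fm[, 3, ] <- 0
  # trace the squeeze path: pooled descriptor of the zeroed channel is 0,
  # so its gate depends only on the aggregation weights (bottleneck biases)
  sq <- eegdep:::nn_gap_forward(
    eegdep:::nn_conv1d_forward(
      eegdep:::nn_gelu_forward(
        eegdep:::nn_conv1d_forward(aperm(fm, c(2, 3, 1)),
                                   m$params$rse$convA$W, m$params$rse$convA$b)$out
      )$out, m$params$rse$convB$W, m$params$rse$convB$b)$out)
  expect_equal(sq$out[3, ], c(0, 0), tolerance = 1e-12)
})

test_that("attention rows sum to one and permute with the time axis", {
  m <- build_model(micro_spec("mrcnn_rse"), 6)
  C <- m$spec$concat_features
  set.seed(6)
  fm <- array(rnorm(2 * C * 3), c(2, C, 3))
  a <- self_attention(m, fm)
  expect_equal(apply(a$attn, c(1, 2), sum), matrix(1, 2, 3), tolerance = 1e-6)
  # permutation equivariance (no positional encoding)
  perm <- c(3, 1, 2)
  a2 <- self_attention(m, fm[, , perm, drop = FALSE])
  expect_equal(a2$attn[1, , ], a$attn[1, perm, perm], tolerance = 1e-9)
  expect_equal(a2$out[, , ], a$out[, , perm], tolerance = 1e-9)
  # sequence length 1: the only attention weight is 1
  a1 <- self_attention(m, fm[, , 1, drop = FALSE])
  expect_equal(as.numeric(a1$attn), rep(1, 2))
})

test_that("zeroed conv and FC weights give the uniform 0.5/0.5 prediction", {
  m <- build_model(micro_spec("mrcnn_lstm"), 7)
  m$params <- eegdep:::tree_map(m$params, function(p) p * 0)
  p <- mrcnn_lstm_forward(m, array(rnorm(4 * 2 * 24), c(4, 2, 24)))
  expect_equal(unname(p), matrix(0.5, 4, 2))
})

test_that("analytic gradients match finite differences in both architectures", {
  for (arch in c("mrcnn_rse", "mrcnn_lstm")) {
    m <- build_model(micro_spec(arch), 2)
    set.seed(99)
    x <- array(rnorm(3 * 2 * 24), c(3, 2, 24))
    y <- diag(2)[sample(1:2, 3, TRUE), ]
    expect_lt(gradcheck_worst(m, x, y), 1e-4)
  }
})

test_that("no parameter leaf is disconnected from the loss", {
  set.seed(8)
  x <- array(rnorm(6 * 2 * 24), c(6, 2, 24))
  y <- diag(2)[rep(1:2, 3), ]
  for (arch in c("mrcnn_rse", "mrcnn_lstm")) {
    m <- build_model(micro_spec(arch), 3)
    g <- model_loss_grads(m, x, y, training = TRUE)$grads
    leaf_norms <- unlist(eegdep:::tree_leaf_apply(g, function(v) sum(abs(v))))
    expect_true(all(leaf_norms > 0),
                info = paste(arch, "zero-grad leaves:",
                             paste(names(leaf_norms)[leaf_norms == 0],
                                   collapse = ", ")))
  }
})

test_that("identical spec and seed reproduce parameters and first-step loss", {
  for (arch in c("mrcnn_rse", "mrcnn_lstm")) {
    m1 <- build_model(micro_spec(arch), 11)
    m2 <- build_model(micro_spec(arch), 11)
    expect_identical(m1$params, m2$params)
    ep <- make_epochs(12, rep(c("DD", "HC"), 6), Tt = 24)
    spec <- micro_spec(arch)
    cfg <- train_config(batch_size = 4, max_epochs = 3, warmup_epochs = 1,
                        seed = 5)
    t1 <- train_model(build_model(spec, 11), ep, cfg)$trace$loss
    t2 <- train_model(build_model(spec, 11), ep, cfg)$trace$loss
    expect_identical(t1, t2)
  }
})

test_that("both architectures learn a separable amplitude effect", {
  # one class carries 3x beta-band amplitude: train 30 epochs, 3 seeds,
  # expect >= 90% held-out accuracy on average
  fs <- 32; Tt <- 64; n <- 90
  gen_set <- function(seed) {
    local({
      set.seed(seed)
      lab <- rep(c("DD", "HC"), length.out = n)
      bf <- signal::butter(4, c(13, 15.9) / (fs / 2), "pass")
      data <- array(0, c(n, 2, Tt))
      for (i in seq_len(n)) {
        amp <- if (lab[i] == "DD") 3 else 1
        for (ch in 1:2) {
          osc <- signal::filtfilt(bf$b, bf$a, rnorm(Tt + 64))[33:(Tt + 32)]
          data[i, ch, ] <- rnorm(Tt, sd = 0.5) + amp * osc / sd(osc)
        }
      }
      epoch_set(data, lab, paste0("s", seq_len(n)), Tt / fs, fs)
    })
  }
  cfg <- train_config(batch_size = 16, max_epochs = 30, warmup_epochs = 5,
                      seed = 2)
  for (arch in c("mrcnn_rse", "mrcnn_lstm")) {
    accs <- vapply(1:3, function(s) {
      tr <- gen_set(100 + s)
      te <- gen_set(200 + s)
      spec <- model_spec(arch, in_channels = 2, in_samples = Tt,
                         conv_filters = c(4, 4, 4), se_reduction = 4,
                         lstm_hidden = 8)
      m <- train_model(build_model(spec, s), tr, cfg)
      mean(predict_labels(m, te) == te$labels)
    }, numeric(1))
    expect_gte(mean(accs), 0.9)
  }
})
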