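# Shared fixtures and helpers, all generated in code.

# small cohort: fast to generate, big enough for band-power statistics
tiny_cohort_spec <- function(n = 4, duration_s = 20, artifact_rate = 0,
                             seed = 7, ...) {
  cohort_spec(n_group_a = n, n_group_b = n, duration_s = duration_s,
              artifact_rate = artifact_rate, seed = seed, ...)
}

# band effects with no group difference anywhere
null_effects <- function() list(
  theta = band_effect(4, 8, 1), alpha = band_effect(8, 13, 1),
  beta = band_effect(13, 30, 1))

# scaled-down MRCNN-RSE used for desk-scale training runs
scaled_rse_spec <- function(in_samples = 500)
  model_spec("mrcnn_rse", in_samples = in_samples,
             conv_filters = c(4, 4, 4), se_reduction = 4)

# minimal specs for gradient checks and contract tests
micro_spec <- function(arch, dropout_rate = 0)
  model_spec(arch, in_channels = 2, in_samples = 24, conv_filters = c(3, 4, 4),
             se_reduction = 2, lstm_hidden = 5, dropout_rate = dropout_rate)

# a labeled epoch set built directly from arrays (no preprocessing)
make_epochs <- function(n, labels, C = 2, Tt = 64, rate = 16, gen = stats::rnorm,
                        subject_ids = paste0("s", seq_len(n))) {
  data <- array(gen(n * C * Tt), c(n, C, Tt))
  epoch_set(data, labels, subject_ids, epoch_len_s = Tt / rate, rate_hz = rate)
}

# finite-difference gradient check over every parameter leaf; returns the
# worst relative error over `n_per_leaf` sampled entries per leaf
gradcheck_worst <- function(model, x, y, n_per_leaf = 2, eps = 1e-5) {
  res <- model_loss_grads(model, x, y, training = TRUE)
  loss_at <- function(params) {
    mm <- model; mm$params <- params
    model_loss_grads(mm, x, y, training = TRUE)$loss
  }
  getl <- function(tr, p) {
    for (q in strsplit(p, ".", fixed = TRUE)[[1]]) tr <- tr[[q]]
    tr
  }
  setl <- function(tr, p, v) {
    ps <- strsplit(p, ".", fixed = TRUE)[[1]]
    if (length(ps) == 1) { tr[[ps]] <- v; return(tr) }
    tr[[ps[1]]] <- setl(tr[[ps[1]]], paste(ps[-1], collapse = "."), v)
    tr
  }
  worst <- 0
  for (pt in names(eegdep:::tree_leaf_apply(model$params, length))) {
    leaf <- getl(model$params, pt)
    gl <- getl(res$grads, pt)
    for (i in sample(length(leaf), min(n_per_leaf, length(leaf)))) {
      lp <- leaf; lp[i] <- lp[i] + eps
      lm <- leaf; lm[i] <- lm[i] - eps
      fd <- (loss_at(setl(model$params, pt, lp)) -
             loss_at(setl(model$params, pt, lm))) / (2 * eps)
      worst <- max(worst, abs(fd - gl[i]) / max(1e-4, abs(fd) + abs(gl[i])))
    }
  }
  worst
}
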