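# Training protocol and cross-validated evaluation: AdamW with a
# warmup-cosine learning-rate schedule, stratified epoch-level or
# subject-level k-fold splits, confusion-matrix metrics with mean +/- SD
# aggregation across folds.

#' Training configuration
#'
#' Defaults follow the study protocol: batch size 32, up to 200 epochs,
#' learning rate warming up linearly from 5e-5 to 1e-3 over 20 epochs and
#' then decaying (cosine) to 5e-4 at the final epoch, decoupled weight decay
#' 1e-3, five-fold cross-validation.
#'
#' @param batch_size mini-batch size.
#' @param max_epochs training epochs (hard cap; no early stopping).
#' @param lr_init,lr_peak,lr_final learning-rate anchors.
#' @param warmup_epochs epochs of the linear warmup.
#' @param weight_decay decoupled (AdamW) weight decay on weight matrices.
#' @param n_folds cross-validation folds.
#' @param fold_unit `"epoch_level"` (stratified over 4-s samples; the same
#'   subject may appear in train and test — a leakage warning is logged) or
#'   `"subject_level"` (whole subjects per fold).
#' @param seed seed controlling initialization, shuffling and fold
#'   assignment.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 32, max_epochs = 200, lr_init = 5e-5,
                         lr_peak = 1e-3, warmup_epochs = 20, lr_final = 5e-4,
                         weight_decay = 1e-3, n_folds = 5,
                         fold_unit = c("epoch_level", "subject_level"),
                         seed = 1) {
  fold_unit <- match.arg(fold_unit)
  if (!is_number(lr_init) || !is_number(lr_peak) || lr_init >= lr_peak)
    stopf("need lr_init < lr_peak")
  if (!is_number(lr_final) || lr_final > lr_peak)
    stopf("need lr_final <= lr_peak")
  if (!is_count(max_epochs) || !is_count(warmup_epochs) ||
      warmup_epochs >= max_epochs)
    stopf("need warmup_epochs < max_epochs")
  if (!is_count(n_folds) || n_folds < 2) stopf("need n_folds >= 2")
  structure(list(batch_size = batch_size, max_epochs = max_epochs,
                 lr_init = lr_init, lr_peak = lr_peak,
                 warmup_epochs = warmup_epochs, lr_final = lr_final,
                 weight_decay = weight_decay, n_folds = n_folds,
                 fold_unit = fold_unit, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Linear warmup from `lr_init` to `lr_peak` over `warmup_epochs`, then
#' cosine decay to `lr_final` at `max_epochs`. Continuous at the warmup
#' boundary; hits all three anchors exactly.
#'
#' @param config a [train_config()].
#' @param epoch epoch index, `0 <= epoch <= max_epochs`.
#' @return Learning rate (numeric scalar; vectorized over `epoch`).
#' @export
lr_at <- function(config, epoch) {
  if (any(epoch < 0) || any(epoch > config$max_epochs))
    stopf("epoch must be in [0, %d]", config$max_epochs)
  w <- config$warmup_epochs
  ifelse(epoch <= w,
         config$lr_init + (config$lr_peak - config$lr_init) * epoch / w,
         config$lr_final + (config$lr_peak - config$lr_final) *
           (1 + cos(pi * (epoch - w) / (config$max_epochs - w))) / 2)
}

#' Stratified k-fold partitions
#'
#' Splits an epoch set into `n_folds` disjoint test folds whose union covers
#' every epoch exactly once. In `epoch_level` mode the split is stratified
#' by class over individual 4-s epochs (each fold's class counts within one
#' item of proportionality); in `subject_level` mode whole subjects are
#' assigned to folds (stratified by the subject's class), so no subject ever
#' contributes to both the train and test side of any fold.
#'
#' @param epochs an [epoch_set()].
#' @param config a [train_config()] (uses `n_folds`, `fold_unit`, `seed`).
#' @return List of `n_folds` elements, each `list(train=, test=)` of epoch
#'   indices.
#' @export
kfold_split <- function(epochs, config) {
  n <- dim(epochs$data)[1]
  k <- config$n_folds
  lab <- epochs$labels
  fold_of <- integer(n)
  local_seed(derive_seed(config$seed, 17), {
    if (config$fold_unit == "epoch_level") {
      for (cl in unique(lab)) {
        idx <- sample(which(lab == cl))
        fold_of[idx] <- rep_len(seq_len(k), length(idx))
      }
    } else {
      subj <- epochs$subject_ids
      us <- unique(subj)
      scl <- vapply(us, function(s) lab[match(s, subj)], character(1))
      for (cl in unique(scl)) {
        ss <- sample(us[scl == cl])
        sf <- rep_len(seq_len(k), length(ss))
        for (i in seq_along(ss)) fold_of[subj == ss[i]] <- sf[i]
      }
    }
  })
  folds <- lapply(seq_len(k), function(f)
    list(train = which(fold_of != f), test = which(fold_of == f)))
  for (f in seq_len(k)) {
    if (length(folds[[f]]$test) == 0)
      stopf("fold %d has an empty test set (too few %ss for %d folds)",
            f, sub("_level", "", config$fold_unit), k)
    if (length(unique(lab[folds[[f]]$train])) < length(unique(lab)))
      stopf("fold %d: a class is absent from the train set", f)
  }
  folds
}

# AdamW update; decoupled weight decay applied to leaves whose name starts
# with "W" (weight matrices), not to biases or normalization parameters
.adamw_step <- function(params, grads, opt, lr, wd,
                        b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1
  bc1 <- 1 - b1^opt$t
  bc2 <- 1 - b2^opt$t
  upd <- function(p, g, m, v, nm) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (k in names(p)) {
        r <- upd(p[[k]], g[[k]], m[[k]], v[[k]], k)
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else {
      m <- b1 * m + (1 - b1) * g
      v <- b2 * v + (1 - b2) * g^2
      step <- lr * (m / bc1) / (sqrt(v / bc2) + eps)
      if (startsWith(nm, "W")) step <- step + lr * wd * p
      list(p = p - step, m = m, v = v)
    }
  }
  r <- upd(params, grads, opt$m, opt$v, "")
  list(params = r$p, opt = list(m = r$m, v = r$v, t = opt$t))
}

.onehot <- function(labels, classes) {
  bad <- setdiff(unique(labels), classes)
  if (length(bad))
    stopf("label(s) outside {%s}: %s", paste(classes, collapse = ", "),
          paste(bad, collapse = ", "))
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(labels), match(labels, classes))] <- 1
  y
}

#' Train a model on an epoch set
#'
#' Mini-batch AdamW optimization of the cross-entropy loss under the
#' [lr_at()] schedule. Inputs are standardized per channel with statistics
#' of the training set (stored in the returned model and re-applied at
#' prediction time). Fully deterministic for a fixed `config$seed`.
#'
#' @param model an untrained [build_model()] result.
#' @param train_set an [epoch_set()] with labels.
#' @param config a [train_config()].
#' @param n_epochs optional cap below `config$max_epochs` (the schedule
#'   still uses `config$max_epochs` as its horizon).
#' @param verbose print per-epoch loss.
#' @return The trained model; `$trace` holds per-epoch loss and learning
#'   rate.
#' @export
train_model <- function(model, train_set, config = train_config(),
                        n_epochs = config$max_epochs, verbose = FALSE) {
  x <- train_set$data
  if (anyNA(train_set$labels)) stopf("training epochs must be labeled")
  mu <- apply(x, 2, mean)
  sdv <- pmax(apply(x, 2, stats::sd), 1e-12)
  model$scaler <- list(mean = mu, sd = sdv)
  x <- .apply_scaler(model, x)
  y <- .onehot(train_set$labels, model$classes)
  n <- dim(x)[1]
  opt <- list(m = tree_map(model$params, function(p) p * 0),
              v = tree_map(model$params, function(p) p * 0), t = 0)
  loss_trace <- lr_trace <- numeric(n_epochs)
  for (e in seq_len(n_epochs) - 1L) {
    lr <- lr_at(config, e)
    losses <- local_seed(derive_seed(config$seed, 100 + e), {
      ord <- sample(n)
      bs <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      vapply(bs, function(bi) {
        r <- model_loss_grads(model, x[bi, , , drop = FALSE],
                              y[bi, , drop = FALSE], training = TRUE)
        if (!is.finite(r$loss))
          stopf("non-finite loss at epoch %d (lr=%g): aborting", e, lr)
        model$state <<- r$state
        st <- .adamw_step(model$params, r$grads, opt, lr, config$weight_decay)
        model$params <<- st$params
        opt <<- st$opt
        r$loss
      }, numeric(1))
    })
    loss_trace[e + 1] <- mean(losses)
    lr_trace[e + 1] <- lr
    if (verbose)
      message(sprintf("epoch %3d  lr %.2e  loss %.4f", e, lr, mean(losses)))
  }
  model$trace <- list(loss = loss_trace, lr = lr_trace)
  model$config <- config
  model
}

#' Predict class labels for an epoch set
#' @param model a trained `eeg_model`.
#' @param epochs an [epoch_set()].
#' @param batch_size evaluation batch size.
#' @return Character vector of predicted labels.
#' @export
predict_labels <- function(model, epochs, batch_size = 64) {
  n <- dim(epochs$data)[1]
  out <- character(n)
  for (s in seq(1, n, by = batch_size)) {
    e <- min(n, s + batch_size - 1)
    p <- predict_proba(model, epochs$data[s:e, , , drop = FALSE])
    out[s:e] <- model$classes[max.col(p, ties.method = "first")]
  }
  out
}
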