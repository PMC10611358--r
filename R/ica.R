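# FastICA-based ocular artifact removal. No installed package provides ICA,
# so the decomposition (whitening + symmetric fixed-point iteration with the
# logcosh contrast) is implemented here directly.

# symmetric decorrelation: W <- (W W^T)^{-1/2} W
.sym_decorrelate <- function(W) {
  e <- eigen(W %*% t(W), symmetric = TRUE)
  e$vectors %*% diag(1 / sqrt(pmax(e$values, 1e-300)), nrow(W)) %*%
    t(e$vectors) %*% W
}

# FastICA on rows-as-channels data; returns unmixing of the whitened data,
# the whitening/dewhitening matrices and the sources
.fastica <- function(X, seed = 1000, max_iter = 200, tol = 1e-6) {
  C <- nrow(X); N <- ncol(X)
  mu <- rowMeans(X)
  Xc <- X - mu
  cv <- (Xc %*% t(Xc)) / N
  e <- eigen(cv, symmetric = TRUE)
  if (min(e$values) < 1e-12 * max(e$values))
    stopf("ICA decomposition failure: input is (near) rank-deficient (eigenvalue ratio %.2e)",
          min(e$values) / max(e$values))
  K <- diag(1 / sqrt(e$values), C) %*% t(e$vectors)      # whitening
  K_inv <- e$vectors %*% diag(sqrt(e$values), C)         # dewhitening
  Z <- K %*% Xc
  W <- local_seed(seed, .sym_decorrelate(matrix(stats::rnorm(C * C), C, C)))
  for (it in seq_len(max_iter)) {
    U <- W %*% Z
    G <- tanh(U)
    Wn <- (G %*% t(Z)) / N - diag(rowMeans(1 - G^2), C) %*% W
    Wn <- .sym_decorrelate(Wn)
    delta <- max(abs(abs(diag(Wn %*% t(W))) - 1))
    W <- Wn
    if (delta < tol) break
  }
  list(W = W, K = K, K_inv = K_inv, mu = mu, S = W %*% Z,
       mixing = K_inv %*% t(W), iterations = it, converged = delta < tol)
}

#' Remove ocular artifacts by ICA
#'
#' Decomposes a recording with FastICA (fixed internal seed, so the result
#' is reproducible), scores every component, rejects artifact components and
#' reconstructs the recording from the retained ones.
#'
#' A component is rejected when it is kurtotic far beyond its peers (robust
#' z-score across components > `kurtosis_z` and excess kurtosis > 1 -- a
#' plain z-score is unstable with only six components) or when its absolute
#' correlation with a frontopolar ocular proxy (the low-passed mean of the
#' two most frontal channels) exceeds `proxy_cor`. With
#' `reject_policy = "keep_all"` nothing is rejected and the reconstruction
#' equals the input to numerical precision.
#'
#' @param rec an [recording()].
#' @param reject_policy `"auto"` (default) or `"keep_all"`.
#' @param kurtosis_z robust z threshold (default 3).
#' @param proxy_cor ocular-proxy correlation threshold (default 0.7).
#' @param seed seed of the FastICA initialization (default 1000).
#' @return List with `$recording` (cleaned) and `$report`, a data frame with
#'   one row per component (kurtosis, robust z, proxy correlation, decision);
#'   attributes record the high-pass state (`"none"`), per-channel variance
#'   retention and convergence.
#' @export
remove_artifacts_ica <- function(rec, reject_policy = c("auto", "keep_all"),
                                 kurtosis_z = 3, proxy_cor = 0.7,
                                 seed = 1000) {
  if (!inherits(rec, "eeg_recording")) stopf("`rec` must be an eeg_recording")
  reject_policy <- match.arg(reject_policy)
  X <- rec$samples
  C <- nrow(X); N <- ncol(X)
  if (N < 20 * C^2)
    stopf("recording too short for a stable ICA decomposition (%d samples < %d)",
          N, 20 * C^2)
  dec <- .fastica(X, seed = seed)

  # ocular proxy: low-passed mean of the two most frontal channels
  fp <- grep("^fp", tolower(rec$channel_labels))
  if (length(fp) < 1) fp <- 1:min(2, C)
  lp <- signal::butter(2, min(4 / (rec$rate_hz / 2), 0.99), type = "low")
  proxy <- signal::filtfilt(lp$b, lp$a, colMeans(X[fp, , drop = FALSE]))

  k <- apply(dec$S, 1, kurtosis_excess)
  medk <- stats::median(k)
  madk <- stats::mad(k)
  z <- if (madk > 0) (k - medk) / madk else rep(0, C)
  pc <- abs(apply(dec$S, 1, stats::cor, y = proxy))
  rejected <- if (reject_policy == "keep_all") rep(FALSE, C)
              else (z > kurtosis_z & k > 1) | pc > proxy_cor
  reason <- ifelse(!rejected, "",
                   ifelse(pc > proxy_cor & !(z > kurtosis_z & k > 1),
                          "ocular proxy", "kurtosis"))

  keep <- which(!rejected)
  Xc <- dec$mixing[, keep, drop = FALSE] %*% dec$S[keep, , drop = FALSE] + dec$mu
  out <- rec
  out$samples <- Xc

  report <- data.frame(component = seq_len(C), kurtosis = k, kurtosis_z = z,
                       proxy_cor = pc, rejected = rejected, reason = reason)
  attr(report, "highpass") <- "none"
  attr(report, "converged") <- dec$converged
  attr(report, "iterations") <- dec$iterations
  v0 <- apply(X, 1, stats::var)
  attr(report, "variance_retained") <- apply(Xc, 1, stats::var) / v0
  list(recording = out, report = report)
}
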