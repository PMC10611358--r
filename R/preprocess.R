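# Preprocessing pipeline: downsampling, baseline correction, ICA artifact
# removal (see ica.R), non-overlapping epoching, Butterworth band filtering.

#' Downsample a recording
#'
#' Anti-alias low-pass (zero-phase Butterworth, cutoff 0.45 x target rate)
#' followed by decimation for integer rate ratios; polyphase resampling for
#' non-integer ratios.
#'
#' @param rec an [recording()].
#' @param target_hz new sampling rate; must not exceed the current rate.
#' @return A [recording()] at `target_hz`.
#' @export
downsample <- function(rec, target_hz) {
  if (!inherits(rec, "eeg_recording")) stopf("`rec` must be an eeg_recording")
  if (!is_number(target_hz) || target_hz <= 0)
    stopf("`target_hz` must be a positive number")
  if (target_hz > rec$rate_hz)
    stopf("`target_hz` [%g] exceeds current rate [%g]", target_hz, rec$rate_hz)
  if (target_hz == rec$rate_hz) return(rec)
  ratio <- rec$rate_hz / target_hz
  if (abs(ratio - round(ratio)) < 1e-9) {
    m <- round(ratio)
    bf <- signal::butter(4, 0.45 * target_hz / (rec$rate_hz / 2), type = "low")
    y <- t(apply(rec$samples, 1, function(ch)
      signal::filtfilt(bf$b, bf$a, ch)[seq(1, length(ch), by = m)]))
  } else {
    # rational resampling p/q
    sc <- 1000
    p <- round(target_hz * sc); q <- round(rec$rate_hz * sc)
    g <- .gcd(p, q); p <- p / g; q <- q / g
    y <- t(apply(rec$samples, 1, function(ch)
      as.numeric(signal::resample(ch, p, q))))
  }
  recording(y, target_hz, rec$channel_labels, rec$subject_id, rec$group_label)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Baseline-correct a recording
#'
#' Removes the DC offset by subtracting each channel's whole-recording mean,
#' so every channel of the output has mean zero.
#'
#' @param rec an [recording()].
#' @return A [recording()] with zero-mean channels.
#' @export
baseline_correct <- function(rec) {
  if (!inherits(rec, "eeg_recording")) stopf("`rec` must be an eeg_recording")
  y <- rec$samples - rowMeans(rec$samples)
  out <- rec
  out$samples <- y
  out
}

#' Select and reorder channels
#'
#' Case-insensitive matching of 10-20 labels; output channels follow the
#' requested order.
#'
#' @param rec an [recording()].
#' @param wanted character vector of channel names.
#' @return A [recording()] with the requested channels.
#' @export
select_channels <- function(rec, wanted) {
  if (!inherits(rec, "eeg_recording")) stopf("`rec` must be an eeg_recording")
  idx <- match(tolower(wanted), tolower(rec$channel_labels))
  if (anyNA(idx))
    stopf("channel(s) not found: %s (available: %s)",
          paste(wanted[is.na(idx)], collapse = ", "),
          paste(rec$channel_labels, collapse = ", "))
  out <- rec
  out$samples <- rec$samples[idx, , drop = FALSE]
  out$channel_labels <- rec$channel_labels[idx]
  out
}

#' Segment a recording into fixed-length epochs
#'
#' Cuts non-overlapping (by default) windows of `epoch_len_s` seconds; the
#' trailing remainder shorter than one epoch is discarded. Every sample
#' appears in at most one epoch when `overlap_s = 0`.
#'
#' @param rec an [recording()].
#' @param epoch_len_s epoch length in seconds (default 4).
#' @param overlap_s overlap between consecutive epochs in seconds (default 0).
#' @return An [epoch_set()] labeled with the recording's group and subject.
#' @export
segment <- function(rec, epoch_len_s = 4, overlap_s = 0) {
  if (!inherits(rec, "eeg_recording")) stopf("`rec` must be an eeg_recording")
  if (!is_number(epoch_len_s) || epoch_len_s <= 0)
    stopf("`epoch_len_s` must be > 0")
  if (!is_number(overlap_s) || overlap_s < 0 || overlap_s >= epoch_len_s)
    stopf("`overlap_s` must be in [0, epoch_len_s)")
  n_per <- round(epoch_len_s * rec$rate_hz)
  n <- ncol(rec$samples)
  if (n < n_per)
    stopf("recording [%g s] shorter than one epoch [%g s]",
          n / rec$rate_hz, epoch_len_s)
  stride <- round((epoch_len_s - overlap_s) * rec$rate_hz)
  starts <- seq(1, n - n_per + 1, by = stride)
  nc <- nrow(rec$samples)
  data <- array(0, c(length(starts), nc, n_per))
  for (i in seq_along(starts))
    data[i, , ] <- rec$samples[, starts[i]:(starts[i] + n_per - 1)]
  epoch_set(data,
            labels = rep(rec$group_label, length(starts)),
            subject_ids = rep(rec$subject_id, length(starts)),
            epoch_len_s = epoch_len_s, rate_hz = rec$rate_hz,
            band = "broadband", channel_labels = rec$channel_labels,
            filter_mode = "none")
}

# anti-symmetric (odd) reflection padding around both endpoints, then filter,
# then trim; keeps the 4th-order bandpass transient out of short epochs
.filter_padded <- function(x, bf, pad_n, mode) {
  n <- length(x)
  p <- min(pad_n, n - 1)
  xp <- if (p > 0)
    c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  else x
  y <- if (mode == "zero-phase") signal::filtfilt(bf$b, bf$a, xp)
       else as.numeric(signal::filter(bf$b, bf$a, xp))
  y[(p + 1):(p + n)]
}

.design_bandpass <- function(band, rate_hz) {
  if (band$high_hz >= rate_hz / 2)
    stopf("band edge %g Hz at or above Nyquist %g Hz", band$high_hz, rate_hz / 2)
  signal::butter(band$order, c(band$low_hz, band$high_hz) / (rate_hz / 2),
                 type = "pass")
}

#' Butterworth bandpass filter
#'
#' Applies a Butterworth bandpass of the order declared in the [band_spec()]
#' (prototype order; the bandpass transform doubles the polynomial order).
#' Default application is zero-phase forward-backward (squared magnitude
#' response, no phase distortion); `mode = "single-pass"` gives the plain
#' causal filter. Epochs are padded by odd reflection (`pad_s` seconds each
#' side) before filtering and trimmed after. The application mode is
#' recorded in the output metadata.
#'
#' @param x an [recording()] or [epoch_set()].
#' @param band a [band_spec()] or band token.
#' @param mode `"zero-phase"` (default) or `"single-pass"`.
#' @param pad_s reflection padding in seconds (default 1).
#' @return Same class as `x`, filtered.
#' @export
bandpass <- function(x, band, mode = c("zero-phase", "single-pass"), pad_s = 1) {
  mode <- match.arg(mode)
  band <- parse_band(band)
  UseMethod("bandpass", x)
}

#' @export
bandpass.eeg_recording <- function(x, band, mode = c("zero-phase", "single-pass"),
                                   pad_s = 1) {
  mode <- match.arg(mode)
  band <- parse_band(band)
  bf <- .design_bandpass(band, x$rate_hz)
  pad_n <- round(pad_s * x$rate_hz)
  out <- x
  out$samples <- t(apply(x$samples, 1, .filter_padded, bf = bf,
                         pad_n = pad_n, mode = mode))
  out$band <- band
  out$filter_mode <- mode
  out
}

#' @export
bandpass.eeg_epochs <- function(x, band, mode = c("zero-phase", "single-pass"),
                                pad_s = 1) {
  mode <- match.arg(mode)
  band <- parse_band(band)
  bf <- .design_bandpass(band, x$rate_hz)
  pad_n <- round(pad_s * x$rate_hz)
  d <- dim(x$data)
  out <- x
  for (i in seq_len(d[1]))
    for (ch in seq_len(d[2]))
      out$data[i, ch, ] <- .filter_padded(x$data[i, ch, ], bf, pad_n, mode)
  out$band <- band
  out$filter_mode <- mode
  out
}

#' Preprocessing pipeline configuration
#'
#' Parameters of the five-stage pipeline applied by [run_pipeline()]:
#' channel selection, downsampling, baseline correction, ICA artifact
#' removal, 4-s segmentation, band filtering (in that order; banding before
#' segmentation is available behind `band_before_segment` but off by
#' default).
#'
#' @param target_hz rate after downsampling (default 125).
#' @param channels channel subset (default: frontal six); `NULL` keeps all.
#' @param epoch_len_s epoch length (default 4 s).
#' @param band band token or [band_spec()] (default `"4-30"`, the broadband
#'   "original data" range); `NULL` skips filtering.
#' @param filter_mode `"zero-phase"` or `"single-pass"`.
#' @param ica run ICA artifact removal (default TRUE).
#' @param ica_seed fixed seed of the ICA decomposition.
#' @param band_before_segment filter the continuous recording instead of the
#'   epochs (default FALSE).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(target_hz = 125, channels = frontal_channels(),
                            epoch_len_s = 4, band = "4-30",
                            filter_mode = "zero-phase", ica = TRUE,
                            ica_seed = 1000, band_before_segment = FALSE) {
  if (!is.null(band)) band <- parse_band(band)
  structure(list(target_hz = target_hz, channels = channels,
                 epoch_len_s = epoch_len_s, band = band,
                 filter_mode = filter_mode, ica = ica, ica_seed = ica_seed,
                 band_before_segment = band_before_segment),
            class = "pipeline_config")
}

#' Run the preprocessing pipeline on one recording
#'
#' Composition select-channels -> downsample -> baseline-correct -> ICA ->
#' segment -> bandpass, with a manifest recording every stage's parameters
#' attached to the result (`$manifest`).
#'
#' @param rec an [recording()].
#' @param config a [pipeline_config()].
#' @return An [epoch_set()].
#' @export
run_pipeline <- function(rec, config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) stopf("`config` must be a pipeline_config")
  manifest <- list(subject = rec$subject_id, input_rate_hz = rec$rate_hz,
                   input_duration_s = duration_s(rec), stages = list())
  add <- function(m, stage, ...) { m$stages[[stage]] <- list(...); m }

  if (!is.null(config$channels)) {
    rec <- select_channels(rec, config$channels)
    manifest <- add(manifest, "select_channels", channels = config$channels)
  }
  if (config$target_hz < rec$rate_hz) {
    rec <- downsample(rec, config$target_hz)
    manifest <- add(manifest, "downsample", target_hz = config$target_hz)
  }
  rec <- baseline_correct(rec)
  manifest <- add(manifest, "baseline_correct", method = "whole-recording mean")
  if (isTRUE(config$ica)) {
    res <- remove_artifacts_ica(rec, seed = config$ica_seed)
    rec <- res$recording
    manifest <- add(manifest, "ica", seed = config$ica_seed,
                    rejected = sum(res$report$rejected),
                    highpass = attr(res$report, "highpass"))
  }
  if (isTRUE(config$band_before_segment) && !is.null(config$band)) {
    rec <- bandpass(rec, config$band, mode = config$filter_mode)
    manifest <- add(manifest, "bandpass", low_hz = config$band$low_hz,
                    high_hz = config$band$high_hz, order = config$band$order,
                    mode = config$filter_mode, when = "before segmentation")
  }
  ep <- segment(rec, config$epoch_len_s)
  manifest <- add(manifest, "segment", epoch_len_s = config$epoch_len_s,
                  overlap_s = 0, n_epochs = dim(ep$data)[1])
  if (!isTRUE(config$band_before_segment) && !is.null(config$band)) {
    ep <- bandpass(ep, config$band, mode = config$filter_mode)
    manifest <- add(manifest, "bandpass", low_hz = config$band$low_hz,
                    high_hz = config$band$high_hz, order = config$band$order,
                    mode = config$filter_mode, when = "after segmentation")
  } else if (isTRUE(config$band_before_segment) && !is.null(config$band)) {
    ep$band <- config$band
    ep$filter_mode <- config$filter_mode
  }
  ep$manifest <- manifest
  ep
}

#' Preprocess a whole cohort and pool the epochs
#'
#' Applies [run_pipeline()] to each recording and concatenates the resulting
#' epoch sets (no epoch ever spans two subjects).
#'
#' @param cohort list of [recording()]s.
#' @param config a [pipeline_config()].
#' @return A pooled [epoch_set()].
#' @export
preprocess_cohort <- function(cohort, config = pipeline_config()) {
  sets <- lapply(cohort, run_pipeline, config = config)
  bind_epochs(sets)
}

#' Concatenate epoch sets
#' @param sets list of [epoch_set()]s with identical geometry and band.
#' @return A single [epoch_set()].
#' @export
bind_epochs <- function(sets) {
  if (!length(sets)) stopf("`sets` must be non-empty")
  d <- dim(sets[[1]]$data)
  ns <- vapply(sets, function(s) dim(s$data)[1], integer(1))
  data <- array(0, c(sum(ns), d[2], d[3]))
  at <- 0
  for (s in sets) {
    k <- dim(s$data)[1]
    data[(at + 1):(at + k), , ] <- s$data
    at <- at + k
  }
  epoch_set(data,
            labels = unlist(lapply(sets, `[[`, "labels")),
            subject_ids = unlist(lapply(sets, `[[`, "subject_ids")),
            epoch_len_s = sets[[1]]$epoch_len_s, rate_hz = sets[[1]]$rate_hz,
            band = sets[[1]]$band, channel_labels = sets[[1]]$channel_labels,
            filter_mode = sets[[1]]$filter_mode)
}
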