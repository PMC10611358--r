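#' EEG recording container
#'
#' A `Recording` holds one subject's continuous multichannel EEG as a
#' channels x time matrix in microvolts, together with the sampling rate,
#' channel labels and (optionally) the subject's group label.
#'
#' @param samples numeric matrix, channels x time, in microvolts.
#' @param rate_hz sampling rate in samples per second.
#' @param channel_labels character vector of channel names, one per row of
#'   `samples`.
#' @param subject_id identifier for the subject.
#' @param group_label `"DD"`, `"HC"` or `NA` when unknown.
#' @return An object of class `eeg_recording`.
#' @export
recording <- function(samples, rate_hz, channel_labels,
                      subject_id = "s1", group_label = NA_character_) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stopf("`samples` must be a numeric channels x time matrix")
  if (!is_number(rate_hz) || rate_hz <= 0)
    stopf("`rate_hz` must be a positive number")
  if (length(channel_labels) != nrow(samples))
    stopf("length(channel_labels) [%d] != number of channels [%d]",
          length(channel_labels), nrow(samples))
  if (any(!is.finite(samples)))
    stopf("`samples` contains non-finite values")
  if (!is.na(group_label) && !group_label %in% c("DD", "HC"))
    stopf("`group_label` must be \"DD\", \"HC\" or NA")
  structure(
    list(samples = samples, rate_hz = rate_hz,
         channel_labels = as.character(channel_labels),
         subject_id = as.character(subject_id),
         group_label = group_label),
    class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s (%s): %d ch x %d samples @ %g Hz (%.1f s)\n",
              x$subject_id,
              if (is.na(x$group_label)) "?" else x$group_label,
              nrow(x$samples), ncol(x$samples), x$rate_hz,
              ncol(x$samples) / x$rate_hz))
  cat("  channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' Recording duration in seconds
#' @param rec an `eeg_recording`.
#' @return duration in seconds.
#' @export
duration_s <- function(rec) ncol(rec$samples) / rec$rate_hz

#' Bandpass definition
#'
#' A frequency band with the Butterworth prototype order used to extract it.
#' The canonical EEG rhythms of this pipeline are available as named tokens
#' through [parse_band()].
#'
#' @param low_hz lower cutoff (Hz).
#' @param high_hz upper cutoff (Hz).
#' @param order Butterworth prototype order (the bandpass transform doubles
#'   the polynomial order); default 4.
#' @return An object of class `band_spec`.
#' @export
band_spec <- function(low_hz, high_hz, order = 4) {
  if (!is_number(low_hz) || !is_number(high_hz) || low_hz <= 0 || high_hz <= low_hz)
    stopf("need 0 < low_hz < high_hz (got %s, %s)", low_hz, high_hz)
  if (!is_count(order)) stopf("`order` must be a positive integer")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = order),
            class = "band_spec")
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %g-%g Hz, order %d\n", x$low_hz, x$high_hz, x$order))
  invisible(x)
}

# the seven band tokens of the study pipeline
.band_tokens <- list(
  theta  = c(4, 8),
  alpha1 = c(8, 10),
  alpha2 = c(10, 13),
  beta   = c(13, 30),
  `4-30`  = c(4, 30),
  `8-30`  = c(8, 30),
  `10-30` = c(10, 30)
)

#' Parse a band token
#'
#' Accepts the canonical rhythm names (`theta`, `alpha1`, `alpha2`, `beta`),
#' the wide-range tokens `4-30`, `8-30`, `10-30`, a free-form `"LOW-HIGH"`
#' string, or an existing [band_spec()] (returned unchanged).
#'
#' @param band token string or `band_spec`.
#' @param order filter order for a newly constructed spec.
#' @return A `band_spec`.
#' @export
parse_band <- function(band, order = 4) {
  if (inherits(band, "band_spec")) return(band)
  if (!is.character(band) || length(band) != 1)
    stopf("`band` must be a band_spec or a single token string")
  if (band %in% names(.band_tokens)) {
    e <- .band_tokens[[band]]
    return(band_spec(e[1], e[2], order))
  }
  m <- regmatches(band, regexec("^([0-9.]+)-([0-9.]+)$", band))[[1]]
  if (length(m) == 3)
    return(band_spec(as.numeric(m[2]), as.numeric(m[3]), order))
  stopf("unknown band token \"%s\" (known: %s, or \"LOW-HIGH\")",
        band, paste(names(.band_tokens), collapse = ", "))
}

#' Epoch set container
#'
#' Fixed-length, temporally disjoint EEG segments ready for model input.
#'
#' @param data numeric array, epochs x channels x samples.
#' @param labels per-epoch group labels (`"DD"`/`"HC"`, or `NA`).
#' @param subject_ids per-epoch subject identifiers.
#' @param epoch_len_s epoch length in seconds.
#' @param rate_hz sampling rate of the epochs.
#' @param band a `band_spec` describing the applied filter, or `"broadband"`.
#' @param channel_labels channel names.
#' @param filter_mode how any bandpass was applied (`"none"`, `"zero-phase"`,
#'   `"single-pass"`).
#' @return An object of class `eeg_epochs`.
#' @export
epoch_set <- function(data, labels, subject_ids, epoch_len_s, rate_hz,
                      band = "broadband", channel_labels = NULL,
                      filter_mode = "none") {
  if (!is.array(data) || length(dim(data)) != 3)
    stopf("`data` must be an epochs x channels x samples array")
  n <- dim(data)[1]
  if (length(labels) != n || length(subject_ids) != n)
    stopf("labels/subject_ids must have one entry per epoch")
  if (dim(data)[3] != round(epoch_len_s * rate_hz))
    stopf("samples per epoch [%d] != epoch_len_s * rate_hz [%g]",
          dim(data)[3], epoch_len_s * rate_hz)
  structure(
    list(data = data, labels = as.character(labels),
         subject_ids = as.character(subject_ids),
         epoch_len_s = epoch_len_s, rate_hz = rate_hz, band = band,
         channel_labels = channel_labels, filter_mode = filter_mode),
    class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  bd <- if (inherits(x$band, "band_spec"))
    sprintf("%g-%g Hz", x$band$low_hz, x$band$high_hz) else as.character(x$band)
  cat(sprintf("<eeg_epochs> %d epochs x %d ch x %d samples @ %g Hz, band %s (%s)\n",
              dim(x$data)[1], dim(x$data)[2], dim(x$data)[3], x$rate_hz,
              bd, x$filter_mode))
  tb <- table(x$labels, useNA = "ifany")
  cat("  labels:", paste(sprintf("%s=%d", names(tb), tb), collapse = ", "),
      sprintf("| %d subjects\n", length(unique(x$subject_ids))))
  invisible(x)
}

#' Subset an epoch set by epoch index
#' @param x an `eeg_epochs`.
#' @param idx integer indices of epochs to keep.
#' @return An `eeg_epochs` with the selected epochs.
#' @export
epochs_subset <- function(x, idx) {
  epoch_set(x$data[idx, , , drop = FALSE], x$labels[idx], x$subject_ids[idx],
            x$epoch_len_s, x$rate_hz, x$band, x$channel_labels, x$filter_mode)
}
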