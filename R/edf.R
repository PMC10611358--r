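# Minimal EDF (European Data Format, 16-bit) reader/writer. EDF is the
# interchange standard for clinical EEG; the format is simple enough that a
# direct implementation is the most robust option here: a 256-byte fixed
# header, 256 bytes per signal of per-signal headers, then data records of
# little-endian int16 samples scaled channel-wise between physical and
# digital extrema.

.pad <- function(x, n) {
  x <- as.character(x)
  if (nchar(x) > n) x <- substr(x, 1, n)
  formatC(x, width = -n, flag = " ")
}

# Encode a physical extremum into EDF's 8-character numeric field, rounded
# outward (lower bound rounds down, upper bound rounds up) so that every
# sample lies inside the encoded range. Returns the string and the exact
# value a reader will parse back.
.enc_bound <- function(v, lower) {
  for (d in 7:1) {
    p <- signif(v, d)
    ulp <- 10^(ceiling(log10(abs(p) + 1e-300)) - d)
    if (!is.finite(ulp) || ulp == 0) ulp <- 10^(-d)
    if (lower && p > v) p <- p - ulp
    if (!lower && p < v) p <- p + ulp
    s <- formatC(p, format = "g", digits = d)
    pv <- as.numeric(s)
    ok <- if (lower) pv <= v else pv >= v
    if (nchar(s) <= 8 && is.finite(pv) && ok)
      return(list(s = .pad(s, 8), value = pv))
  }
  stopf("cannot encode %g in an 8-character EDF field", v)
}

#' Write a recording to an EDF file
#'
#' Samples are quantized to 16 bits between each channel's physical extrema
#' (microvolts); data records are 1 s long, and a trailing partial second is
#' dropped.
#'
#' @param rec an [recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  if (!inherits(rec, "eeg_recording")) stopf("`rec` must be an eeg_recording")
  fs <- rec$rate_hz
  if (abs(fs - round(fs)) > 1e-9)
    stopf("EDF writer requires an integer sampling rate (got %g)", fs)
  fs <- round(fs)
  C <- nrow(rec$samples)
  n_rec <- floor(ncol(rec$samples) / fs)
  if (n_rec < 1) stopf("recording shorter than one 1-s data record")
  X <- rec$samples[, seq_len(n_rec * fs), drop = FALSE]

  pmin_ <- apply(X, 1, min); pmax_ <- apply(X, 1, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  # encode extrema in the 8-character header fields, rounded outward, and
  # quantize against the encoded values so reader and writer agree exactly
  enc_min <- lapply(pmin_, .enc_bound, lower = TRUE)
  enc_max <- lapply(pmax_, .enc_bound, lower = FALSE)
  pmin_ <- vapply(enc_min, `[[`, numeric(1), "value")
  pmax_ <- vapply(enc_max, `[[`, numeric(1), "value")
  dmin <- -32768; dmax <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(s) writeChar(s, con, nchars = nchar(s), eos = NULL)
  wr(.pad("0", 8))
  wr(.pad(paste("X X X", rec$subject_id), 80))
  wr(.pad(paste("Startdate 01-JAN-2026", rec$subject_id,
                if (is.na(rec$group_label)) "X" else rec$group_label), 80))
  wr(.pad("01.01.26", 8)); wr(.pad("00.00.00", 8))
  wr(.pad(256 * (1 + C), 8))
  wr(.pad("", 44))
  wr(.pad(n_rec, 8)); wr(.pad("1", 8)); wr(.pad(C, 4))
  for (i in seq_len(C)) wr(.pad(rec$channel_labels[i], 16))
  for (i in seq_len(C)) wr(.pad("AgAgCl electrode", 80))
  for (i in seq_len(C)) wr(.pad("uV", 8))
  for (i in seq_len(C)) wr(enc_min[[i]]$s)
  for (i in seq_len(C)) wr(enc_max[[i]]$s)
  for (i in seq_len(C)) wr(.pad(dmin, 8))
  for (i in seq_len(C)) wr(.pad(dmax, 8))
  for (i in seq_len(C)) wr(.pad("", 80))
  for (i in seq_len(C)) wr(.pad(fs, 8))
  for (i in seq_len(C)) wr(.pad("", 32))

  scale <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(C)) {
      dig <- round((X[i, idx] - pmin_[i]) * scale[i]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' All requested channels must share one sampling rate; physical values are
#' returned as-is (the writer uses microvolts). A file whose size does not
#' match its header is rejected rather than partially read.
#'
#' @param path EDF file path.
#' @param channels optional channel subset (case-insensitive), in the
#'   requested order.
#' @param subject_id,group_label optional overrides; by default the subject
#'   field of the EDF header is used and the group is parsed from the
#'   recording-id field when present.
#' @return An [recording()].
#' @export
read_edf <- function(path, channels = NULL, subject_id = NULL,
                     group_label = NULL) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  rd(8)                                  # version
  patient <- rd(80)
  recinfo <- rd(80)
  rd(8); rd(8)                           # date, time
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  C <- as.integer(rd(4))
  if (is.na(C) || C < 1 || is.na(n_rec)) stopf("corrupt EDF header in %s", path)
  labels <- vapply(seq_len(C), function(i) rd(16), character(1))
  for (i in seq_len(C)) rd(80)           # transducer
  dims <- vapply(seq_len(C), function(i) rd(8), character(1))
  pmin_ <- as.numeric(vapply(seq_len(C), function(i) rd(8), character(1)))
  pmax_ <- as.numeric(vapply(seq_len(C), function(i) rd(8), character(1)))
  dmin <- as.numeric(vapply(seq_len(C), function(i) rd(8), character(1)))
  dmax <- as.numeric(vapply(seq_len(C), function(i) rd(8), character(1)))
  for (i in seq_len(C)) rd(80)           # prefilter
  spr <- as.integer(vapply(seq_len(C), function(i) rd(8), character(1)))
  for (i in seq_len(C)) rd(32)

  sel <- seq_len(C)
  if (!is.null(channels)) {
    sel <- match(tolower(channels), tolower(labels))
    if (anyNA(sel))
      stopf("channel(s) not found in %s: %s (available: %s)", path,
            paste(channels[is.na(sel)], collapse = ", "),
            paste(labels, collapse = ", "))
  }
  if (length(unique(spr[sel])) != 1)
    stopf("requested channels have mixed sampling rates: %s",
          paste(unique(spr[sel]), collapse = ", "))
  fs <- spr[sel[1]] / rec_dur

  expected <- hdr_bytes + 2 * n_rec * sum(spr)
  if (file.size(path) < expected)
    stopf("truncated EDF file %s: %d bytes, expected %d",
          path, file.size(path), expected)

  rec_len <- sum(spr)
  X <- matrix(0, length(sel), n_rec * spr[sel[1]])
  for (r in seq_len(n_rec)) {
    raw <- readBin(con, integer(), n = rec_len, size = 2, endian = "little")
    off <- c(0, cumsum(spr))
    for (j in seq_along(sel)) {
      i <- sel[j]
      dig <- raw[(off[i] + 1):(off[i] + spr[i])]
      phys <- pmin_[i] + (dig - dmin[i]) * (pmax_[i] - pmin_[i]) / (dmax[i] - dmin[i])
      X[j, ((r - 1) * spr[i] + 1):(r * spr[i])] <- phys
    }
  }
  if (is.null(subject_id)) {
    m <- regmatches(patient, regexec("^X X X (.+)$", patient))[[1]]
    subject_id <- if (length(m) == 2) m[2] else patient
    if (!nzchar(subject_id)) subject_id <- basename(path)
  }
  if (is.null(group_label)) {
    group_label <- if (grepl("\\bDD\\b", recinfo)) "DD"
                   else if (grepl("\\bHC\\b", recinfo)) "HC"
                   else NA_character_
  }
  recording(X, fs, labels[sel], subject_id, group_label)
}

#' Write a recording in the package array-on-disk format
#'
#' Raw little-endian float64 samples (channel-major) plus a JSON sidecar
#' carrying the sampling rate, channel labels, subject id, group label and
#' any provenance fields in `extra`.
#'
#' @param rec an [recording()].
#' @param path output path for the `.dat` file; the sidecar is `path` with
#'   `.json` appended.
#' @param extra named list merged into the sidecar (e.g. the generator seed).
#' @return `path`, invisibly.
#' @export
write_recording_array <- function(rec, path, extra = list()) {
  con <- file(path, "wb")
  writeBin(as.numeric(t(rec$samples)), con, size = 8, endian = "little")
  close(con)
  meta <- c(list(subject_id = rec$subject_id, group_label = rec$group_label,
                 rate_hz = rec$rate_hz, channel_labels = rec$channel_labels,
                 n_channels = nrow(rec$samples), n_samples = ncol(rec$samples),
                 format = "float64-le, channel-major"), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a recording from the package array-on-disk format
#' @param path path to the `.dat` file written by [write_recording_array()].
#' @return An [recording()].
#' @export
read_recording_array <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  n <- meta$n_channels * meta$n_samples
  con <- file(path, "rb")
  x <- readBin(con, numeric(), n = n, size = 8, endian = "little")
  close(con)
  if (length(x) != n) stopf("truncated array file %s", path)
  recording(matrix(x, meta$n_channels, meta$n_samples, byrow = TRUE),
            meta$rate_hz, meta$channel_labels, meta$subject_id,
            if (is.null(meta$group_label) || is.na(meta$group_label))
              NA_character_ else meta$group_label)
}

#' Write a cohort to a directory
#'
#' One EDF file per subject (or the array format), plus a cohort manifest
#' JSON recording the generator seed and the subject/group table.
#'
#' @param cohort list of [recording()]s.
#' @param dir output directory (created if needed).
#' @param format `"edf"` (default) or `"array"`.
#' @param seed optional generator seed recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, format = c("edf", "array"), seed = NULL) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(cohort))
  for (i in seq_along(cohort)) {
    rec <- cohort[[i]]
    files[i] <- file.path(dir, paste0(rec$subject_id,
                                      if (format == "edf") ".edf" else ".dat"))
    if (format == "edf") write_edf(rec, files[i])
    else write_recording_array(rec, files[i], extra = list(seed = seed))
  }
  manifest <- list(format = format, seed = seed,
                   subjects = data.frame(
                     subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
                     group_label = vapply(cohort, `[[`, character(1), "group_label"),
                     file = basename(files)))
  jsonlite::write_json(manifest, file.path(dir, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#' @param dir cohort directory containing `cohort.json`.
#' @return List of [recording()]s.
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "cohort.json")
  if (!file.exists(mf)) stopf("no cohort manifest in %s", dir)
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  lapply(seq_len(nrow(manifest$subjects)), function(i) {
    row <- manifest$subjects[i, ]
    path <- file.path(dir, row$file)
    if (manifest$format == "edf")
      read_edf(path, subject_id = row$subject_id, group_label = row$group_label)
    else read_recording_array(path)
  })
}
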