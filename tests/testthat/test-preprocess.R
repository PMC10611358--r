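# Preprocessing pipeline: downsampling, baseline correction, segmentation,
# Butterworth banding, channel selection, composition.

make_rec <- function(x, fs, labels = NULL, ...) {
  if (is.vector(x)) x <- matrix(x, 1)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(x)))
  recording(x, fs, labels, ...)
}

test_that("downsampling 250->125 Hz halves the sample count, preserves duration", {
  sp <- tiny_cohort_spec(n = 1, duration_s = 20)
  rec <- generate_cohort(sp)[[1]]
  dn <- downsample(rec, 125)
  expect_equal(dn$rate_hz, 125)
  expect_equal(ncol(dn$samples), 20 * 125)
  expect_lt(abs(duration_s(dn) - duration_s(rec)), 1 / 125)
  expect_identical(downsample(rec, 250), rec)
  expect_error(downsample(rec, 500), "exceeds")
})

test_that("downsampling keeps a 10 Hz sine peak at 10 Hz", {
  fs <- 250; t <- seq(0, 20, by = 1 / fs)[-1]
  rec <- make_rec(sin(2 * pi * 10 * t), fs)
  peak_hz <- function(x, fs) {
    n <- length(x); p <- Mod(fft(x))^2
    f <- (seq_len(n) - 1) * fs / n
    f[f <= fs / 2][which.max(p[f <= fs / 2])]
  }
  dn <- downsample(rec, 125)
  expect_lt(abs(peak_hz(dn$samples[1, ], 125) - 10), 125 / ncol(dn$samples) + 1e-9)
})

test_that("baseline correction zeroes the per-channel mean and only that", {
  rec <- make_rec(rbind(rep(5, 1000), rnorm(1000)), 100)
  bc <- baseline_correct(rec)
  expect_equal(max(abs(rowMeans(bc$samples))), 0, tolerance = 1e-12)
  expect_equal(bc$samples[1, ], rep(0, 1000))
  # sine + offset: the sine is recovered
  t <- seq_len(500) / 100
  s <- sin(2 * pi * 3 * t); s <- s - mean(s)
  rec2 <- make_rec(s + 3.2, 100)
  expect_equal(baseline_correct(rec2)$samples[1, ], s, tolerance = 1e-12)
})

test_that("segmentation follows the floor rule and reconstructs the source", {
  fs <- 125
  n <- round(601.5 * fs)
  rec <- make_rec(matrix(rnorm(6 * n), 6, n), fs,
                  labels = frontal_channels(), group_label = "DD")
  ep <- segment(rec, 4)
  expect_equal(dim(ep$data), c(150, 6, 500))
  expect_equal(ep$labels, rep("DD", 150))
  # concatenating the epochs reproduces the first 600 s exactly
  recon <- do.call(cbind, lapply(seq_len(150), function(i) ep$data[i, , ]))
  expect_identical(recon, rec$samples[, 1:(150 * 500)])
  expect_error(segment(rec, 0), "epoch_len_s")
  expect_error(segment(make_rec(rnorm(100), 100), 4), "shorter")
})

test_that("Butterworth beta band has the analytic passband/stopband behavior", {
  fs <- 125
  t <- seq_len(60 * fs) / fs
  mid <- seq(10 * fs, 50 * fs)          # steady-state section
  band <- parse_band("beta")
  # 20 Hz passes within 5% RMS (single-pass and zero-phase)
  s20 <- make_rec(sin(2 * pi * 20 * t), fs)
  for (mode in c("single-pass", "zero-phase")) {
    out <- bandpass(s20, band, mode = mode)
    r <- eegdep:::rms(out$samples[1, mid]) / eegdep:::rms(s20$samples[1, mid])
    expect_lt(abs(r - 1), 0.05)
    expect_equal(out$filter_mode, mode)
  }
  # 2 Hz attenuated by > 20 dB
  s2 <- make_rec(sin(2 * pi * 2 * t), fs)
  out2 <- bandpass(s2, band, mode = "single-pass")
  expect_lt(20 * log10(eegdep:::rms(out2$samples[1, mid]) /
                       eegdep:::rms(s2$samples[1, mid])), -20)
  # cutoff frequency sits at -3 dB +/- 0.5 dB in single-pass mode
  s13 <- make_rec(sin(2 * pi * 13 * t), fs)
  out13 <- bandpass(s13, band, mode = "single-pass")
  db <- 20 * log10(eegdep:::rms(out13$samples[1, mid]) /
                   eegdep:::rms(s13$samples[1, mid]))
  expect_lt(abs(db + 3), 0.5)
  # band edges at or above Nyquist are rejected
  expect_error(bandpass(s20, band_spec(13, 70)), "Nyquist")
})

test_that("designed filters are stable: the impulse response decays", {
  fs <- 125
  x <- c(1, rep(0, 20 * fs - 1))
  for (tok in c("theta", "alpha1", "alpha2", "beta", "4-30", "8-30", "10-30")) {
    b <- parse_band(tok)
    bf <- signal::butter(b$order, c(b$low_hz, b$high_hz) / (fs / 2), "pass")
    h <- as.numeric(signal::filter(bf$b, bf$a, x))
    tail10 <- h[(10 * fs):(20 * fs)]
    expect_lt(max(abs(tail10)), 1e-6 * max(abs(h)))
  }
})

test_that("band-passed power never exceeds broadband power", {
  sp <- tiny_cohort_spec(n = 1, duration_s = 10)
  rec <- baseline_correct(generate_cohort(sp)[[1]])
  for (tok in c("theta", "beta", "4-30")) {
    out <- bandpass(rec, tok)
    expect_lt(sum(out$samples^2), sum(rec$samples^2) * 1.01)
  }
})

test_that("channel selection matches case-insensitively and reorders", {
  sp <- tiny_cohort_spec(n = 1, duration_s = 5)
  rec <- generate_cohort(sp)[[1]]
  sel <- select_channels(rec, c("f4", "FP1"))
  expect_equal(sel$channel_labels, c("F4", "Fp1"))
  expect_equal(sel$samples[1, ], rec$samples[4, ])
  expect_identical(select_channels(rec, rec$channel_labels)$samples, rec$samples)
  expect_error(select_channels(rec, c("Fp1", "XX")), "XX")
})

test_that("the pipeline equals the manual composition of its stages", {
  sp <- tiny_cohort_spec(n = 1, duration_s = 24)
  rec <- generate_cohort(sp)[[1]]
  cfg <- pipeline_config(band = "beta", ica = FALSE)
  ep <- run_pipeline(rec, cfg)
  manual <- bandpass(segment(baseline_correct(downsample(
    select_channels(rec, frontal_channels()), 125)), 4), "beta")
  expect_equal(ep$data, manual$data, tolerance = 1e-12)
  expect_equal(ep$band$low_hz, 13)
  expect_equal(ep$filter_mode, "zero-phase")
  expect_named(ep$manifest$stages,
               c("select_channels", "downsample", "baseline_correct",
                 "segment", "bandpass"))
  # determinism of the full pipeline (including ICA with its fixed seed)
  cfg2 <- pipeline_config(band = "beta", ica = TRUE)
  expect_identical(run_pipeline(rec, cfg2)$data, run_pipeline(rec, cfg2)$data)
})

test_that("banding before segmentation is available behind a config flag", {
  sp <- tiny_cohort_spec(n = 1, duration_s = 16)
  rec <- generate_cohort(sp)[[1]]
  ep <- run_pipeline(rec, pipeline_config(band = "beta", ica = FALSE,
                                          band_before_segment = TRUE))
  expect_equal(dim(ep$data), c(4, 6, 500))
  expect_equal(ep$band$low_hz, 13)
  expect_equal(ep$manifest$stages$bandpass$when, "before segmentation")
})

test_that("epoch accounting over a cohort: sum of per-subject floors, no mixing", {
  sp <- tiny_cohort_spec(n = 2, duration_s = 22)
  co <- generate_cohort(sp)
  ep <- preprocess_cohort(co, pipeline_config(ica = FALSE, band = NULL))
  expect_equal(dim(ep$data)[1], 4 * floor(22 / 4))
  expect_equal(unname(table(ep$subject_ids)), rep(5L, 4), ignore_attr = TRUE)
  for (s in unique(ep$subject_ids))
    expect_length(unique(ep$labels[ep$subject_ids == s]), 1)
})
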