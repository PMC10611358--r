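#' Default frontal six-channel montage
#'
#' The six frontal 10-20 electrodes used throughout this package
#' (configurable everywhere they appear).
#' @return Character vector of channel names.
#' @export
frontal_channels <- function() c("Fp1", "Fp2", "F3", "F4", "F7", "F8")

#' Describe a planted band effect
#'
#' One oscillatory component of the synthetic cohort: a frequency band, the
#' group-B/group-A band-power ratio, and the component's baseline level
#' relative to the 1/f background power inside the band.
#'
#' @param low_hz,high_hz band edges in Hz.
#' @param ratio target total band-power ratio group B (DD) over group A (HC);
#'   must be positive. `1` plants no group difference.
#' @param level group-A component variance as a multiple of the in-band
#'   background power (default 1: oscillation as strong as the background
#'   within its band).
#' @return A list describing the effect.
#' @export
band_effect <- function(low_hz, high_hz, ratio = 1, level = 1) {
  if (!is_number(ratio) || ratio <= 0) stopf("`ratio` must be > 0")
  if (!is_number(level) || level < 0) stopf("`level` must be >= 0")
  band_spec(low_hz, high_hz) # validates edges
  list(low_hz = low_hz, high_hz = high_hz, ratio = ratio, level = level)
}

.default_band_effects <- function() list(
  theta = band_effect(4, 8, 1),
  alpha = band_effect(8, 13, 1),
  beta  = band_effect(13, 30, 1.8)
)

#' Specification of a synthetic two-group EEG cohort
#'
#' Defines the study conditions the generator emulates: two groups of
#' resting-state recordings consisting of 1/f^alpha background noise plus
#' band-limited oscillatory components whose power differs between groups by
#' configurable ratios, optional ocular artifacts, and a per-subject random
#' amplitude gain. Group A carries the label `"HC"`, group B the label
#' `"DD"`; the default effect raises DD beta-band (13-30 Hz) power by a
#' factor 1.8 and leaves theta/alpha exchangeable.
#'
#' @param n_group_a number of group-A (HC) subjects.
#' @param n_group_b number of group-B (DD) subjects.
#' @param duration_s recording length per subject in seconds.
#' @param rate_hz sampling rate (must exceed twice the highest band edge).
#' @param n_channels number of channels (6 uses the frontal montage names).
#' @param band_effects list of [band_effect()]s.
#' @param artifact_rate ocular-artifact events per minute.
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background.
#' @param background_sd background standard deviation in microvolts.
#' @param subject_gain_sdlog sdlog of the per-subject lognormal amplitude gain.
#' @param seed integer seed; identical spec + seed gives bit-identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_group_a = 34, n_group_b = 41, duration_s = 600,
                        rate_hz = 250, n_channels = 6,
                        band_effects = .default_band_effects(),
                        artifact_rate = 4, noise_exponent = 1,
                        background_sd = 10, subject_gain_sdlog = 0.1,
                        seed = 1) {
  if (!is_count(n_group_a)) stopf("`n_group_a` must be a positive integer")
  if (!is_count(n_group_b)) stopf("`n_group_b` must be a positive integer")
  if (!is_number(duration_s) || duration_s <= 0) stopf("`duration_s` must be > 0")
  if (!is_count(n_channels)) stopf("`n_channels` must be a positive integer")
  if (!is_number(artifact_rate) || artifact_rate < 0)
    stopf("`artifact_rate` must be >= 0")
  if (!is_number(noise_exponent) || noise_exponent < 0)
    stopf("`noise_exponent` must be >= 0")
  if (length(band_effects)) {
    hi <- max(vapply(band_effects, function(e) e$high_hz, numeric(1)))
    if (!is_number(rate_hz) || rate_hz <= 2 * hi)
      stopf("`rate_hz` [%g] must exceed twice the highest band edge [%g]",
            rate_hz, hi)
    if (any(vapply(band_effects, function(e) e$ratio, numeric(1)) <= 0))
      stopf("`band_effects` power ratios must be > 0")
  } else if (!is_number(rate_hz) || rate_hz <= 0) {
    stopf("`rate_hz` must be > 0")
  }
  structure(
    list(n_group_a = n_group_a, n_group_b = n_group_b, duration_s = duration_s,
         rate_hz = rate_hz, n_channels = n_channels,
         band_effects = band_effects, artifact_rate = artifact_rate,
         noise_exponent = noise_exponent, background_sd = background_sd,
         subject_gain_sdlog = subject_gain_sdlog, seed = as.integer(seed)),
    class = "cohort_spec")
}

# 1/f^alpha Gaussian noise by Fourier spectral shaping, unit variance
.pink_noise <- function(n, alpha) {
  nf <- (n - 1) %/% 2            # strictly positive, non-Nyquist bins
  f <- seq_len(nf) / n
  amp <- f^(-alpha / 2)
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * amp
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- z
  if (n %% 2 == 0) spec[n / 2 + 1] <- stats::rnorm(1) * (0.5)^(-alpha / 2)
  spec[n:(n - nf + 1)] <- Conj(z)
  x <- Re(stats::fft(spec, inverse = TRUE)) / n
  x / stats::sd(x)
}

# fraction of 1/f^alpha background variance lying inside [lo, hi]
.pink_band_fraction <- function(n, fs, alpha, lo, hi) {
  nf <- (n - 1) %/% 2
  f <- seq_len(nf) / n * fs
  w <- f^(-alpha)
  sum(w[f >= lo & f <= hi]) / sum(w)
}

# band-limited Gaussian component with exact target variance
.band_component <- function(n, fs, lo, hi, variance) {
  if (variance <= 0) return(numeric(n))
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  x <- signal::filtfilt(bf$b, bf$a, stats::rnorm(n))
  x * sqrt(variance / stats::var(x))
}

# raised-cosine ocular transient template, unit peak
.blink_template <- function(width_samples) {
  t <- seq_len(width_samples)
  0.5 * (1 - cos(2 * pi * t / (width_samples + 1)))
}

# spatial gains of the stereotyped ocular source: strongest on the
# frontopolar pair, decaying towards lateral/posterior channels
.artifact_gains <- function(n_channels) {
  g <- c(1, 1, 0.5, 0.5, 0.3, 0.3)
  if (n_channels <= 6) g[seq_len(n_channels)]
  else c(g, rep(0.2, n_channels - 6))
}

.generate_recording <- function(spec, subject_id, group, seed) {
  n <- round(spec$duration_s * spec$rate_hz)
  fs <- spec$rate_hz
  labels <- if (spec$n_channels == 6) frontal_channels()
            else sprintf("EEG%02d", seq_len(spec$n_channels))
  # per-band component variances for this subject's group, fixed across
  # channels: group A gets level x in-band background power; group B solves
  # (P_bg + v_B) = ratio x (P_bg + v_A) so the planted ratio is the total
  # band-power ratio
  variances <- vapply(spec$band_effects, function(be) {
    p_bg <- spec$background_sd^2 *
      .pink_band_fraction(n, fs, spec$noise_exponent, be$low_hz, be$high_hz)
    v_a <- be$level * p_bg
    if (group == "HC") v_a else {
      vb <- be$ratio * (p_bg + v_a) - p_bg
      if (vb < 0) {
        warnf("band %g-%g Hz: ratio %g unreachable at level %g; component variance clamped to 0",
              be$low_hz, be$high_hz, be$ratio, be$level)
        0
      } else vb
    }
  }, numeric(1))
  local_seed(seed, {
    gain <- stats::rlnorm(1, 0, spec$subject_gain_sdlog)
    x <- matrix(0, spec$n_channels, n)
    for (ch in seq_len(spec$n_channels)) {
      sig <- spec$background_sd * .pink_noise(n, spec$noise_exponent)
      for (bi in seq_along(spec$band_effects)) {
        be <- spec$band_effects[[bi]]
        sig <- sig + .band_component(n, fs, be$low_hz, be$high_hz,
                                     variances[bi])
      }
      x[ch, ] <- gain * sig
    }
    art <- list(n_events = 0L, times_s = numeric(0),
                gains = .artifact_gains(spec$n_channels))
    if (spec$artifact_rate > 0) {
      n_ev <- stats::rpois(1, spec$artifact_rate * spec$duration_s / 60)
      if (n_ev > 0) {
        ref_sd <- spec$background_sd * gain
        times <- sort(stats::runif(n_ev, 0, spec$duration_s))
        for (tt in times) {
          w <- round(stats::runif(1, 0.5, 2) * fs)
          amp <- stats::runif(1, 5, 10) * ref_sd
          i0 <- max(1, round(tt * fs))
          i1 <- min(n, i0 + w - 1)
          tpl <- .blink_template(w)[seq_len(i1 - i0 + 1)]
          x[, i0:i1] <- x[, i0:i1] + outer(art$gains, amp * tpl)
        }
        art$n_events <- n_ev
        art$times_s <- times
      }
    }
    rec <- recording(x, fs, labels, subject_id, group)
    rec$artifact <- art
    rec
  })
}

#' Generate a labeled two-group synthetic EEG cohort
#'
#' Produces `n_group_a + n_group_b` recordings per the [cohort_spec()]:
#' group A labeled `"HC"`, group B labeled `"DD"`. Each channel is
#' 1/f^alpha background plus band-limited oscillatory components whose total
#' band power follows the configured planted ratios, scaled by a per-subject
#' random gain, with optional raised-cosine ocular transients strongest on
#' the frontopolar channels. Fixed spec + seed gives bit-identical output.
#'
#' @param spec a [cohort_spec()].
#' @return List of [recording()]s; each carries an `$artifact` element with
#'   event times and the spatial gain profile.
#' @export
generate_cohort <- function(spec) {
  if (!inherits(spec, "cohort_spec")) stopf("`spec` must be a cohort_spec")
  n_tot <- spec$n_group_a + spec$n_group_b
  groups <- c(rep("HC", spec$n_group_a), rep("DD", spec$n_group_b))
  ids <- c(sprintf("HC%02d", seq_len(spec$n_group_a)),
           sprintf("DD%02d", seq_len(spec$n_group_b)))
  lapply(seq_len(n_tot), function(i)
    .generate_recording(spec, ids[i], groups[i], derive_seed(spec$seed, i)))
}

#' Periodogram band power
#'
#' Integrated power (variance contribution, microvolt^2) of a signal in
#' `[low_hz, high_hz]`, from the raw FFT periodogram. This is deliberately
#' independent of the Butterworth filtering path so it can serve as an
#' oracle for planted band effects.
#'
#' @param x numeric vector.
#' @param rate_hz sampling rate.
#' @param low_hz,high_hz band edges; `high_hz` must not exceed Nyquist.
#' @return Band power (numeric scalar).
#' @export
band_power <- function(x, rate_hz, low_hz, high_hz) {
  if (high_hz > rate_hz / 2)
    stopf("band edge %g Hz exceeds Nyquist %g Hz", high_hz, rate_hz / 2)
  if (low_hz <= 0 || low_hz >= high_hz) stopf("need 0 < low_hz < high_hz")
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x)))^2 / n^2   # two-sided power per bin
  f <- (seq_len(n) - 1) * rate_hz / n
  k <- which(f >= low_hz & f <= high_hz & f <= rate_hz / 2)
  2 * sum(p[k])
}

#' Measure a planted band effect in a cohort
#'
#' Computes, per subject, the channel-averaged periodogram band power, and
#' returns group means and the DD/HC (group-B/group-A) ratio.
#'
#' @param cohort list of [recording()]s with group labels.
#' @param band a [band_spec()] or band token (see [parse_band()]).
#' @return List with per-subject powers, group means and `ratio`.
#' @export
planted_effect_summary <- function(cohort, band) {
  if (!length(cohort)) stopf("`cohort` must be non-empty")
  band <- parse_band(band)
  pow <- vapply(cohort, function(rec) {
    mean(apply(rec$samples, 1, band_power, rate_hz = rec$rate_hz,
               low_hz = band$low_hz, high_hz = band$high_hz))
  }, numeric(1))
  grp <- vapply(cohort, function(rec) rec$group_label, character(1))
  mean_a <- mean(pow[grp == "HC"])
  mean_b <- mean(pow[grp == "DD"])
  structure(
    list(band = band, per_subject = data.frame(subject = vapply(
           cohort, function(r) r$subject_id, character(1)),
           group = grp, power = pow),
         mean_hc = mean_a, mean_dd = mean_b, ratio = mean_b / mean_a),
    class = "band_effect_summary")
}

#' @export
print.band_effect_summary <- function(x, ...) {
  cat(sprintf("<band_effect_summary> %g-%g Hz: HC %.3g uV^2, DD %.3g uV^2, ratio DD/HC = %.3f\n",
              x$band$low_hz, x$band$high_hz, x$mean_hc, x$mean_dd, x$ratio))
  invisible(x)
}
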