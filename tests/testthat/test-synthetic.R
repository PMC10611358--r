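# Synthetic cohort generator: determinism, planted band effects, spectral
# contract, artifact injection.

test_that("fixed spec and seed give bit-identical cohorts", {
  sp <- tiny_cohort_spec(n = 2, duration_s = 10, artifact_rate = 4, seed = 7)
  expect_identical(generate_cohort(sp), generate_cohort(sp))
  sp2 <- tiny_cohort_spec(n = 2, duration_s = 10, artifact_rate = 4, seed = 8)
  expect_false(identical(generate_cohort(sp)[[1]]$samples,
                         generate_cohort(sp2)[[1]]$samples))
})

test_that("cohort structure matches the spec: sizes, labels, rate, duration", {
  sp <- tiny_cohort_spec(n = 3, duration_s = 12)
  co <- generate_cohort(sp)
  expect_length(co, 6)
  expect_equal(vapply(co, function(r) r$group_label, character(1)),
               c(rep("HC", 3), rep("DD", 3)))
  expect_equal(ncol(co[[1]]$samples), 12 * 250)
  expect_equal(co[[1]]$channel_labels, frontal_channels())
})

test_that("invalid cohort parameters are rejected by name", {
  expect_error(cohort_spec(n_group_a = 0), "n_group_a")
  expect_error(cohort_spec(duration_s = -1), "duration_s")
  expect_error(cohort_spec(rate_hz = 50), "rate_hz")
  expect_error(band_effect(13, 30, ratio = -1), "ratio")
  expect_error(cohort_spec(artifact_rate = -2), "artifact_rate")
})

test_that("planted beta ratio is recovered by periodogram band power", {
  sp <- cohort_spec(n_group_a = 20, n_group_b = 20, duration_s = 20,
                    artifact_rate = 0, seed = 21)   # default beta ratio 1.8
  co <- generate_cohort(sp)
  s <- planted_effect_summary(co, "beta")
  expect_gt(s$ratio, 1.4)
  expect_lt(s$ratio, 2.2)

  # Welch t-test on log beta power separates the groups decisively
  pow <- s$per_subject
  tt <- t.test(log(pow$power[pow$group == "DD"]),
               log(pow$power[pow$group == "HC"]))
  expect_lt(tt$p.value, 0.01)

  # effect localization: theta stays at the null ratio
  th <- planted_effect_summary(co, "theta")
  expect_gt(th$ratio, 0.8)
  expect_lt(th$ratio, 1.25)

  # band with no planted content above the background: ratio ~ 1
  hi <- planted_effect_summary(co, band_spec(45, 50))
  expect_gt(hi$ratio, 0.8)
  expect_lt(hi$ratio, 1.25)
})

test_that("all-null effects make the groups statistically exchangeable", {
  n_nonsig <- 0
  for (r in 1:20) {
    sp <- cohort_spec(n_group_a = 20, n_group_b = 20, duration_s = 10,
                      band_effects = null_effects(), artifact_rate = 0,
                      seed = 100 + r)
    s <- planted_effect_summary(generate_cohort(sp), "beta")
    pow <- s$per_subject
    p <- t.test(log(pow$power[pow$group == "DD"]),
                log(pow$power[pow$group == "HC"]))$p.value
    if (p >= 0.05) n_nonsig <- n_nonsig + 1
  }
  expect_gte(n_nonsig, 18)
})

test_that("background periodogram slope tracks the noise exponent", {
  for (alpha in c(0.5, 1)) {
    sp <- cohort_spec(n_group_a = 1, n_group_b = 1, duration_s = 40,
                      band_effects = list(), artifact_rate = 0,
                      noise_exponent = alpha, seed = 3)
    rec <- generate_cohort(sp)[[1]]
    # average periodogram over channels, log-log fit over 1-40 Hz
    n <- ncol(rec$samples)
    f <- (seq_len(n) - 1) * rec$rate_hz / n
    keep <- f >= 1 & f <= 40
    pmean <- rowMeans(apply(rec$samples, 1, function(x) Mod(fft(x))^2 / n))[keep]
    fit <- lm(log(pmean) ~ log(f[keep]))
    expect_lt(abs(unname(coef(fit)[2]) + alpha), 0.3)
  }
})

test_that("ocular artifacts are frontally dominant, rate-controlled transients", {
  sp <- tiny_cohort_spec(n = 1, duration_s = 60, artifact_rate = 10, seed = 5)
  rec <- generate_cohort(sp)[[1]]
  expect_gt(rec$artifact$n_events, 2)
  # kurtosis raised on the frontopolar channels relative to artifact-free twin
  sp0 <- tiny_cohort_spec(n = 1, duration_s = 60, artifact_rate = 0, seed = 5)
  rec0 <- generate_cohort(sp0)[[1]]
  k1 <- eegdep:::kurtosis_excess(rec$samples[1, ])
  k0 <- eegdep:::kurtosis_excess(rec0$samples[1, ])
  expect_gt(k1, k0 + 1)
  # spatial profile decays away from the frontopolar pair
  g <- rec$artifact$gains
  expect_true(all(g[1:2] >= g[3:4]) && all(g[3:4] >= g[5:6]))
})

test_that("band_power validates band edges against Nyquist", {
  x <- rnorm(1000)
  expect_error(band_power(x, 100, 10, 60), "Nyquist")
  expect_error(planted_effect_summary(list(), "beta"), "non-empty")
})

test_that("unreachable ratio under the component budget is clamped with a warning", {
  sp <- cohort_spec(n_group_a = 1, n_group_b = 1, duration_s = 5,
                    band_effects = list(beta = band_effect(13, 30, 0.2)),
                    artifact_rate = 0, seed = 2)
  expect_warning(generate_cohort(sp), "clamped")
})
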