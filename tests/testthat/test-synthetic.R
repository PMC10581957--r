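test_that("background generator matches the requested spectral slope and RMS", {
  for (beta in c(0, 1)) {
    bg <- generate_background(60, 512, noise_model(beta, scale = 1),
                              n_channels = 1, seed = 7)
    expect_equal(sqrt(mean(bg$samples^2)), 1, tolerance = 1e-9)
    psd <- welch_psd(bg)
    sel <- psd$freqs >= 1 & psd$freqs <= 100
    slope <- unname(coef(lm(log10(psd$psd[1, sel]) ~
                              log10(psd$freqs[sel])))[2])
    expect_equal(slope, -beta, tolerance = 0.15)
  }
})

test_that("zero-scale background is all zero and invalid inputs error", {
  bg <- generate_background(2, 512, noise_model(1, scale = 0), seed = 1)
  expect_true(all(bg$samples == 0))
  expect_error(generate_background(-1, 512), "positive")
  expect_error(generate_background(10, 0), "positive")
})

test_that("a pure sinusoid carries band power A^2/2", {
  zero <- signal_epoch(matrix(0, 2, 12 * 512), fs = 512)
  out <- add_oscillation(zero, oscillation_spec(6, bandwidth = 0,
                                                amplitude = 10), seed = 3)
  bp <- band_power(welch_psd(out), 4, 8)
  expect_equal(bp$mean, 10^2 / 2, tolerance = 0.02)
  # narrowband noise carries the same calibrated power (looser: spectral
  # leakage moves a little energy past the band edges)
  nb <- add_oscillation(zero, oscillation_spec(6, bandwidth = 1,
                                               amplitude = 10), seed = 3)
  expect_equal(band_power(welch_psd(nb), 4, 8)$mean, 50, tolerance = 0.1)
})

test_that("oscillations are additive and reproducible under a fixed seed", {
  base <- gaussian_epoch(seed = 5, duration = 4, n_channels = 2)
  spec <- oscillation_spec(6, 1, 5)
  out <- add_oscillation(base, spec, seed = 11)
  expect_equal(add_oscillation(base, spec, seed = 11)$samples, out$samples)
  # zero amplitude leaves the input untouched
  same <- add_oscillation(base, oscillation_spec(6, 1, 0), seed = 1)
  expect_identical(same$samples, base$samples)
  # subtracting the seeded realization recovers the input exactly
  osc_only <- add_oscillation(signal_epoch(matrix(0, 2, n_samples(base)),
                                           fs = base$fs), spec, seed = 11)
  expect_equal(out$samples - osc_only$samples, base$samples,
               tolerance = 1e-12)
  expect_error(add_oscillation(base, oscillation_spec(300, 0, 1)),
               "Nyquist|inside")
})

test_that("spike injection returns onsets matching a threshold-detection oracle", {
  base <- generate_background(13, 512, noise_model(1, scale = 2),
                              n_channels = 4, seed = 9)
  res <- inject_spikes(base, spike_model(rate = 0.5, amplitude = 100,
                                         width = 0.05), seed = 2)
  expect_true(length(res$onsets) > 0)
  expect_true(all(res$onsets >= 0 & res$onsets <= 13))
  # oracle: cluster threshold crossings on the strongest channel
  rms_bg <- sqrt(mean(base$samples[1, ]^2))
  hot <- which(abs(res$epoch$samples[1, ]) > 5 * rms_bg)
  clusters <- sum(diff(c(-1000, hot)) > 0.2 * 512)
  expect_equal(clusters, length(res$onsets))
  # rate 0: identity and empty onsets
  none <- inject_spikes(base, spike_model(rate = 0), seed = 1)
  expect_identical(none$epoch$samples, base$samples)
  expect_length(none$onsets, 0)
})

test_that("component stages commute in the final sample values", {
  fs <- 512
  osc <- oscillation_spec(6, 0, 5)
  spk <- spike_model(rate = 0.3, amplitude = 80)
  bg <- generate_background(5, fs, noise_model(1, 5), n_channels = 2,
                            seed = 2)
  a <- inject_spikes(add_oscillation(bg, osc, seed = 3), spk,
                     seed = 4)$epoch
  b <- add_oscillation(inject_spikes(bg, spk, seed = 4)$epoch, osc,
                       seed = 3)
  expect_equal(a$samples, b$samples, tolerance = 1e-12)
})

test_that("session generation fills ground truth and tracks the gain trajectory", {
  plan <- small_plan(n_trials = 6, seed = 1)
  lrn <- learner_model(theta_gain_by_session = c(1, 2), jitter_sd = 0)
  gs <- generate_session(plan, lrn, noise_model(1, 5),
                         oscillation_spec(6, 1, 5), spikes = NULL,
                         session = 1, seed = 10)
  expect_equal(nrow(gs$truth$trials), 6)
  expect_equal(gs$truth$trials$theta_factor, rep(1, 6))
  expect_equal(epoch_duration(gs$recording), session_duration(plan))
  # deterministic given the seed
  gs2 <- generate_session(plan, lrn, noise_model(1, 5),
                          oscillation_spec(6, 1, 5), spikes = NULL,
                          session = 1, seed = 10)
  expect_identical(gs$recording$samples, gs2$recording$samples)
  expect_identical(gs$truth$trials, gs2$truth$trials)
  # session index outside the gain trajectory errors
  expect_error(generate_session(plan, lrn, session = 3), "trajectory")
})

test_that("spike onsets stay inside the session and land in the recording", {
  plan <- small_plan(n_trials = 4, seed = 3)
  gs <- generate_session(plan, learner_model(rep(1, 1)),
                         noise_model(1, 5), oscillation_spec(6, 1, 5),
                         spike_model(rate = 0.1, amplitude = 120),
                         session = 1, seed = 5)
  expect_true(all(gs$truth$spike_onsets >= 0 &
                    gs$truth$spike_onsets <= session_duration(plan)))
})

test_that("doubling the theta gain raises measured encoding theta power", {
  lrn_hi <- learner_model(c(1, 2))
  wins <- 0
  for (r in 1:10) {
    s1 <- simulate_session_spectra(1, lrn_hi, n_trials = 5,
                                   seed = 600 + r)
    s2 <- simulate_session_spectra(2, lrn_hi, n_trials = 5,
                                   seed = 700 + r)
    wins <- wins + (mean(s2$meta$theta_power) > mean(s1$meta$theta_power))
  }
  expect_gte(wins, 9)
})
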