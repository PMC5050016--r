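cfg0 <- synth_config(rng_seed = 1)

test_that("wave trains are reproducible renewal processes", {
  a <- generate_wave_train(cfg0, "L", seed = 7)
  b <- generate_wave_train(cfg0, "L", seed = 7)
  expect_identical(a, b)
  expect_true(all(diff(a$start) > 0))
  expect_true(all(a$scale > 0) && all(a$amp > 0))
  # renewal count: 60 s at 22 +/- 3 ms intervals, floor 5 ms
  n_exp <- 60 / 0.022
  sd_n <- sqrt(n_exp) * 3 / 22
  expect_lt(abs(nrow(a) - n_exp), 3 * sd_n)
  tiny <- generate_wave_train(synth_config(epoch_length = 0.001), seed = 1)
  expect_lte(nrow(tiny), 1)
  expect_error(generate_wave_train(synth_config(epoch_length = 1,
                                                sampling_rate = -1)),
               "positive")
})

test_that("config validation rejects bad parameters", {
  expect_error(synth_config(epoch_length = -1), "positive")
  expect_error(synth_config(unilateral_fraction_left = 1.5), "\\[0, 1\\]")
  expect_error(synth_config(amplitude_covariation = 2), "\\[0, 1\\]")
  expect_error(synth_config(generator_profiles = list(1:3)),
               "per channel")
})

test_that("contralateral derivation obeys the configured lag law", {
  cfg <- synth_config(epoch_length = 5, bilateral_lag_mean = 1,
                      bilateral_lag_sd = 0, amplitude_covariation = 1,
                      pair_scale_jitter = 0,
                      unilateral_fraction_left = 0,
                      unilateral_fraction_right = 0, rng_seed = 2)
  tr <- generate_wave_train(cfg, "L", seed = 3)
  der <- derive_contralateral_train(tr, cfg, seed = 4)
  expect_equal(nrow(der$pairs), nrow(tr))
  # right-lead-positive config lag of 1 ms: stored pair lag is right
  # start minus left start = -1 ms, exactly
  expect_equal(der$pairs$lag_ms, rep(-1, nrow(tr)), tolerance = 1e-9)
  # perfect covariation, zero jitter: amplitudes copied exactly
  expect_equal(der$waves$amp[der$pairs$right_idx], tr$amp,
               tolerance = 1e-9)
  # stored lags always equal right start minus left start
  expect_equal(der$pairs$lag_ms,
               (der$waves$start[der$pairs$right_idx] -
                  tr$start[der$pairs$left_idx]) * 1000,
               tolerance = 1e-9)
})

test_that("paired amplitudes reach the configured Pearson covariation", {
  cfg <- synth_config(epoch_length = 230, amplitude_covariation = 0.5,
                      unilateral_fraction_left = 0,
                      unilateral_fraction_right = 0, rng_seed = 5)
  tr <- generate_wave_train(cfg, "L", seed = 6)
  expect_gt(nrow(tr), 9000)
  der <- derive_contralateral_train(tr, cfg, seed = 7)
  r <- stats::cor(tr$amp[der$pairs$left_idx],
                  der$waves$amp[der$pairs$right_idx])
  expect_lt(abs(r - 0.5), 0.03)
})

test_that("ground-truth pair lags centre on the configured mean", {
  cfg <- synth_config(epoch_length = 60, bilateral_lag_mean = 0.6,
                      bilateral_lag_sd = 0.5, rng_seed = 8)
  tr <- generate_wave_train(cfg, "L", seed = 9)
  der <- derive_contralateral_train(tr, cfg, seed = 10)
  lags <- -der$pairs$lag_ms            # right-lead positive
  se <- stats::sd(lags) / sqrt(length(lags))
  expect_lt(abs(mean(lags) - 0.6), 3 * se)
  # unilateral fractions within binomial bounds of configuration
  n <- nrow(tr)
  p_uni <- 1 - nrow(der$pairs) / n
  expect_lt(abs(p_uni - cfg$unilateral_fraction_left),
            1.96 * sqrt(0.055 * 0.945 / n) + 1e-9)
})

test_that("mixing is the exact linear forward model", {
  gens <- list(sin(2 * pi * 3 * (0:999) / 1000) * 50,
               cos(2 * pi * 7 * (0:999) / 1000) * 20)
  V <- matrix(c(1, 0, 0.5, 0, 1, 0.25), nrow = 3)
  rec <- mix_to_channels(gens, V, noise_sd = 0, rate = 1000)
  expect_equal(rec$voltages,
               V %*% rbind(gens[[1]], gens[[2]]), tolerance = 1e-12)
  recI <- mix_to_channels(gens, diag(2), noise_sd = 0, rate = 1000)
  expect_equal(recI$voltages[1, ], gens[[1]], tolerance = 1e-12)
  expect_error(mix_to_channels(gens, diag(3), rate = 1000), "mismatch")
  # additive noise SD at 60 s, 1 kHz: within 2%
  z <- mix_to_channels(list(numeric(60000)), matrix(1), noise_sd = 10,
                       seed = 11, rate = 1000)
  expect_lt(abs(stats::sd(z$voltages[1, ]) - 10) / 10, 0.02)
})

test_that("spike generation follows the coupling model", {
  cfg <- synth_config(epoch_length = 20, rng_seed = 12,
                      unilateral_fraction_left = 0,
                      unilateral_fraction_right = 0)
  trL <- generate_wave_train(cfg, "L", seed = 13)
  der <- derive_contralateral_train(trL, cfg, seed = 14)
  up <- data.frame(unit_id = "u1", class = "IN", side = "L",
                   base_rate = 5, latency_ms = 3, strength = 0,
                   jitter_ms = 0)
  sp <- generate_spike_trains(trL, der$waves, up, epoch = 20, seed = 15)
  # strength 0: pure Poisson background within 99% bounds
  expect_gte(nrow(sp), stats::qpois(0.005, 100))
  expect_lte(nrow(sp), stats::qpois(0.995, 100))
  # deterministic coupling: one spike 3 ms after each eligible wave
  up2 <- data.frame(unit_id = "u2", class = "IN", side = "L",
                    base_rate = 0, latency_ms = 3, strength = 1,
                    jitter_ms = 0)
  sp2 <- generate_spike_trains(trL, der$waves, up2, epoch = 20, seed = 16)
  keep <- trL$start + 0.003 < 20
  expect_equal(sort(sp2$time_s), sort(trL$start[keep] + 0.003),
               tolerance = 1e-9)
  # PC with no bilateral waves reduces to background
  cfg_uni <- synth_config(epoch_length = 20, rng_seed = 17,
                          unilateral_fraction_left = 1,
                          unilateral_fraction_right = 1)
  trU <- generate_wave_train(cfg_uni, "L", seed = 18)
  derU <- derive_contralateral_train(trU, cfg_uni, seed = 19)
  up3 <- data.frame(unit_id = "u3", class = "PC", side = "L",
                    base_rate = 0, latency_ms = 3, strength = 1,
                    jitter_ms = 0)
  sp3 <- generate_spike_trains(trU, derU$waves, up3, epoch = 20, seed = 20)
  expect_true(is.null(sp3) || nrow(sp3) == 0)
})

test_that("rendered rhythm concentrates power at low gamma", {
  cfg <- synth_config(rng_seed = 21)
  tr <- generate_wave_train(cfg, seed = 22)
  # isolate the rhythm: constant amplitudes (the heavy-tailed amplitude
  # marginal adds broadband shot noise on top of the rhythmic peak)
  trc <- tr
  trc$amp <- 200
  x <- render_generator(trc, 1000, 60)
  x <- x - mean(x)
  sp <- Mod(stats::fft(x))^2
  fr <- (seq_along(x) - 1) / length(x) * 1000
  half <- fr > 0 & fr <= 500
  share <- sum(sp[fr >= 30 & fr <= 60]) / sum(sp[half])
  expect_gte(share, 0.6)
  # under the full default amplitude law the spectral peak stays in-band
  xf <- render_generator(tr, 1000, 60)
  xf <- xf - mean(xf)
  spf <- Mod(stats::fft(xf))^2
  sm <- stats::filter(spf[half], rep(1 / 31, 31), sides = 2)
  pk_f <- fr[half][which.max(replace(sm, fr[half] < 10, NA))]
  expect_gte(pk_f, 30)
  expect_lte(pk_f, 60)
})

test_that("full synthetic recordings are reproducible and consistent", {
  cfg <- synth_config(epoch_length = 2, rng_seed = 23)
  a <- synth_recording(cfg)
  b <- synth_recording(cfg)
  expect_identical(a$recording$voltages, b$recording$voltages)
  expect_identical(a$spikes, b$spikes)
  expect_equal(dim(a$recording$voltages), c(64, 2000))
  expect_equal(ncol(a$truth$mixing), 4)
  # every stored pair refers to existing waves
  for (g in 1:2) {
    p <- a$truth$pairs[[g]]
    expect_true(all(p$left_idx <= nrow(a$truth$waves$L[[g]])))
    expect_true(all(p$right_idx <= nrow(a$truth$waves$R[[g]])))
  }
})
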