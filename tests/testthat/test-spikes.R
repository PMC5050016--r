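test_that("spike-window classification conserves spikes and time", {
  wl <- gw(c(0.1, 0.2), 0.02, side = "L")
  wr <- gw(c(0.105, 0.5), 0.02, side = "R")
  sp <- c(0.05, 0.11, 0.205, 0.505)
  cs <- classify_spike_windows(sp, wl, wr, 1)
  expect_equal(unname(cs$counts), c(1, 1, 1, 1))
  expect_equal(sum(cs$counts), length(sp))
  expect_equal(sum(cs$ratios), 1, tolerance = 1e-12)
  # no waves: everything is None
  none <- classify_spike_windows(sp, gw(numeric(0), numeric(0)),
                                 gw(numeric(0), numeric(0)), 1)
  expect_equal(unname(none$counts), c(4, 0, 0, 0))
  expect_equal(unname(none$ratios), c(1, 0, 0, 0))
  # boundary: a spike exactly at a wave start is inside (closed start),
  # exactly at the end is outside (open end)
  wb <- gw(0.25, 0.25, side = "L")   # binary-exact interval [0.25, 0.5)
  b <- classify_spike_windows(c(0.25, 0.5), wb,
                              gw(numeric(0), numeric(0)), 1)
  expect_equal(unname(b$counts), c(1, 0, 1, 0))
  expect_error(classify_spike_windows(sp, wl, wr, 0), "epoch")
  expect_error(classify_spike_windows(2, wl, wr, 1), "cover")
})

test_that("window classification matches the brute-force oracle", {
  for (i in 1:25) {
    wl <- random_wave_table(sample(1:40, 1), seed = 600 + i)
    wr <- random_wave_table(sample(1:40, 1), seed = 700 + i)
    sp <- gammasync:::with_seed(800 + i,
                                sort(stats::runif(sample(1:50, 1), 0, 2)))
    cs <- classify_spike_windows(sp, wl, wr, 2)
    expect_identical(cs$counts, brute_force_windows(sp, wl, wr),
                     label = paste("instance", i))
  }
})

test_that("window flags have nominal type-I rates for random trains", {
  cfg <- synth_config(epoch_length = 30, rng_seed = 121)
  wl <- {
    tr <- generate_wave_train(cfg, "L", seed = 122)
    gw(tr$start, 2.27 * tr$scale, tr$amp, "L")
  }
  wr <- {
    tr <- generate_wave_train(cfg, "R", seed = 123)
    gw(tr$start, 2.27 * tr$scale, tr$amp, "R")
  }
  above <- below <- 0L
  n_rep <- 250
  set.seed(124)
  for (r in seq_len(n_rep)) {
    sp <- sort(stats::runif(stats::rpois(1, 150), 0, 30))
    cs <- classify_spike_windows(sp, wl, wr, 30)
    above <- above + sum(cs$flags == "above")
    below <- below + sum(cs$flags == "below")
  }
  n_tests <- 4 * n_rep
  bound <- 1.96 * sqrt(0.05 * 0.95 / n_tests)
  expect_lt(abs(above / n_tests - 0.05), bound + 0.01)
  expect_lt(abs(below / n_tests - 0.05), bound + 0.01)
})

test_that("comodulogram accumulates lag combinations additively", {
  wl <- gw(0.0915, 0.02, side = "L")  # L start - spike = -8.5 ms
  wr <- gw(0.0905, 0.02, side = "R")  # R start - spike = -9.5 ms
  cm <- comodulogram(0.1, wl, wr)
  expect_equal(sum(cm$H), 1)
  # bin index: floor((lag + 40)/1) + 1 -> rows are R lags
  expect_equal(cm$H[31, 32], 1L)
  expect_equal(sum(comodulogram(numeric(0), wl, wr)$H), 0)
  # additivity over spike trains
  wl2 <- random_wave_table(40, seed = 131)
  wr2 <- random_wave_table(40, seed = 132)
  s1 <- gammasync:::with_seed(133, sort(stats::runif(30, 0, 2)))
  s2 <- gammasync:::with_seed(134, sort(stats::runif(25, 0, 2)))
  expect_equal(comodulogram(c(s1, s2), wl2, wr2)$H,
               comodulogram(s1, wl2, wr2)$H +
                 comodulogram(s2, wl2, wr2)$H)
})

test_that("the Poisson chance threshold follows its closed form", {
  expect_equal(chance_threshold(0, 1000, 100, 500, 0.001), 0)
  expect_equal(chance_threshold(1000, 0, 100, 500, 0.001), 0)
  P <- (1 - exp(-0.01))^2
  expect_equal(chance_threshold(1000, 1000, 100, 500, 0.001),
               P * 500 + stats::qnorm(0.95) * sqrt(500 * P * (1 - P)),
               tolerance = 1e-12)
  # monotone in each argument
  base <- chance_threshold(500, 600, 100, 400, 0.001)
  expect_gte(chance_threshold(600, 600, 100, 400, 0.001), base)
  expect_gte(chance_threshold(500, 700, 100, 400, 0.001), base)
  expect_gte(chance_threshold(500, 600, 100, 500, 0.001), base)
  expect_gte(chance_threshold(500, 600, 100, 400, 0.002), base)
})

test_that("significant density clips at the threshold", {
  H <- matrix(0:8, 3)
  expect_equal(significant_density(H, 10), matrix(0, 3, 3))
  expect_equal(significant_density(H, 0), H)
  H2 <- matrix(0, 3, 3); H2[2, 2] <- 12
  out <- significant_density(H2, 7)
  expect_equal(out[2, 2], 5)
  expect_equal(sum(out), 5)
  expect_error(significant_density(H, -1), ">= 0")
})

test_that("comodulogram flags coupled synthetic units, not random ones", {
  cfg <- synth_config(epoch_length = 40, bilateral_lag_mean = 1,
                      rng_seed = 141)
  trL <- generate_wave_train(cfg, "L", seed = 142)
  der <- derive_contralateral_train(trL, cfg, seed = 143)
  up <- data.frame(unit_id = "in1", class = "IN", side = "R",
                   base_rate = 2, latency_ms = 3, strength = 0.6,
                   jitter_ms = 0.5)
  sp <- generate_spike_trains(trL, der$waves, up, 40, seed = 144)
  wl <- gw(trL$start, 2.27 * trL$scale, trL$amp, "L")
  wr <- gw(der$waves$start, 2.27 * der$waves$scale, der$waves$amp, "R")
  cm <- comodulogram(sp$time_s, wl, wr)
  thr <- chance_threshold(nrow(wl), nrow(wr), 40, nrow(sp), 0.001)
  hs <- significant_density(cm, thr)
  expect_gt(sum(hs > 0), 0)
  # mass concentrates at the coupling latency: R lag -3 ms (bin 38)
  peak <- which(hs == max(hs), arr.ind = TRUE)[1, ]
  expect_lte(abs(peak[["row"]] - 38), 2)
  # Poisson waves + independent Poisson spikes in the regime the chance
  # model assumes (sparse waves per bin, sparse firing, long epoch):
  # exceedance of the alpha = 0.05 threshold stays near nominal.
  # Rhythmic waves violate the Poisson assumption along diagonal bands,
  # and dense regimes expose the normal approximation's skew.
  T_cal <- 50000
  wlp <- random_wave_table(250000, epoch = T_cal, seed = 147)
  wrp <- random_wave_table(250000, epoch = T_cal, seed = 247)
  spr <- gammasync:::with_seed(346,
                               sort(stats::runif(2e6, 0, T_cal)))
  thrp <- chance_threshold(250000, 250000, T_cal, length(spr), 0.001)
  hr <- significant_density(comodulogram(spr, wlp, wrp), thrp)
  expect_lt(sum(hr > 0) / length(hr), 0.07)
})

test_that("power profile recovers the two-exponent amplitude law", {
  law <- amplitude_power_law(amp_min = 20)
  cfg <- synth_config(epoch_length = 60, rng_seed = 146,
                      wave_amplitude_law = law)
  tr <- generate_wave_train(cfg, seed = 147)
  x <- render_generator(tr, 1000, 60)
  pp <- power_profile(x, list(), 1000)
  expect_false(pp$degenerate)
  expect_lt(abs(pp$exponents[["k1"]] - (-1.22)), 0.3)
  expect_lt(abs(pp$exponents[["k2"]] - (-2.66)), 0.3)
  # power axis normalized to the fitted breakpoint
  expect_equal(sum(pp$power_grid < 1), sum(pp$edges[-1] < pp$critical_power))
  # constant-amplitude sinusoid: no two-regime structure
  s <- 100 * sin(2 * pi * 45 * (0:59999) / 1000)
  expect_true(suppressWarnings(power_profile(s, list(), 1000))$degenerate)
})

test_that("differential spike-power densities are calibrated", {
  law <- amplitude_power_law(amp_min = 20)
  cfg <- synth_config(epoch_length = 40, rng_seed = 151,
                      wave_amplitude_law = law)
  tr <- generate_wave_train(cfg, seed = 152)
  x <- render_generator(tr, 1000, 40)
  # random spikes: differential inside the resampled band nearly always
  sp <- gammasync:::with_seed(153, sort(stats::runif(300, 0, 40)))
  pp <- power_profile(x, list(null = sp), 1000, seed = 154)
  d <- pp$differential$null
  frac_out <- mean(d$diff < d$band_low | d$diff > d$band_high)
  expect_lte(frac_out, 0.1)
  # spikes biased to high power: strongly outside the band
  p <- x^2
  hot <- which(p > stats::quantile(p, 0.98))
  sph <- gammasync:::with_seed(155, sort(sample(hot, 300, TRUE)) / 1000)
  pph <- power_profile(x, list(hot = sph), 1000, seed = 156)
  dh <- pph$differential$hot
  expect_gt(mean(dh$diff < dh$band_low | dh$diff > dh$band_high), 0.2)
  expect_warning(power_profile(x, list(few = c(1, 2)), 1000, seed = 1),
                 "fewer than")
})
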