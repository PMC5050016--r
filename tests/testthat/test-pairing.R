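test_that("overlap index follows the temporal-overlap definition", {
  expect_equal(overlap_index(0.1, 0.02, 0.1, 0.02), 1)
  expect_equal(overlap_index(0.1, 0.02, 0.5, 0.02), 0)
  # durations 20, overlap 14 (integer-exact arithmetic): omega exactly
  # 0.7, NOT pairable under the strict inequality
  om <- overlap_index(0, 20, 6, 20)
  expect_equal(om, 0.7, tolerance = 1e-12)
  wa <- gw(0, 20)
  wb <- gw(6, 20)
  expect_equal(nrow(pair_waves(wa, wb, window_s = 50)$pairs), 0)
  # nudge into pairing range
  wb2 <- gw(5.9, 20)
  expect_equal(nrow(pair_waves(wa, wb2, window_s = 50)$pairs), 1)
  expect_error(overlap_index(0.1, 0, 0.1, 0.02), "d1 > 0")
})

test_that("overlap index is symmetric and shift invariant", {
  set.seed(101)
  for (i in 1:50) {
    s <- stats::runif(2, 0, 1)
    d <- stats::runif(2, 0.005, 0.04)
    sh <- stats::runif(1, -5, 5)
    o1 <- overlap_index(s[1], d[1], s[2], d[2])
    expect_equal(o1, overlap_index(s[2], d[2], s[1], d[1]))
    expect_equal(o1, overlap_index(s[1] + sh, d[1], s[2] + sh, d[2]),
                 tolerance = 1e-9)
    expect_gte(o1, 0)
    expect_lte(o1, 1)
  }
})

test_that("pairing handles empty and exact fixtures", {
  wa <- gw(c(0.1, 0.2, 0.3), 0.02)
  p0 <- pair_waves(wa, gw(numeric(0), numeric(0)))
  expect_equal(nrow(p0$pairs), 0)
  expect_equal(p0$unpaired_a, 1:3)
  # no-jitter synthetic pairs recovered perfectly, no spurious
  cfg <- synth_config(epoch_length = 20, bilateral_lag_mean = 1,
                      bilateral_lag_sd = 0,
                      unilateral_fraction_left = 0.1,
                      unilateral_fraction_right = 0.05, rng_seed = 102)
  tr <- generate_wave_train(cfg, "L", seed = 103)
  der <- derive_contralateral_train(tr, cfg, seed = 104)
  span <- 2.27
  wl <- gw(tr$start, span * tr$scale, tr$amp, "L")
  wr <- gw(der$waves$start, span * der$waves$scale, der$waves$amp, "R")
  pr <- pair_waves(wl, wr)
  truth <- paste(der$pairs$left_idx, der$pairs$right_idx)
  got <- paste(pr$pairs$idx_a, pr$pairs$idx_b)
  expect_gte(mean(truth %in% got), 0.995)
  expect_lte(nrow(pr$pairs), nrow(der$pairs) + 2)
})

test_that("pairing is symmetric with negated lags", {
  wa <- random_wave_table(60, seed = 105)
  wb <- random_wave_table(55, seed = 106)
  ab <- pair_waves(wa, wb)
  ba <- pair_waves(wb, wa)
  expect_equal(nrow(ab$pairs), nrow(ba$pairs))
  ka <- paste(ab$pairs$idx_a, ab$pairs$idx_b)
  kb <- paste(ba$pairs$idx_b, ba$pairs$idx_a)
  expect_setequal(ka, kb)
  m <- match(ka, kb)
  expect_equal(ab$pairs$lag_ms, -ba$pairs$lag_ms[m], tolerance = 1e-9)
})

test_that("pairing agrees with the exhaustive brute-force matching", {
  for (i in 1:25) {
    wa <- random_wave_table(sample(3:40, 1), seed = 200 + i)
    wb <- random_wave_table(sample(3:40, 1), seed = 300 + i)
    pr <- pair_waves(wa, wb)
    bf <- brute_force_pairs(wa, wb)
    expect_identical(unname(cbind(pr$pairs$idx_a, pr$pairs$idx_b)),
                     unname(matrix(as.integer(bf), ncol = 2)),
                     label = paste("instance", i))
  }
})

test_that("lag statistics use the uncorrected-SD t interval", {
  wa <- gw(seq(0.1, 2, by = 0.1), 0.02)
  wb <- gw(seq(0.1, 2, by = 0.1) + 0.001, 0.02)
  ls <- lag_statistics(pair_waves(wa, wb), alpha = 0.01)
  expect_equal(ls$mean_lag, 1, tolerance = 1e-9)
  expect_equal(unname(diff(ls$ci)), 0, tolerance = 1e-9)
  # symmetric lags average to zero
  wb2 <- gw(seq(0.1, 2, by = 0.1) + rep(c(-0.001, 0.001), 10), 0.02)
  ls2 <- lag_statistics(pair_waves(wa, wb2))
  expect_equal(ls2$mean_lag, 0, tolerance = 1e-9)
  expect_error(lag_statistics(pair_waves(wa[1, ], wb[1, ])), "2 pairs")
  # CI formula against a hand computation
  lags <- c(0.4, 0.9, 1.1, 1.6)
  wb3 <- gw(wa$start[1:4] + lags / 1000, 0.02)
  ls3 <- lag_statistics(pair_waves(wa[1:4, ], wb3), alpha = 0.05)
  s <- sqrt(mean((lags - mean(lags))^2))
  half <- stats::qt(0.975, 3) * s / sqrt(3)
  expect_equal(unname(ls3$ci), c(mean(lags) - half, mean(lags) + half),
               tolerance = 1e-9)
})

test_that("lag CI has nominal coverage on simulated pairings", {
  hits <- 0
  for (r in 1:100) {
    set.seed(400 + r)
    lags <- stats::rnorm(1000, 1, 0.5)
    wa <- gw(seq_len(1000) * 0.03, 0.02)
    wb <- gw(wa$start + lags / 1000, 0.02)
    ls <- lag_statistics(pair_waves(wa, wb), alpha = 0.01)
    if (ls$ci[1] <= 1 && 1 <= ls$ci[2]) hits <- hits + 1
    if (r == 1) expect_lt(abs(ls$mean_lag - 1), 0.05)
  }
  expect_gte(hits, 98)
})

test_that("covariation uses the principal-axis slope", {
  x <- seq(1, 10, length.out = 50)
  mk <- function(y) {
    wa <- gw(seq_len(50) * 0.05, 0.02, amp = x)
    wb <- gw(wa$start + 0.001, 0.02, amp = y)
    pair_waves(wa, wb)
  }
  c1 <- covariation(mk(x), "amplitude")
  expect_equal(c1$slope, 1, tolerance = 1e-9)
  expect_equal(c1$r, 1, tolerance = 1e-9)
  c2 <- covariation(mk(2 * x), "amplitude")
  expect_equal(c2$slope, 2, tolerance = 1e-9)
  expect_error(covariation(mk(rep(5, 50)), "amplitude"), "zero-variance")
  # bivariate normal, rho = 0.5, n = 5000
  set.seed(107)
  z1 <- stats::rnorm(5000)
  z2 <- 0.5 * z1 + sqrt(1 - 0.25) * stats::rnorm(5000)
  wa <- gw(seq_len(5000) * 0.05, 0.02, amp = 100 + 10 * z1)
  wb <- gw(wa$start + 0.001, 0.02, amp = 100 + 10 * z2)
  expect_lt(abs(covariation(pair_waves(wa, wb), "amplitude")$r - 0.5),
            0.03)
})

test_that("unilateral percentages match configured fractions", {
  cfg <- synth_config(epoch_length = 40, bilateral_lag_mean = 0.6,
                      unilateral_fraction_left = 0.1,
                      unilateral_fraction_right = 0.05, rng_seed = 108)
  tr <- generate_wave_train(cfg, "L", seed = 109)
  der <- derive_contralateral_train(tr, cfg, seed = 110)
  wl <- gw(tr$start, 2.27 * tr$scale, tr$amp, "L")
  wr <- gw(der$waves$start, 2.27 * der$waves$scale, der$waves$amp, "R")
  ls <- lag_statistics(pair_waves(wl, wr))
  for (s in c("a", "b")) {
    p0 <- if (s == "a") 0.1 else 0.05
    n <- if (s == "a") nrow(wl) else nrow(wr)
    bound <- 1.96 * sqrt(p0 * (1 - p0) / n) * 100
    expect_lt(abs(ls$unilateral_pct[[s]] - 100 * p0), bound + 1.5)
  }
})
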