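make_two_source_rec <- function(epoch = 8, noise_sd = 0, seed = 31,
                                rate = 1000) {
  cfg <- synth_config(epoch_length = epoch, noise_sd = noise_sd,
                      rng_seed = seed)
  t1 <- generate_wave_train(cfg, "L", seed = seed + 1)
  t2 <- generate_wave_train(cfg, "L", seed = seed + 2)
  s1 <- render_generator(t1, rate, epoch)
  s2 <- render_generator(t2, rate, epoch)
  nch <- 16
  prof <- default_profiles(nch)
  V <- cbind(prof[[1]], prof[[2]])
  rec <- mix_to_channels(list(s1, s2), V, noise_sd = noise_sd,
                         seed = seed + 3, rate = rate)
  list(rec = rec, s = rbind(s1, s2), V = V)
}

test_that("high-pass preprocessing removes DC and keeps gamma", {
  rate <- 1000
  tt <- (0:9999) / rate
  s45 <- sin(2 * pi * 45 * tt)
  rec <- lfp_recording(rbind(s45 + 100, tt * 0 + 3), rate)
  out <- preprocess(rec, highpass_hz = 1)
  mid <- 2000:8000   # avoid filter edge transients
  expect_lt(abs(stats::sd(out$voltages[1, mid]) - stats::sd(s45[mid])) /
              stats::sd(s45[mid]), 0.01)
  expect_lt(abs(mean(out$voltages[1, ])), 1e-3)  # edge transients only
  expect_lt(max(abs(out$voltages[2, ])), 1e-6 * 3 + 1e-9)
  z <- preprocess(lfp_recording(matrix(0, 1, 1000), rate))
  expect_true(all(z$voltages == 0))
  expect_error(preprocess(rec, highpass_hz = 600), "Nyquist")
})

test_that("sharp-wave masking finds injected slow deflections", {
  rate <- 1000
  flat <- stats::rnorm(10000, 0, 1)
  expect_equal(nrow(mask_sharp_waves(flat * 0, rate)), 0)
  # one large 60 ms deflection on a gamma-like background
  tt <- (0:9999) / rate
  bg <- 30 * sin(2 * pi * 45 * tt)
  spw <- 600 * exp(-(tt - 5)^2 / (2 * 0.015^2))
  m <- mask_sharp_waves(bg + spw, rate)
  expect_equal(nrow(m), 1)
  expect_lte(m[1, 1], 5)
  expect_gte(m[1, 2], 5)
  # explicit intervals returned verbatim
  iv <- cbind(c(1, 2), c(1.5, 2.5))
  expect_equal(unname(mask_sharp_waves(flat, rate, intervals = iv)),
               unname(iv))
})

test_that("decomposition recovers synthetic generators", {
  # orthogonal spatial profiles, zero noise, 20 s epoch
  cfg <- synth_config(epoch_length = 20, rng_seed = 31)
  s1 <- render_generator(generate_wave_train(cfg, seed = 32), 1000, 20)
  s2 <- render_generator(generate_wave_train(cfg, seed = 33), 1000, 20)
  V <- cbind(exp(-((1:16) - 4)^2 / 8), exp(-((1:16) - 12)^2 / 8))
  V[9:16, 1] <- 0
  V[1:8, 2] <- 0
  fx <- list(rec = mix_to_channels(list(s1, s2), V, noise_sd = 0,
                                   rate = 1000),
             s = rbind(s1, s2), V = V)
  dec <- decompose(fx$rec, 2, seed = 1)
  cc <- abs(stats::cor(t(dec$activations), t(fx$s)))
  # best match per true source after sign/permutation matching
  expect_gt(max(cc[, 1]), 0.999)
  expect_gt(max(cc[, 2]), 0.999)
  # mixing recovered up to permutation/sign/scale within 1%
  vm <- abs(stats::cor(dec$mixing, fx$V))
  expect_gt(max(vm[, 1]), 0.99)
  expect_gt(max(vm[, 2]), 0.99)
  # normalization conventions
  expect_equal(unname(apply(abs(dec$mixing), 2, max)), c(1, 1),
               tolerance = 1e-9)
  for (k in 1:2) {
    s <- dec$activations[k, ]
    big <- abs(s - mean(s)) > 3 * stats::sd(s)
    expect_gt(mean(s[big]), 0)
  }
  expect_true(all(diff(dec$variance_share) <= 1e-12))
})

test_that("complete decompositions explain all variance", {
  set.seed(41)
  X <- matrix(stats::rnorm(4 * 4000), 4)
  rec <- lfp_recording(X, 1000)
  dec <- decompose(rec, 4, seed = 2)
  expect_lt(abs(sum(dec$variance_share) - 1), 1e-6)
  # reconstruction residual matches 1 - sum(variance_share)
  Xc <- X - rowMeans(X)
  R <- dec$mixing %*% dec$activations - Xc
  res <- sum(R^2) / sum(Xc^2)
  expect_lt(abs(res - (1 - sum(dec$variance_share))), 1e-6)
})

test_that("rank-deficient input is reported with its dimension", {
  X <- matrix(stats::rnorm(2000), 2)
  X <- rbind(X, X[1, ] + X[2, ])     # third channel linearly dependent
  expect_error(decompose(lfp_recording(X, 1000), 3),
               "rank-deficient.*3")
  expect_error(decompose(lfp_recording(X, 1000), 5), "channel count")
})

test_that("masked epochs are excluded from the fit", {
  fx <- make_two_source_rec(noise_sd = 2, seed = 55)
  v <- fx$rec$voltages
  # corrupt one second; mask it out
  v[, 3001:4000] <- v[, 3001:4000] + 5000
  rec <- lfp_recording(v, 1000, epoch_masks = cbind(3.0, 4.0))
  dec <- decompose(rec, 2, seed = 1)
  keep <- setdiff(seq_len(ncol(v)), 3001:4000)
  cc <- abs(stats::cor(t(dec$activations[, keep]), t(fx$s[, keep])))
  expect_gt(max(cc[, 1]), 0.99)
  expect_gt(max(cc[, 2]), 0.99)
})

test_that("components match across shanks by spatial profile", {
  fx <- make_two_source_rec(noise_sd = 3, seed = 61)
  dec <- decompose(fx$rec, 2, seed = 1)
  self <- match_components(dec, dec)
  expect_equal(self$pairs$a_idx, self$pairs$b_idx)
  expect_equal(self$pairs$score, c(1, 1), tolerance = 1e-12)
  # permuted copy: inverse permutation recovered
  perm <- dec
  perm$mixing <- dec$mixing[, 2:1]
  mp <- match_components(dec, perm)
  expect_equal(mp$pairs$b_idx[mp$pairs$a_idx], c(2, 1))
  # independent-noise second shank with the same profiles
  fx2 <- make_two_source_rec(noise_sd = 3, seed = 62)
  dec2 <- decompose(fx2$rec, 2, seed = 1)
  m <- match_components(dec, dec2)
  expect_true(all(m$pairs$score > 0.9))
  lab <- label_generators(dec, default_profiles(16))
  expect_setequal(lab$labels, c("schaffer", "ca3som"))
})
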