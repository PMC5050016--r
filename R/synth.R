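#' Configuration for the synthetic bilateral gamma recording generator
#'
#' Builds and validates the parameter set describing the statistical structure
#' the analysis pipeline assumes: strings of pulse-like gamma waves repeating
#' at ~20--25 ms intervals in each hemisphere, bilateral wave pairs with a
#' sub-millisecond right-lead lag and partial amplitude covariation, a
#' minority of unilateral waves, linear spatial mixing onto multichannel
#' probes, and additive sensor noise.
#'
#' @param n_channels_per_shank electrode contacts per shank.
#' @param n_shanks shanks per hemisphere (anterior/posterior).
#' @param sampling_rate sampling rate in Hz. The default 1 kHz is ample for
#'   analyses confined below 100 Hz.
#' @param epoch_length epoch length in seconds.
#' @param generator_profiles optional list of per-generator spatial weight
#'   curves, one value per channel of a single shank; defaults to two smooth
#'   depth profiles (a Schaffer-like and a CA3som-like bump).
#' @param wave_interval_mean,wave_interval_jitter mean and SD (ms) of the
#'   truncated-normal inter-wave interval law (floor
#'   `wave_interval_floor` ms).
#' @param wave_interval_floor hard lower bound (ms) on intervals.
#' @param wave_amplitude_law distribution spec for peak amplitudes; see
#'   [amplitude_power_law()]. Default: two-exponent power law in the
#'   instantaneous-power domain.
#' @param wave_scale,wave_scale_sd,wave_scale_floor alpha-kernel time-scale
#'   law (ms): truncated normal.
#' @param bilateral_lag_mean signed mean bilateral start-time lag in ms,
#'   right-lead positive (the right wave starts earlier).
#' @param bilateral_lag_sd SD of the lag law (ms).
#' @param amplitude_covariation target Pearson correlation in \[0,1\] between
#'   paired-wave peak amplitudes (achieved through an internally calibrated
#'   Gaussian copula).
#' @param pair_scale_jitter SD (ms) of the paired-wave kernel-scale
#'   perturbation, giving partial duration covariation.
#' @param unilateral_fraction_left,unilateral_fraction_right proportion of
#'   waves on each side lacking a contralateral partner.
#' @param noise_sd additive white channel noise SD (uV).
#' @param power_law_exponents two log-log slopes (k1, k2) of the default
#'   amplitude-shaping law below/above the critical power.
#' @param rng_seed integer seed from which all per-stage seeds derive.
#' @return an object of class `synth_config` (a validated list).
#' @seealso [synth_recording()], [generate_wave_train()]
#' @export
synth_config <- function(n_channels_per_shank = 16,
                         n_shanks = 2,
                         sampling_rate = 1000,
                         epoch_length = 60,
                         generator_profiles = NULL,
                         wave_interval_mean = 22,
                         wave_interval_jitter = 3,
                         wave_interval_floor = 5,
                         wave_amplitude_law = NULL,
                         wave_scale = 8,
                         wave_scale_sd = 2,
                         wave_scale_floor = 3,
                         bilateral_lag_mean = 0.6,
                         bilateral_lag_sd = 0.5,
                         amplitude_covariation = 0.5,
                         pair_scale_jitter = 1,
                         unilateral_fraction_left = 0.055,
                         unilateral_fraction_right = 0.117,
                         noise_sd = 5,
                         power_law_exponents = c(-1.22, -2.66),
                         rng_seed = 1L) {
  if (sampling_rate <= 0) stop("sampling_rate must be positive")
  if (epoch_length <= 0) stop("epoch_length must be positive")
  if (unilateral_fraction_left < 0 || unilateral_fraction_left > 1 ||
      unilateral_fraction_right < 0 || unilateral_fraction_right > 1)
    stop("unilateral fractions must lie in [0, 1]")
  if (amplitude_covariation < 0 || amplitude_covariation > 1)
    stop("amplitude_covariation must lie in [0, 1]")
  if (wave_interval_mean <= 0 || wave_scale <= 0)
    stop("wave interval and scale must be positive")
  if (is.null(wave_amplitude_law))
    wave_amplitude_law <- amplitude_power_law(exponents = power_law_exponents)
  cfg <- list(n_channels_per_shank = as.integer(n_channels_per_shank),
              n_shanks = as.integer(n_shanks),
              sampling_rate = sampling_rate, epoch_length = epoch_length,
              generator_profiles = generator_profiles,
              wave_interval_mean = wave_interval_mean,
              wave_interval_jitter = wave_interval_jitter,
              wave_interval_floor = wave_interval_floor,
              wave_amplitude_law = wave_amplitude_law,
              wave_scale = wave_scale, wave_scale_sd = wave_scale_sd,
              wave_scale_floor = wave_scale_floor,
              bilateral_lag_mean = bilateral_lag_mean,
              bilateral_lag_sd = bilateral_lag_sd,
              amplitude_covariation = amplitude_covariation,
              pair_scale_jitter = pair_scale_jitter,
              unilateral_fraction_left = unilateral_fraction_left,
              unilateral_fraction_right = unilateral_fraction_right,
              noise_sd = noise_sd,
              power_law_exponents = power_law_exponents,
              rng_seed = rng_seed)
  if (!is.null(generator_profiles)) {
    len <- vapply(generator_profiles, length, 1L)
    if (any(len != n_channels_per_shank))
      stop("each generator profile needs one value per channel of a shank")
  }
  structure(cfg, class = "synth_config")
}

#' Two-exponent power-law amplitude distribution
#'
#' Distribution spec for gamma-wave peak amplitudes. Amplitudes are drawn so
#' that the wave-peak *power* \eqn{a = A^2} follows a piecewise power law:
#' density proportional to \eqn{a^{k_1}} below the critical power and to
#' \eqn{a^{k_2}} above it (continuous at the break). Sub-detection events
#' (below `amp_min`) are regarded as noise, not gamma waves, and are not
#' generated.
#'
#' @param exponents numeric pair (k1, k2), both < -0.5.
#' @param amp_min,amp_crit,amp_max support floor, critical point and cap of
#'   the peak amplitude, in uV.
#' @return a list of class `amplitude_law` with `draw`, `cdf` and `quantile`
#'   closures operating on amplitudes (uV).
#' @export
amplitude_power_law <- function(exponents = c(-1.22, -2.66),
                                amp_min = 50, amp_crit = 250, amp_max = 1500) {
  k1 <- exponents[1]; k2 <- exponents[2]
  stopifnot(k1 < -0.5, k2 < -1, amp_min < amp_crit, amp_crit < amp_max)
  a0 <- amp_min^2; ac <- amp_crit^2; a1 <- amp_max^2
  # Piecewise density c * a^k1 (a0..ac), c * ac^(k1-k2) * a^k2 (ac..a1).
  i1 <- (ac^(k1 + 1) - a0^(k1 + 1)) / (k1 + 1)
  i2 <- ac^(k1 - k2) * (a1^(k2 + 1) - ac^(k2 + 1)) / (k2 + 1)
  z <- i1 + i2
  pcut <- i1 / z
  qfun <- function(u) {
    a <- numeric(length(u))
    lo <- u <= pcut
    a[lo] <- (a0^(k1 + 1) + u[lo] * z * (k1 + 1))^(1 / (k1 + 1))
    r <- u[!lo] * z - i1
    a[!lo] <- (ac^(k2 + 1) + r * (k2 + 1) / ac^(k1 - k2))^(1 / (k2 + 1))
    sqrt(a)
  }
  pfun <- function(amp) {
    a <- pmin(pmax(amp^2, a0), a1)
    p <- ifelse(a <= ac,
                (a^(k1 + 1) - a0^(k1 + 1)) / (k1 + 1),
                i1 + ac^(k1 - k2) * (a^(k2 + 1) - ac^(k2 + 1)) / (k2 + 1))
    pmin(pmax(p / z, 0), 1)
  }
  structure(list(type = "power_law", exponents = c(k1, k2),
                 amp_min = amp_min, amp_crit = amp_crit, amp_max = amp_max,
                 draw = function(n) qfun(stats::runif(n)),
                 cdf = pfun, quantile = qfun),
            class = "amplitude_law")
}

# Calibrate the Gaussian-copula parameter so the Pearson correlation of
# paired amplitudes matches `target`. Deterministic: fixed internal
# Monte-Carlo draws, monotone interpolation of rho -> cor.
.copula_cache <- new.env(parent = emptyenv())
calibrate_copula <- function(law, target) {
  if (target <= 0) return(0)
  if (target >= 1) return(1)
  key <- paste(signif(unlist(law[c("exponents", "amp_min", "amp_crit",
                                   "amp_max")]), 8), signif(target, 6),
               collapse = "_")
  if (!is.null(.copula_cache[[key]])) return(.copula_cache[[key]])
  n <- 2e5
  zz <- with_seed(982451653, list(z1 = stats::rnorm(n), e = stats::rnorm(n)))
  a1 <- law$quantile(stats::pnorm(zz$z1))
  rhos <- seq(0, 0.995, by = 0.015)
  cors <- vapply(rhos, function(r) {
    stats::cor(a1, law$quantile(stats::pnorm(r * zz$z1 +
                                               sqrt(1 - r^2) * zz$e)))
  }, 1)
  cors <- cummax(cors)  # enforce monotonicity against MC wiggle
  rho <- stats::approx(cors, rhos, xout = target, rule = 2)$y
  .copula_cache[[key]] <- rho
  rho
}

#' Generate one side's train of true gamma waves
#'
#' Draws a renewal process of wave start times (truncated-normal intervals),
#' kernel scales and peak amplitudes according to the configured laws.
#'
#' @param config a [synth_config()].
#' @param side side label, `"L"` or `"R"` (metadata only).
#' @param seed integer seed; identical seeds give identical trains.
#' @return data.frame with columns `start` (s, strictly increasing), `scale`
#'   (s) and `amp` (uV), with attribute `side`.
#' @export
generate_wave_train <- function(config, side = "L", seed = NULL) {
  if (config$epoch_length <= 0 || config$sampling_rate <= 0)
    stop("configuration error: non-positive epoch or rate")
  mu <- config$wave_interval_mean / 1000
  sj <- config$wave_interval_jitter / 1000
  fl <- config$wave_interval_floor / 1000
  with_seed(seed, {
    n_guess <- ceiling(config$epoch_length / mu * 1.25) + 20
    iv <- rtnorm(n_guess, mu, sj, lower = fl)
    starts <- cumsum(iv)
    while (starts[length(starts)] < config$epoch_length) {
      iv <- rtnorm(n_guess, mu, sj, lower = fl)
      starts <- c(starts, starts[length(starts)] + cumsum(iv))
    }
    starts <- starts[starts < config$epoch_length]
    n <- length(starts)
    scl <- rtnorm(n, config$wave_scale / 1000, config$wave_scale_sd / 1000,
                  lower = config$wave_scale_floor / 1000)
    amp <- config$wave_amplitude_law$draw(n)
    structure(data.frame(start = starts, scale = scl, amp = amp),
              side = side)
  })
}

#' Derive the contralateral wave train with pairing ground truth
#'
#' Each source wave is copied to the other hemisphere with probability
#' 1 minus the source side's unilateral fraction; copies are shifted by a
#' draw from the bilateral lag law and receive an amplitude correlated with
#' the source amplitude through a Gaussian copula calibrated to the
#' configured Pearson covariation. Independent unilateral waves are then
#' inserted on the target side at its configured fraction.
#'
#' @param train source-side wave train from [generate_wave_train()].
#' @param config a [synth_config()].
#' @param seed integer seed.
#' @param source_side `"L"` or `"R"`; the output train is the opposite side.
#' @return list with `waves` (target-side train, sorted by start) and
#'   `pairs`, a data.frame `(left_idx, right_idx, lag_ms)` where `lag_ms` is
#'   right start minus left start (negative when the right side leads).
#' @export
derive_contralateral_train <- function(train, config, seed = NULL,
                                       source_side = "L") {
  stopifnot(!is.unsorted(train$start))
  target_side <- if (source_side == "L") "R" else "L"
  u_src <- if (source_side == "L") config$unilateral_fraction_left
           else config$unilateral_fraction_right
  u_tgt <- if (target_side == "L") config$unilateral_fraction_left
           else config$unilateral_fraction_right
  law <- config$wave_amplitude_law
  rho <- calibrate_copula(law, config$amplitude_covariation)
  n <- nrow(train)
  with_seed(seed, {
    copied <- stats::runif(n) >= u_src
    idx_src <- which(copied)
    m <- length(idx_src)
    lag_ms <- stats::rnorm(m, config$bilateral_lag_mean,
                           config$bilateral_lag_sd)
    # right-lead-positive lag: the right wave starts |lag| earlier
    shift_s <- if (source_side == "L") -lag_ms / 1000 else lag_ms / 1000
    t_start <- train$start[idx_src] + shift_s
    z1 <- stats::qnorm(pmin(pmax(law$cdf(train$amp[idx_src]), 1e-12),
                            1 - 1e-12))
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(m)
    t_amp <- law$quantile(stats::pnorm(z2))
    t_scale <- rtnorm(m, train$scale[idx_src],
                      config$pair_scale_jitter / 1000,
                      lower = config$wave_scale_floor / 1000)
    n_ins <- if (u_tgt >= 1) 0L else round(m * u_tgt / (1 - u_tgt))
    # unilateral waves belong to the same gamma stream: keep them at
    # least the interval floor away from the existing waves
    floor_s <- config$wave_interval_floor / 1000
    ins_start <- numeric(0)
    tries <- 0L
    while (length(ins_start) < n_ins && tries < 50L) {
      cand <- stats::runif(n_ins - length(ins_start), 0,
                           config$epoch_length)
      occ <- sort(c(t_start, ins_start))
      j <- findInterval(cand, occ)
      d_prev <- ifelse(j >= 1, cand - occ[pmax(j, 1)], Inf)
      d_next <- ifelse(j < length(occ), occ[pmin(j + 1, length(occ))] - cand,
                       Inf)
      ok <- d_prev >= floor_s & d_next >= floor_s
      ins_start <- c(ins_start, cand[ok])
      tries <- tries + 1L
    }
    n_ins <- length(ins_start)
    ins_scale <- rtnorm(n_ins, config$wave_scale / 1000,
                        config$wave_scale_sd / 1000,
                        lower = config$wave_scale_floor / 1000)
    ins_amp <- law$draw(n_ins)
    waves <- data.frame(start = c(t_start, ins_start),
                        scale = c(t_scale, ins_scale),
                        amp = c(t_amp, ins_amp))
    ord <- order(waves$start)
    waves <- waves[ord, , drop = FALSE]
    rownames(waves) <- NULL
    tgt_idx <- match(seq_len(m), ord)  # position of each copy after sorting
    pairs <- if (source_side == "L")
      data.frame(left_idx = idx_src, right_idx = tgt_idx,
                 lag_ms = (t_start - train$start[idx_src]) * 1000)
    else
      data.frame(left_idx = tgt_idx, right_idx = idx_src,
                 lag_ms = (train$start[idx_src] - t_start) * 1000)
    list(waves = structure(waves, side = target_side), pairs = pairs)
  })
}

#' Render a generator time course from a wave list
#'
#' Sums alpha kernels, each scaled so its peak equals the wave's stored peak
#' amplitude; the trace is exactly zero where no wave contributes.
#'
#' @param waves data.frame with `start` (s), `scale` (s), `amp` (uV).
#' @param rate sampling rate (Hz).
#' @param length epoch length (s).
#' @return numeric vector of `round(rate * length)` samples (uV).
#' @export
render_generator <- function(waves, rate, length) {
  stopifnot(rate > 0, length > 0)
  n <- round(rate * length)
  tr <- numeric(n)
  tt <- (seq_len(n) - 1) / rate
  if (is.null(waves) || nrow(waves) == 0) return(tr)
  for (i in seq_len(nrow(waves))) {
    tau <- waves$start[i]; dl <- waves$scale[i]
    i0 <- max(1L, floor(tau * rate) + 1L)
    i1 <- min(n, ceiling((tau + 6 * dl) * rate) + 1L)
    if (i0 > n || i1 < 1) next
    seg <- i0:i1
    tr[seg] <- tr[seg] + render_kernel(tt[seg], tau, dl, waves$amp[i])
  }
  tr
}

#' Mix generator time courses onto recording channels
#'
#' Implements the linear forward model: each channel is the weighted sum of
#' the generator traces plus independent Gaussian sensor noise.
#'
#' @param generators list of equal-length generator traces (uV).
#' @param mixing channel x generator weight matrix.
#' @param noise_sd additive noise SD (uV).
#' @param seed integer seed for the noise.
#' @param rate sampling rate (Hz).
#' @param channel_meta optional per-channel metadata data.frame.
#' @return an [lfp_recording()].
#' @export
mix_to_channels <- function(generators, mixing, noise_sd = 0, seed = NULL,
                            rate, channel_meta = NULL) {
  S <- do.call(rbind, lapply(generators, as.numeric))
  if (ncol(mixing) != nrow(S))
    stop("dimension mismatch: mixing has ", ncol(mixing),
         " columns but there are ", nrow(S), " generators")
  U <- mixing %*% S
  if (noise_sd > 0)
    U <- U + with_seed(seed,
      matrix(stats::rnorm(length(U), 0, noise_sd), nrow(U), ncol(U)))
  lfp_recording(U, rate = rate, channel_meta = channel_meta)
}

#' Generate spike trains coupled to gamma waves
#'
#' Each unit fires a homogeneous Poisson background superposed with
#' wave-triggered spikes at the unit's latency and strength.
#' Interneuron-like units (`class == "IN"`) couple to every ipsilateral
#' wave; pyramidal-cell-like units (`class == "PC"`) receive the
#' firing-probability boost only for waves that are bilaterally paired
#' (temporal-overlap criterion on the true waves).
#'
#' @param waves_l,waves_r true wave trains for the two sides.
#' @param unit_params data.frame with columns `unit_id`, `class`
#'   (`"PC"`/`"IN"`), `side` (`"L"`/`"R"`), `base_rate` (Hz), `latency_ms`,
#'   `strength` (per-wave spike probability in \[0,1\]) and optionally
#'   `jitter_ms` (default 1).
#' @param epoch epoch length (s).
#' @param seed integer seed.
#' @param duration_correction factor applied to raw kernel support when
#'   building the true wave intervals used for the bilateral criterion.
#' @return data.frame `(unit_id, class, time_s)`, sorted within unit.
#' @export
generate_spike_trains <- function(waves_l, waves_r, unit_params, epoch,
                                  seed = NULL, duration_correction = 0.75) {
  stopifnot(epoch > 0)
  if (is.null(unit_params$jitter_ms)) unit_params$jitter_ms <- 1
  x5 <- .kernel_x5()
  span <- (x5["hi"] - x5["lo"]) * duration_correction
  gw <- function(w, side) gamma_waves(start = w$start, scale = w$scale,
                                      amp = w$amp,
                                      duration = as.numeric(span) * w$scale,
                                      side = side)
  wl <- gw(waves_l, "L"); wr <- gw(waves_r, "R")
  pr <- pair_waves(wl, wr)
  bil_l <- pr$pairs$idx_a; bil_r <- pr$pairs$idx_b
  out <- vector("list", nrow(unit_params))
  with_seed(seed, {
    for (i in seq_len(nrow(unit_params))) {
      p <- unit_params[i, ]
      own <- if (p$side == "L") waves_l else waves_r
      eligible <- if (p$class == "IN") seq_len(nrow(own))
                  else if (p$side == "L") bil_l else bil_r
      n_bg <- stats::rpois(1, p$base_rate * epoch)
      t_bg <- stats::runif(n_bg, 0, epoch)
      fire <- eligible[stats::runif(length(eligible)) < p$strength]
      t_tr <- own$start[fire] + p$latency_ms / 1000 +
        if (p$jitter_ms > 0) stats::rnorm(length(fire), 0, p$jitter_ms / 1000)
        else 0
      tt <- sort(c(t_bg, t_tr))
      tt <- tt[tt >= 0 & tt < epoch]
      out[[i]] <- if (length(tt)) data.frame(unit_id = p$unit_id,
                                             class = p$class, time_s = tt)
                  else NULL
    }
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Default smooth depth profiles for two generators on one shank: a
# Schaffer-like bump in str. radiatum depths and a deeper CA3som-like bump.
default_profiles <- function(nch) {
  d <- seq(0, 1, length.out = nch)
  list(schaffer = exp(-(d - 0.35)^2 / (2 * 0.14^2)),
       ca3som = exp(-(d - 0.75)^2 / (2 * 0.11^2)))
}

default_unit_params <- function() {
  data.frame(unit_id = c("pc_l1", "pc_l2", "pc_r1", "pc_r2",
                         "in_l1", "in_r1"),
             class = c("PC", "PC", "PC", "PC", "IN", "IN"),
             side = c("L", "L", "R", "R", "L", "R"),
             base_rate = c(1, 1.5, 1, 1.5, 6, 6),
             latency_ms = c(4, 5, 4, 5, 3, 3),
             strength = c(0.12, 0.10, 0.12, 0.10, 0.35, 0.35),
             jitter_ms = 1)
}

#' Generate a full synthetic bilateral recording with ground truth
#'
#' Top-level generator: builds wave trains for each of two generators in
#' each hemisphere (left train drawn first, right train derived with the
#' bilateral lag/covariation law), renders and mixes them onto
#' `2 * n_shanks` shanks with additive noise, and generates coupled spike
#' trains.
#'
#' @param config a [synth_config()].
#' @param unit_params optional spike-unit parameter table; see
#'   [generate_spike_trains()]. `NULL` for the built-in default population,
#'   `NA` to skip spikes.
#' @return list of class `synth_recording` with elements `recording`
#'   ([lfp_recording()]), `truth` (mixing matrix, per-side/per-generator
#'   wave tables, pair tables, unit parameters), `spikes` and `config`.
#' @export
synth_recording <- function(config = synth_config(), unit_params = NULL) {
  seed <- config$rng_seed
  nch <- config$n_channels_per_shank
  prof <- config$generator_profiles
  if (is.null(prof)) prof <- default_profiles(nch)
  ngen <- length(prof)
  trains <- vector("list", ngen)
  for (g in seq_len(ngen)) {
    wl <- generate_wave_train(config, "L", seed = sub_seed(seed, 10 + g))
    der <- derive_contralateral_train(wl, config,
                                      seed = sub_seed(seed, 20 + g),
                                      source_side = "L")
    trains[[g]] <- list(L = wl, R = der$waves, pairs = der$pairs)
  }
  rate <- config$sampling_rate
  len <- config$epoch_length
  traces <- lapply(trains, function(tr)
    list(L = render_generator(tr$L, rate, len),
         R = render_generator(tr$R, rate, len)))
  # block mixing: each hemisphere's shanks see only that hemisphere's
  # generators, with identical depth profiles on every shank
  shank_block <- do.call(cbind, lapply(prof, function(p) rep(p, config$n_shanks)))
  M <- 2 * config$n_shanks * nch
  V <- matrix(0, M, 2 * ngen)
  V[1:(M / 2), 1:ngen] <- shank_block
  V[(M / 2 + 1):M, (ngen + 1):(2 * ngen)] <- shank_block
  gens <- c(lapply(traces, `[[`, "L"), lapply(traces, `[[`, "R"))
  meta <- data.frame(
    channel = seq_len(M),
    shank = rep(seq_len(2 * config$n_shanks), each = nch),
    side = rep(c("L", "R"), each = M / 2),
    site = rep(rep(c("a", "p"), length.out = config$n_shanks, each = 1),
               each = nch, times = 2),
    depth_um = rep((seq_len(nch) - 1) * 20, 2 * config$n_shanks))
  rec <- mix_to_channels(gens, V, noise_sd = config$noise_sd,
                         seed = sub_seed(seed, 99), rate = rate,
                         channel_meta = meta)
  spikes <- NULL
  if (!(length(unit_params) == 1 && is.na(unit_params))) {
    if (is.null(unit_params)) unit_params <- default_unit_params()
    spikes <- generate_spike_trains(trains[[1]]$L, trains[[1]]$R,
                                    unit_params, epoch = len,
                                    seed = sub_seed(seed, 77))
  }
  truth <- list(
    mixing = V,
    waves = list(L = lapply(trains, `[[`, "L"),
                 R = lapply(trains, `[[`, "R")),
    pairs = lapply(trains, `[[`, "pairs"),
    generator_labels = rep(names(prof), 2),
    unit_params = if (is.null(spikes)) NULL else unit_params)
  structure(list(recording = rec, truth = truth, spikes = spikes,
                 config = config),
            class = "synth_recording")
}

#' @export
print.synth_recording <- function(x, ...) {
  cat("Synthetic bilateral gamma recording\n")
  cat("  channels:", nrow(x$recording$voltages),
      " samples:", ncol(x$recording$voltages),
      " rate:", x$recording$rate, "Hz\n")
  nL <- sum(vapply(x$truth$waves$L, nrow, 1L))
  nR <- sum(vapply(x$truth$waves$R, nrow, 1L))
  cat("  true waves: L", nL, "/ R", nR,
      " pairs:", sum(vapply(x$truth$pairs, nrow, 1L)), "\n")
  if (!is.null(x$spikes))
    cat("  spikes:", nrow(x$spikes), "from",
        length(unique(x$spikes$unit_id)), "units\n")
  invisible(x)
}

#' Inject sharp-wave-like events into a recording
#'
#' Adds large, slow, spatially broad deflections (Gaussian envelope in time,
#' uniform polarity across channels scaled by each channel's maximum
#' generator weight) for testing sharp-wave masking. Not part of the default
#' generator: analysis assumes sharp waves are excluded.
#'
#' @param rec an [lfp_recording()].
#' @param times event centre times (s).
#' @param amplitude peak amplitude (uV).
#' @param width Gaussian SD (s); the default 0.015 s gives ~60 ms events.
#' @return the recording with events added.
#' @export
inject_spw <- function(rec, times, amplitude = 800, width = 0.015) {
  tt <- (seq_len(ncol(rec$voltages)) - 1) / rec$rate
  prof <- apply(abs(rec$voltages), 1, max)
  prof <- prof / max(prof)
  for (tc in times) {
    env <- amplitude * exp(-(tt - tc)^2 / (2 * width^2))
    rec$voltages <- rec$voltages + outer(prof, env)
  }
  rec
}
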