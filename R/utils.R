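# Internal numeric helpers shared across modules.

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All user-facing stochastic operations
# funnel through this so a fixed seed gives bit-identical output regardless
# of the surrounding session state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic sub-seed derivation, kept well inside 32-bit range.
sub_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + 7919 * k) %% 2147483587
}

# Truncated-normal draws by rejection; trivial rejection rates for the
# parameter regimes used here (floor several SDs below the mean).
rtnorm <- function(n, mean, sd, lower = -Inf) {
  if (sd <= 0) return(pmax(rep(mean, n), lower))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lower]
  }
  out
}

# Analytic signal via FFT: x + i * H[x]. Instantaneous phase/amplitude of
# band-limited traces.
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  c(p[1], p[1] + cumsum(dp))
}

# Zero-phase Butterworth filtering (order doubled by the forward-backward
# pass). type: "high", "low", "pass".
zerophase_filter <- function(x, rate, cutoff, type, order = 2L) {
  ny <- rate / 2
  if (any(cutoff >= ny))
    stop("filter cutoff must lie below the Nyquist frequency (", ny, " Hz)")
  bf <- signal::butter(order, cutoff / ny, type = type)
  as.numeric(signal::filtfilt(bf, x))
}

# Rayleigh test of circular uniformity. Returns mean direction, resultant
# length and the standard finite-n corrected p-value.
rayleigh_test <- function(theta) {
  n <- length(theta)
  C <- mean(cos(theta)); S <- mean(sin(theta))
  rbar <- sqrt(C^2 + S^2)
  mu <- atan2(S, C)
  Z <- n * rbar^2
  p <- exp(-Z) * (1 + (2 * Z - Z^2) / (4 * n) -
                    (24 * Z - 132 * Z^2 + 76 * Z^3 - 9 * Z^4) / (288 * n^2))
  list(mean = mu, rbar = rbar, statistic = Z, p.value = max(min(p, 1), 0))
}

circular_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

# Merge possibly overlapping [start, end] intervals; returns a 2-column
# matrix sorted by start, or a 0-row matrix.
merge_intervals <- function(int) {
  if (is.null(int) || nrow(int) == 0)
    return(matrix(numeric(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  int <- int[order(int[, 1]), , drop = FALSE]
  out <- int[1, , drop = FALSE]
  if (nrow(int) > 1) for (i in 2:nrow(int)) {
    if (int[i, 1] <= out[nrow(out), 2])
      out[nrow(out), 2] <- max(out[nrow(out), 2], int[i, 2])
    else out <- rbind(out, int[i, , drop = FALSE])
  }
  colnames(out) <- c("start", "end")
  out
}

# Total measure of the union of intervals already merged.
interval_measure <- function(int) if (nrow(int) == 0) 0 else sum(int[, 2] - int[, 1])

# Membership of points in a merged interval set; closed start, open end.
in_intervals <- function(x, int) {
  if (nrow(int) == 0) return(rep(FALSE, length(x)))
  idx <- findInterval(x, int[, 1])
  idx > 0 & x < int[cbind(pmax(idx, 1), 2)]
}

# Welch cross/auto spectra: Hann-tapered overlapping segments.
# Returns list(freq, pxx, pyy, pxy) with two-sided normalization folded to
# one side; only used for coherence ratios so the absolute scale cancels.
welch_spectra <- function(x, y, rate, window_s = 1, overlap = 0.5) {
  nwin <- round(window_s * rate)
  if (nwin < 8) stop("window too short")
  step <- max(1L, round(nwin * (1 - overlap)))
  starts <- seq(1L, length(x) - nwin + 1L, by = step)
  if (length(starts) < 4)
    stop("epoch too short: need at least 4 averaging windows")
  taper <- 0.5 - 0.5 * cos(2 * pi * seq_len(nwin) / (nwin + 1))
  nf <- nwin %/% 2
  pxx <- pyy <- numeric(nf)
  pxy <- complex(nf)
  for (s in starts) {
    seg <- s:(s + nwin - 1L)
    X <- stats::fft((x[seg] - mean(x[seg])) * taper)[2:(nf + 1)]
    Y <- stats::fft((y[seg] - mean(y[seg])) * taper)[2:(nf + 1)]
    pxx <- pxx + Mod(X)^2
    pyy <- pyy + Mod(Y)^2
    pxy <- pxy + X * Conj(Y)
  }
  list(freq = (1:nf) * rate / nwin, pxx = pxx, pyy = pyy, pxy = pxy,
       n_windows = length(starts))
}

# Phase-randomized surrogate preserving the amplitude spectrum exactly.
phase_randomize <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  half <- if (n %% 2 == 0) n / 2 - 1 else (n - 1) / 2
  ph <- stats::runif(half, 0, 2 * pi)
  Xs <- X
  Xs[2:(half + 1)] <- Mod(X[2:(half + 1)]) * exp(1i * ph)
  Xs[n:(n - half + 1)] <- Conj(Xs[2:(half + 1)])
  # DC (and Nyquist, if present) keep their original values: real, amplitude
  # preserved.
  Re(stats::fft(Xs, inverse = TRUE) / n)
}
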