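#' Alpha kernel: the canonical pulse shape of a single gamma wave
#'
#' Evaluates \eqn{f(t; \delta) = H(t) \, (t/\delta^2) \, e^{-t^2/2\delta^2}},
#' where \eqn{H} is the Heaviside step. The kernel is a unit-area density on
#' \eqn{t > 0}: it rises from zero, peaks at \eqn{t = \delta} with value
#' \eqn{e^{-1/2}/\delta}, and decays with a Gaussian tail. It models one
#' pulse-like LFP deflection (gamma wave) in a generator time course; a wave
#' train is a weighted sum of shifted kernels.
#'
#' @param t numeric vector of times (s) relative to the wave start.
#' @param delta kernel time scale \eqn{\delta} (s), strictly positive.
#' @return numeric vector of kernel values (1/s, unit area).
#' @examples
#' tt <- seq(-0.01, 0.06, by = 1e-4)
#' y <- alpha_kernel(tt, delta = 0.008)
#' max(y) * 0.008            # e^{-1/2}
#' @export
alpha_kernel <- function(t, delta) {
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) || delta <= 0)
    stop("'delta' must be a single positive number")
  ifelse(t > 0, (t / delta^2) * exp(-t^2 / (2 * delta^2)), 0)
}

# Dimensionless support bounds of the kernel at a relative level:
# solutions x of x * exp((1 - x^2)/2) = level on either side of the peak
# (x = t/delta, peak at x = 1). Used for raw wave durations (5% level).
kernel_support_x <- function(level = 0.05) {
  g <- function(x) x * exp((1 - x^2) / 2) - level
  lo <- stats::uniroot(g, c(1e-9, 1), tol = 1e-12)$root
  hi <- stats::uniroot(g, c(1, 12), tol = 1e-12)$root
  c(lo = lo, hi = hi)
}

# Cached 5% support bounds (x_lo ~ 0.030, x_hi ~ 3.21); raw duration of a
# fitted wave is (x_hi - x_lo) * delta.
.kernel_x5 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- kernel_support_x(0.05)
    cache
  }
})

# Peak value of the kernel for a given scale.
kernel_peak <- function(delta) exp(-0.5) / delta

# Render one wave with stored peak amplitude A: A * f(t - tau; delta) / peak.
render_kernel <- function(t, tau, delta, amp) {
  amp * alpha_kernel(t - tau, delta) / kernel_peak(delta)
}
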