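# Shared fixture builders and independent oracles.

# Small wave table with explicit fields.
gw <- function(start, dur, amp = 100, side = NA_character_) {
  gamma_waves(start = start, scale = rep_len(dur, length(start)) / 2.27,
              amp = rep_len(amp, length(start)),
              duration = rep_len(dur, length(start)), side = side)
}

# Fraction of true starts matched by an estimated start within tol.
detection_rate <- function(true_start, est_start, tol = 0.002) {
  if (!length(est_start)) return(0)
  mean(vapply(true_start,
              function(s) min(abs(est_start - s)) <= tol, TRUE))
}

# Relative amplitude errors of matched waves.
matched_amp_err <- function(true, est, tol = 0.002) {
  idx <- vapply(seq_len(nrow(true)), function(i) {
    j <- which.min(abs(est$start - true$start[i]))
    if (abs(est$start[j] - true$start[i]) <= tol) j else NA_integer_
  }, 1L)
  ok <- !is.na(idx)
  abs(est$amp[idx[ok]] - true$amp[ok]) / true$amp[ok]
}

# Brute-force pairing oracle: enumerate every cross pair, keep those with
# overlap index > omega_min, and accept greedily by decreasing overlap
# (ties: smaller |lag|, then earlier start), one-to-one. Quadratic and
# window-free, independent of pair_waves' candidate pruning.
brute_force_pairs <- function(wa, wb, omega_min = 0.7) {
  cand <- expand.grid(i = seq_len(nrow(wa)), j = seq_len(nrow(wb)))
  om <- mapply(function(i, j)
    overlap_index(wa$start[i], wa$duration[i], wb$start[j],
                  wb$duration[j]),
    cand$i, cand$j)
  keep <- om > omega_min
  cand <- cand[keep, , drop = FALSE]
  om <- om[keep]
  lag <- wb$start[cand$j] - wa$start[cand$i]
  ord <- order(-om, abs(lag), pmin(wa$start[cand$i], wb$start[cand$j]))
  used_a <- used_b <- integer(0)
  out <- NULL
  for (r in ord) {
    i <- cand$i[r]; j <- cand$j[r]
    if (i %in% used_a || j %in% used_b) next
    used_a <- c(used_a, i); used_b <- c(used_b, j)
    out <- rbind(out, c(i, j))
  }
  if (is.null(out)) return(matrix(integer(0), ncol = 2))
  out[order(wa$start[out[, 1]]), , drop = FALSE]
}

# Brute-force spike-window oracle: per-spike scan over every wave
# interval (closed start, open end).
brute_force_windows <- function(spikes, wl, wr) {
  inside <- function(t, w) {
    if (nrow(w) == 0) return(FALSE)
    any(t >= w$start & t < w$start + w$duration)
  }
  cls <- vapply(spikes, function(t) {
    l <- inside(t, wl); r <- inside(t, wr)
    if (l && r) "Bilateral" else if (l) "L" else if (r) "R" else "None"
  }, "")
  c(None = sum(cls == "None"), R = sum(cls == "R"), L = sum(cls == "L"),
    Bilateral = sum(cls == "Bilateral"))
}

# Random small wave tables for oracle-equivalence checks.
random_wave_table <- function(n, epoch = 2, seed = NULL) {
  gammasync:::with_seed(seed, {
    start <- sort(stats::runif(n, 0, epoch))
    dur <- stats::runif(n, 0.004, 0.03)
    gw(start, dur, amp = stats::runif(n, 25, 300))
  })
}
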