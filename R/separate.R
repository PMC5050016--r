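#' Decompose a multichannel LFP recording into LFP generators
#'
#' Fits the linear mixing model: every channel is a weighted sum of a few
#' spatially fixed generator time courses. Dimensionality is first reduced
#' by PCA to `n_components`, then a FastICA rotation maximizes the mutual
#' independence of the retained dimensions. Masked epochs (e.g. sharp
#' waves) are excluded from fitting; activations are nevertheless returned
#' for the full timeline by least-squares projection.
#'
#' Indeterminacies are resolved by convention: each generator's mixing
#' column is scaled so its maximum absolute weight is 1 (activations carry
#' the voltage scale, so the activation equals the contributed voltage at
#' the dominant site), and the activation sign is chosen so that the mean of
#' samples beyond 3 SD is positive (gamma waves point up). Generators are
#' ordered by descending share of the preprocessed-LFP variance.
#'
#' @param rec an [lfp_recording()] (already high-passed; see
#'   [preprocess()]).
#' @param n_components number of generators to retain (<= channel count).
#' @param seed optional integer seed for the ICA rotation's random starting
#'   point; with `NULL` a fixed identity start is used (deterministic).
#' @param maxit,tol FastICA iteration controls.
#' @return object of class `generator_decomposition`: `mixing` (channel x
#'   generator, uV per unit activation, max abs weight 1), `activations`
#'   (generator x sample), `variance_share`, `labels`, plus the recording's
#'   rate and channel metadata.
#' @export
decompose <- function(rec, n_components, seed = NULL, maxit = 200,
                      tol = 1e-7) {
  stopifnot(inherits(rec, "lfp_recording"))
  X <- rec$voltages
  M <- nrow(X); N <- ncol(X)
  if (n_components > M)
    stop("n_components exceeds the channel count")
  drop_idx <- masked_samples(N, rec$rate, rec$epoch_masks)
  fit_cols <- if (length(drop_idx)) setdiff(seq_len(N), drop_idx)
              else seq_len(N)
  Xf <- X[, fit_cols, drop = FALSE]
  mu <- rowMeans(Xf)
  Xc <- Xf - mu
  ev <- eigen(tcrossprod(Xc) / ncol(Xc), symmetric = TRUE)$values
  bad <- which(ev < 1e-10 * ev[1])
  if (length(bad) && min(bad) <= n_components)
    stop("rank-deficient input: dimension ", min(bad),
         " carries no variance")
  R0 <- if (is.null(seed)) diag(n_components) else
    with_seed(seed, qr.Q(qr(matrix(stats::rnorm(n_components^2),
                                   n_components))))
  fit <- ica::icafast(t(Xc), nc = n_components, center = TRUE,
                      maxit = maxit, tol = tol, Rmat = R0)
  V <- fit$M                       # channels x components
  A <- t(fit$S)                    # components x samples (fit epochs)
  # full-timeline activations by least squares against the centred data
  Afull <- solve(crossprod(V), crossprod(V, X - rowMeans(X)))
  # normalization: max |weight| = 1; waves positive
  for (k in seq_len(n_components)) {
    sc <- max(abs(V[, k]))
    V[, k] <- V[, k] / sc
    A[k, ] <- A[k, ] * sc
    Afull[k, ] <- Afull[k, ] * sc
    s <- A[k, ]
    big <- abs(s - mean(s)) > 3 * stats::sd(s)
    flip <- if (any(big)) mean(s[big]) < 0 else max(s) < max(-s)
    if (flip) {
      V[, k] <- -V[, k]
      A[k, ] <- -A[k, ]
      Afull[k, ] <- -Afull[k, ]
    }
  }
  varn <- function(x) mean((x - mean(x))^2)
  tot <- sum(apply(Xc, 1, varn))
  share <- vapply(seq_len(n_components),
                  function(k) sum(V[, k]^2) * varn(A[k, ]) / tot, 1)
  ord <- order(share, decreasing = TRUE)
  structure(list(mixing = V[, ord, drop = FALSE],
                 activations = Afull[ord, , drop = FALSE],
                 variance_share = share[ord],
                 labels = rep(NA_character_, n_components),
                 rate = rec$rate, channel_meta = rec$channel_meta,
                 epoch_masks = rec$epoch_masks),
            class = "generator_decomposition")
}

#' @export
print.generator_decomposition <- function(x, ...) {
  cat("Generator decomposition:", nrow(x$activations), "generators,",
      ncol(x$activations), "samples @", x$rate, "Hz\n")
  for (k in seq_along(x$variance_share))
    cat(sprintf("  %d%s: variance share %.3f\n", k,
                if (is.na(x$labels[k])) "" else paste0(" (", x$labels[k], ")"),
                x$variance_share[k]))
  invisible(x)
}

#' Plot generator depth profiles
#'
#' @param x a `generator_decomposition`.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.generator_decomposition <- function(x, ...) {
  graphics::matplot(x$mixing, seq_len(nrow(x$mixing)), type = "l", lty = 1,
                    xlab = "voltage weight", ylab = "channel",
                    ylim = c(nrow(x$mixing), 1), ...)
  graphics::abline(v = 0, col = "grey")
  invisible(x)
}

#' Match generators of two decompositions by their spatial profiles
#'
#' Greedy maximum-correlation assignment between depth-aligned spatial
#' weight curves (e.g. anterior vs posterior shank, or two hemispheres with
#' homotopic channel layouts). Each accepted pairing is reported with its
#' correlation; leftover components of the larger decomposition are
#' returned as unmatched.
#'
#' @param a,b `generator_decomposition` objects sharing channel-depth
#'   semantics (equal mixing-row counts).
#' @return list with `pairs` (data.frame `a_idx, b_idx, score`) and
#'   `unmatched_a`, `unmatched_b` (integer vectors).
#' @export
match_components <- function(a, b) {
  Va <- a$mixing; Vb <- b$mixing
  if (nrow(Va) != nrow(Vb))
    stop("decompositions must share channel-depth semantics")
  cc <- stats::cor(Va, Vb)
  na <- ncol(Va); nb <- ncol(Vb)
  pairs <- data.frame(a_idx = integer(0), b_idx = integer(0),
                      score = numeric(0))
  free_a <- rep(TRUE, na); free_b <- rep(TRUE, nb)
  for (i in seq_len(min(na, nb))) {
    sub <- cc
    sub[!free_a, ] <- -Inf
    sub[, !free_b] <- -Inf
    best <- arrayInd(which.max(sub), dim(sub))
    pairs <- rbind(pairs, data.frame(a_idx = best[1], b_idx = best[2],
                                     score = cc[best[1], best[2]]))
    free_a[best[1]] <- FALSE
    free_b[best[2]] <- FALSE
  }
  list(pairs = pairs[order(pairs$a_idx), ],
       unmatched_a = which(free_a), unmatched_b = which(free_b))
}

#' Label generators by user-supplied depth templates
#'
#' Assigns each generator the label of the template profile with which its
#' spatial weight curve correlates best (no automatic anatomy inference).
#'
#' @param dec a `generator_decomposition`.
#' @param templates named list of per-channel weight curves.
#' @param min_score minimum correlation to accept a label.
#' @return the decomposition with `labels` filled in.
#' @export
label_generators <- function(dec, templates, min_score = 0.6) {
  tm <- do.call(cbind, templates)
  cc <- stats::cor(dec$mixing, tm)
  for (k in seq_len(ncol(dec$mixing))) {
    j <- which.max(cc[k, ])
    if (cc[k, j] >= min_score) dec$labels[k] <- names(templates)[j]
  }
  dec
}
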