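# Simulation-based edge mask: which parcel pairs can the forward-inverse
# chain resolve above surrogate level?

#' Simulate parcel activity with exactly one synchronized pair
#'
#' All parcels carry independent noise except the requested pair, which
#' shares a band-limited oscillation with a fixed quarter-cycle lag.
#'
#' @param pair two distinct 1-based parcel indices.
#' @param n_parcels parcel count.
#' @param fs sampling rate (Hz).
#' @param duration_s simulated length (s).
#' @param freq carrier frequency (Hz).
#' @param seed integer seed.
#' @param noise_rel RMS of the independent noise on the coupled parcels,
#'   relative to the oscillation.
#' @return list: `sources` (parcels x samples), `pair`,
#'   `pair_signals` (2 x samples clean oscillations).
#' @export
simulate_pair_synchrony <- function(pair, n_parcels, fs = 250,
                                    duration_s = 1, freq = 10, seed = 1,
                                    noise_rel = 0.1) {
  pair <- as.integer(pair)
  stopifnot(length(pair) == 2, pair[1] != pair[2],
            all(pair >= 1), all(pair <= n_parcels))
  n <- round(fs * duration_s)
  with_seed(seed, {
    src <- matrix(rnorm(n_parcels * n), n_parcels, n)
    ph <- 2 * pi * freq * seq_len(n) / fs + runif(1, 0, 2 * pi)
    s1 <- sqrt(2) * cos(ph)
    s2 <- sqrt(2) * cos(ph + pi / 2)       # fixed nonzero (quarter-cycle) lag
    src[pair[1], ] <- s1 + noise_rel * src[pair[1], ]
    src[pair[2], ] <- s2 + noise_rel * src[pair[2], ]
    list(sources = src, pair = pair, pair_signals = rbind(s1, s2))
  })
}

#' Compute the fidelity edge mask
#'
#' For every parcel pair: simulate activity where only that pair is
#' synchronized, project it to sensors through the forward model, apply
#' the inverse, collapse to parcels, and correlate the reconstructed
#' parcel signals with the original artificial activity.  The pair's
#' statistic per iteration is the minimum over the two members of the
#' correlation between the reconstructed member and its original signal
#' (conservative combiner); the surrogate pool collects, globally over
#' all pairs and iterations, the absolute correlations between
#' reconstructed non-synchronous parcels and the original synchronized
#' activity (signal leakage null).  A pair is retained when the median
#' of its statistic across iterations exceeds the surrogate
#' `percentile`.
#'
#' @param bundle a `lead_field_bundle`.
#' @param inv matching `inverse_operator`.
#' @param n_iter iterations per pair (>= 10; the reference analysis uses
#'   500).
#' @param percentile surrogate percentile in (50, 100), default 99.
#' @param fs,duration_s,freq per-iteration simulation parameters.
#' @param snr_db sensor SNR of the synthetic EEG.
#' @param seed integer seed.
#' @param surrogates_per_iter how many non-synchronous parcels enter the
#'   surrogate pool per iteration (subsampled for speed; all when
#'   `Inf`).
#' @return an `edge_mask`: `keep` (logical symmetric matrix, diagonal
#'   `NA`), `score` (per-edge median statistic), `threshold`,
#'   `n_excluded`, `excluded_fraction`, `percentile`, `n_iter`.
#' @export
compute_edge_mask <- function(bundle, inv, n_iter = 500, percentile = 99,
                              fs = 250, duration_s = 1, freq = 10,
                              snr_db = 20, seed = 1,
                              surrogates_per_iter = 4) {
  stopifnot(inherits(bundle, "lead_field_bundle"),
            inherits(inv, "inverse_operator"))
  if (n_iter < 10) stop("n_iter must be >= 10")
  if (percentile <= 50 || percentile >= 100) stop("percentile must be in (50, 100)")
  p <- bundle$n_parcels
  n <- round(fs * duration_s)
  # whole chain parcel -> sensor -> parcel as two linear maps
  P_op <- parcel_operator(bundle, inv)             # parcels x sensors
  expand <- bundle$gain[, , drop = FALSE] %*%
    outer(bundle$parcel_map, seq_len(p), `==`)     # sensors x parcels
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  score <- matrix(NA_real_, p, p)
  with_seed(seed, {
    surr <- numeric(0)
    stat_med <- numeric(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      stats_k <- numeric(n_iter)
      for (it in seq_len(n_iter)) {
        src <- matrix(rnorm(p * n), p, n)
        ph <- 2 * pi * freq * seq_len(n) / fs + runif(1, 0, 2 * pi)
        s1 <- sqrt(2) * cos(ph); s2 <- sqrt(2) * cos(ph + pi / 2)
        src[i, ] <- s1 + 0.1 * src[i, ]
        src[j, ] <- s2 + 0.1 * src[j, ]
        sens <- expand %*% src                    # synthetic EEG
        if (is.finite(snr_db)) {
          p_sig <- mean(sens^2)
          if (p_sig > 0)
            sens <- sens + matrix(rnorm(length(sens),
                                        sd = sqrt(p_sig / 10^(snr_db / 10))),
                                  nrow(sens), n)
        }
        recon <- P_op %*% sens                    # inverse + collapse
        c1 <- suppressWarnings(cor(recon[i, ], s1))
        c2 <- suppressWarnings(cor(recon[j, ], s2))
        stats_k[it] <- min(ifelse(is.na(c1), 0, c1), ifelse(is.na(c2), 0, c2))
        others <- setdiff(seq_len(p), c(i, j))
        if (is.finite(surrogates_per_iter) && surrogates_per_iter < length(others))
          others <- sample(others, surrogates_per_iter)
        sv <- vapply(others, function(o) {
          v <- suppressWarnings(cor(recon[o, ], s1))
          if (is.na(v)) 0 else abs(v)
        }, numeric(1))
        surr <- c(surr, sv)
      }
      stat_med[k] <- median(stats_k)
    }
    thr <- as.numeric(quantile(surr, percentile / 100, names = FALSE))
    keep <- matrix(NA, p, p)
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      score[i, j] <- score[j, i] <- stat_med[k]
      keep[i, j] <- keep[j, i] <- stat_med[k] > thr
    }
    n_excl <- sum(!keep[upper.tri(keep)])
    structure(list(keep = keep, score = score, threshold = thr,
                   n_excluded = n_excl,
                   excluded_fraction = n_excl / nrow(pairs),
                   percentile = percentile, n_iter = n_iter, seed = seed),
              class = "edge_mask")
  })
}

#' @export
print.edge_mask <- function(x, ...) {
  p <- nrow(x$keep)
  cat(sprintf("<edge_mask> %d parcels: %d of %d edges excluded (%.2f%%), threshold %.3f (p%g, %d iters)\n",
              p, x$n_excluded, p * (p - 1) / 2, 100 * x$excluded_fraction,
              x$threshold, x$percentile, x$n_iter))
  invisible(x)
}

#' Apply a fidelity mask to an adjacency matrix
#'
#' Excluded cells become `NA` (masked); downstream statistics skip
#' masked cells.
#'
#' @param m an `adjacency_matrix` (or plain symmetric matrix).
#' @param mask an `edge_mask` of matching dimension.
#' @return same type as `m`, masked.
#' @export
apply_mask <- function(m, mask) {
  stopifnot(inherits(mask, "edge_mask"))
  if (inherits(m, "adjacency_matrix")) {
    if (!all(dim(m$values) == dim(mask$keep))) stop("mask shape mismatch")
    m$values[which(!mask$keep)] <- NA_real_
    m
  } else {
    if (!all(dim(m) == dim(mask$keep))) stop("mask shape mismatch")
    m[which(!mask$keep)] <- NA_real_
    m
  }
}
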