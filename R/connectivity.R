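# Amplitude (orthogonalized envelope correlation, oCC) and phase
# (debiased squared weighted phase-lag index, dwPLI) coupling between
# band-limited parcel signals.

#' Analytic signal of band-limited data
#'
#' Hilbert transform per continuous segment: returns the complex signal
#' whose real part equals the input, magnitude the amplitude envelope,
#' and argument the instantaneous phase.  Segments shorter than two
#' cycles of `fc` are skipped with a message.
#'
#' @param x numeric vector or channels x samples matrix (real); or an
#'   [eeg_recording()].
#' @param segments optional two-column matrix of segment boundaries
#'   (sample indices); defaults to the recording's segments or one
#'   segment.
#' @param fs,fc sampling rate and band centre frequency, used only for
#'   the minimum-length check (skipped if either is `NULL`).
#' @return complex matrix (channels x samples kept), with attribute
#'   `"segments"` for the retained segments.
#' @export
analytic_signal <- function(x, segments = NULL, fs = NULL, fc = NULL) {
  if (inherits(x, "eeg_recording")) {
    segments <- segments %||% x$segments
    fs <- fs %||% x$fs
    x <- x$data
  }
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (is.null(segments)) segments <- cbind(1L, ncol(x))
  min_len <- if (!is.null(fs) && !is.null(fc)) ceiling(2 * fs / fc) else 2L
  keep <- list(); bounds <- NULL
  for (i in seq_len(nrow(segments))) {
    idx <- segments[i, 1]:segments[i, 2]
    if (length(idx) < min_len) {
      message(sprintf("segment %d shorter than 2 cycles of fc; skipped", i))
      next
    }
    seg <- x[, idx, drop = FALSE]
    out <- matrix(0i, nrow(seg), ncol(seg))
    for (ch in seq_len(nrow(seg))) out[ch, ] <- analytic_vector(seg[ch, ])
    keep[[length(keep) + 1]] <- out
  }
  if (length(keep) == 0) stop("no segment long enough for analytic signal")
  lens <- vapply(keep, ncol, integer(1))
  ends <- cumsum(lens)
  res <- do.call(cbind, keep)
  attr(res, "segments") <- cbind(c(1L, head(ends, -1) + 1L), ends)
  res
}

# Window index list: non-overlapping windows of wlen samples inside each
# segment; partial trailing windows dropped.
window_indices <- function(n_total, segments, wlen) {
  if (is.null(segments)) segments <- cbind(1L, n_total)
  wins <- list()
  for (i in seq_len(nrow(segments))) {
    a <- segments[i, 1]; b <- segments[i, 2]
    nw <- (b - a + 1L) %/% wlen
    if (nw < 1) next
    for (w in seq_len(nw))
      wins[[length(wins) + 1]] <- (a + (w - 1L) * wlen):(a + w * wlen - 1L)
  }
  wins
}

#' Orthogonalized envelope correlation (oCC)
#'
#' Amplitude-amplitude coupling insensitive to zero-lag (volume
#' conduction) mixing.  In each non-overlapping window, the analytic
#' signal of `y` is orthogonalized against `x` sample-wise
#' (`y_perp = Im(y * Conj(x) / |x|)`, the component with the
#' instantaneous phase of `x` removed); the window-wise envelopes
#' `|y_perp|` and `|x|` are concatenated across windows and Pearson
#' correlated.  The roles are then swapped and the two coefficients
#' averaged.  `y = x` returns exactly 0 (self-orthogonalization).
#'
#' @param x,y complex analytic signals (equal length vectors).
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds (default 1).
#' @param segments optional segment boundaries (windows never span a
#'   boundary).
#' @param min_windows minimum usable windows required (error below).
#' @return scalar in `[-1, 1]`; attribute `"degenerate"` is `TRUE` when
#'   an input had zero envelope throughout (value 0).
#' @export
occ <- function(x, y, fs, window_s = 1, segments = NULL, min_windows = 30) {
  stopifnot(length(x) == length(y))
  wlen <- round(window_s * fs)
  wins <- window_indices(length(x), segments, wlen)
  if (length(wins) < min_windows)
    stop(sprintf("only %d usable windows (< %d)", length(wins), min_windows))
  idx <- unlist(wins)
  xs <- x[idx]; ys <- y[idx]
  ax <- Mod(xs); ay <- Mod(ys)
  if (all(ax < 1e-12) || all(ay < 1e-12)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  e_yx <- abs(Im(ys * Conj(xs) / pmax(ax, 1e-12)))   # y orthogonalized to x
  e_xy <- abs(Im(xs * Conj(ys) / pmax(ay, 1e-12)))   # x orthogonalized to y
  r1 <- if (sd(e_yx) < 1e-14 || sd(ax) < 1e-14) 0 else cor(e_yx, ax)
  r2 <- if (sd(e_xy) < 1e-14 || sd(ay) < 1e-14) 0 else cor(e_xy, ay)
  (r1 + r2) / 2
}

#' Debiased squared weighted phase-lag index (dwPLI)
#'
#' Phase-phase coupling weighted by the imaginary cross-spectrum,
#' insensitive to zero-lag coupling, with the small-sample bias of the
#' squared estimator removed.  Per non-overlapping window `j`,
#' `I_j = Im(mean(x * Conj(y)))`; then
#' `dwPLI = ((sum I)^2 - sum I^2) / ((sum |I|)^2 - sum I^2)`.
#' The raw (possibly slightly negative) value is returned; adjacency
#' matrices store `max(value, 0)` per the 0-1 scaling convention.
#'
#' @param x,y complex analytic signals (equal length).
#' @param fs sampling rate (Hz).
#' @param window_s window length in seconds; the matrix builder uses
#'   `max(1, 4 / fc)` so every window holds at least four carrier cycles.
#' @param segments optional segment boundaries.
#' @param min_windows minimum number of cross-spectral samples.
#' @param debias set `FALSE` for the plain squared wPLI (used to
#'   demonstrate the small-sample bias the debiasing removes).
#' @return scalar; attribute `"degenerate"` is `TRUE` when all `I_j` are
#'   zero (pure zero-lag; value 0).
#' @export
dwpli <- function(x, y, fs, window_s = 1, segments = NULL,
                  min_windows = 30, debias = TRUE) {
  stopifnot(length(x) == length(y))
  wlen <- round(window_s * fs)
  wins <- window_indices(length(x), segments, wlen)
  if (length(wins) < min_windows)
    stop(sprintf("only %d usable windows (< %d)", length(wins), min_windows))
  I <- vapply(wins, function(w) mean(Im(x[w] * Conj(y[w]))), numeric(1))
  sI <- sum(I); sI2 <- sum(I^2); sAbs <- sum(abs(I))
  if (sAbs < 1e-300 || all(abs(I) < 1e-15)) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  if (debias) {
    den <- sAbs^2 - sI2
    if (den <= 0) {
      out <- 0
      attr(out, "degenerate") <- TRUE
      return(out)
    }
    (sI^2 - sI2) / den
  } else {
    (sI / sAbs)^2
  }
}

#' Connectivity adjacency matrix
#'
#' Computes the symmetric parcels x parcels coupling matrix for one
#' subject, band, and mode (`"aac"` = oCC, `"ppc"` = dwPLI).  All
#' unordered pairs are computed (1653 for 58 parcels); the diagonal is
#' masked (`NA`), never 0 or 1.  For `"ppc"` the stored values are
#' clipped at 0 (raw values kept in attribute `"raw"`).
#'
#' @param parcels parcels x samples real matrix (band-filtered), an
#'   [eeg_recording()], or a complex analytic matrix.
#' @param mode `"aac"` or `"ppc"`.
#' @param fs sampling rate (Hz).
#' @param fc band centre frequency (metadata; also sets the default
#'   dwPLI window `max(1, 4 / fc)` seconds).
#' @param window_s window length override (seconds).
#' @param segments optional segment boundaries.
#' @param subject optional subject id (metadata).
#' @param min_windows minimum usable windows per pair.
#' @return an `adjacency_matrix`: list with `values`, `mode`, `fc`,
#'   `subject`, `n_windows`.
#' @export
connectivity_matrix <- function(parcels, mode = c("aac", "ppc"), fs,
                                fc = NULL, window_s = NULL, segments = NULL,
                                subject = NA_character_, min_windows = 30) {
  mode <- match.arg(mode)
  if (inherits(parcels, "eeg_recording")) {
    segments <- segments %||% parcels$segments
    fs <- fs %||% parcels$fs
    parcels <- parcels$data
  }
  if (is.complex(parcels)) {
    an <- parcels
    segments <- segments %||% attr(parcels, "segments")
  } else {
    segments <- segments %||% attr(parcels, "segments")
    an <- analytic_signal(parcels, segments = segments, fs = fs, fc = fc)
    segments <- attr(an, "segments")
  }
  p <- nrow(an)
  if (is.null(window_s))
    window_s <- if (mode == "ppc" && !is.null(fc)) max(1, 4 / fc) else 1
  wlen <- round(window_s * fs)
  wins <- window_indices(ncol(an), segments, wlen)
  nw <- length(wins)
  vals <- matrix(NA_real_, p, p)
  raw <- matrix(NA_real_, p, p)
  fun <- if (mode == "aac") {
    function(i, j) occ(an[i, ], an[j, ], fs, window_s = window_s,
                       segments = segments, min_windows = min_windows)
  } else {
    function(i, j) dwpli(an[i, ], an[j, ], fs, window_s = window_s,
                         segments = segments, min_windows = min_windows)
  }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      v <- tryCatch(as.numeric(fun(i, j)), error = function(e) NA_real_)
      raw[i, j] <- raw[j, i] <- v
      vals[i, j] <- vals[j, i] <- if (mode == "ppc" && !is.na(v)) max(v, 0) else v
    }
  }
  structure(list(values = vals, raw = raw, mode = toupper(mode), fc = fc,
                 subject = subject, n_windows = nw),
            class = "adjacency_matrix")
}

#' @export
print.adjacency_matrix <- function(x, ...) {
  cat(sprintf("<adjacency_matrix> %s, %d parcels, fc = %s Hz, %d windows, mean = %.4f\n",
              x$mode, nrow(x$values),
              if (is.null(x$fc)) "?" else format(x$fc, digits = 3),
              x$n_windows, mean(x$values[upper.tri(x$values)], na.rm = TRUE)))
  invisible(x)
}

#' Global mean of an adjacency matrix
#'
#' Mean over unmasked off-diagonal cells (each unordered pair counted
#' once).
#'
#' @param m an `adjacency_matrix` or plain symmetric matrix with `NA`
#'   masked cells.
#' @return scalar mean.
#' @export
global_mean <- function(m) {
  v <- if (inherits(m, "adjacency_matrix")) m$values else m
  mean(v[upper.tri(v)], na.rm = TRUE)
}
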