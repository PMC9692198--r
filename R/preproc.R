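#' Geometric band ladder
#'
#' Builds the narrow-band filter ladder used throughout the pipeline:
#' centre frequencies follow a geometric progression (each centre is
#' `ratio` times the previous one), with passband edges at
#' `[0.85, 1.15] * fc` and stopband edges at `[0.5, 1.5] * fc`.  The
#' default ladder (`f0 = 0.5`, `ratio = 1.2`, `n = 25`) spans 0.5-39.7 Hz.
#'
#' @param f0 first centre frequency (Hz), > 0.
#' @param ratio geometric ratio between consecutive centres, > 1.
#' @param n number of bands, >= 1.
#' @param fs optional sampling rate; if given, an error is raised when the
#'   top stopband reaches the Nyquist frequency.
#' @param attenuation_db stopband attenuation spec carried by each band.
#'
#' @return data.frame with one row per band: `fc`, `pass_lo`, `pass_hi`,
#'   `stop_lo`, `stop_hi`, `attenuation_db`.
#' @examples
#' ladder <- design_band_ladder(0.5, 1.2, 25)
#' round(ladder$fc[25], 1)  # 39.7
#' @export
design_band_ladder <- function(f0 = 0.5, ratio = 1.2, n = 25, fs = NULL,
                               attenuation_db = 40) {
  stopifnot(f0 > 0, ratio > 1, n >= 1)
  fc <- f0 * ratio^(seq_len(n) - 1)
  bands <- data.frame(
    fc = fc,
    pass_lo = 0.85 * fc, pass_hi = 1.15 * fc,
    stop_lo = 0.5 * fc,  stop_hi = 1.5 * fc,
    attenuation_db = attenuation_db)
  if (!is.null(fs)) {
    bad <- which(bands$stop_hi >= fs / 2)
    if (length(bad))
      stop(sprintf("band %d (fc = %.2f Hz) has stopband edge %.2f Hz >= Nyquist %.2f Hz",
                   bad[1], bands$fc[bad[1]], bands$stop_hi[bad[1]], fs / 2))
  }
  bands
}

# Kaiser window parameters for a target stopband attenuation A (dB).
kaiser_beta <- function(A) {
  if (A > 50) 0.1102 * (A - 8.7)
  else if (A >= 21) 0.5842 * (A - 21)^0.4 + 0.07886 * (A - 21)
  else 0
}

#' Kaiser-window FIR band-pass design
#'
#' Designs a linear-phase FIR band-pass meeting the band's contract: at
#' least `attenuation_db` attenuation at both stopband edges and passband
#' deviation below 1 dB at the centre frequency.  Cutoffs sit at the
#' transition midpoints; the order follows the standard Kaiser estimate
#' from the narrower transition width.
#'
#' @param band one row of a [design_band_ladder()] data.frame (or any list
#'   with `fc`, `pass_lo`, `pass_hi`, `stop_lo`, `stop_hi`,
#'   `attenuation_db`).
#' @param fs sampling rate (Hz); `band$stop_hi` must be below `fs / 2`.
#' @param max_length cap on the filter length; exceeded -> error.
#' @return numeric vector of symmetric (odd-length) FIR coefficients with
#'   attributes `fc` and `fs`.
#' @export
design_kaiser_bandpass <- function(band, fs, max_length = 2^16 + 1) {
  if (band$stop_hi >= fs / 2)
    stop(sprintf("stopband edge %.2f Hz not below Nyquist %.2f Hz",
                 band$stop_hi, fs / 2))
  A <- band$attenuation_db %||% 40
  trans <- min(band$pass_lo - band$stop_lo, band$stop_hi - band$pass_hi)
  if (trans <= 0) stop("degenerate transition width")
  # design with a 6 dB margin so the measured response meets the
  # attenuation contract at the stop edges themselves
  Ad <- A + 6
  dw <- 2 * pi * trans / fs
  N <- ceiling((Ad - 7.95) / (2.285 * dw))
  if (N %% 2 == 1) N <- N + 1      # even order -> odd length, type-I FIR
  L <- N + 1
  if (L > max_length)
    stop(sprintf("required filter length %d exceeds cap %d (transition %.3g Hz at fs %g)",
                 L, max_length, trans, fs))
  beta <- kaiser_beta(Ad)
  k <- seq_len(L) - 1
  m <- k - N / 2
  # ideal band-pass with cutoffs at transition midpoints
  w1 <- 2 * pi * (band$stop_lo + band$pass_lo) / 2 / fs
  w2 <- 2 * pi * (band$stop_hi + band$pass_hi) / 2 / fs
  h <- ifelse(m == 0, (w2 - w1) / pi,
              (sin(w2 * m) - sin(w1 * m)) / (pi * m))
  arg <- beta * sqrt(pmax(0, 1 - (2 * k / N - 1)^2))
  win <- besselI(arg, 0) / besselI(beta, 0)
  h <- h * win
  attr(h, "fc") <- band$fc
  attr(h, "fs") <- fs
  h
}

#' FIR frequency-response magnitude
#'
#' Evaluates the magnitude response of FIR coefficients `h` at frequencies
#' `f` (Hz) for sampling rate `fs`.
#'
#' @param h FIR coefficients.
#' @param f frequencies (Hz).
#' @param fs sampling rate (Hz).
#' @return magnitude response, same length as `f`.
#' @export
fir_response <- function(h, f, fs) {
  k <- seq_along(h) - 1
  vapply(f, function(fi) {
    Mod(sum(h * exp(-2i * pi * fi * k / fs)))
  }, numeric(1))
}

# Kaiser low-pass (for anti-alias decimation): pass to f_pass, stop at
# f_stop, attenuation A dB.
design_kaiser_lowpass <- function(f_pass, f_stop, fs, A = 60) {
  dw <- 2 * pi * (f_stop - f_pass) / fs
  N <- ceiling((A - 7.95) / (2.285 * dw))
  if (N %% 2 == 1) N <- N + 1
  L <- N + 1
  beta <- kaiser_beta(A)
  k <- seq_len(L) - 1
  m <- k - N / 2
  wc <- 2 * pi * (f_pass + f_stop) / 2 / fs
  h <- ifelse(m == 0, wc / pi, sin(wc * m) / (pi * m))
  arg <- beta * sqrt(pmax(0, 1 - (2 * k / N - 1)^2))
  h * besselI(arg, 0) / besselI(beta, 0)
}

#' Resample a recording
#'
#' Downsamples (or resamples) all channels to `target_fs`.  Integer
#' decimation applies a Kaiser anti-alias low-pass (stopband at the new
#' Nyquist, 60 dB) before picking every k-th sample; non-integer ratios
#' use polyphase resampling ([signal::resample()]).  Each segment is
#' resampled independently.
#'
#' @param rec an [eeg_recording()].
#' @param target_fs target sampling rate (Hz), `<= rec$fs`.
#' @return resampled [eeg_recording()].
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_fs <= 0) stop("target_fs must be positive")
  if (target_fs > rec$fs) stop("upsampling not supported")
  if (target_fs == rec$fs) return(rec)
  ratio <- rec$fs / target_fs
  integer_ratio <- abs(ratio - round(ratio)) < 1e-9
  segs <- segment_indices(rec)
  pieces <- vector("list", length(segs))
  if (integer_ratio) {
    k <- round(ratio)
    nyq <- target_fs / 2
    h <- design_kaiser_lowpass(0.8 * nyq, nyq, rec$fs)
    for (i in seq_along(segs)) {
      seg <- rec$data[, segs[[i]], drop = FALSE]
      seg <- fft_filter_rows(seg, h)
      pieces[[i]] <- seg[, seq(1, ncol(seg), by = k), drop = FALSE]
    }
  } else {
    pq <- find_rational(target_fs / rec$fs)
    for (i in seq_along(segs)) {
      seg <- rec$data[, segs[[i]], drop = FALSE]
      pieces[[i]] <- t(apply(seg, 1, function(x)
        as.numeric(signal::resample(x, pq[1], pq[2]))))
    }
  }
  lens <- vapply(pieces, ncol, integer(1))
  ends <- cumsum(lens)
  eeg_recording(do.call(cbind, pieces), target_fs,
                ch_names = rec$ch_names, positions = rec$positions,
                reference = rec$reference, bad = rec$bad,
                segments = cbind(c(1L, head(ends, -1) + 1L), ends))
}

find_rational <- function(x, max_den = 1000) {
  for (q in seq_len(max_den)) {
    p <- x * q
    if (abs(p - round(p)) < 1e-9) return(c(round(p), q))
  }
  stop("cannot express resampling ratio as a small rational")
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean across channels from every channel,
#' so that each column (sample) has zero mean.  Idempotent.  Bad channels
#' should be interpolated first.
#'
#' @param rec an [eeg_recording()].
#' @return re-referenced [eeg_recording()] with `reference = "average"`.
#' @export
rereference_average <- function(rec) {
  stopifnot(inherits(rec, "eeg_recording"))
  data <- sweep(rec$data, 2, colMeans(rec$data))
  eeg_recording(data, rec$fs, ch_names = rec$ch_names,
                positions = rec$positions, reference = "average",
                bad = rec$bad, segments = rec$segments)
}

# Spherical spline interpolation matrix (Perrin et al. 1989 family):
# g(cos theta) = sum_n (2n+1) / (n(n+1))^m P_n(cos theta) / (4 pi).
spline_g <- function(cosang, m = 4, nmax = 50) {
  n <- seq_len(nmax)
  coef <- (2 * n + 1) / (n * (n + 1))^m / (4 * pi)
  P <- legendre_table(pmin(1, pmax(-1, as.vector(cosang))), nmax)
  matrix(P %*% coef, nrow = nrow(as.matrix(cosang)))
}

#' Spherical-spline interpolation of bad channels
#'
#' Replaces each bad channel by a spherical-spline estimate fitted to the
#' good channels' instantaneous values on the unit-sphere montage; good
#' channels are untouched.
#'
#' @param rec an [eeg_recording()] with electrode positions.
#' @param bad character vector of channel names to interpolate (defaults
#'   to `rec$bad`).
#' @param m spline order (stiffness), default 4.
#' @param nmax number of Legendre terms, default 50.
#' @param lambda ridge regularization added to the spline system.
#' @return [eeg_recording()] with bad channels replaced and `bad` cleared.
#' @export
interpolate_bad_channels <- function(rec, bad = rec$bad, m = 4, nmax = 50,
                                     lambda = 1e-8) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (length(bad) == 0) return(rec)
  if (is.null(rec$positions)) stop("montage positions required for interpolation")
  idx_bad <- match(bad, rec$ch_names)
  if (anyNA(idx_bad)) stop("unknown bad channel name")
  if (length(idx_bad) >= nrow(rec$data) / 4)
    stop("too many bad channels (>= 1/4 of montage)")
  good <- setdiff(seq_len(nrow(rec$data)), idx_bad)
  pos <- rec$positions
  Ggg <- spline_g(tcrossprod(pos[good, , drop = FALSE]), m, nmax)
  Gbg <- spline_g(pos[idx_bad, , drop = FALSE] %*% t(pos[good, , drop = FALSE]),
                  m, nmax)
  ng <- length(good)
  A <- rbind(cbind(Ggg + lambda * diag(ng), rep(1, ng)),
             c(rep(1, ng), 0))
  rhs <- rbind(rec$data[good, , drop = FALSE], 0)
  sol <- solve(A, rhs)
  est <- Gbg %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], nrow = length(idx_bad), ncol = ncol(rec$data),
           byrow = TRUE)
  data <- rec$data
  data[idx_bad, ] <- est
  eeg_recording(data, rec$fs, ch_names = rec$ch_names,
                positions = rec$positions, reference = rec$reference,
                bad = character(), segments = rec$segments)
}

#' Broadband conditioning filter
#'
#' Band-pass conditioning (default 0.15-48 Hz) applied before
#' downsampling, using the same Kaiser design as the narrow bands (40 dB,
#' stop edges at half / 1.5 times the passband corners).  The 0.15 Hz
#' high-pass corner makes this filter several seconds long; transients
#' are trimmed only when `trim = TRUE` (the synthetic generator produces
#' in-band data, so the pipeline skips conditioning by default).
#'
#' @param rec an [eeg_recording()].
#' @param lo,hi passband corners (Hz).
#' @param trim drop one filter length from each segment end.
#' @return filtered [eeg_recording()].
#' @export
condition_broadband <- function(rec, lo = 0.15, hi = 48, trim = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  band <- list(fc = sqrt(lo * hi), pass_lo = lo, pass_hi = hi,
               stop_lo = lo / 2, stop_hi = min(1.5 * hi, 0.98 * rec$fs / 2),
               attenuation_db = 40)
  h <- design_kaiser_bandpass(band, rec$fs)
  filter_recording(rec, h, trim = trim)
}

# Apply one zero-phase FIR per segment; optionally trim one filter length
# from each segment end (transient pads).  Segments shorter than
# 3 * filter length are skipped with a message when trimming.
filter_recording <- function(rec, h, trim = TRUE) {
  L <- length(h)
  segs <- segment_indices(rec)
  pieces <- list()
  for (i in seq_along(segs)) {
    n <- length(segs[[i]])
    if (trim && n < 3 * L) {
      message(sprintf("segment %d (%d samples) shorter than 3 x filter length %d; skipped",
                      i, n, L))
      next
    }
    seg <- fft_filter_rows(rec$data[, segs[[i]], drop = FALSE], h)
    if (trim) seg <- seg[, (L + 1):(n - L), drop = FALSE]
    pieces[[length(pieces) + 1]] <- seg
  }
  if (length(pieces) == 0) stop("no segment long enough for this filter")
  lens <- vapply(pieces, ncol, integer(1))
  ends <- cumsum(lens)
  eeg_recording(do.call(cbind, pieces), rec$fs, ch_names = rec$ch_names,
                positions = rec$positions, reference = rec$reference,
                bad = rec$bad,
                segments = cbind(c(1L, head(ends, -1) + 1L), ends))
}

#' Apply the narrow-band filter bank
#'
#' Filters a conditioned recording into each ladder band with zero-phase
#' Kaiser FIR filters.  Each continuous segment is filtered independently
#' and one filter length is dropped from each segment end; segments
#' shorter than three filter lengths at a band are skipped for that band
#' with a message.
#'
#' @param rec an [eeg_recording()] (average-referenced, 250 Hz typical).
#' @param bands data.frame from [design_band_ladder()] (any subset of
#'   rows).
#' @return named list of band-filtered [eeg_recording()]s (names
#'   `"fc=<value>"`), each with attribute `fc`.
#' @export
apply_filter_bank <- function(rec, bands) {
  stopifnot(inherits(rec, "eeg_recording"))
  out <- vector("list", nrow(bands))
  names(out) <- sprintf("fc=%.4g", bands$fc)
  for (i in seq_len(nrow(bands))) {
    h <- design_kaiser_bandpass(bands[i, ], rec$fs)
    r <- filter_recording(rec, h, trim = TRUE)
    attr(r, "fc") <- bands$fc[i]
    out[[i]] <- r
  }
  out
}
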