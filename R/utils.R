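# Internal numerical helpers: FFT convolution, analytic signal, Legendre
# recurrences, von Mises sampling, seeded evaluation.

#' Evaluate an expression with a fixed RNG seed
#'
#' Runs `expr` under `set.seed(seed)` without disturbing the caller's RNG
#' state.  All stochastic operations in the package funnel through this so
#' that identical (inputs, seed) give bit-identical outputs.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Linear convolution of x with FIR h via FFT, compensating the group delay
# of a symmetric (linear-phase, odd-length) filter: output is aligned with
# the input (zero-phase) and has the same length.
fft_filter <- function(x, h) {
  nx <- length(x)
  nh <- length(h)
  if (nh %% 2 != 1) stop("fft_filter expects an odd-length symmetric FIR")
  d <- (nh - 1L) / 2L
  nfft <- stats::nextn(nx + nh - 1L, 2)
  X <- fft(c(x, numeric(nfft - nx)))
  H <- fft(c(h, numeric(nfft - nh)))
  y <- Re(fft(X * H, inverse = TRUE)) / nfft
  y[(d + 1L):(d + nx)]
}

# Zero-phase filter each row of a channels x samples matrix.
fft_filter_rows <- function(m, h) {
  out <- m
  for (i in seq_len(nrow(m))) out[i, ] <- fft_filter(m[i, ], h)
  out
}

# Analytic signal (Hilbert transform) of a real vector via FFT.
# Real part equals x; |.| is the envelope; Arg(.) the instantaneous phase.
analytic_vector <- function(x) {
  n <- length(x)
  if (n == 0) return(complex(0))
  X <- fft(x)
  w <- numeric(n)
  if (n %% 2 == 0) {
    w[1] <- 1; w[n / 2 + 1] <- 1; w[2:(n / 2)] <- 2
  } else {
    w[1] <- 1; w[2:((n + 1) / 2)] <- 2
  }
  fft(X * w, inverse = TRUE) / n
}

# Legendre polynomials P_1..P_nmax evaluated at vector t in [-1, 1].
# Returns a length(t) x nmax matrix; three-term recurrence.
legendre_table <- function(t, nmax) {
  out <- matrix(0, length(t), nmax)
  pm1 <- rep(1, length(t))   # P_0
  p   <- t                   # P_1
  out[, 1] <- p
  if (nmax >= 2) {
    for (n in 2:nmax) {
      pn <- ((2 * n - 1) * t * p - (n - 1) * pm1) / n
      pm1 <- p
      p <- pn
      out[, n] <- p
    }
  }
  out
}

# von Mises sampler (Best & Fisher 1979 rejection method).
# mu in radians, kappa >= 0; kappa = 0 degenerates to uniform.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u1 <- runif(1); u2 <- runif(1); u3 <- runif(1)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u2 > 0 || log(cc / u2) + 1 - cc >= 0) {
      out[i] <- sign(u3 - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out + mu
}

# 1/f^alpha coloured noise of length n (power spectrum ~ f^-alpha),
# unit variance, plus an optional Gaussian spectral bump.
colored_noise <- function(n, fs, alpha = 1.1, bump_hz = NULL,
                          bump_width = 1.5, bump_rel = 0) {
  nfft <- stats::nextn(n, 2)
  f <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  amp <- c(0, f[-1]^(-alpha / 2))
  if (!is.null(bump_hz) && bump_rel > 0) {
    amp <- amp + bump_rel * mean(amp[f >= 1 & f <= 20]) *
      exp(-0.5 * ((f - bump_hz) / bump_width)^2)
  }
  # hermitian spectrum from white Gaussian phases
  half <- (amp * complex(real = rnorm(nfft / 2 + 1),
                         imaginary = rnorm(nfft / 2 + 1)))
  half[1] <- 0
  half[nfft / 2 + 1] <- complex(real = Re(half[nfft / 2 + 1]))
  spec <- c(half, Conj(rev(half[2:(nfft / 2)])))
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  x / sd(x)
}

# Band-limited noise: white noise filtered to [lo, hi] Hz with a quick
# frequency-domain brick wall softened by a raised cosine (internal
# generator use only; analysis filtering always uses the Kaiser designs).
bandlimited_noise <- function(n, fs, lo, hi, roll = 0.15) {
  nfft <- stats::nextn(n, 2)
  f <- seq(0, fs / 2, length.out = nfft / 2 + 1)
  g <- rep(0, length(f))
  g[f >= lo & f <= hi] <- 1
  w <- (hi - lo) * roll
  lo_t <- f >= lo - w & f < lo
  hi_t <- f > hi & f <= hi + w
  g[lo_t] <- 0.5 * (1 + cos(pi * (lo - f[lo_t]) / w))
  g[hi_t] <- 0.5 * (1 + cos(pi * (f[hi_t] - hi) / w))
  half <- g * complex(real = rnorm(length(f)), imaginary = rnorm(length(f)))
  half[1] <- 0
  half[length(f)] <- complex(real = Re(half[length(f)]))
  spec <- c(half, Conj(rev(half[2:(nfft / 2)])))
  x <- Re(fft(spec, inverse = TRUE))[seq_len(n)]
  x / sd(x)
}

# Slow (lowpass) standard-normal process used for envelope modulators:
# Gaussian noise lowpassed to [lo, hi] Hz band, standardized.
slow_gaussian <- function(n, fs, lo = 0.1, hi = 0.5) {
  x <- bandlimited_noise(n, fs, lo, hi)
  (x - mean(x)) / sd(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
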