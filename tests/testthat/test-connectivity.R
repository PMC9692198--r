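test_that("analytic signal recovers envelope and phase of known signals", {
  fs <- 250
  t <- seq_len(fs * 10) / fs
  a <- analytic_signal(cos(2 * pi * 8 * t))
  interior <- 500:2000
  expect_equal(Mod(a[1, interior]), rep(1, length(interior)), tolerance = 1e-3)
  dph <- diff(Arg(a[1, interior]))
  dph <- dph[dph > 0]
  expect_equal(median(dph), 2 * pi * 8 / fs, tolerance = 1e-3)
  # slow AM envelope recovered within 5% in the interior
  am <- (1.5 + cos(2 * pi * 0.3 * t)) * cos(2 * pi * 8 * t)
  env <- Mod(analytic_signal(am)[1, interior])
  expect_lt(max(abs(env - (1.5 + cos(2 * pi * 0.3 * t[interior]))) /
                  (1.5 + cos(2 * pi * 0.3 * t[interior]))), 0.05)
  expect_equal(max(Mod(analytic_signal(rep(0, 1000)))), 0)
  expect_equal(Re(analytic_signal(am)[1, ]), am, tolerance = 1e-9)
})

test_that("analytic signal respects segment boundaries", {
  fs <- 250
  x <- matrix(rnorm(fs * 4), 1)
  segs <- rbind(c(1, fs * 2), c(fs * 2 + 1, fs * 4))
  a <- analytic_signal(x, segments = segs)
  a1 <- analytic_signal(x[, 1:(fs * 2), drop = FALSE])
  expect_equal(a[, 1:(fs * 2)], a1[, ], ignore_attr = TRUE)
  expect_message(
    analytic_signal(x, segments = rbind(c(1, 10), c(11, fs * 4)),
                    fs = fs, fc = 10), "skipped")
})

test_that("oCC suppresses zero-lag coupling by construction", {
  fs <- 250
  x <- band_analytic(rnorm(fs * 60), fs, 10)
  expect_equal(as.numeric(occ(x, x, fs)), 0)
  # scaled copy (pure volume conduction) also vanishes
  expect_equal(as.numeric(occ(x, 2.5 * x, fs)), 0, tolerance = 1e-10)
  zero <- x * 0
  out <- occ(x, zero, fs)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "degenerate"))
  expect_error(occ(x[1:1000], x[1:1000], fs), "windows")
})

test_that("oCC null on independent narrow-band noise stays small", {
  fs <- 250
  set.seed(31)
  vals <- replicate(8, {
    a <- band_analytic(rnorm(fs * 120), fs, 10)
    b <- band_analytic(rnorm(fs * 120), fs, 10)
    abs(occ(a, b, fs))
  })
  expect_lt(median(vals), 0.05)
  expect_lt(mean(vals > 0.1), 0.2)
})

test_that("oCC recovers generator envelope coupling and is monotone in strength", {
  fs <- 250
  rec <- vapply(c(0.2, 0.45, 0.7, 0.9), function(s) {
    cs <- coupling_spec(c(1, 2), "envelope", 13, strength = s,
                        carrier = "locked", lag = pi / 2)
    x <- simulate_parcel_sources(list(cs), 2, fs, 240, seed = 40 + round(100 * s))
    occ(band_analytic(x[1, ], fs, 13.3), band_analytic(x[2, ], fs, 13.3), fs)
  }, numeric(1))
  expect_gte(cor(rec, c(0.2, 0.45, 0.7, 0.9), method = "spearman"), 0.9)
  expect_equal(rec[3], 0.7, tolerance = 0.15 / 0.7)
})

test_that("dwPLI has the correct limits and closed two-window form", {
  fs <- 250
  t <- seq_len(fs * 60) / fs
  x <- analytic_signal(cos(2 * pi * 10 * t))[1, ]
  y <- analytic_signal(cos(2 * pi * 10 * t - pi / 2))[1, ]
  expect_equal(as.numeric(dwpli(x, x, fs)), 0)     # zero lag ignored
  expect_gte(as.numeric(dwpli(x, y, fs)), 0.99)    # consistent quarter lag
  # two windows: closed form ((I1+I2)^2 - I1^2 - I2^2) / ((|I1|+|I2|)^2 - ...)
  set.seed(7)
  a <- band_analytic(rnorm(fs * 2), fs, 10)
  b <- band_analytic(rnorm(fs * 2), fs, 10)
  I <- vapply(1:2, function(w) {
    idx <- ((w - 1) * fs + 1):(w * fs)
    mean(Im(a[idx] * Conj(b[idx])))
  }, numeric(1))
  byhand <- (2 * I[1] * I[2]) / (2 * abs(I[1]) * abs(I[2]))
  expect_equal(as.numeric(dwpli(a, b, fs, min_windows = 2)), byhand)
})

test_that("debiasing removes the small-sample bias of squared wPLI", {
  fs <- 250
  set.seed(17)
  dwn <- numeric(40); plain <- numeric(40)
  for (s in seq_len(40)) {
    a <- cortnet:::analytic_vector(cortnet:::bandlimited_noise(fs * 50, fs, 8, 12))
    b <- cortnet:::analytic_vector(cortnet:::bandlimited_noise(fs * 50, fs, 8, 12))
    dwn[s] <- dwpli(a, b, fs, window_s = 1)
    plain[s] <- dwpli(a, b, fs, window_s = 1, debias = FALSE)
  }
  expect_lt(abs(mean(dwn)), 0.02)
  expect_gt(mean(plain), 0.005)        # biased null ~ 1 / n_windows
})

test_that("connectivity matrices cover all pairs and are equivariant", {
  fs <- 250
  x <- simulate_parcel_sources(list(coupling_spec(c(1, 2), "phase", 10)),
                               4, fs, 60, seed = 5)
  h <- design_kaiser_bandpass(ladder_band(10), fs)
  an <- analytic_signal(cortnet:::fft_filter_rows(x, h))
  m <- connectivity_matrix(an, "ppc", fs = fs, fc = 10)
  expect_equal(sum(!is.na(m$values[upper.tri(m$values)])), 6)
  expect_true(all(is.na(diag(m$values))))
  expect_equal(m$values, t(m$values))
  expect_true(all(m$values[upper.tri(m$values)] >= 0))
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  m2 <- connectivity_matrix(an[perm, ], "ppc", fs = fs, fc = 10)
  expect_equal(m2$values, m$values[perm, perm], tolerance = 1e-12)
  # AAC values bounded in [-1, 1]
  ma <- connectivity_matrix(an, "aac", fs = fs, fc = 10)
  expect_true(all(abs(ma$values[upper.tri(ma$values)]) <= 1))
})

test_that("instantaneous mixing of independent sources yields null networks", {
  fs <- 250
  set.seed(11)
  nsrc <- 6
  S <- t(vapply(seq_len(nsrc), function(i)
    cortnet:::bandlimited_noise(fs * 90, fs, 8, 12), numeric(fs * 90)))
  A <- matrix(runif(nsrc * nsrc, 0.2, 1), nsrc)
  X <- A %*% S
  an <- t(vapply(seq_len(nsrc), function(i) band_analytic(X[i, ], fs, 10),
                 complex(fs * 90)))
  oc <- c(); dw <- c()
  for (i in seq_len(nsrc - 1)) for (j in (i + 1):nsrc) {
    oc <- c(oc, abs(occ(an[i, ], an[j, ], fs)))
    dw <- c(dw, dwpli(an[i, ], an[j, ], fs))
  }
  expect_lt(median(oc), 0.05)
  expect_lt(median(dw), 0.05)
})
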