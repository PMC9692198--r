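test_that("generation is a pure function of the seed", {
  cs <- list(coupling_spec(c(1, 2), "envelope", 13, strength = 0.5))
  a <- simulate_parcel_sources(cs, 4, 250, 60, seed = 9)
  b <- simulate_parcel_sources(cs, 4, 250, 60, seed = 9)
  expect_identical(a, b)
  c2 <- simulate_parcel_sources(cs, 4, 250, 60, seed = 10)
  expect_false(identical(a, c2))
})

test_that("uncoupled parcels have near-zero envelope correlations", {
  x <- simulate_parcel_sources(list(), 4, 250, 60, seed = 2)
  expect_equal(dim(x), c(4, 15000))
  env <- lapply(1:4, function(p) Mod(band_analytic(x[p, ], 250, 13.3)))
  for (i in 1:3) for (j in (i + 1):4)
    expect_lt(abs(cor(env[[i]], env[[j]])), 0.1)
})

test_that("envelope coupling hits its target correlation on ground truth", {
  cs <- coupling_spec(c(1, 2), "envelope", 13, strength = 0.6)
  x <- simulate_parcel_sources(list(cs), 2, 250, 600, seed = 7)
  e1 <- Mod(band_analytic(x[1, ], 250, 13.3))
  e2 <- Mod(band_analytic(x[2, ], 250, 13.3))
  expect_equal(cor(e1, e2), 0.6, tolerance = 0.1 / 0.6)
})

test_that("phase coupling realizes the requested lag", {
  cp <- coupling_spec(c(1, 2), "phase", 10, lag = pi / 2, kappa = 50)
  y <- simulate_parcel_sources(list(cp), 3, 250, 120, seed = 3)
  a1 <- cortnet:::analytic_vector(y[1, ])
  a2 <- cortnet:::analytic_vector(y[2, ])
  circ_mean <- Arg(mean(exp(1i * Arg(a2 * Conj(a1)))))
  expect_lt(abs(circ_mean - pi / 2), 0.1)
})

test_that("contradictory coupling specs on one pair are rejected", {
  s1 <- coupling_spec(c(1, 2), "envelope", 13, strength = 0.5)
  s2 <- coupling_spec(c(2, 1), "phase", 10)
  expect_error(simulate_parcel_sources(list(s1, s2), 4, 250, 60),
               "conflicting")
  # disjoint epochs on the same pair are allowed
  s3 <- coupling_spec(c(1, 2), "envelope", 13, epochs = cbind(0, 20))
  s4 <- coupling_spec(c(1, 2), "phase", 10, epochs = cbind(30, 50))
  expect_silent(simulate_parcel_sources(list(s3, s4), 4, 250, 60, seed = 1))
  expect_error(simulate_parcel_sources(list(), 4, 250, 30), "duration")
})

test_that("injected spindles are exact, non-overlapping, and strong in band", {
  x <- simulate_parcel_sources(list(), 4, 250, 300, seed = 6)
  none <- inject_spindles(x, 250, rate_per_min = 0)
  expect_identical(none$data, x)
  expect_equal(nrow(none$truth), 0)
  inj <- inject_spindles(x, 250, rate_per_min = 5, freq_hz = 13,
                         duration_s = 1, amplitude_rel = 3, seed = 8)
  k <- nrow(inj$truth)
  expect_gt(k, 5)                      # Poisson(25) range
  expect_lt(k, 50)
  expect_true(all(diff(inj$truth$start_s) >
                    (inj$truth$end_s - inj$truth$start_s)[-k]))
  # 11-15 Hz band power inside events at least 4x the local baseline
  h <- design_kaiser_bandpass(list(fc = 13, pass_lo = 11, pass_hi = 15,
                                   stop_lo = 9, stop_hi = 17,
                                   attenuation_db = 40), 250)
  xb <- cortnet:::fft_filter(inj$data[1, ], h)
  base_b <- cortnet:::fft_filter(x[1, ], h)
  for (i in seq_len(min(5, k))) {
    idx <- (round(inj$truth$start_s[i] * 250) + 1):round(inj$truth$end_s[i] * 250)
    expect_gt(mean(xb[idx]^2) / mean(base_b^2), 4)
  }
  expect_error(inject_spindles(x, 250, rate_per_min = 500, seed = 1),
               "overlap")
})

test_that("disjoint channel profiles give tagged, additive truth intervals", {
  x <- simulate_parcel_sources(list(), 6, 250, 120, seed = 4)
  i1 <- inject_spindles(x, 250, 0, channels = 1:3, at = c(10, 40), profile = 1L)
  i2 <- inject_spindles(i1$data, 250, 0, channels = 4:6, at = c(70, 100),
                        profile = 2L)
  truth <- rbind(i1$truth, i2$truth)
  expect_setequal(truth$profile, c(1L, 2L))
  total <- sum(truth$end_s - truth$start_s)
  expect_equal(total, 4 * 1)            # union = sum of lengths (disjoint)
  expect_error(inject_spindles(x, 250, 0, at = c(10, 10.5)), "overlap")
})

test_that("sensor projection respects identity, noise-only, and SNR bookkeeping", {
  idb <- make_toy_bundle(8, 8, 8, identity = TRUE)
  x <- simulate_parcel_sources(list(), 8, 250, 60, seed = 5)
  rec <- project_to_sensors(x, idb, snr_db = Inf)
  expect_equal(rec$data, x, ignore_attr = TRUE)
  noise <- project_to_sensors(0 * x, idb, snr_db = -Inf, seed = 2, noise_sd = 1.5)
  cv <- cov(t(noise$data))
  expect_equal(mean(diag(cv)), 1.5^2, tolerance = 0.05)
  expect_lt(max(abs(cv[upper.tri(cv)])), 0.1)
  bundle <- make_toy_bundle(64, 256, 12, seed = 1)
  x12 <- simulate_parcel_sources(list(), 12, 250, 60, seed = 5)
  sig <- project_to_sensors(x12, bundle, snr_db = Inf)
  noisy <- project_to_sensors(x12, bundle, snr_db = 10, seed = 3)
  p_sig <- mean(sig$data^2)
  p_tot <- mean(noisy$data^2)
  expect_equal(p_tot, p_sig * (1 + 10^(-10 / 10)), tolerance = 0.05)
  expect_error(project_to_sensors(x, bundle), "parcel count")
})

test_that("per-group coupling offsets are detectable on ground truth at n=15", {
  man <- cohort_manifest(c(Typical = 15, Severe = 15), seed = 1)
  coh <- simulate_cohort(man, grouping = "neuro_2y",
                         offsets = c(Typical = 0.2, Mild = 0, Severe = -0.2),
                         base_strength = 0.5, n_parcels = 2,
                         duration_s = 60, seed = 11)
  meas <- vapply(coh$sources, function(s) {
    cor(Mod(band_analytic(s[1, ], 250, 13.3)),
        Mod(band_analytic(s[2, ], 250, 13.3)))
  }, numeric(1))
  g <- coh$manifest$neuro_2y
  expect_lt(wilcox.test(meas[g == "Typical"], meas[g == "Severe"],
                        alternative = "greater")$p.value, 0.01)
})

test_that("matrix-level cohort generator implants exactly the requested edges", {
  sim <- simulate_cohort_matrices(6, 6, 10, n_effect = 5, effect = 0.4,
                                  noise_sd = 0.05, seed = 3)
  expect_equal(dim(sim$A), c(6, 10, 10))
  expect_equal(nrow(sim$effect_edges), 5)
  for (k in seq_len(5)) {
    i <- sim$effect_edges[k, 1]; j <- sim$effect_edges[k, 2]
    expect_gt(mean(sim$A[, i, j]) - mean(sim$B[, i, j]), 0.2)
    expect_equal(sim$A[, i, j], sim$A[, j, i])   # symmetry
  }
  expect_true(all(is.na(sim$A[, 1, 1])))         # diagonal masked
})
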