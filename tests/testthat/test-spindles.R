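test_that("noise-only records yield no spindle detections", {
  set.seed(1)
  x <- rnorm(250 * 60)
  det <- detect_spindles_channel(x, 250)
  expect_equal(nrow(det), 0)
  expect_error(detect_spindles_channel(rnorm(250 * 20), 250), "30 s")
})

test_that("sub-threshold durations are rejected by the duration gate", {
  # constant-envelope sigma background so the extension threshold region
  # is exactly the burst plus the smoothing spread
  fs <- 250
  t <- seq_len(fs * 60) / fs
  base <- sin(2 * pi * 13 * t)
  short <- base
  idx <- 5001:5075                       # 0.3 s burst (< 0.5 s gate)
  short[idx] <- 6 * short[idx]
  det <- detect_spindles_channel(short, fs)
  expect_false(any(intervals_overlap(det$start_s, det$end_s, 19.8, 20.5)))
  long <- base
  idx2 <- 5001:5250                      # 1 s burst is kept
  long[idx2] <- 6 * long[idx2]
  det2 <- detect_spindles_channel(long, fs)
  expect_true(any(intervals_overlap(det2$start_s, det2$end_s, 19.9, 21.1)))
})

test_that("detector recalls injected spindles with high precision", {
  x <- simulate_parcel_sources(list(), 8, 250, 300, seed = 6)
  inj <- inject_spindles(x, 250, rate_per_min = 5, freq_hz = 13,
                         duration_s = 1, amplitude_rel = 3, seed = 8)
  ann <- detect_spindles(eeg_recording(inj$data, 250))
  expect_gte(interval_recall(inj$truth, ann$global), 0.9)
  expect_gte(interval_precision(inj$truth, ann$global), 0.9)
})

test_that("the detector is translation-equivariant", {
  base <- simulate_parcel_sources(list(), 1, 250, 120, seed = 9)[1, ]
  shift <- 250 * 2
  burst_at <- function(x, t0) {
    idx <- (t0 * 250 + 1):(t0 * 250 + 250)
    x[idx] <- x[idx] + 5 * sd(x) * sin(2 * pi * 13 * seq_along(idx) / 250) *
      0.5 * (1 - cos(2 * pi * seq_along(idx) / 251))
    x
  }
  d1 <- detect_spindles_channel(burst_at(base, 30), 250)
  x2 <- c(base[(shift + 1):length(base)], base[1:shift])  # rotate background
  d2 <- detect_spindles_channel(burst_at(x2, 32), 250)
  expect_equal(nrow(d1), nrow(d2))
  expect_equal(d2$start_s, d1$start_s + 2, tolerance = 0.05)
})

test_that("the cross-channel power gate drops unsupported candidates", {
  x <- simulate_parcel_sources(list(), 16, 250, 120, seed = 10)
  # strong events on all channels, weak event on one channel only
  i1 <- inject_spindles(x, 250, 0, at = c(20, 50, 80), amplitude_rel = 3)
  i2 <- inject_spindles(i1$data, 250, 0, at = 100, amplitude_rel = 3,
                        channels = 7)
  rec <- eeg_recording(i2$data, 250)
  ann <- detect_spindles(rec)
  expect_true(all(vapply(c(20, 50, 80), function(t0)
    any(intervals_overlap(ann$global$start_s, ann$global$end_s, t0, t0 + 1)),
    logical(1))))
  expect_false(any(intervals_overlap(ann$global$start_s, ann$global$end_s,
                                     100, 101)))
  # theta = 0 disables the gate: the single-channel event comes back
  ann0 <- detect_spindles(rec, spindle_params(theta = 0))
  expect_true(any(intervals_overlap(ann0$global$start_s, ann0$global$end_s,
                                    100, 101)))
  # gating never creates intervals absent from per-channel detections
  allch <- do.call(rbind, lapply(ann0$channel, function(d) d))
  for (i in seq_len(nrow(ann0$global)))
    expect_true(any(intervals_overlap(allch$start_s, allch$end_s,
                                      ann0$global$start_s[i],
                                      ann0$global$end_s[i])))
})

test_that("spindle grouping arithmetic matches its definition", {
  ann <- structure(list(
    channel = list(ch1 = data.frame(start_s = c(0, 1.2),
                                    end_s = c(1, 2.2), peak = c(1, 1))),
    global = data.frame(start_s = c(0, 1.2), end_s = c(1, 2.2),
                        peak_power = c(1, 1)),
    params = spindle_params()), class = "spindle_annotations")
  g1 <- group_spindles(ann, duration_s = 60, gap_s = 0.5)
  expect_equal(nrow(g1$groups), 1)
  expect_equal(g1$groups$end_s - g1$groups$start_s, 2.2)
  expect_equal(unname(g1$spindles_per_group["mean"]), 2)
  g2 <- group_spindles(ann, duration_s = 60, gap_s = 0.1)
  expect_equal(nrow(g2$groups), 2)
  expect_equal(unname(g2$spindles_per_group["mean"]), 1)
  expect_equal(g2$spindles_per_min, 2)
})

test_that("co-detection across channels shows up in spindles per group", {
  x <- simulate_parcel_sources(list(), 15, 250, 120, seed = 12)
  inj <- inject_spindles(x, 250, 0, at = c(20, 60, 100), amplitude_rel = 3)
  ann <- detect_spindles(eeg_recording(inj$data, 250))
  gm <- group_spindles(ann, 120)
  expect_equal(unname(gm$spindles_per_group["mean"]), 15, tolerance = 0.25)
})

test_that("spindle excision removes exactly the padded intervals and re-segments", {
  x <- simulate_parcel_sources(list(), 4, 250, 240, seed = 13)
  rec <- eeg_recording(x, 250)
  empty <- structure(list(channel = list(),
                          global = data.frame(start_s = numeric(0),
                                              end_s = numeric(0),
                                              peak_power = numeric(0)),
                          params = spindle_params()),
                     class = "spindle_annotations")
  expect_identical(remove_spindles(rec, empty), rec)
  one <- empty
  one$global <- data.frame(start_s = 100, end_s = 101, peak_power = 1)
  out <- remove_spindles(rec, one, pad_s = 0.25)
  expect_equal(ncol(rec$data) - ncol(out$data), round(1.5 * 250), tolerance = 2 / 375)
  expect_equal(nrow(out$segments), 2)
  far <- empty
  far$global <- data.frame(start_s = 500, end_s = 501, peak_power = 1)
  expect_error(remove_spindles(rec, far), "beyond")
})

test_that("removing zero-amplitude spindles leaves connectivity unchanged", {
  fs <- 250
  set.seed(14)
  x <- matrix(rnorm(4 * fs * 240), 4)
  inj <- inject_spindles(x, fs, 0, at = c(30, 90, 150), amplitude_rel = 1e-9)
  rec <- eeg_recording(inj$data, fs)
  ann <- detect_spindles(rec)                # nothing detectable
  out <- remove_spindles(rec, ann)
  conn_of <- function(r) {
    br <- apply_filter_bank(r, ladder_band(13.3))[[1]]
    connectivity_matrix(br, "ppc", fs = fs, fc = 13.3)$values
  }
  expect_equal(conn_of(out), conn_of(rec), tolerance = 1e-10)
})
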