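# Synthetic N2-sleep EEG with known ground truth: parcel-level sources
# with controllable envelope / phase couplings, injected sleep spindles,
# forward projection to sensors, and cohort-level group structure.

#' Coupling specification for the source generator
#'
#' Describes one ground-truth coupling between a pair of parcels, either
#' in the amplitude domain (`mode = "envelope"`: the two parcels' slow
#' amplitude envelopes share a common log-normal modulator mixed to reach
#' a target Pearson correlation) or in the phase domain
#' (`mode = "phase"`: the two parcels share a carrier with a fixed phase
#' lag plus von Mises jitter).
#'
#' @param pair integer vector of two distinct 1-based parcel indices.
#' @param mode `"envelope"` or `"phase"`.
#' @param band_hz carrier centre frequency (Hz), within `[0.4, 45]`.
#' @param strength envelope mode: target envelope correlation in `[0, 1]`.
#' @param lag phase mode: phase lag in radians (also used as the carrier
#'   lag in envelope mode when `carrier = "locked"`).
#' @param kappa phase mode: von Mises concentration of the phase jitter.
#' @param carrier envelope mode: `"independent"` (default) for
#'   phase-unrelated carriers, or `"locked"` for a shared carrier offset
#'   by `lag` (used to emulate co-oscillating sources).
#' @param epochs optional matrix/data.frame of `[start, end)` times in
#'   seconds during which the coupling is active; `NULL` = whole record.
#' @return a `coupling_spec` list.
#' @export
coupling_spec <- function(pair, mode = c("envelope", "phase"), band_hz,
                          strength = 0.5, lag = pi / 2, kappa = 20,
                          carrier = c("independent", "locked"),
                          epochs = NULL) {
  mode <- match.arg(mode)
  carrier <- match.arg(carrier)
  pair <- as.integer(pair)
  stopifnot(length(pair) == 2, pair[1] != pair[2], all(pair >= 1))
  if (band_hz < 0.4 || band_hz > 45) stop("band_hz outside [0.4, 45]")
  if (mode == "envelope" && (strength < 0 || strength > 1))
    stop("envelope strength must lie in [0, 1]")
  if (mode == "phase" && kappa < 0) stop("kappa must be non-negative")
  if (!is.null(epochs)) {
    epochs <- as.matrix(epochs)
    stopifnot(ncol(epochs) == 2, all(epochs[, 2] > epochs[, 1]))
  }
  structure(list(pair = sort(pair), mode = mode, band_hz = band_hz,
                 strength = strength, lag = lag, kappa = kappa,
                 carrier = carrier, epochs = epochs),
            class = "coupling_spec")
}

# Overlap check for two specs on the same pair: whole-record specs always
# clash; epoch-limited specs clash when intervals intersect.
specs_conflict <- function(a, b) {
  if (!all(a$pair == b$pair)) return(FALSE)
  if (is.null(a$epochs) || is.null(b$epochs)) return(TRUE)
  for (i in seq_len(nrow(a$epochs)))
    for (j in seq_len(nrow(b$epochs)))
      if (a$epochs[i, 1] < b$epochs[j, 2] && b$epochs[j, 1] < a$epochs[i, 2])
        return(TRUE)
  FALSE
}

# Slowly drifting carrier phase at frequency f: linear phase plus a slow
# random phase modulation (band 0.1-0.5 Hz) to give a realistic linewidth.
drifting_phase <- function(n, fs, f, drift_rad = 0.8) {
  2 * pi * f * seq_len(n) / fs + drift_rad * slow_gaussian(n, fs)
}

# Log-normal slow envelope with unit-ish scale; z is a standard normal
# slow process, sigma the log-sd.
lognormal_envelope <- function(z, sigma = 0.4) exp(sigma * z - sigma^2 / 2)

# Mixing weight on the log scale that yields a target Pearson correlation
# rho between two log-normal envelopes with log-sd sigma.
lognormal_mix_rho <- function(rho, sigma = 0.4) {
  log(1 + rho * (exp(sigma^2) - 1)) / sigma^2
}

#' Simulate parcel source signals with known couplings
#'
#' Generates `n_parcels` source time courses: a 1/f^alpha background with
#' a sigma-band resting bump for uncoupled parcels, and for each
#' [coupling_spec()] an oscillatory pair realizing the requested envelope
#' correlation (shared log-normal slow modulator) or phase coupling
#' (shared carrier with fixed lag plus von Mises jitter).  A pure
#' function of `seed`.
#'
#' @param spec list of [coupling_spec()]s (may be empty).
#' @param n_parcels number of parcels.
#' @param fs sampling rate (Hz), >= 100.
#' @param duration_s record length (s), >= 60.
#' @param seed integer seed.
#' @param alpha background spectral slope (power ~ 1/f^alpha).
#' @param bump_hz,bump_rel centre and relative amplitude of the resting
#'   spectral bump (defaults 12 Hz, mimicking infant N2 sigma activity).
#' @param background_rel RMS of the broadband background mixed into
#'   coupled parcels, relative to their oscillation RMS.
#' @param sigma log-sd of the log-normal envelopes.
#' @return matrix `n_parcels x (fs * duration_s)`, with attribute
#'   `"truth"` (the list of coupling specifications).
#' @export
simulate_parcel_sources <- function(spec = list(), n_parcels, fs, duration_s,
                                    seed = 1, alpha = 1.1, bump_hz = 12,
                                    bump_rel = 0.6, background_rel = 0.25,
                                    sigma = 0.4) {
  if (fs < 100) stop("fs must be >= 100 Hz")
  if (duration_s < 60) stop("duration_s must be >= 60 s")
  if (length(spec)) {
    for (i in seq_along(spec)) {
      if (!inherits(spec[[i]], "coupling_spec")) stop("spec must be coupling_spec objects")
      if (max(spec[[i]]$pair) > n_parcels) stop("parcel index exceeds n_parcels")
      if (i > 1) for (j in seq_len(i - 1))
        if (specs_conflict(spec[[i]], spec[[j]]))
          stop(sprintf("conflicting coupling specs on pair (%d, %d)",
                       spec[[i]]$pair[1], spec[[i]]$pair[2]))
    }
  }
  n <- round(fs * duration_s)
  with_seed(seed, {
    x <- matrix(0, n_parcels, n)
    for (p in seq_len(n_parcels))
      x[p, ] <- colored_noise(n, fs, alpha, bump_hz = bump_hz,
                              bump_rel = bump_rel)
    for (cs in spec) {
      osc <- generate_coupled_pair(cs, n, fs, sigma)
      for (k in 1:2) {
        p <- cs$pair[k]
        x[p, ] <- osc[k, ] + background_rel * x[p, ]
      }
    }
    attr(x, "truth") <- spec
    x
  })
}

# Build the two coupled oscillations for one spec; returns 2 x n matrix.
generate_coupled_pair <- function(cs, n, fs, sigma = 0.4) {
  f <- cs$band_hz
  if (cs$mode == "envelope") {
    rho_z <- lognormal_mix_rho(cs$strength, sigma)
    zm <- slow_gaussian(n, fs)
    z1 <- sqrt(1 - rho_z) * slow_gaussian(n, fs) + sqrt(rho_z) * zm
    z2 <- sqrt(1 - rho_z) * slow_gaussian(n, fs) + sqrt(rho_z) * zm
    e1 <- lognormal_envelope(z1, sigma)
    e2 <- lognormal_envelope(z2, sigma)
    if (cs$carrier == "locked") {
      ph <- drifting_phase(n, fs, f)
      osc <- rbind(e1 * cos(ph), e2 * cos(ph + cs$lag))
    } else {
      osc <- rbind(e1 * cos(drifting_phase(n, fs, f)),
                   e2 * cos(drifting_phase(n, fs, f)))
    }
  } else {
    ph <- drifting_phase(n, fs, f)
    # piecewise-constant von Mises jitter refreshed every 0.5 s, linearly
    # interpolated to sample resolution
    nblk <- max(2, ceiling(n / (0.5 * fs)))
    jit <- rvonmises(nblk, 0, cs$kappa)
    jt <- approx(seq(0, 1, length.out = nblk), jit,
                 xout = seq(0, 1, length.out = n))$y
    e1 <- lognormal_envelope(slow_gaussian(n, fs), sigma)
    e2 <- lognormal_envelope(slow_gaussian(n, fs), sigma)
    osc <- rbind(e1 * cos(ph), e2 * cos(ph + cs$lag + jt))
  }
  if (!is.null(cs$epochs)) {
    # couple only inside epochs; independent oscillation elsewhere,
    # blended over a 20 ms ramp to avoid discontinuities
    mask <- numeric(n)
    for (i in seq_len(nrow(cs$epochs))) {
      a <- max(1, floor(cs$epochs[i, 1] * fs) + 1)
      b <- min(n, ceiling(cs$epochs[i, 2] * fs))
      if (b >= a) mask[a:b] <- 1
    }
    ramp <- max(3, round(0.02 * fs))
    mask <- as.numeric(stats::filter(mask, rep(1 / ramp, ramp), sides = 2))
    mask[is.na(mask)] <- 0
    free <- rbind(
      lognormal_envelope(slow_gaussian(n, fs), sigma) * cos(drifting_phase(n, fs, f)),
      lognormal_envelope(slow_gaussian(n, fs), sigma) * cos(drifting_phase(n, fs, f)))
    osc <- sweep(osc, 2, mask, `*`) + sweep(free, 2, 1 - mask, `*`)
  }
  osc
}

#' Inject sleep spindles into parcel or channel signals
#'
#' Adds waxing-waning sigma-band bursts with raised-cosine envelopes at
#' random non-overlapping times, and returns the exact ground-truth
#' intervals.
#'
#' @param sources channels/parcels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param rate_per_min expected events per minute (Poisson), >= 0.
#' @param freq_hz carrier frequency, in `[11, 15]`.
#' @param duration_s event duration (s), in `[0.5, 3]`.
#' @param amplitude_rel burst amplitude relative to each target channel's
#'   background RMS, > 0.
#' @param channels spatial weight profile: numeric vector (length = rows
#'   of `sources`) or indices of rows carrying the burst.
#' @param seed integer seed.
#' @param at optional vector of fixed event start times (s); overrides
#'   the Poisson placement (`rate_per_min` is then ignored).
#' @param profile integer tag attached to the truth intervals.
#' @return list with `data` (matrix with spindles added) and `truth`
#'   (data.frame `start_s`, `end_s` half-open, `profile`).
#' @export
inject_spindles <- function(sources, fs, rate_per_min, freq_hz = 13,
                            duration_s = 1, amplitude_rel = 3,
                            channels = NULL, seed = 1, profile = 1L,
                            at = NULL) {
  stopifnot(rate_per_min >= 0, amplitude_rel > 0)
  if (freq_hz < 11 || freq_hz > 15) stop("freq_hz outside [11, 15]")
  if (duration_s < 0.5 || duration_s > 3) stop("duration_s outside [0.5, 3]")
  n <- ncol(sources)
  nch <- nrow(sources)
  total_s <- n / fs
  if (duration_s > total_s) stop("spindle duration exceeds record length")
  w <- numeric(nch)
  if (is.null(channels)) w[] <- 1
  else if (length(channels) == nch && !all(channels == floor(channels) & channels >= 1))
    w <- as.numeric(channels)
  else w[as.integer(channels)] <- 1
  truth <- data.frame(start_s = numeric(0), end_s = numeric(0),
                      profile = integer(0))
  if (rate_per_min == 0 && is.null(at))
    return(list(data = sources, truth = truth))
  with_seed(seed, {
    len <- round(duration_s * fs)
    if (is.null(at)) {
      k <- rpois(1, rate_per_min * total_s / 60)
      if (k == 0) return(list(data = sources, truth = truth))
      if (k * len > 0.8 * n)
        stop("spindle rate too high: events cannot be placed without overlap")
      starts <- integer(0)
      tries <- 0
      while (length(starts) < k) {
        cand <- sample.int(n - len, 1)
        if (all(abs(cand - starts) >= len + round(0.1 * fs))) {
          starts <- c(starts, cand)
        }
        tries <- tries + 1
        if (tries > 1000 * k)
          stop("spindle rate too high: events cannot be placed without overlap")
      }
    } else {
      starts <- round(at * fs) + 1L
      if (any(starts < 1) || any(starts + len - 1 > n))
        stop("fixed spindle start times do not fit within the record")
      if (length(starts) > 1 && any(diff(sort(starts)) < len))
        stop("fixed spindle start times overlap")
    }
    starts <- sort(starts)
    rms <- sqrt(rowMeans(sources^2))
    env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))  # raised cosine
    for (s0 in starts) {
      phase <- runif(1, 0, 2 * pi)
      burst <- env * cos(2 * pi * freq_hz * seq_len(len) / fs + phase)
      idx <- s0:(s0 + len - 1)
      for (ch in which(w > 0))
        sources[ch, idx] <- sources[ch, idx] + amplitude_rel * rms[ch] * w[ch] * burst
    }
    truth <- data.frame(start_s = (starts - 1) / fs,
                        end_s = (starts - 1 + len) / fs,
                        profile = as.integer(profile))
    list(data = sources, truth = truth)
  })
}

#' Project parcel sources to sensors through a lead field
#'
#' Maps each parcel's signal to its member dipoles, applies the gain
#' matrix, and adds spatially white sensor noise scaled to a target SNR.
#' `snr_db = Inf` gives a noise-free projection; `snr_db = -Inf` zeroes
#' the signal and returns pure noise with standard deviation `noise_sd`.
#'
#' @param sources parcels x samples matrix (rows must match the bundle's
#'   parcel count).
#' @param bundle a [make_toy_bundle()] (or user-supplied) lead-field
#'   bundle.
#' @param snr_db signal-to-noise ratio in dB (total sensor signal power
#'   over noise power).
#' @param seed integer seed for the sensor noise.
#' @param noise_sd noise standard deviation used when the signal is zero.
#' @return an [eeg_recording()] (sensors x samples) with the bundle's
#'   sensor positions.
#' @export
project_to_sensors <- function(sources, bundle, snr_db = 20, seed = 1,
                               fs = 250, noise_sd = 1) {
  stopifnot(inherits(bundle, "lead_field_bundle"))
  if (nrow(sources) != bundle$n_parcels)
    stop("source matrix rows do not match bundle parcel count")
  sens <- bundle$gain %*% sources[bundle$parcel_map, , drop = FALSE]
  with_seed(seed, {
    if (identical(snr_db, -Inf)) {
      sens <- matrix(rnorm(length(sens), sd = noise_sd), nrow(sens))
    } else if (!identical(snr_db, Inf)) {
      p_sig <- mean(sens^2)
      p_noise <- p_sig / 10^(snr_db / 10)
      sens <- sens + matrix(rnorm(length(sens), sd = sqrt(p_noise)), nrow(sens))
    }
    eeg_recording(sens, fs, ch_names = paste0("E", seq_len(nrow(sens))),
                  positions = bundle$sensor_pos, reference = "original")
  })
}

#' Simulate a cohort of subjects with group-dependent coupling
#'
#' Generates one source matrix per subject in a manifest, with the
#' coupling strength of a designated parcel pair offset per group.  Used
#' to validate that downstream group statistics recover implanted
#' effects.
#'
#' @param manifest data.frame with columns `subject`, and the grouping
#'   column named by `grouping`.
#' @param grouping name of the manifest column holding group labels.
#' @param offsets named numeric vector: additive strength offset per
#'   group label.
#' @param base_strength baseline coupling strength.
#' @param pair,mode,band_hz coupling definition (see [coupling_spec()]).
#' @param carrier carrier convention for envelope-mode cohorts
#'   (`"independent"` keeps the phase channel null; `"locked"` adds a
#'   quarter-cycle carrier lag).
#' @param n_parcels,fs,duration_s generator geometry.
#' @param seed integer seed; subject i uses `seed + i`.
#' @return list with `manifest` (plus `true_strength` column) and
#'   `sources` (named list of parcel source matrices).
#' @export
simulate_cohort <- function(manifest, grouping = "neuro_2y",
                            offsets = c(Typical = 0.2, Mild = 0, Severe = -0.2),
                            base_strength = 0.5, pair = c(1, 2),
                            mode = "envelope", band_hz = 13,
                            carrier = "independent",
                            n_parcels = 4, fs = 250, duration_s = 60,
                            seed = 1) {
  stopifnot(grouping %in% names(manifest), "subject" %in% names(manifest))
  labs <- as.character(manifest[[grouping]])
  if (!all(labs %in% names(offsets))) stop("missing offset for some group label")
  strength <- pmin(0.95, pmax(0.02, base_strength + offsets[labs]))
  sources <- vector("list", nrow(manifest))
  names(sources) <- manifest$subject
  for (i in seq_len(nrow(manifest))) {
    cs <- coupling_spec(pair, mode = mode, band_hz = band_hz,
                        strength = strength[i], carrier = carrier)
    sources[[i]] <- simulate_parcel_sources(list(cs), n_parcels, fs,
                                            duration_s, seed = seed + i)
  }
  manifest$true_strength <- as.numeric(strength)
  list(manifest = manifest, sources = sources)
}

#' Build a cohort manifest with syndrome and outcome labels
#'
#' Assembles a subject manifest with an epilepsy-syndrome label and
#' neurocognitive outcome labels at 1 and 2 years, plus the derived
#' `trajectory` label (`"<1y>-<2y>"`).
#'
#' @param n_per_neuro2 named integer vector of subjects per 2-year
#'   outcome group (`Typical`, `Mild`, `Severe`).
#' @param seed integer seed for the random syndrome / 1-year labels.
#' @return data.frame `subject`, `syndrome`, `neuro_1y`, `neuro_2y`,
#'   `trajectory`.
#' @export
cohort_manifest <- function(n_per_neuro2 = c(Typical = 14, Mild = 10, Severe = 25),
                            seed = 1) {
  syndromes <- c("self-limited", "West", "unclassified focal", "other")
  lv <- c("Typical", "Mild", "Severe")
  with_seed(seed, {
    neuro2 <- rep(names(n_per_neuro2), n_per_neuro2)
    n <- length(neuro2)
    # 1-year label equal to or one step better than the 2-year label
    neuro1 <- vapply(neuro2, function(g) {
      i <- match(g, lv)
      sample(lv[max(1, i - 1):i], 1)
    }, character(1))
    data.frame(subject = sprintf("S%02d", seq_len(n)),
               syndrome = sample(syndromes, n, replace = TRUE,
                                 prob = c(0.25, 0.55, 0.16, 0.04)),
               neuro_1y = neuro1, neuro_2y = neuro2,
               trajectory = paste(neuro1, neuro2, sep = "-"))
  })
}

#' Simulate cohort adjacency matrices with implanted edge effects
#'
#' Direct matrix-level cohort generator: per-subject symmetric adjacency
#' matrices drawn around a common baseline, with an additive offset
#' implanted in a chosen set of edges for one group.  This is the
#' ground-truth fixture for validating edge-wise group statistics and
#' FDR control without re-running the full signal pipeline.
#'
#' @param n_a,n_b subjects per group.
#' @param n_parcels matrix dimension.
#' @param n_effect number of edges receiving the offset in group A.
#' @param effect additive offset on the implanted edges.
#' @param base baseline edge strength.
#' @param noise_sd between-subject standard deviation per edge.
#' @param seed integer seed.
#' @return list with arrays `A`, `B` (`n x p x p`), and `effect_edges`
#'   (two-column matrix of implanted edges, i < j).
#' @export
simulate_cohort_matrices <- function(n_a = 15, n_b = 15, n_parcels = 58,
                                     n_effect = 100, effect = 0.3,
                                     base = 0.2, noise_sd = 0.1, seed = 1) {
  p <- n_parcels
  pairs <- which(upper.tri(matrix(0, p, p)), arr.ind = TRUE)
  if (n_effect > nrow(pairs)) stop("n_effect exceeds number of edges")
  with_seed(seed, {
    eff_idx <- if (n_effect > 0) sample.int(nrow(pairs), n_effect) else integer(0)
    make_group <- function(nsub, offset_edges) {
      arr <- array(NA_real_, c(nsub, p, p))
      for (s in seq_len(nsub)) {
        v <- base + rnorm(nrow(pairs), sd = noise_sd)
        if (length(offset_edges)) v[offset_edges] <- v[offset_edges] + effect
        m <- matrix(NA_real_, p, p)
        m[pairs] <- v
        m[pairs[, c(2, 1)]] <- v
        arr[s, , ] <- m
      }
      arr
    }
    list(A = make_group(n_a, eff_idx), B = make_group(n_b, integer(0)),
         effect_edges = pairs[eff_idx, , drop = FALSE])
  })
}
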