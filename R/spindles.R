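# Sleep-spindle detection (per-channel envelope detector + cross-channel
# power gate), spindle-group metrics, and spindle excision.

#' Spindle detector parameters
#'
#' @param band_lo,band_hi spindle band corners (Hz), default 11-15.
#' @param k_upper event threshold as a multiple of the channel mean
#'   envelope.
#' @param k_lower extension threshold (events extend until the envelope
#'   falls below `k_lower` times the mean).
#' @param min_dur_s,max_dur_s duration gates (s).
#' @param smooth_s envelope smoothing (moving average) length (s).
#' @param theta cross-channel gate: a candidate is kept when the summed
#'   spindle-band power envelope within it peaks above `theta` times the
#'   mean of all candidates' peaks; `0` disables the gate.
#' @return list of parameters.
#' @export
spindle_params <- function(band_lo = 11, band_hi = 15, k_upper = 3,
                           k_lower = 1.5, min_dur_s = 0.5, max_dur_s = 3,
                           smooth_s = 0.1, theta = 0.5) {
  list(band_lo = band_lo, band_hi = band_hi, k_upper = k_upper,
       k_lower = k_lower, min_dur_s = min_dur_s, max_dur_s = max_dur_s,
       smooth_s = smooth_s, theta = theta)
}

# Spindle-band Kaiser band-pass for detection (stop edges 2 Hz outside
# the passband, 40 dB).
spindle_band_filter <- function(params, fs) {
  band <- list(fc = (params$band_lo + params$band_hi) / 2,
               pass_lo = params$band_lo, pass_hi = params$band_hi,
               stop_lo = params$band_lo - 2, stop_hi = params$band_hi + 2,
               attenuation_db = 40)
  design_kaiser_bandpass(band, fs)
}

# Smoothed amplitude envelope of one band-filtered channel.
smooth_envelope <- function(x, fs, smooth_s) {
  env <- Mod(analytic_vector(x))
  k <- max(1, round(smooth_s * fs))
  as.numeric(stats::filter(env, rep(1 / k, k), sides = 2, circular = TRUE))
}

# Threshold-crossing intervals: above k_upper * mean, extended to where
# the envelope falls below k_lower * mean; duration-gated.
envelope_events <- function(env, fs, k_upper, k_lower, min_dur_s, max_dur_s) {
  m <- mean(env)
  hi <- env >= k_upper * m
  lo <- env >= k_lower * m
  if (!any(hi)) return(data.frame(start_s = numeric(0), end_s = numeric(0),
                                  peak = numeric(0)))
  # runs of the extension mask that contain at least one upper crossing
  r <- rle(lo)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  out <- list()
  for (k in keep) {
    idx <- starts[k]:ends[k]
    if (!any(hi[idx])) next
    dur <- length(idx) / fs
    if (dur < min_dur_s || dur > max_dur_s) next
    out[[length(out) + 1]] <- c(starts[k], ends[k], max(env[idx]))
  }
  if (length(out) == 0) return(data.frame(start_s = numeric(0),
                                          end_s = numeric(0),
                                          peak = numeric(0)))
  m2 <- do.call(rbind, out)
  data.frame(start_s = (m2[, 1] - 1) / fs, end_s = m2[, 2] / fs,
             peak = m2[, 3])
}

#' Per-channel spindle detection
#'
#' Band-passes one channel to the spindle band, forms the rectified
#' smoothed amplitude envelope, and flags events where the envelope
#' exceeds `k_upper` times the channel mean envelope, extended to where
#' it falls below `k_lower` times the mean, keeping durations within
#' `[min_dur_s, max_dur_s]`.
#'
#' @param x single-channel broadband signal (numeric vector).
#' @param fs sampling rate (Hz); records shorter than 30 s are rejected
#'   (baseline unstable).
#' @param params [spindle_params()].
#' @return data.frame `start_s`, `end_s` (half-open), `peak`.
#' @export
detect_spindles_channel <- function(x, fs, params = spindle_params()) {
  if (length(x) / fs < 30) stop("record shorter than 30 s: baseline unstable")
  h <- spindle_band_filter(params, fs)
  xb <- fft_filter(x, h)
  env <- smooth_envelope(xb, fs, params$smooth_s)
  envelope_events(env, fs, params$k_upper, params$k_lower,
                  params$min_dur_s, params$max_dur_s)
}

#' Gate candidate spindles by summed cross-channel power
#'
#' Computes the summed spindle-band power envelope over all channels and
#' retains a candidate interval only if that summed envelope peaks,
#' within the interval, above `theta` times the mean of the per-candidate
#' peak amplitudes (computed once per recording).  `theta = 0` retains
#' all candidates.
#'
#' @param detections named list (per channel) of per-channel detection
#'   data.frames from [detect_spindles_channel()].
#' @param band_signals channels x samples matrix already filtered to the
#'   spindle band (or broadband; filtered internally when
#'   `filtered = FALSE`).
#' @param fs sampling rate (Hz).
#' @param params [spindle_params()].
#' @param filtered set `TRUE` when `band_signals` is already in the
#'   spindle band.
#' @return a `spindle_annotations` object: `channel` (per-channel
#'   detections, gated), `global` (merged gated intervals:
#'   `start_s`, `end_s`, `peak_power`), `params`.
#' @export
gate_by_global_power <- function(detections, band_signals, fs,
                                 params = spindle_params(),
                                 filtered = FALSE) {
  if (!filtered) {
    h <- spindle_band_filter(params, fs)
    band_signals <- fft_filter_rows(as.matrix(band_signals), h)
  }
  env2 <- matrix(0, nrow(band_signals), ncol(band_signals))
  for (ch in seq_len(nrow(band_signals)))
    env2[ch, ] <- smooth_envelope(band_signals[ch, ], fs, params$smooth_s)^2
  power_sum <- colSums(env2)           # summed spindle power envelope
  cand <- do.call(rbind, lapply(detections, function(d)
    d[, c("start_s", "end_s"), drop = FALSE]))
  ann <- structure(list(channel = detections,
                        global = data.frame(start_s = numeric(0),
                                            end_s = numeric(0),
                                            peak_power = numeric(0)),
                        params = params),
                   class = "spindle_annotations")
  if (is.null(cand) || nrow(cand) == 0) return(ann)
  # merge overlapping candidates into unique segments
  merged <- merge_intervals(cand, gap_s = 0)
  peaks <- vapply(seq_len(nrow(merged)), function(i) {
    a <- max(1, floor(merged$start_s[i] * fs) + 1)
    b <- min(length(power_sum), ceiling(merged$end_s[i] * fs))
    max(power_sum[a:b])
  }, numeric(1))
  thr <- params$theta * mean(peaks)
  keep <- peaks >= thr
  merged <- merged[keep, , drop = FALSE]
  merged$peak_power <- peaks[keep]
  # drop per-channel detections not inside any retained global interval
  gated_channel <- lapply(detections, function(d) {
    if (nrow(d) == 0 || nrow(merged) == 0) return(d[0, , drop = FALSE])
    inside <- vapply(seq_len(nrow(d)), function(i)
      any(d$start_s[i] < merged$end_s & merged$start_s < d$end_s[i]),
      logical(1))
    d[inside, , drop = FALSE]
  })
  ann$channel <- gated_channel
  ann$global <- merged
  ann
}

# Merge sorted [start, end) intervals whose gaps are <= gap_s.
merge_intervals <- function(iv, gap_s = 0) {
  if (nrow(iv) == 0) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  iv <- iv[order(iv$start_s), , drop = FALSE]
  out_s <- iv$start_s[1]; out_e <- iv$end_s[1]
  res <- list()
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv$start_s[i] - tail(out_e, 1) <= gap_s) {
      out_e[length(out_e)] <- max(tail(out_e, 1), iv$end_s[i])
    } else {
      out_s <- c(out_s, iv$start_s[i]); out_e <- c(out_e, iv$end_s[i])
    }
  }
  data.frame(start_s = out_s, end_s = out_e)
}

#' Detect spindles on a multichannel recording
#'
#' Convenience wrapper: runs [detect_spindles_channel()] on every
#' channel and gates the candidates with [gate_by_global_power()].
#'
#' @param rec an [eeg_recording()] (broadband, 250 Hz typical).
#' @param params [spindle_params()].
#' @return a `spindle_annotations` object.
#' @export
detect_spindles <- function(rec, params = spindle_params()) {
  stopifnot(inherits(rec, "eeg_recording"))
  det <- setNames(lapply(seq_len(nrow(rec$data)), function(ch)
    detect_spindles_channel(rec$data[ch, ], rec$fs, params)),
    rec$ch_names)
  gate_by_global_power(det, rec$data, rec$fs, params)
}

#' @export
print.spindle_annotations <- function(x, ...) {
  cat(sprintf("<spindle_annotations> %d gated events, %d channel-level detections\n",
              nrow(x$global), sum(vapply(x$channel, nrow, integer(1)))))
  invisible(x)
}

#' Spindle-group metrics
#'
#' Merges gated spindle intervals whose gaps are at most `gap_s` into
#' spindle groups and summarizes rates, group durations, and the number
#' of channel-level detections falling inside each group span.
#'
#' @param ann a `spindle_annotations` object.
#' @param duration_s analysed record duration (s), for the per-minute
#'   rates.
#' @param gap_s maximum within-group gap (s), > 0.
#' @return list: `spindles_per_min`, `groups_per_min`,
#'   `group_duration_s` (`mean`, `sd`), `spindles_per_group`
#'   (`mean`, `sd`), and `groups` (the merged intervals).
#' @export
group_spindles <- function(ann, duration_s, gap_s = 1.0) {
  stopifnot(inherits(ann, "spindle_annotations"), gap_s > 0)
  g <- ann$global
  groups <- merge_intervals(g[, c("start_s", "end_s"), drop = FALSE], gap_s)
  chdet <- do.call(rbind, lapply(ann$channel, function(d)
    d[, c("start_s", "end_s"), drop = FALSE]))
  per_group <- if (nrow(groups)) vapply(seq_len(nrow(groups)), function(i) {
    if (is.null(chdet) || nrow(chdet) == 0) return(0)
    sum(chdet$start_s < groups$end_s[i] & groups$start_s[i] < chdet$end_s)
  }, numeric(1)) else numeric(0)
  durs <- groups$end_s - groups$start_s
  list(spindles_per_min = nrow(g) / (duration_s / 60),
       groups_per_min = nrow(groups) / (duration_s / 60),
       group_duration_s = c(mean = if (length(durs)) mean(durs) else 0,
                            sd = if (length(durs) > 1) sd(durs) else 0),
       spindles_per_group = c(mean = if (length(per_group)) mean(per_group) else 0,
                              sd = if (length(per_group) > 1) sd(per_group) else 0),
       groups = groups)
}

#' Excise spindle intervals from a recording
#'
#' Removes the gated spindle intervals (padded by `pad_s` on each side)
#' from the record and re-segments the remaining data, so that
#' downstream filtering and windowed metrics never span a cut.  If less
#' than 3 minutes of data remain, the output carries attribute
#' `"short_record" = TRUE` (inclusion floor).
#'
#' @param rec an [eeg_recording()].
#' @param ann a `spindle_annotations` object on this recording's
#'   timeline.
#' @param pad_s padding excised around each interval (s).
#' @return [eeg_recording()] with spindle epochs removed.
#' @export
remove_spindles <- function(rec, ann, pad_s = 0.25) {
  stopifnot(inherits(rec, "eeg_recording"),
            inherits(ann, "spindle_annotations"))
  g <- ann$global
  if (nrow(g) == 0) return(rec)
  n <- ncol(rec$data)
  if (max(g$end_s) * rec$fs > n + 1)
    stop("annotations extend beyond this recording")
  cut <- merge_intervals(data.frame(start_s = pmax(0, g$start_s - pad_s),
                                    end_s = g$end_s + pad_s), gap_s = 0)
  keep_mask <- rep(TRUE, n)
  for (i in seq_len(nrow(cut))) {
    a <- max(1, floor(cut$start_s[i] * rec$fs) + 1)
    b <- min(n, ceiling(cut$end_s[i] * rec$fs))
    keep_mask[a:b] <- FALSE
  }
  # intersect retained samples with existing segments
  pieces <- list(); lens <- integer(0)
  for (i in seq_len(nrow(rec$segments))) {
    idx <- rec$segments[i, 1]:rec$segments[i, 2]
    m <- keep_mask[idx]
    r <- rle(m)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      pieces[[length(pieces) + 1]] <- rec$data[, idx[starts[k]:ends[k]],
                                               drop = FALSE]
      lens <- c(lens, ends[k] - starts[k] + 1L)
    }
  }
  if (length(pieces) == 0) stop("spindle removal left no data")
  ends <- cumsum(lens)
  out <- eeg_recording(do.call(cbind, pieces), rec$fs,
                       ch_names = rec$ch_names, positions = rec$positions,
                       reference = rec$reference, bad = rec$bad,
                       segments = cbind(c(1L, head(ends, -1) + 1L), ends))
  if (segment_duration(out) < 180) {
    warning("less than 3 minutes of data remain after spindle removal")
    attr(out, "short_record") <- TRUE
  }
  out
}
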