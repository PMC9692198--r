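# Shared fixtures: ladder rows, band-filtered analytic signals, interval
# overlap helpers.  All fixtures are generated in code at test time.

the_ladder <- design_band_ladder(0.5, 1.2, 25)

ladder_band <- function(fc_target) {
  the_ladder[which.min(abs(the_ladder$fc - fc_target)), , drop = FALSE]
}

# analytic signal of x band-filtered to the ladder band nearest fc.
band_analytic <- function(x, fs, fc_target) {
  h <- design_kaiser_bandpass(ladder_band(fc_target), fs)
  cortnet:::analytic_vector(cortnet:::fft_filter(x, h))
}

intervals_overlap <- function(a_start, a_end, b_start, b_end) {
  a_start < b_end & b_start < a_end
}

# fraction of rows in `truth` hit by any interval in `det`, and vice versa
interval_recall <- function(truth, det) {
  if (nrow(truth) == 0) return(NA_real_)
  mean(vapply(seq_len(nrow(truth)), function(i)
    any(intervals_overlap(det$start_s, det$end_s,
                          truth$start_s[i], truth$end_s[i])), logical(1)))
}
interval_precision <- function(truth, det) {
  if (nrow(det) == 0) return(NA_real_)
  mean(vapply(seq_len(nrow(det)), function(i)
    any(intervals_overlap(truth$start_s, truth$end_s,
                          det$start_s[i], det$end_s[i])), logical(1)))
}

# Kruskal-Wallis H statistic (tie-free data), for permutation oracles.
kw_H <- function(x, g) {
  r <- rank(x); N <- length(x)
  12 / (N * (N + 1)) *
    sum(tapply(r, g, function(v) length(v) * mean(v)^2)) - 3 * (N + 1)
}
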