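#' EEG recording container
#'
#' Lightweight S3 container for a multichannel EEG record: a channels x
#' samples matrix in microvolts, the sampling rate, channel names, 3-D
#' montage positions on a unit sphere, a reference tag, a bad-channel
#' list, and segment boundaries.  Segments delimit continuous stretches of
#' data (discontinuous N2 epochs after visual staging or after spindle
#' excision); filtering and windowed metrics never cross a segment
#' boundary.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param ch_names character vector of channel names (defaults to
#'   `"ch1"..`).
#' @param positions optional n_channels x 3 matrix of electrode positions;
#'   normalized onto the unit sphere.
#' @param reference reference tag, e.g. `"original"` or `"average"`.
#' @param bad character vector of bad channel names.
#' @param segments two-column matrix or data.frame of segment start/end
#'   sample indices (1-based, inclusive); defaults to one segment spanning
#'   the record.  Must be sorted and non-overlapping.
#'
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, ch_names = NULL, positions = NULL,
                          reference = "original", bad = character(),
                          segments = NULL) {
  data <- as.matrix(data)
  if (any(!is.finite(data))) stop("recording data contains non-finite values")
  if (fs <= 0) stop("sampling rate must be positive")
  nch <- nrow(data)
  ch_names <- ch_names %||% paste0("ch", seq_len(nch))
  if (length(ch_names) != nch) stop("ch_names length does not match data")
  if (!is.null(positions)) {
    positions <- as.matrix(positions)
    if (nrow(positions) != nch || ncol(positions) != 3)
      stop("positions must be n_channels x 3")
    positions <- positions / sqrt(rowSums(positions^2))
  }
  if (is.null(segments)) segments <- cbind(1L, ncol(data))
  segments <- matrix(as.integer(as.matrix(segments)), ncol = 2)
  if (any(segments[, 1] > segments[, 2]) ||
      any(segments < 1) || any(segments > ncol(data)))
    stop("invalid segment boundaries")
  if (nrow(segments) > 1) {
    o <- order(segments[, 1])
    segments <- segments[o, , drop = FALSE]
    if (any(segments[-1, 1] <= segments[-nrow(segments), 2]))
      stop("segments overlap")
  }
  structure(list(data = data, fs = fs, ch_names = ch_names,
                 positions = positions, reference = reference,
                 bad = bad, segments = segments),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s, %d segment%s, ref: %s)\n",
    nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
    nrow(x$segments), if (nrow(x$segments) == 1) "" else "s", x$reference))
  if (length(x$bad)) cat("  bad channels:", paste(x$bad, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

# List of sample-index vectors, one per segment.
segment_indices <- function(rec) {
  lapply(seq_len(nrow(rec$segments)),
         function(i) seq.int(rec$segments[i, 1], rec$segments[i, 2]))
}

# Total retained duration in seconds (sum over segments).
segment_duration <- function(rec) {
  sum(rec$segments[, 2] - rec$segments[, 1] + 1) / rec$fs
}
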