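# Minimal European Data Format (EDF) reader/writer for continuous
# multichannel recordings: fixed 256-byte ASCII header + 256 bytes per
# signal, then 16-bit little-endian data records with physical scaling.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Stores the recording as 16-bit EDF with physical units in microvolts
#' and one-second data records.  Multi-segment recordings are written as
#' concatenated data (EDF has no gap encoding); segment boundaries go to
#' a JSON sidecar when `sidecar = TRUE`.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @param sidecar write `<path>.segments.json` with segment boundaries.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path, sidecar = nrow(rec$segments) > 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  ns <- nrow(rec$data)
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9) stop("EDF export needs an integer sampling rate")
  fs <- as.integer(round(fs))
  spr <- fs                         # samples per record (1 s records)
  n_rec <- floor(ncol(rec$data) / spr)
  if (n_rec < 1) stop("recording shorter than one EDF data record")
  data <- rec$data[, seq_len(n_rec * spr), drop = FALSE]
  pmin_ <- apply(data, 1, min); pmax_ <- apply(data, 1, max)
  flat <- pmax_ - pmin_ < 1e-9
  pmax_[flat] <- pmin_[flat] + 1
  dmin <- -32768L; dmax <- 32767L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad("X X X X", 80), edf_pad("X X X", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (1 + ns), 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    vapply(rec$ch_names, edf_pad, "", width = 16),
    rep(edf_pad("AgAgCl electrode", 80), ns),
    rep(edf_pad("uV", 8), ns),
    vapply(sprintf("%.8g", pmin_), edf_pad, "", width = 8),
    vapply(sprintf("%.8g", pmax_), edf_pad, "", width = 8),
    rep(edf_pad(dmin, 8), ns), rep(edf_pad(dmax, 8), ns),
    rep(edf_pad("", 80), ns), rep(edf_pad(spr, 8), ns),
    rep(edf_pad("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  gain <- (dmax - dmin) / (pmax_ - pmin_)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- round((data[ch, idx] - pmin_[ch]) * gain[ch]) + dmin
      writeBin(as.integer(pmin(pmax(dig, dmin), dmax)), con, size = 2,
               endian = "little")
    }
  }
  if (sidecar) {
    jsonlite::write_json(
      list(fs = fs, segments = rec$segments,
           reference = rec$reference),
      paste0(path, ".segments.json"), auto_unbox = TRUE)
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Reads a continuous 16-bit EDF recording back into an
#' [eeg_recording()] (physical units honoured).  A
#' `<path>.segments.json` sidecar written by [write_edf()] restores
#' segment boundaries.
#'
#' @param path EDF file path.
#' @return an [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(nch) {
    out <- readChar(con, nch, useBytes = TRUE)
    if (nchar(out, type = "bytes") < nch)
      stop(sprintf("corrupt EDF '%s': truncated header near byte offset %d",
                   path, seek(con)))
    trimws(out)
  }
  rd(8)                      # version
  rd(80); rd(80); rd(8); rd(8)
  as.integer(rd(8))          # header bytes
  rd(44)
  n_rec <- as.integer(rd(8))
  dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec) || n_rec < 1)
    stop(sprintf("corrupt EDF '%s': invalid header counts at byte offset 236", path))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)       # transducer
  for (i in seq_len(ns)) rd(8)        # units
  pmin_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  pmax_ <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmin <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  dmax <- vapply(seq_len(ns), function(i) as.numeric(rd(8)), 0)
  for (i in seq_len(ns)) rd(80)       # prefiltering
  spr <- vapply(seq_len(ns), function(i) as.integer(rd(8)), 0L)
  for (i in seq_len(ns)) rd(32)
  if (length(unique(spr)) != 1)
    stop("mixed per-signal sampling rates are not supported")
  fs <- spr[1] / dur
  gain <- (pmax_ - pmin_) / (dmax - dmin)
  data <- matrix(0, ns, n_rec * spr[1])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(ns)) {
      raw <- readBin(con, integer(), n = spr[ch], size = 2, endian = "little",
                     signed = TRUE)
      if (length(raw) < spr[ch])
        stop(sprintf("corrupt EDF '%s': truncated data record %d (byte offset %d)",
                     path, r, seek(con)))
      data[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <-
        (raw - dmin[ch]) * gain[ch] + pmin_[ch]
    }
  }
  segments <- NULL
  sc <- paste0(path, ".segments.json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    segments <- matrix(as.integer(meta$segments), ncol = 2)
  }
  eeg_recording(data, fs, ch_names = labels, segments = segments)
}
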