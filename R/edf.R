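# Minimal EDF (European Data Format, 16-bit) reader/writer. Supports the
# standard header, one fixed sampling rate per file and integer-second data
# records -- enough to round-trip referential neonatal recordings.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = width, flag = "-")
}

#' Write a recording to an EDF file
#'
#' Serialises a referential [recording] as 16-bit EDF with one-second data
#' records. The sampling rate must be a positive integer; a trailing partial
#' second is dropped. Amplitudes are quantised per channel over a symmetric
#' physical range covering the data, so the round-trip error is below one
#' part in 2^15 of the channel's peak amplitude.
#'
#' @param rec a [recording].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (fs != round(fs) || fs <= 0) {
    stop_value("EDF writer requires a positive integer sampling rate, got %s", fs)
  }
  fs <- as.integer(fs)
  ns <- nrow(rec$data)
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1L) stop_value("recording shorter than one data record (1 s)")

  pmax_ch <- pmax(apply(abs(rec$data[, seq_len(n_rec * fs), drop = FALSE]), 1L, max), 1e-6)
  dmin <- -32767L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr_bytes <- 256L + 256L * ns
  header <- paste0(
    edf_pad("0", 8), edf_pad(rec$subject_id %||% "X", 80),
    edf_pad("Startdate 01-JAN-2020", 80),
    edf_pad("01.01.20", 8), edf_pad("00.00.00", 8),
    edf_pad(hdr_bytes, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  fld <- function(vals, width) paste(vapply(vals, edf_pad, "", width = width), collapse = "")
  header <- paste0(
    header,
    fld(rec$labels, 16), fld(rep("", ns), 80), fld(rep("uV", ns), 8),
    fld(sprintf("%.6g", -pmax_ch), 8), fld(sprintf("%.6g", pmax_ch), 8),
    fld(rep(dmin, ns), 8), fld(rep(dmax, ns), 8),
    fld(rep("", ns), 80), fld(rep(fs, ns), 8), fld(rep("", ns), 32))
  writeBin(charToRaw(header), con)

  scale <- (2 * pmax_ch) / (dmax - dmin)
  dig <- round(sweep(rec$data[, seq_len(n_rec * fs), drop = FALSE], 1L, scale, "/"))
  dig <- pmin(pmax(dig, dmin), dmax)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    block <- as.integer(t(dig[, idx, drop = FALSE]))
    writeBin(block, con, size = 2L, endian = "little")
  }
  invisible(path)
}

# Parse the EDF header and signal table of `path`.
read_edf_header <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) rawToChar(readBin(con, "raw", n))
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  version <- trimws(rd(8))
  patient <- trimws(rd(80)); recording <- trimws(rd(80))
  rd(16)                                  # start date + time
  hdr_bytes <- num(rd(8)); rd(44)
  n_rec <- num(rd(8)); rec_dur <- num(rd(8)); ns <- num(rd(4))
  if (is.na(ns) || ns < 1 || is.na(n_rec)) stop_parse("malformed EDF header in %s", path)
  sfield <- function(w) vapply(seq_len(ns), function(i) trimws(rd(w)), "")
  labels <- sfield(16); sfield(80)
  dim_ <- sfield(8)
  pmin <- as.numeric(sfield(8)); pmax <- as.numeric(sfield(8))
  dmin <- as.numeric(sfield(8)); dmax <- as.numeric(sfield(8))
  sfield(80)
  nsamp <- as.numeric(sfield(8)); sfield(32)
  if (anyNA(c(pmin, pmax, dmin, dmax, nsamp))) stop_parse("malformed EDF signal table in %s", path)
  list(version = version, patient = patient, recording = recording,
       header_bytes = hdr_bytes, n_records = n_rec, record_dur = rec_dur,
       ns = ns, labels = labels, dim = dim_, pmin = pmin, pmax = pmax,
       dmin = dmin, dmax = dmax, nsamp = nsamp)
}

# Raw EDF payload as channels x samples matrix in physical units.
read_edf_data <- function(path, hdr) {
  con <- file(path, "rb")
  on.exit(close(con))
  seek(con, hdr$header_bytes)
  per_rec <- sum(hdr$nsamp)
  total <- per_rec * hdr$n_records
  raw <- readBin(con, "integer", n = total, size = 2L, endian = "little")
  if (length(raw) < total) stop_parse("EDF file %s truncated", path)
  out <- matrix(NA_real_, nrow = hdr$ns, ncol = 0)
  scale <- (hdr$pmax - hdr$pmin) / (hdr$dmax - hdr$dmin)
  chans <- vector("list", hdr$ns)
  offs <- c(0, cumsum(hdr$nsamp))
  for (s in seq_len(hdr$ns)) {
    idx <- as.vector(outer(seq_len(hdr$nsamp[s]), (seq_len(hdr$n_records) - 1L) * per_rec, "+") + offs[s])
    chans[[s]] <- (raw[idx] - hdr$dmin[s]) * scale[s] + hdr$pmin[s]
  }
  n <- min(lengths(chans))
  out <- do.call(rbind, lapply(chans, function(x) x[seq_len(n)]))
  rownames(out) <- hdr$labels
  out
}
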