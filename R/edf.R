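#' Read a 16-bit EDF file
#'
#' A compact reader for the European Data Format: fixed-layout ASCII header
#' (256 bytes plus 256 per signal) followed by data records of little-endian
#' 16-bit integers, mapped to physical units per channel by the header's
#' physical/digital ranges. All signals must share one sampling rate;
#' annotation channels are not supported.
#'
#' @param path EDF file path.
#' @param subject_id,group optional provenance for the result.
#' @return An `"eeg_recording"` in the file's physical units.
#' @export
read_edf <- function(path, subject_id = NA_character_,
                     group = NA_character_) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readChar(con, 256L, useBytes = TRUE)
  if (nchar(hdr, type = "bytes") < 256L)
    stop_eegms("truncated EDF header", "eegms_parse_error")
  fld <- function(s, from, len) substr(s, from, from + len - 1L)
  num <- function(x, what) {
    v <- suppressWarnings(as.numeric(trimws(x)))
    if (anyNA(v)) stop_eegms(sprintf("EDF header field '%s' is not numeric",
                                     what), "eegms_parse_error")
    v
  }
  n_records <- num(fld(hdr, 237, 8), "number of records")
  rec_dur <- num(fld(hdr, 245, 8), "record duration")
  ns <- as.integer(num(fld(hdr, 253, 4), "number of signals"))
  if (ns < 1L) stop_eegms("EDF file declares no signals", "eegms_parse_error")
  sig_hdr <- readChar(con, 256L * ns, useBytes = TRUE)
  if (nchar(sig_hdr, type = "bytes") < 256L * ns)
    stop_eegms("truncated EDF signal header", "eegms_parse_error")
  # per-field blocks are stored contiguously across signals
  take <- function(offset, len)
    vapply(seq_len(ns), function(i)
      substr(sig_hdr, offset + (i - 1L) * len + 1L,
             offset + i * len), "")
  labels <- trimws(take(0L, 16L))
  phys_min <- num(take(ns * (16L + 80L + 8L), 8L), "physical minimum")
  phys_max <- num(take(ns * (16L + 80L + 8L) + ns * 8L, 8L),
                  "physical maximum")
  dig_min <- num(take(ns * (16L + 80L + 8L + 8L + 8L), 8L), "digital minimum")
  dig_max <- num(take(ns * (16L + 80L + 8L + 8L + 8L) + ns * 8L, 8L),
                 "digital maximum")
  spr <- as.integer(num(take(ns * (16L + 80L + 8L + 8L + 8L + 8L + 8L + 80L),
                             8L), "samples per record"))
  if (length(unique(spr)) != 1L)
    stop_eegms("EDF signals with differing sampling rates are not supported",
               "eegms_parse_error")
  if (rec_dur <= 0)
    stop_eegms("EDF header field 'record duration' must be positive",
               "eegms_parse_error")
  fs <- spr[1L] / rec_dur
  data <- matrix(NA_real_, ns, spr[1L] * n_records)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      raw <- readBin(con, "integer", n = spr[s], size = 2L, signed = TRUE,
                     endian = "little")
      if (length(raw) < spr[s])
        stop_eegms("truncated EDF data record", "eegms_parse_error")
      data[s, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        (raw - dig_min[s]) * scale[s] + phys_min[s]
    }
  }
  recording(data, fs, labels, subject_id = subject_id, group = group)
}

#' Write a 16-bit EDF file
#'
#' Companion writer to [read_edf()], mainly for fixtures and interchange.
#' Data are quantized to the 16-bit digital range over each channel's
#' physical range, in records of one second; a trailing remainder shorter
#' than one record is dropped.
#'
#' @param rec an `"eeg_recording"`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  x <- rec$data
  ns <- nrow(x)
  fs <- rec$sampling_rate
  if (fs != round(fs))
    stop_eegms("write_edf needs an integer sampling rate",
               "eegms_invalid_config")
  spr <- as.integer(fs)
  n_records <- ncol(x) %/% spr
  if (n_records < 1L)
    stop_eegms("recording shorter than one 1-s EDF record",
               "eegms_invalid_input")
  phys_max <- apply(abs(x), 1L, max)
  phys_max[phys_max == 0] <- 1
  phys_min <- -phys_max
  dig_min <- -32768; dig_max <- 32767
  pad <- function(v, w) formatC(as.character(v), width = w, flag = "-")
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(paste0(
    pad("0", 8), pad("X", 80), pad("eegms", 80), pad("01.01.00", 8),
    pad("00.00.00", 8), pad(256L * (1L + ns), 8), pad("", 44),
    pad(n_records, 8), pad("1", 8), pad(ns, 4)), con, eos = NULL)
  fmt8 <- function(v) vapply(v, function(x) {
    for (d in 7:1) {            # shrink precision until it fits 8 bytes
      s <- formatC(x, format = "g", digits = d)
      if (nchar(s) <= 8L) return(formatC(s, width = 8L, flag = "-"))
    }
    stop_eegms("physical range not representable in an 8-byte EDF field",
               "eegms_invalid_input")
  }, "")
  writeChar(paste0(
    paste(pad(rec$channel_names, 16), collapse = ""),
    paste(pad(rep("", ns), 80), collapse = ""),
    paste(pad(rep("uV", ns), 8), collapse = ""),
    paste(fmt8(phys_min), collapse = ""),
    paste(fmt8(phys_max), collapse = ""),
    paste(pad(rep(dig_min, ns), 8), collapse = ""),
    paste(pad(rep(dig_max, ns), 8), collapse = ""),
    paste(pad(rep("", ns), 80), collapse = ""),
    paste(pad(rep(spr, ns), 8), collapse = ""),
    paste(pad(rep("", ns), 32), collapse = "")), con, eos = NULL)
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    cols <- ((r - 1L) * spr + 1L):(r * spr)
    for (s in seq_len(ns)) {
      dig <- round((x[s, cols] - phys_min[s]) / scale[s]) + dig_min
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con, size = 2L,
               endian = "little")
    }
  }
  invisible(path)
}
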