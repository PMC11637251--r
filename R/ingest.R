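#' Construct an EEG recording
#'
#' A light container for one continuous multichannel recording: a
#' channels x samples potential matrix in microvolts plus metadata.
#'
#' @param data channels x samples numeric matrix (µV).
#' @param sampling_rate sampling rate in Hz.
#' @param channel_names character vector, one name per row of `data`.
#' @param subject_id,group optional provenance.
#' @return An object of class `"eeg_recording"`.
#' @export
recording <- function(data, sampling_rate, channel_names = NULL,
                      subject_id = NA_character_, group = NA_character_) {
  data <- as.matrix(data)
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_eegms("sampling_rate must be positive", "eegms_invalid_config")
  if (is.null(channel_names))
    channel_names <- default_channel_names(nrow(data))
  if (nrow(data) < 2L)
    stop_eegms("a recording needs at least 2 channels", "eegms_invalid_input")
  if (length(channel_names) != nrow(data))
    stop_eegms("channel_names length must match rows of data",
               "eegms_invalid_input")
  structure(list(data = data, sampling_rate = sampling_rate,
                 channel_names = channel_names, subject_id = subject_id,
                 group = group), class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$sampling_rate,
              ncol(x$data) / x$sampling_rate))
  if (!is.na(x$subject_id))
    cat(sprintf("  subject %s, group %s\n", x$subject_id, x$group))
  invisible(x)
}

#' Read a recording from EDF or the CSV channel-matrix dialect
#'
#' CSV dialect: a required header comment `# sampling_rate: <Hz>`, then one
#' row per channel with the channel name in the first column and samples in
#' the remaining columns. EDF files are read with the built-in 16-bit EDF
#' reader ([read_edf()]).
#'
#' @param path file path; the format is taken from the extension unless
#'   `format` is given.
#' @param format `"auto"`, `"edf"` or `"csv"`.
#' @param subject_id,group optional provenance attached to the result.
#' @return An `"eeg_recording"`.
#' @export
read_recording <- function(path, format = c("auto", "edf", "csv"),
                           subject_id = NA_character_,
                           group = NA_character_) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path))
    stop_eegms(sprintf("file not found: %s", path), "eegms_parse_error")
  if (format == "edf") return(read_edf(path, subject_id = subject_id,
                                       group = group))
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  m <- regmatches(hdr, regexpr("sampling_rate:\\s*[0-9.eE+-]+", hdr))
  if (!length(m))
    stop_eegms("CSV dialect requires a '# sampling_rate: <Hz>' header line",
               "eegms_invalid_config")
  fs <- as.numeric(sub("sampling_rate:\\s*", "", m[[1]]))
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(body) < 2L)
    stop_eegms("CSV epoch file holds fewer than 2 channel rows",
               "eegms_parse_error")
  parts <- strsplit(body, ",", fixed = TRUE)
  nc <- length(parts[[1]])
  if (any(vapply(parts, length, 0L) != nc))
    stop_eegms("CSV rows have inconsistent field counts (truncated file?)",
               "eegms_parse_error")
  chans <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-1L]))
    if (anyNA(v))
      stop_eegms(sprintf("non-numeric sample in channel row '%s'", p[[1L]]),
                 "eegms_parse_error")
    v
  }, numeric(nc - 1L))
  recording(t(vals), fs, chans, subject_id = subject_id, group = group)
}

#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean over channels from every sample, the
#' standard average-reference montage. Idempotent.
#'
#' @param rec an `"eeg_recording"` or a channels x samples matrix.
#' @return Same type as the input, re-referenced.
#' @export
average_reference <- function(rec) {
  if (inherits(rec, "eeg_recording")) {
    rec$data <- average_reference(rec$data)
    return(rec)
  }
  if (nrow(rec) < 2L)
    stop_eegms("average reference needs at least 2 channels",
               "eegms_invalid_input")
  sweep(rec, 2L, colMeans(rec))
}

#' The five canonical frequency bands
#'
#' @return A data.frame with columns `name`, `low`, `high` (Hz):
#'   delta 0.5–4, theta 4–8, alpha 8–13, beta 13–30, gamma 30–45.
#' @export
eeg_bands <- function() {
  data.frame(name = c("delta", "theta", "alpha", "beta", "gamma"),
             low = c(0.5, 4, 8, 13, 30), high = c(4, 8, 13, 30, 45))
}

# zero-phase 4th-order Butterworth band-pass with odd-reflection padding
bandpass_vector <- function(x, fs, low, high, order = 4L) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  n <- length(x)
  np <- min(n - 1L, max(3L * order * 10L, ceiling(2 * fs / low)))
  left <- 2 * x[1L] - x[(np + 1L):2L]
  right <- 2 * x[n] - x[(n - 1L):(n - np)]
  padded <- c(left, x, right)
  y <- signal::filtfilt(bf, padded)
  y[(np + 1L):(np + n)]
}

#' Zero-phase band-pass filter
#'
#' Forward-backward (zero group delay) 4th-order Butterworth band-pass,
#' applied per channel with odd-reflection edge padding. Accepts a band by
#' name (see [eeg_bands()]) or explicit edges.
#'
#' @param rec an `"eeg_recording"` or channels x samples matrix.
#' @param band a band name, or `NULL` when `low`/`high` are given.
#' @param low,high band edges in Hz (`0 < low < high < fs/2`).
#' @param fs sampling rate, required for the matrix method.
#' @return Filtered object of the same type.
#' @export
bandpass <- function(rec, band = NULL, low = NULL, high = NULL, fs = NULL) {
  if (!is.null(band)) {
    b <- eeg_bands()
    row <- b[b$name == band, ]
    if (!nrow(row)) stop_eegms(sprintf("unknown band '%s'", band),
                               "eegms_invalid_band")
    low <- row$low; high <- row$high
  }
  if (inherits(rec, "eeg_recording")) {
    rec$data <- bandpass(rec$data, low = low, high = high,
                         fs = rec$sampling_rate)
    return(rec)
  }
  if (is.null(fs)) stop_eegms("fs is required for matrix input",
                              "eegms_invalid_config")
  if (!(0 < low && low < high && high < fs / 2))
    stop_eegms("band edges must satisfy 0 < low < high < fs/2",
               "eegms_invalid_band")
  t(apply(rec, 1L, bandpass_vector, fs = fs, low = low, high = high))
}

#' Cut a recording into non-overlapping epochs
#'
#' @param rec an `"eeg_recording"`.
#' @param length epoch length in seconds (default 5).
#' @return An `"eeg_epochs"` object: list of channels x samples matrices plus
#'   provenance. Yields `floor(duration/length)` epochs; the trailing
#'   remainder is discarded; a too-short recording gives an empty set with a
#'   warning.
#' @export
epoch_recording <- function(rec, length = 5) {
  stopifnot(inherits(rec, "eeg_recording"))
  spe <- round(length * rec$sampling_rate)
  n <- ncol(rec$data)
  k <- n %/% spe
  if (k == 0L)
    warning("recording shorter than one epoch; returning an empty epoch set")
  eps <- lapply(seq_len(k), function(i)
    rec$data[, ((i - 1L) * spe + 1L):(i * spe), drop = FALSE])
  structure(list(epochs = eps, epoch_length = length,
                 sampling_rate = rec$sampling_rate,
                 channel_names = rec$channel_names,
                 subject_id = rep(rec$subject_id, k),
                 group = rep(rec$group, k)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  cat(sprintf("<eeg_epochs> %d epochs of %g s @ %g Hz, %d channels\n",
              length(x$epochs), x$epoch_length, x$sampling_rate,
              if (length(x$epochs)) nrow(x$epochs[[1]]) else 0L))
  invisible(x)
}

#' Stratified train/test split of a feature table
#'
#' `mode = "epoch"` splits rows independently within each group (the common
#' published design, but epochs of one subject can land on both sides —
#' optimistic through leakage). `mode = "subject"` keeps all epochs of a
#' subject on one side and is the leakage-safe choice.
#'
#' @param table a feature table (`data.frame` with `group` and, for subject
#'   mode, `subject_id` columns).
#' @param train_fraction fraction in (0, 1) assigned to training.
#' @param seed integer seed; the partition is deterministic given it.
#' @param mode `"epoch"` or `"subject"`.
#' @return `list(train, test)` of two data.frames.
#' @export
split_table <- function(table, train_fraction = 0.7, seed = 1L,
                        mode = c("epoch", "subject")) {
  mode <- match.arg(mode)
  if (!(train_fraction > 0 && train_fraction < 1))
    stop_eegms("train_fraction must lie in (0, 1)", "eegms_invalid_config")
  idx <- split_indices(table, train_fraction, seed, mode)
  if (mode == "epoch")
    warning("epoch-mode split: epochs of one subject may appear in both ",
            "train and test (information leakage); consider mode='subject'",
            call. = FALSE)
  list(train = table[idx$train, , drop = FALSE],
       test = table[idx$test, , drop = FALSE])
}

split_indices <- function(table, train_fraction, seed, mode) {
  groups <- unique(table$group)
  train <- integer()
  with_seed(seed, {
    for (g in groups) {
      rows <- which(table$group == g)
      units <- if (mode == "subject") unique(table$subject_id[rows]) else rows
      if (length(units) < 2L)
        stop_eegms(sprintf("group '%s' has fewer than 2 units to split", g),
                   "eegms_stratification_error")
      n_tr <- round(train_fraction * length(units))
      n_tr <- max(1L, min(length(units) - 1L, n_tr))
      chosen <- sample(units, n_tr)
      train <- c(train, if (mode == "subject")
        rows[table$subject_id[rows] %in% chosen] else chosen)
    }
  })
  list(train = sort(train), test = sort(setdiff(seq_len(nrow(table)), train)))
}

#' Read a participants table
#'
#' Tab-separated with columns `Participant_ID`, `Gender`, `Age`, `Group`
#' (`A` = Alzheimer's disease, `C` = healthy control) and `MMSE` (0–30).
#'
#' @param path TSV path.
#' @return A validated `data.frame`.
#' @export
read_participants <- function(path) {
  df <- utils::read.delim(path, colClasses = c(Participant_ID = "character",
                                               Gender = "character",
                                               Group = "character"))
  need <- c("Participant_ID", "Gender", "Age", "Group", "MMSE")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_eegms(paste("participants table lacks column(s):",
                     paste(missing, collapse = ", ")), "eegms_parse_error")
  validate_participants(df)
  df
}

validate_participants <- function(df) {
  if (!all(df$Group %in% c("A", "C")))
    stop_eegms("Group must be 'A' or 'C'", "eegms_validation_error")
  if (!all(df$Gender %in% c("F", "M")))
    stop_eegms("Gender must be 'F' or 'M'", "eegms_validation_error")
  if (any(df$MMSE < 0 | df$MMSE > 30))
    stop_eegms("MMSE must lie in [0, 30]", "eegms_validation_error")
  invisible(df)
}

#' Demographic summary per group
#'
#' Per-group counts and mean/SD (sample SD, n−1 denominator) of age and
#' MMSE. Groups are keyed `A` (disease) and `C` (control). With a single
#' record in a group the SD is undefined and reported as `NA` with a
#' warning.
#'
#' @param records a participants `data.frame` (see [read_participants()]).
#' @return A `data.frame`, one row per group: `group`, `n`, `age_mean`,
#'   `age_sd`, `mmse_mean`, `mmse_sd`.
#' @export
summarize_participants <- function(records) {
  if (!nrow(records)) stop_eegms("empty participants table",
                                 "eegms_invalid_input")
  validate_participants(records)
  groups <- sort(unique(records$Group))
  out <- do.call(rbind, lapply(groups, function(g) {
    r <- records[records$Group == g, ]
    if (nrow(r) == 1L)
      warning(sprintf("group %s has a single record; SD undefined", g))
    data.frame(group = g, n = nrow(r),
               age_mean = mean(r$Age),
               age_sd = if (nrow(r) > 1L) sd(r$Age) else NA_real_,
               mmse_mean = mean(r$MMSE),
               mmse_sd = if (nrow(r) > 1L) sd(r$MMSE) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
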