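#' Entropy and complexity settings
#'
#' @param m embedding dimension for ApEn/SampEn/FuEn (default 2).
#' @param r match tolerance as a fraction of the signal SD (default 0.2).
#' @param fuzz_n fuzzy membership exponent (default 2).
#' @param lzc_threshold binarisation rule for Lempel–Ziv complexity,
#'   `"median"` (default) or `"mean"`.
#' @param strict use the strict `< r` match inequality for ApEn instead of
#'   the standard `<= r` (default `FALSE`).
#' @return A validated list of class `"entropy_config"`.
#' @export
entropy_config <- function(m = 2L, r = 0.2, fuzz_n = 2,
                           lzc_threshold = c("median", "mean"),
                           strict = FALSE) {
  lzc_threshold <- match.arg(lzc_threshold)
  if (!is_count(m)) stop_eegms("m must be a positive integer",
                               "eegms_invalid_config")
  if (!(r > 0)) stop_eegms("r must be > 0", "eegms_invalid_config")
  if (!(fuzz_n >= 1)) stop_eegms("fuzz_n must be >= 1",
                                 "eegms_invalid_config")
  structure(list(m = as.integer(m), r = r, fuzz_n = fuzz_n,
                 lzc_threshold = lzc_threshold, strict = strict),
            class = "entropy_config")
}

#' Welch power spectral density
#'
#' Hann-windowed segments (default 1 s) with 50% overlap, averaged
#' one-sided periodograms with density scaling.
#'
#' @param x single-channel series.
#' @param fs sampling rate (Hz).
#' @param seg_length segment length in samples (default `round(fs)`).
#' @param overlap fractional overlap (default 0.5).
#' @return List with `freq` (0 to Nyquist) and `psd`.
#' @export
welch_psd <- function(x, fs, seg_length = round(fs), overlap = 0.5) {
  n <- length(x)
  L <- min(seg_length, n)
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, n - L + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(L) / (L + 1)))   # Hann
  scale <- fs * sum(w^2)
  nb <- L %/% 2L + 1L
  acc <- numeric(nb)
  for (s0 in starts) {
    seg <- x[s0:(s0 + L - 1L)] * w
    p <- Mod(fft(seg))^2 / scale
    p <- p[seq_len(nb)]
    if (L %% 2L == 0L) p[2:(nb - 1L)] <- 2 * p[2:(nb - 1L)]
    else p[2:nb] <- 2 * p[2:nb]
    acc <- acc + p
  }
  list(freq = (seq_len(nb) - 1L) * fs / L, psd = acc / length(starts))
}

#' Linear (time and spectral domain) features of one signal
#'
#' Mean, median, RMS, sample SD and variance (the variance doubles as
#' Hjorth activity), mean Welch PSD over 0–Nyquist, spectral flatness
#' (geometric / arithmetic mean of the PSD bins), Hjorth mobility
#' `sqrt(var(diff(x))/var(x))` and complexity (mobility of the first
#' difference over mobility of the signal), and the standardised third and
#' fourth central moments (kurtosis not excess). A constant signal has
#' undefined mobility/complexity, reported as 0 with a warning.
#'
#' @param x numeric series of length >= 3.
#' @param fs sampling rate (Hz), used for the spectral features.
#' @return Named numeric vector of 11 values.
#' @export
linear_features <- function(x, fs) {
  if (length(x) < 3L || any(!is.finite(x)))
    stop_eegms("need >= 3 finite samples", "eegms_invalid_input")
  n <- length(x)
  mu <- mean(x)
  s <- sd(x)
  v <- var(x)
  p <- welch_psd(x, fs)
  flat <- if (all(p$psd > 0))
    exp(mean(log(p$psd))) / mean(p$psd) else 0
  if (v > 0) {
    d1 <- diff(x); d2 <- diff(d1)
    mob <- sqrt(var(d1) / v)
    mob_d <- if (var(d1) > 0) sqrt(var(d2) / var(d1)) else 0
    comp <- if (mob > 0) mob_d / mob else 0
    skew <- mean(((x - mu) / s)^3)
    kurt <- mean(((x - mu) / s)^4)
  } else {
    warning("constant signal: Hjorth mobility/complexity undefined, ",
            "returning 0")
    mob <- comp <- skew <- kurt <- 0
  }
  c(mean = mu, median = median(x), rms = sqrt(mean(x^2)), sd = s,
    variance = v, mean_psd = mean(p$psd), spectral_flatness = flat,
    hjorth_mobility = mob, hjorth_complexity = comp, skewness = skew,
    kurtosis = kurt)
}

#' Petrosian fractal dimension
#'
#' `PFD = log10(k) / (log10(k) + log10(k / (k + 0.4 * N_delta)))` with `k`
#' the series length and `N_delta` the number of sign changes of the first
#' difference. A strictly monotone signal gives exactly 1.
#'
#' @param x numeric series of length >= 2.
#' @return The fractal dimension (>= 1).
#' @export
pfd <- function(x) {
  k <- length(x)
  if (k < 2L) stop_eegms("need at least 2 samples", "eegms_invalid_input")
  d <- diff(x)
  nd <- sum(d[-1L] * d[-length(d)] < 0)
  log10(k) / (log10(k) + log10(k / (k + 0.4 * nd)))
}

#' Lempel–Ziv complexity
#'
#' Binarises the signal at its median (or mean), counts the exhaustive-
#' history phrases `c(n)` of the Lempel–Ziv 1976 parsing, and returns the
#' normalised complexity `c(n) * log2(n) / n`. A constant signal has a
#' single phrase by convention (`c(n) = 1`, with a warning).
#'
#' @param x numeric series of length >= 2.
#' @param threshold `"median"` (default) or `"mean"`.
#' @return Normalised complexity value.
#' @export
lzc <- function(x, threshold = c("median", "mean")) {
  threshold <- match.arg(threshold)
  n <- length(x)
  if (n < 2L) stop_eegms("need at least 2 samples", "eegms_invalid_input")
  if (sd(x) == 0) {
    warning("constant signal: c(n) = 1 by convention")
    return(log2(n) / n)
  }
  thr <- if (threshold == "median") median(x) else mean(x)
  b <- as.integer(x > thr)
  lz76_cpp(b) * log2(n) / n
}

entropy_tolerance <- function(x, r) r * sd(x)

#' Approximate entropy
#'
#' `ApEn(m, r, N) = Phi^m(r) - Phi^(m+1)(r)` with Chebyshev distances on
#' embedded windows, tolerance `r` scaled by the signal SD, and self-matches
#' included. The standard `<= r` match test is used; `cfg$strict` switches
#' to the strict inequality.
#'
#' @param x numeric series of length > m + 1.
#' @param cfg an [entropy_config()].
#' @return The entropy value (0 for a constant signal).
#' @export
apen <- function(x, cfg = entropy_config()) {
  check_entropy_input(x, cfg)
  if (sd(x) == 0) return(0)
  apen_cpp(as.numeric(x), cfg$m, entropy_tolerance(x, cfg$r), cfg$strict)
}

#' Sample entropy
#'
#' `SampEn(m, r, N) = -log(A / B)` where `B` and `A` count template pairs
#' within tolerance at lengths `m` and `m + 1` (Chebyshev distance,
#' self-pairs excluded, `N - m` templates at both lengths). With no match
#' at length `m + 1` the value is undefined and returned as `NA` with a
#' warning.
#'
#' @inheritParams apen
#' @return The entropy value (0 for a constant signal).
#' @export
sampen <- function(x, cfg = entropy_config()) {
  check_entropy_input(x, cfg)
  if (sd(x) == 0) return(0)
  ab <- sampen_counts_cpp(as.numeric(x), cfg$m, entropy_tolerance(x, cfg$r))
  if (ab[1L] == 0 || ab[2L] == 0) {
    warning("no template match at length m+1: sample entropy undefined")
    return(NA_real_)
  }
  -log(ab[1L] / ab[2L])
}

#' Fuzzy entropy
#'
#' `FuEn(m, r, n) = ln phi^m(r) - ln phi^(m+1)(r)` with mean-centred
#' embedded windows and fuzzy membership `exp(-d^n / r)` (Chebyshev `d`,
#' self-pairs excluded), tolerance `r` scaled by the signal SD.
#'
#' @inheritParams apen
#' @return The entropy value (0 for a constant signal).
#' @export
fuzzen <- function(x, cfg = entropy_config()) {
  check_entropy_input(x, cfg)
  if (sd(x) == 0) return(0)
  fuzzen_cpp(as.numeric(x), cfg$m, entropy_tolerance(x, cfg$r), cfg$fuzz_n)
}

check_entropy_input <- function(x, cfg) {
  if (length(x) <= cfg$m + 1L)
    stop_eegms("series must be longer than m + 1", "eegms_invalid_input")
  invisible(x)
}

#' The 16 conventional features of one epoch
#'
#' Computes the 11 linear features, Petrosian fractal dimension,
#' Lempel–Ziv complexity and the three entropies per channel and averages
#' them across channels into one 16-value row (set `aggregate = "channel"`
#' to keep per-channel values).
#'
#' @param epoch channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param cfg an [entropy_config()].
#' @param aggregate `"mean"` (default) or `"channel"`.
#' @return Named numeric vector of 16 values (`aggregate = "mean"`) or a
#'   channels x 16 matrix.
#' @export
conventional_vector <- function(epoch, fs, cfg = entropy_config(),
                                aggregate = c("mean", "channel")) {
  aggregate <- match.arg(aggregate)
  epoch <- as.matrix(epoch)
  per_channel <- t(apply(epoch, 1L, function(ch) {
    c(linear_features(ch, fs), pfd = pfd(ch),
      lzc = lzc(ch, cfg$lzc_threshold), apen = apen(ch, cfg),
      sampen = sampen(ch, cfg), fuzzen = fuzzen(ch, cfg))
  }))
  if (aggregate == "channel") per_channel else colMeans(per_channel)
}

#' Assemble the conventional feature table
#'
#' One 16-column row per epoch plus `subject_id` and `group`, matching the
#' layout of [microstate_features()].
#'
#' @param epochs list of channels x samples matrices or an `"eeg_epochs"`.
#' @param fs sampling rate (taken from `epochs` when it is `"eeg_epochs"`).
#' @param cfg an [entropy_config()].
#' @param subject_id,group per-epoch provenance (recycled if length 1).
#' @return A `data.frame` feature table.
#' @export
conventional_features <- function(epochs, fs = NULL,
                                  cfg = entropy_config(),
                                  subject_id = NA, group = NA) {
  if (inherits(epochs, "eeg_epochs")) {
    fs <- fs %||% epochs$sampling_rate
    if (all(is.na(subject_id))) subject_id <- epochs$subject_id
    if (all(is.na(group))) group <- epochs$group
    epochs <- epochs$epochs
  }
  if (is.matrix(epochs)) epochs <- list(epochs)
  if (is.null(fs)) stop_eegms("fs is required", "eegms_invalid_config")
  rows <- t(vapply(epochs, conventional_vector, numeric(16L), fs = fs,
                   cfg = cfg))
  data.frame(subject_id = rep_len(subject_id, nrow(rows)),
             group = rep_len(group, nrow(rows)),
             as.data.frame(rows), check.names = FALSE)
}
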