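#' Configuration for the synthetic microstate EEG generator
#'
#' Bundles every knob of the generator: montage size, sampling rate, the
#' semi-Markov state dynamics (geometric run lengths with a target mean
#' duration, a row-stochastic transition matrix with zero diagonal), epoch
#' geometry, signal-to-noise ratio, and the planted case/control contrast.
#'
#' The defaults emulate 21-channel eyes-closed resting EEG whose topography
#' alternates among `n_states = 4` quasi-stable maps with mean run length
#' 100 ms, cut into 5-s epochs at 250 Hz. The disease ("AD") group differs
#' from the control ("HC") group by a relative increase of the mean state
#' duration (`ad_duration_shift`, default +30%) and a perturbed transition
#' row for state 1 (`ad_transition_shift` of probability mass moved towards
#' state 2), mirroring reported microstate alterations in Alzheimer's
#' disease; both magnitudes are configurable.
#'
#' @param n_channels number of electrodes.
#' @param sampling_rate sampling rate in Hz.
#' @param n_states number of template maps K.
#' @param mean_duration target mean state run length in seconds.
#' @param transition_matrix K x K row-stochastic matrix with zero diagonal;
#'   default: uniform over the other states.
#' @param epoch_length epoch length in seconds.
#' @param n_epochs_per_subject epochs generated per subject.
#' @param n_subjects_per_group subjects per group.
#' @param snr root-mean-square amplitude ratio of the template signal to the
#'   additive sensor noise.
#' @param polarity_period period (s) of the alternating polarity factor; the
#'   generated topography flips sign with this period so that downstream code
#'   is genuinely exercised for polarity invariance.
#' @param envelope_freq frequency (Hz) of the smooth positive amplitude
#'   envelope modulating global field power.
#' @param envelope_depth modulation depth in (0, 1) of that envelope.
#' @param carrier_band optional `c(low, high)` in Hz; when set, the clean
#'   template signal is band-limited to this range before noise is added, so
#'   the planted group contrast lives only in that band. `NULL` (default)
#'   leaves the switching signal broadband.
#' @param noise one of `"white"` (default) or `"pink"` (1/f) sensor noise.
#' @param ad_duration_shift relative mean-duration increase in the AD group.
#' @param ad_transition_shift probability mass moved to state 2 in the AD
#'   group's transition row for state 1.
#' @param seed integer seed making the whole dataset reproducible.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_channels = 21, sampling_rate = 250, n_states = 4,
                       mean_duration = 0.10, transition_matrix = NULL,
                       epoch_length = 5, n_epochs_per_subject = 10,
                       n_subjects_per_group = 6, snr = 5,
                       polarity_period = 0.5,
                       envelope_freq = 0.7, envelope_depth = 0.4,
                       carrier_band = NULL,
                       noise = c("white", "pink"),
                       ad_duration_shift = 0.30, ad_transition_shift = 0.15,
                       seed = 1L) {
  noise <- match.arg(noise)
  for (nm in c("n_channels", "n_states", "n_epochs_per_subject",
               "n_subjects_per_group")) {
    if (!is_count(get(nm)))
      stop_eegms(sprintf("%s must be a positive integer", nm),
                 "eegms_invalid_config")
  }
  if (!(mean_duration > 0)) stop_eegms("mean_duration must be > 0",
                                       "eegms_invalid_config")
  if (!(snr > 0)) stop_eegms("snr must be > 0", "eegms_invalid_config")
  if (!(sampling_rate > 0)) stop_eegms("sampling_rate must be > 0",
                                       "eegms_invalid_config")
  if (n_states > n_channels)
    stop_eegms("n_states must not exceed n_channels", "eegms_invalid_config")
  if (is.null(transition_matrix))
    transition_matrix <- uniform_transitions(n_states)
  validate_transition_matrix(transition_matrix, n_states)
  structure(list(
    n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
    n_states = as.integer(n_states), mean_duration = mean_duration,
    transition_matrix = transition_matrix, epoch_length = epoch_length,
    n_epochs_per_subject = as.integer(n_epochs_per_subject),
    n_subjects_per_group = as.integer(n_subjects_per_group), snr = snr,
    polarity_period = polarity_period, envelope_freq = envelope_freq,
    envelope_depth = envelope_depth, carrier_band = carrier_band,
    noise = noise, ad_duration_shift = ad_duration_shift,
    ad_transition_shift = ad_transition_shift, seed = as.integer(seed)),
    class = "sim_config")
}

uniform_transitions <- function(k) {
  if (k == 1L) return(matrix(0, 1, 1))
  p <- matrix(1 / (k - 1), k, k)
  diag(p) <- 0
  p
}

validate_transition_matrix <- function(p, k) {
  if (!is.matrix(p) || nrow(p) != k || ncol(p) != k)
    stop_eegms("transition_matrix must be K x K", "eegms_invalid_config")
  if (k == 1L) return(invisible(p))  # no transitions exist for a single state
  if (any(abs(diag(p)) > 0))
    stop_eegms("transition_matrix diagonal must be zero",
               "eegms_invalid_config")
  if (any(p < 0) || any(abs(rowSums(p) - 1) > 1e-12))
    stop_eegms("transition_matrix rows must sum to 1", "eegms_invalid_config")
  invisible(p)
}

#' Generate template topographies
#'
#' Draws `n_states` scalp maps, each zero-mean across channels (average
#' reference) and of unit Euclidean norm. Within the zero-mean subspace the
#' maps are orthogonalised, so pairwise dot products vanish whenever
#' `n_states <= n_channels - 1`; the zero-mean subspace has only
#' `n_channels - 1` dimensions, so when `n_states == n_channels` the last map
#' re-uses an earlier direction.
#'
#' @param n_states number of maps (at most `n_channels`).
#' @param n_channels number of electrodes.
#' @param seed integer seed; the result is deterministic given the seed.
#' @return A `n_states` x `n_channels` matrix, one map per row.
#' @export
make_templates <- function(n_states, n_channels, seed = 1L) {
  if (!is_count(n_states) || !is_count(n_channels))
    stop_eegms("n_states and n_channels must be positive integers",
               "eegms_invalid_config")
  if (n_states > n_channels)
    stop_eegms("n_states must not exceed n_channels", "eegms_invalid_config")
  n <- n_channels
  # Orthonormal basis of the zero-mean (average-reference) subspace.
  basis <- qr.Q(qr(cbind(rep(1, n), diag(n)[, -n])))[, -1, drop = FALSE]
  with_seed(seed, {
    g <- matrix(rnorm((n - 1) * min(n_states, n - 1)), n - 1)
    q <- qr.Q(qr(g))
    if (n_states > ncol(q))  # recycle directions once the subspace is spent
      q <- cbind(q, q[, seq_len(n_states - ncol(q)), drop = FALSE])
    t(basis %*% q)
  })
}

#' Simulate microstate label sequences
#'
#' Generates per-sample state indices for a set of epochs from a semi-Markov
#' chain: run lengths are geometric on \{1, 2, ...\} with mean
#' `mean_duration * sampling_rate` samples, and the state entered after each
#' run is drawn from the transition matrix (no self-transitions).
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed.
#' @param n_epochs number of epochs (default `cfg$n_epochs_per_subject`).
#' @param mean_duration,transition_matrix overrides of the corresponding
#'   `cfg` entries (used to plant group contrasts).
#' @return A list of integer vectors, one per epoch, each of length
#'   `epoch_length * sampling_rate`.
#' @export
simulate_state_sequence <- function(cfg, seed = cfg$seed,
                                    n_epochs = cfg$n_epochs_per_subject,
                                    mean_duration = cfg$mean_duration,
                                    transition_matrix = cfg$transition_matrix) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_transition_matrix(transition_matrix, cfg$n_states)
  n <- round(cfg$epoch_length * cfg$sampling_rate)
  k <- cfg$n_states
  d <- mean_duration * cfg$sampling_rate
  with_seed(seed, lapply(seq_len(n_epochs), function(e) {
    if (k == 1L) return(rep(1L, n))
    out <- integer(n)
    pos <- 0L
    s <- sample.int(k, 1L)
    while (pos < n) {
      len <- rgeom(1L, prob = 1 / d) + 1L
      len <- min(len, n - pos)
      out[(pos + 1L):(pos + len)] <- s
      pos <- pos + len
      s <- sample.int(k, 1L, prob = transition_matrix[s, ])
    }
    out
  }))
}

#' Ground truth for a two-group synthetic dataset
#'
#' Draws templates and per-subject state sequences for an "HC" group using
#' the base dynamics and an "AD" group with the planted contrast
#' (lengthened mean duration, perturbed transition row for state 1), and
#' records the empirical per-state duration, occurrence and coverage of the
#' generated sequences.
#'
#' @param cfg a [sim_config()].
#' @param seed integer seed (default `cfg$seed`).
#' @return An object of class `"ms_ground_truth"`: templates, per-group
#'   dynamics parameters, state sequences keyed by subject, and empirical
#'   per-state summaries.
#' @export
make_ground_truth <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  seeds <- child_seeds(seed, 1L + 2L * cfg$n_subjects_per_group)
  templates <- make_templates(cfg$n_states, cfg$n_channels, seeds[[1]])
  p_ad <- perturb_transitions(cfg$transition_matrix, cfg$ad_transition_shift)
  d_ad <- cfg$mean_duration * (1 + cfg$ad_duration_shift)
  subjects <- list()
  i <- 1L
  for (grp in c("HC", "AD")) {
    md <- if (grp == "AD") d_ad else cfg$mean_duration
    tm <- if (grp == "AD") p_ad else cfg$transition_matrix
    for (s in seq_len(cfg$n_subjects_per_group)) {
      id <- sprintf("%s%02d", grp, s)
      subjects[[id]] <- list(
        id = id, group = grp,
        states = simulate_state_sequence(cfg, seed = seeds[[1L + i]],
                                         mean_duration = md,
                                         transition_matrix = tm))
      i <- i + 1L
    }
  }
  structure(list(
    templates = templates, config = cfg,
    mean_duration = c(HC = cfg$mean_duration, AD = d_ad),
    transition_matrix = list(HC = cfg$transition_matrix, AD = p_ad),
    subjects = subjects,
    summary = truth_summary(subjects, cfg)), class = "ms_ground_truth")
}

perturb_transitions <- function(p, shift) {
  k <- nrow(p)
  if (k < 3L || shift <= 0) return(p)
  row <- p[1L, ]
  donors <- setdiff(seq_len(k), c(1L, 2L))
  # move `shift` of mass (or as much as available) from states 3..K to state 2
  take <- row[donors] * min(1, shift / sum(row[donors]))
  row[donors] <- row[donors] - take
  row[2L] <- row[2L] + sum(take)
  p[1L, ] <- row
  p
}

# Empirical per-state duration/occurrence/coverage per group, computed with
# base rle() so it stays independent of the package's own run-length code.
truth_summary <- function(subjects, cfg) {
  groups <- unique(vapply(subjects, `[[`, "", "group"))
  out <- lapply(groups, function(g) {
    labs <- unlist(lapply(Filter(function(s) s$group == g, subjects),
                          function(s) lapply(s$states, identity)),
                   recursive = FALSE)
    k <- cfg$n_states
    dur <- occ <- cov <- numeric(k)
    total_runs <- trans <- matrix(0, k, k)
    n_tot <- 0
    run_len <- vector("list", k)
    n_runs <- numeric(k)
    for (ep in labs) {
      r <- rle(ep)
      for (s in seq_len(k)) {
        run_len[[s]] <- c(run_len[[s]], r$lengths[r$values == s])
        cov[s] <- cov[s] + sum(ep == s)
      }
      v <- r$values
      if (length(v) > 1)
        for (i in seq_len(length(v) - 1))
          trans[v[i], v[i + 1]] <- trans[v[i], v[i + 1]] + 1
      n_tot <- n_tot + length(ep)
    }
    dur <- vapply(run_len, function(l) if (length(l)) mean(l) else 0, 0) /
      cfg$sampling_rate
    n_runs <- vapply(run_len, length, 0L)
    epochs_s <- length(labs) * cfg$epoch_length
    rs <- rowSums(trans)
    tp <- trans / ifelse(rs > 0, rs, 1)
    list(mean_duration = dur, occurrence = n_runs / epochs_s,
         coverage = cov / n_tot, transition_matrix = tp)
  })
  names(out) <- groups
  out
}

#' Simulate multichannel EEG from planted microstate structure
#'
#' Each sample is `a_t * s_t * template[state_t] + noise_t`: `a_t > 0` is a
#' smooth sinusoidal amplitude envelope (global field power modulation),
#' `s_t` is a square-wave polarity factor alternating with period
#' `cfg$polarity_period` (microstate analysis must be invariant to it), and
#' the noise is zero-mean sensor noise scaled so the RMS amplitude ratio of
#' clean signal to noise equals `cfg$snr`, then re-referenced to the channel
#' average. With `cfg$carrier_band` set, the clean signal is band-limited
#' before noise is added.
#'
#' @param cfg a [sim_config()].
#' @param truth an [make_ground_truth()] result (or a list with `templates`
#'   and `subjects`).
#' @param seed integer seed.
#' @return A list of subjects; each has `id`, `group`, `states` and
#'   `epochs`, a list of `n_channels` x `n_samples` matrices.
#' @export
simulate_eeg <- function(cfg, truth, seed = cfg$seed) {
  stopifnot(inherits(cfg, "sim_config"))
  templates <- truth$templates
  if (ncol(templates) != cfg$n_channels)
    stop_eegms("template/channel dimension mismatch", "eegms_dimension_error")
  n <- round(cfg$epoch_length * cfg$sampling_rate)
  tt <- (seq_len(n) - 1) / cfg$sampling_rate
  seeds <- child_seeds(seed, length(truth$subjects))
  subjects <- truth$subjects
  for (i in seq_along(subjects)) {
    sub <- subjects[[i]]
    sub$epochs <- with_seed(seeds[[i]], lapply(sub$states, function(st) {
      phase <- runif(2, 0, 2 * pi)
      a <- 1 + cfg$envelope_depth * sin(2 * pi * cfg$envelope_freq * tt +
                                          phase[1])
      s <- ifelse(((tt + phase[2] / (2 * pi) * cfg$polarity_period) %%
                     cfg$polarity_period) < cfg$polarity_period / 2, 1, -1)
      clean <- templates[st, , drop = FALSE] * (a * s)   # n x C
      if (!is.null(cfg$carrier_band))
        clean <- apply(clean, 2, bandpass_vector, fs = cfg$sampling_rate,
                       low = cfg$carrier_band[1], high = cfg$carrier_band[2])
      if (is.finite(cfg$snr)) {
        noise <- if (cfg$noise == "pink") {
          matrix(pink_noise(n * cfg$n_channels), n)
        } else matrix(rnorm(n * cfg$n_channels), n)
        noise <- noise - rowMeans(noise)                 # average reference
        nr <- sqrt(mean(noise^2))
        sr <- sqrt(mean(clean^2))
        if (nr > 0) noise <- noise * (sr / (cfg$snr * nr))
        clean <- clean + noise
      }
      t(clean)
    }))
    subjects[[i]] <- sub
  }
  subjects
}

pink_noise <- function(n) {
  # spectral 1/f shaping of white Gaussian noise
  w <- rnorm(n)
  f <- fft(w)
  freq <- c(1, seq_len(n - 1))
  f <- f / sqrt(pmin(freq, n - freq + 1))
  x <- Re(fft(f, inverse = TRUE)) / n
  (x - mean(x)) / sd(x)
}

#' One-call synthetic dataset
#'
#' Convenience wrapper: [make_ground_truth()] then [simulate_eeg()].
#'
#' @inheritParams simulate_eeg
#' @return A list with `subjects` (epochs + planted labels) and `truth`.
#' @export
simulate_dataset <- function(cfg, seed = cfg$seed) {
  seeds <- child_seeds(seed, 2L)
  truth <- make_ground_truth(cfg, seeds[[1]])
  list(subjects = simulate_eeg(cfg, truth, seeds[[2]]), truth = truth)
}

#' Two-class Gaussian feature fixture
#'
#' A feature table for exercising the classifier harness: `n_per_class` rows
#' per group, `n_features` standard-normal columns, with the group mean of
#' the first feature shifted by `separation` standard deviations in the AD
#' class. `separation = 0` makes the classes exchangeable.
#'
#' @param n_per_class rows per class (at least 2).
#' @param separation effect size (SD units) on feature 1.
#' @param seed integer seed.
#' @param n_features number of feature columns (default 4: one carrying the
#'   effect, three nuisance dimensions, so the planted separation dominates
#'   distance-based classifiers).
#' @return A `data.frame` with `subject_id`, `group` and feature columns.
#' @export
make_feature_fixture <- function(n_per_class, separation = 0, seed = 1L,
                                 n_features = 4L) {
  if (!is_count(n_per_class) || n_per_class < 2)
    stop_eegms("n_per_class must be an integer >= 2", "eegms_invalid_config")
  n <- 2L * n_per_class
  with_seed(seed, {
    x <- matrix(rnorm(n * n_features), n)
    grp <- rep(c("AD", "HC"), each = n_per_class)
    x[grp == "AD", 1L] <- x[grp == "AD", 1L] + separation
    out <- data.frame(subject_id = sprintf("S%03d", seq_len(n)), group = grp,
                      x)
    names(out)[-(1:2)] <- sprintf("f%02d", seq_len(n_features))
    out
  })
}

#' Write a synthetic dataset to disk
#'
#' Epochs are written as CSV channel-matrix files (one per epoch, channels as
#' rows, a `# sampling_rate:` header line), subjects as a participants TSV
#' with columns `Participant_ID`, `Gender`, `Age`, `Group`, `MMSE`, and the
#' ground truth as JSON.
#'
#' @param dataset a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- dataset$truth$config
  chans <- default_channel_names(cfg$n_channels)
  paths <- character()
  rows <- list()
  for (sub in dataset$subjects) {
    for (e in seq_along(sub$epochs)) {
      p <- file.path(dir, sprintf("%s_epoch%03d.csv", sub$id, e))
      write_epoch_csv(sub$epochs[[e]], cfg$sampling_rate, chans, p)
      paths <- c(paths, p)
    }
    rows[[sub$id]] <- data.frame(
      Participant_ID = sub$id, Gender = "F", Age = 70L,
      Group = if (sub$group == "AD") "A" else "C",
      MMSE = if (sub$group == "AD") 20L else 30L)
  }
  pt <- file.path(dir, "participants.tsv")
  utils::write.table(do.call(rbind, rows), pt, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tj <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(list(
    templates = dataset$truth$templates,
    mean_duration = as.list(dataset$truth$mean_duration),
    transition_matrix = dataset$truth$transition_matrix),
    tj, digits = NA, auto_unbox = TRUE)
  invisible(c(paths, pt, tj))
}

write_epoch_csv <- function(epoch, fs, channel_names, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate: %g", fs), con)
  df <- data.frame(channel = channel_names, epoch, check.names = FALSE)
  utils::write.table(df, con, sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

default_channel_names <- function(n) {
  std <- c("Fp1", "Fpz", "Fp2", "F7", "F3", "Fz", "F4", "F8", "T3", "C3",
           "Cz", "C4", "T4", "T5", "P3", "Pz", "P4", "T6", "O1", "Oz", "O2")
  if (n <= length(std)) std[seq_len(n)] else
    c(std, sprintf("CH%02d", seq_len(n - length(std))))
}
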