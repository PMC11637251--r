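#' Run-length encode a label sequence
#'
#' Maximal constant runs of a microstate label sequence; concatenating the
#' runs reproduces the input exactly.
#'
#' @param labels integer (or factor-like) vector of per-sample states.
#' @return A list with `values`, `starts` (1-based), `lengths`.
#' @export
run_lengths <- function(labels) {
  n <- length(labels)
  if (!n) stop_eegms("empty label sequence", "eegms_invalid_input")
  ends <- c(which(labels[-1L] != labels[-n]), n)
  starts <- c(1L, head(ends, -1L) + 1L)
  list(values = labels[starts], starts = starts,
       lengths = ends - starts + 1L)
}

#' Microstate parameters of one segmented epoch
#'
#' The per-state temporal statistics of a label sequence, computed run-wise:
#' \describe{
#'   \item{duration}{mean run length of the state, seconds;}
#'   \item{occurrence}{number of runs of the state per second of epoch;}
#'   \item{coverage}{fraction of samples labelled with the state (so
#'     `duration * occurrence = coverage` for every state present);}
#'   \item{mean_corr}{mean absolute spatial correlation over the state's
#'     samples;}
#'   \item{gev}{the state's share of global explained variance;}
#'   \item{transition probabilities}{`p_jk` = fraction of runs of state j
#'     whose successor run is state k. Self-transitions cannot occur by run
#'     construction, so diagonal entries are 0; a state with no outgoing
#'     run leaves its row all zero.}
#' }
#' A state absent from the epoch reports 0 for every quantity. For K = 4
#' this yields the canonical 36-feature vector (5 scalars x 4 states + 16
#' transition entries).
#'
#' @param seg an `"ms_segmentation"` from [backfit()] (or a bare list with
#'   `labels`, `correlations`, `per_state_gev`, `k`).
#' @param sampling_rate sampling rate in Hz.
#' @return Named numeric vector of length `5k + k^2`, names
#'   `duration_A ... gev_D, p_AA ... p_DD` (per the segmentation's labels).
#' @export
microstate_parameters <- function(seg, sampling_rate) {
  if (!is.numeric(sampling_rate) || sampling_rate <= 0)
    stop_eegms("sampling_rate must be positive", "eegms_invalid_config")
  k <- seg$k
  labels <- seg$labels
  n <- length(labels)
  epoch_s <- n / sampling_rate
  lab_chr <- seg$state_labels %||% LETTERS[seq_len(k)]
  r <- run_lengths(labels)
  dur <- occ <- cov <- mcorr <- numeric(k)
  for (j in seq_len(k)) {
    lens <- r$lengths[r$values == j]
    cov[j] <- sum(labels == j) / n
    if (length(lens)) {
      dur[j] <- mean(lens) / sampling_rate
      occ[j] <- length(lens) / epoch_s
      mcorr[j] <- mean(seg$correlations[labels == j])
    }
  }
  trans <- matrix(0, k, k)
  v <- r$values
  if (length(v) > 1L)
    for (i in seq_len(length(v) - 1L))
      trans[v[i], v[i + 1L]] <- trans[v[i], v[i + 1L]] + 1
  rs <- rowSums(trans)
  trans <- trans / ifelse(rs > 0, rs, 1)
  gev_k <- seg$per_state_gev %||% numeric(k)
  out <- c(stats_vec("duration", dur, lab_chr),
           stats_vec("occurrence", occ, lab_chr),
           stats_vec("coverage", cov, lab_chr),
           stats_vec("mean_corr", mcorr, lab_chr),
           stats_vec("gev", gev_k, lab_chr),
           trans_vec(trans, lab_chr))
  out
}

stats_vec <- function(prefix, x, labels) {
  names(x) <- paste(prefix, labels, sep = "_")
  x
}

trans_vec <- function(trans, labels) {
  k <- nrow(trans)
  out <- as.vector(t(trans))
  names(out) <- as.vector(t(outer(labels, labels,
                                  function(a, b) paste0("p_", a, b))))
  out
}

#' Assemble the microstate feature table
#'
#' One row per segmented epoch, the `5k + k^2` named parameter columns
#' (36 for the canonical K = 4), plus `subject_id` and `group`.
#'
#' @param segs list of `"ms_segmentation"` objects backfitted against one
#'   template set.
#' @param sampling_rate Hz.
#' @param subject_id,group per-epoch provenance (recycled if length 1).
#' @return A `data.frame` feature table.
#' @export
microstate_features <- function(segs, sampling_rate, subject_id = NA,
                                group = NA) {
  if (inherits(segs, "ms_segmentation")) segs <- list(segs)
  ks <- vapply(segs, function(s) as.integer(s$k), 0L)
  if (length(unique(ks)) != 1L)
    stop_eegms("segmentations disagree on the number of states",
               "eegms_invalid_input")
  rows <- lapply(segs, microstate_parameters, sampling_rate = sampling_rate)
  nm <- names(rows[[1L]])
  if (!all(vapply(rows, function(r) identical(names(r), nm), TRUE)))
    stop_eegms("segmentations disagree on state labels",
               "eegms_invalid_input")
  out <- as.data.frame(do.call(rbind, rows))
  data.frame(subject_id = rep_len(subject_id, nrow(out)),
             group = rep_len(group, nrow(out)), out, check.names = FALSE)
}

# Pooled dynamics across epochs: mean duration weighted by runs, run-count
# transition matrix, coverage, mean GEV. Used by the fit object and the
# recovery checks.
pooled_dynamics <- function(segs, sampling_rate) {
  k <- segs[[1L]]$k
  lab_chr <- segs[[1L]]$state_labels %||% LETTERS[seq_len(k)]
  len_sum <- run_sum <- cov_sum <- numeric(k)
  trans <- matrix(0, k, k, dimnames = list(lab_chr, lab_chr))
  n_tot <- 0
  for (seg in segs) {
    r <- run_lengths(seg$labels)
    for (j in seq_len(k)) {
      lens <- r$lengths[r$values == j]
      len_sum[j] <- len_sum[j] + sum(lens)
      run_sum[j] <- run_sum[j] + length(lens)
      cov_sum[j] <- cov_sum[j] + sum(seg$labels == j)
    }
    v <- r$values
    if (length(v) > 1L)
      for (i in seq_len(length(v) - 1L))
        trans[v[i], v[i + 1L]] <- trans[v[i], v[i + 1L]] + 1
    n_tot <- n_tot + length(seg$labels)
  }
  rs <- rowSums(trans)
  list(mean_duration = stats::setNames(
         len_sum / pmax(run_sum, 1) / sampling_rate, lab_chr),
       occurrence = stats::setNames(run_sum / (n_tot / sampling_rate),
                                    lab_chr),
       coverage = stats::setNames(cov_sum / n_tot, lab_chr),
       transition_matrix = trans / ifelse(rs > 0, rs, 1),
       mean_gev = mean(vapply(segs, `[[`, 0, "gev")))
}
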