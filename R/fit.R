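#' Fit a microstate model to EEG epochs
#'
#' The central estimator: computes global field power per epoch, selects the
#' topographies at smoothed-GFP peaks, clusters them with the
#' polarity-invariant modified K-means (two-level — subject then group —
#' when epochs come from more than one subject), labels the templates A–D
#' against a reference set, and backfits every training epoch to summarise
#' the temporal dynamics (duration, occurrence, coverage, transitions, GEV).
#'
#' @param x epochs: an `"eeg_epochs"` object, a list of channels x samples
#'   matrices, or a single matrix.
#' @param k number of microstate classes (default 4).
#' @param fs sampling rate in Hz (taken from `x` when it is `"eeg_epochs"`).
#' @param subjects optional per-epoch subject ids; more than one distinct id
#'   triggers two-level clustering.
#' @param peak_window Gaussian GFP smoothing width in samples (default 50).
#' @param n_init,max_iter,tol modified K-means settings, see
#'   [microstate_kmeans()].
#' @param min_duration temporal-smoothing minimum run length in samples used
#'   when backfitting (default 3).
#' @param reference template set for A–D labelling; defaults to
#'   [canonical_templates()] when the montage uses standard 10–20 names,
#'   otherwise templates keep their fitted order with letter labels.
#' @param seed integer seed; the fit is deterministic given it.
#' @return An object of class `"microstates"` with components `templates`
#'   (K x N, labelled rows), `gev` (explained variance of the peak maps),
#'   `dynamics` (pooled backfit statistics), `segmentations` count, and the
#'   configuration. Methods: `print`, `summary`, `coef`, `predict`, `plot`,
#'   `simulate`.
#' @seealso [backfit()], [microstate_features()], [simulate.microstates()]
#' @export
microstates <- function(x, k = 4L, fs = NULL, subjects = NULL,
                        peak_window = 50L, n_init = 50L, max_iter = 300L,
                        tol = 1e-6, min_duration = 3L, reference = NULL,
                        seed = 1L) {
  cl <- match.call()
  chan <- NULL
  if (inherits(x, "eeg_epochs")) {
    fs <- fs %||% x$sampling_rate
    subjects <- subjects %||% x$subject_id
    chan <- x$channel_names
    x <- x$epochs
  }
  if (is.matrix(x)) x <- list(x)
  if (!length(x)) stop_eegms("no epochs supplied", "eegms_invalid_input")
  if (is.null(fs)) stop_eegms("fs is required", "eegms_invalid_config")
  chan <- chan %||% rownames(x[[1L]]) %||%
    default_channel_names(nrow(x[[1L]]))
  subjects <- subjects %||% rep("s1", length(x))
  if (anyNA(subjects)) subjects <- rep("s1", length(x))

  peak_maps <- lapply(x, function(ep) {
    pk <- pick_gfp_peaks(gfp(ep), window = peak_window)
    t(ep[, pk$peaks, drop = FALSE])
  })
  by_subject <- lapply(split(peak_maps, subjects), function(l)
    do.call(rbind, l))
  seeds <- child_seeds(seed, 2L)
  fitted <- if (length(by_subject) > 1L) {
    two_level_cluster(by_subject, k, n_init = n_init, max_iter = max_iter,
                      tol = tol, seed = seeds[[1L]])
  } else {
    microstate_kmeans(by_subject[[1L]], k, n_init = n_init,
                      max_iter = max_iter, tol = tol, seed = seeds[[1L]])
  }
  templ <- fitted$templates
  if (is.null(reference) && k == 4L)
    reference <- tryCatch(canonical_templates(chan), error = function(e) NULL)
  if (!is.null(reference)) {
    ordered <- order_templates(templ, reference)
    templ <- ordered$maps
  } else {
    rownames(templ) <- LETTERS[seq_len(k)]
  }
  colnames(templ) <- chan
  ts <- structure(list(maps = templ, labels = rownames(templ),
                       channels = chan), class = "ms_templates")
  segs <- lapply(x, function(ep) backfit(ts, ep, min_duration = min_duration))
  dyn <- pooled_dynamics(segs, fs)
  structure(list(
    templates = templ, labels = rownames(templ), k = k, gev = fitted$gev,
    dynamics = dyn, channel_names = chan, fs = fs,
    n_epochs = length(x), n_subjects = length(by_subject),
    n_peak_maps = sum(vapply(peak_maps, nrow, 0L)),
    config = list(peak_window = peak_window, n_init = n_init,
                  max_iter = max_iter, tol = tol,
                  min_duration = min_duration, seed = seed),
    call = cl), class = "microstates")
}

#' @export
print.microstates <- function(x, ...) {
  cat(sprintf("Microstate model: %d classes (%s), %d channels\n",
              x$k, paste(x$labels, collapse = ""), ncol(x$templates)))
  cat(sprintf("  fitted on %d epochs / %d subject(s), %d GFP-peak maps\n",
              x$n_epochs, x$n_subjects, x$n_peak_maps))
  cat(sprintf("  GEV of peak maps: %.3f; mean backfit GEV: %.3f\n",
              x$gev, x$dynamics$mean_gev))
  invisible(x)
}

#' @export
summary.microstates <- function(object, ...) {
  d <- object$dynamics
  tab <- data.frame(state = object$labels,
                    duration_ms = 1000 * d$mean_duration,
                    occurrence_hz = d$occurrence,
                    coverage = d$coverage)
  structure(list(fit = object, states = tab,
                 transition_matrix = d$transition_matrix),
            class = "summary.microstates")
}

#' @export
print.summary.microstates <- function(x, ...) {
  print(x$fit)
  cat("\nTemporal dynamics (pooled over training epochs):\n")
  print(x$states, row.names = FALSE, digits = 3L)
  cat("\nRun-wise transition probabilities:\n")
  print(round(x$transition_matrix, 3L))
  invisible(x)
}

#' @export
coef.microstates <- function(object, ...) object$templates

#' Backfit new epochs with a fitted microstate model
#'
#' @param object a `"microstates"` fit.
#' @param newdata an epoch matrix, list of epochs, or `"eeg_epochs"`.
#' @param min_duration temporal smoothing, defaults to the fit's setting.
#' @param ... unused.
#' @return One `"ms_segmentation"` for a single matrix, else a list of them.
#' @export
predict.microstates <- function(object, newdata,
                                min_duration = object$config$min_duration,
                                ...) {
  single <- is.matrix(newdata)
  if (inherits(newdata, "eeg_epochs")) newdata <- newdata$epochs
  if (single) newdata <- list(newdata)
  out <- lapply(newdata, function(ep)
    backfit(object$templates, ep, min_duration = min_duration))
  if (single) out[[1L]] else out
}

#' Plot fitted template topographies
#'
#' One panel per microstate class, the template weight of each electrode
#' drawn at its 10–20 position (disc area and shade by magnitude, filled =
#' positive, open = negative). Montages without known positions fall back to
#' a profile plot over channel index.
#'
#' @param x a `"microstates"` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.microstates <- function(x, ...) {
  coords <- tryCatch({
    alias <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
    nm <- ifelse(x$channel_names %in% names(alias),
                 alias[x$channel_names], x$channel_names)
    ten_twenty_coords()[nm, , drop = FALSE]
  }, error = function(e) NULL)
  k <- x$k
  op <- graphics::par(mfrow = c(1, k), mar = c(1, 1, 2, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(k)) {
    v <- x$templates[j, ]
    if (is.null(coords)) {
      graphics::plot(v, type = "h", main = x$labels[j], xlab = "channel",
                     ylab = "weight", ...)
    } else {
      graphics::plot(coords, asp = 1, axes = FALSE, xlab = "", ylab = "",
                     main = x$labels[j], type = "n",
                     xlim = c(-1.2, 1.2), ylim = c(-1.2, 1.2), ...)
      graphics::symbols(0, 0, circles = 1.15, inches = FALSE, add = TRUE)
      graphics::points(coords, pch = ifelse(v >= 0, 19, 1),
                       cex = 0.5 + 2.5 * abs(v) / max(abs(v)))
    }
  }
  invisible(x)
}

#' Simulate epochs from a fitted microstate model
#'
#' Generates synthetic epochs whose templates are the fitted maps and whose
#' semi-Markov dynamics (mean duration and transition matrix) are the
#' pooled statistics estimated during fitting — a parametric bootstrap of
#' the fitted model.
#'
#' @param object a `"microstates"` fit.
#' @param nsim number of epochs.
#' @param seed integer seed.
#' @param snr signal-to-noise ratio of the simulated epochs (default 5).
#' @param epoch_length epoch length in seconds (default 5).
#' @param ... unused.
#' @return A list of channels x samples matrices with a `"states"`
#'   attribute holding the generating label sequences.
#' @export
simulate.microstates <- function(object, nsim = 1L, seed = 1L, snr = 5,
                                 epoch_length = 5, ...) {
  d <- object$dynamics
  tm <- unname(d$transition_matrix)
  rs <- rowSums(tm)
  for (j in which(rs == 0)) {   # states never left: jump uniformly
    tm[j, ] <- 1 / (object$k - 1)
    tm[j, j] <- 0
  }
  tm <- tm / rowSums(tm)
  cfg <- sim_config(n_channels = ncol(object$templates),
                    sampling_rate = object$fs, n_states = object$k,
                    mean_duration = mean(d$mean_duration),
                    transition_matrix = tm, epoch_length = epoch_length,
                    n_epochs_per_subject = nsim, n_subjects_per_group = 1L,
                    snr = snr, seed = seed)
  seeds <- child_seeds(seed, 2L)
  states <- simulate_state_sequence(cfg, seed = seeds[[1L]])
  truth <- list(templates = unname(object$templates),
                subjects = list(list(id = "sim", group = "HC",
                                     states = states)))
  eps <- simulate_eeg(cfg, truth, seed = seeds[[2L]])[[1L]]$epochs
  attr(eps, "states") <- states
  eps
}
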