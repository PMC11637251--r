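#' Global field power
#'
#' The spatial standard deviation of the scalp potential at each sample:
#' `sqrt(mean((u_i - u_bar)^2))` over the `N` electrodes (population
#' convention, divisor `N`). High GFP marks moments of pronounced
#' topographic structure; flat maps give GFP near zero.
#'
#' @param epoch channels x samples numeric matrix.
#' @return Numeric vector of per-sample GFP values (same units as the data).
#' @export
gfp <- function(epoch) {
  epoch <- as.matrix(epoch)
  if (nrow(epoch) < 2L)
    stop_eegms("GFP needs at least 2 channels", "eegms_invalid_input")
  cm <- colMeans(epoch)
  sqrt(colMeans(sweep(epoch, 2L, cm)^2))
}

gaussian_kernel <- function(window) {
  # an even width has no centre sample and would shift peaks by half a
  # sample; round the kernel length up to odd, keeping sigma = window / 6
  len <- if (window %% 2L == 0L) window + 1L else as.integer(window)
  half <- (len - 1L) %/% 2L
  k <- dnorm(seq.int(-half, half), sd = window / 6)
  k / sum(k)
}

#' Smooth a GFP series and pick its peaks
#'
#' Convolves the series with a Gaussian moving average of total width
#' `window` samples (sigma = `window / 6`), handling edges by reflection,
#' then returns the strict interior local maxima of the smoothed series —
#' the samples whose topographies feed the clustering.
#'
#' @param values per-sample GFP series.
#' @param window kernel width in samples (default 50).
#' @return A list with `values`, `smoothed`, and `peaks` (integer indices).
#' @export
pick_gfp_peaks <- function(values, window = 50L) {
  n <- length(values)
  if (n <= window)
    stop_eegms("series must be longer than the smoothing window",
               "eegms_invalid_input")
  k <- gaussian_kernel(window)
  half <- (length(k) - 1L) %/% 2L
  padded <- c(values[(half + 1L):2L], values, values[(n - 1L):(n - half)])
  sm <- stats::filter(padded, k, sides = 2L)
  sm <- as.numeric(sm)[(half + 1L):(half + n)]
  inner <- 2:(n - 1)
  peaks <- inner[sm[inner] > sm[inner - 1L] & sm[inner] > sm[inner + 1L]]
  list(values = values, smoothed = sm, peaks = as.integer(peaks))
}

# Center map rows (average reference across channels).
center_rows <- function(m) m - rowMeans(m)

#' Polarity-invariant modified K-means for topographies
#'
#' Clusters `M` scalp maps into `K` classes ignoring polarity: each map is
#' assigned to the template maximising the squared spatial correlation, and
#' each template is updated to the dominant eigenvector of the outer-product
#' sum of its assigned maps (equivalently the first right singular vector of
#' the stacked maps). Iterations stop when the relative change in global
#' explained variance (GEV) falls below `tol` or after `max_iter` sweeps;
#' the best of `n_init` random restarts by GEV is returned.
#'
#' @param maps M x N matrix, one topography per row.
#' @param k number of classes (`1 <= k <= M`).
#' @param n_init random restarts (default 50).
#' @param max_iter iteration cap per restart (default 300).
#' @param tol relative-GEV convergence threshold (default 1e-6).
#' @param seed integer seed; results are deterministic given it.
#' @return A list: `templates` (K x N, rows zero-mean unit-norm),
#'   `assignment` (per-map class), `correlation` (per-map signed spatial
#'   correlation with its template), `gev`, `per_state_gev`, `n_iter`.
#' @export
microstate_kmeans <- function(maps, k, n_init = 50L, max_iter = 300L,
                              tol = 1e-6, seed = NULL) {
  maps <- as.matrix(maps)
  m <- nrow(maps)
  if (m < k) stop_eegms("need at least k maps", "eegms_invalid_input")
  xc <- center_rows(maps)
  norms <- sqrt(rowSums(xc^2))
  if (all(norms < 1e-12))
    stop_eegms("all maps are flat (zero variance)", "eegms_degenerate_input")
  keep <- norms > 1e-12
  if (!all(keep)) { xc <- xc[keep, , drop = FALSE]; norms <- norms[keep] }
  m <- nrow(xc)
  if (m < k) stop_eegms("need at least k non-flat maps",
                        "eegms_invalid_input")
  denom <- sum(norms^2)
  seeds <- child_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1L),
                       n_init)
  best <- NULL
  for (init in seq_len(n_init)) {
    res <- with_seed(seeds[[init]],
                     kmeans_once(xc, norms, denom, k, max_iter, tol))
    if (is.null(best) || res$gev > best$gev) best <- res
  }
  # canonical sign: strongest-magnitude channel positive
  for (j in seq_len(k)) {
    v <- best$templates[j, ]
    if (v[which.max(abs(v))] < 0) best$templates[j, ] <- -v
  }
  a <- best$templates %*% t(xc)
  r_signed <- a[cbind(best$assignment, seq_len(m))] / norms
  per_state <- vapply(seq_len(k), function(j) {
    i <- best$assignment == j
    sum((r_signed[i] * norms[i])^2) / denom
  }, 0)
  full_assign <- integer(length(keep))
  full_assign[keep] <- best$assignment
  full_corr <- numeric(length(keep))
  full_corr[keep] <- r_signed
  list(templates = best$templates, assignment = full_assign,
       correlation = full_corr, gev = best$gev, per_state_gev = per_state,
       n_iter = best$n_iter, gev_trace = best$gev_trace, k = k)
}

kmeans_once <- function(xc, norms, denom, k, max_iter, tol) {
  m <- nrow(xc)
  init_rows <- sample.int(m, k)
  templ <- xc[init_rows, , drop = FALSE] / norms[init_rows]
  gev_prev <- -Inf
  assign <- integer(m)
  trace <- numeric(0)
  for (iter in seq_len(max_iter)) {
    a <- xc %*% t(templ)                       # M x K dot products
    assign <- max.col(a^2, ties.method = "first")
    fit2 <- a[cbind(seq_len(m), assign)]^2
    # re-seed empty classes with the worst-explained map
    for (j in which(tabulate(assign, k) == 0L)) {
      worst <- which.min(fit2 / norms^2)
      assign[worst] <- j
      fit2[worst] <- norms[worst]^2
    }
    for (j in seq_len(k)) {
      idx <- which(assign == j)
      templ[j, ] <- if (length(idx) == 1L) xc[idx, ] / norms[idx] else
        svd(xc[idx, , drop = FALSE], nu = 0L, nv = 1L)$v[, 1L]
    }
    a <- xc %*% t(templ)
    assign <- max.col(a^2, ties.method = "first")
    gev <- sum(a[cbind(seq_len(m), assign)]^2) / denom
    trace <- c(trace, gev)
    if (is.finite(gev_prev) &&
        abs(gev - gev_prev) / max(gev_prev, .Machine$double.eps) < tol) break
    gev_prev <- gev
  }
  list(templates = templ, assignment = assign, gev = gev, n_iter = iter,
       gev_trace = trace)
}

#' Two-level (subject, then group) clustering
#'
#' Runs the modified K-means on each subject's GFP-peak maps, pools the
#' resulting subject templates, and clusters those again to obtain the group
#' template set — the standard two-stage aggregation that keeps every
#' subject's contribution balanced.
#'
#' @param peak_maps_by_subject list of M_s x N matrices, one per subject.
#' @param k number of classes.
#' @inheritParams microstate_kmeans
#' @return A list: `templates` (group K x N), `gev` (at the group stage),
#'   `subject_templates` (list of per-subject K x N matrices).
#' @export
two_level_cluster <- function(peak_maps_by_subject, k, n_init = 50L,
                              max_iter = 300L, tol = 1e-6, seed = NULL) {
  if (!length(peak_maps_by_subject))
    stop_eegms("no subjects supplied", "eegms_invalid_input")
  seeds <- child_seeds(seed %||% sample.int(.Machine$integer.max - 1L, 1L),
                       length(peak_maps_by_subject) + 1L)
  subj <- lapply(seq_along(peak_maps_by_subject), function(i)
    microstate_kmeans(peak_maps_by_subject[[i]], k, n_init = n_init,
                      max_iter = max_iter, tol = tol,
                      seed = seeds[[i]])$templates)
  pooled <- do.call(rbind, subj)
  top <- microstate_kmeans(pooled, k, n_init = n_init, max_iter = max_iter,
                           tol = tol, seed = seeds[[length(seeds)]])
  list(templates = top$templates, gev = top$gev, subject_templates = subj)
}

ten_twenty_coords <- function() {
  m <- rbind(
    Fp1 = c(-0.31, 0.95), Fpz = c(0, 1.00), Fp2 = c(0.31, 0.95),
    F7 = c(-0.81, 0.59), F3 = c(-0.55, 0.48), Fz = c(0, 0.50),
    F4 = c(0.55, 0.48), F8 = c(0.81, 0.59),
    T3 = c(-1.00, 0), C3 = c(-0.50, 0), Cz = c(0, 0), C4 = c(0.50, 0),
    T4 = c(1.00, 0),
    T5 = c(-0.81, -0.59), P3 = c(-0.55, -0.48), Pz = c(0, -0.50),
    P4 = c(0.55, -0.48), T6 = c(0.81, -0.59),
    O1 = c(-0.31, -0.95), Oz = c(0, -1.00), O2 = c(0.31, -0.95))
  colnames(m) <- c("x", "y")
  m
}

#' Idealised canonical reference maps (classes A–D)
#'
#' Built-in reference topographies used only to give fitted templates a
#' deterministic A–D labelling: A is a left-posterior to right-frontal
#' gradient, B its mirror image, C an occipital–frontal midline gradient,
#' and D a fronto-central focal map. Defined on the standard 10–20 names
#' (modern aliases T7/T8/P7/P8 accepted); for other montages supply your own
#' reference to [order_templates()].
#'
#' @param channel_names electrode names to build the maps on.
#' @return An `"ms_templates"` object: `maps` (4 x N zero-mean unit-norm),
#'   `labels` `c("A","B","C","D")`, `channels`.
#' @export
canonical_templates <- function(channel_names) {
  alias <- c(T7 = "T3", T8 = "T4", P7 = "T5", P8 = "T6")
  nm <- ifelse(channel_names %in% names(alias),
               alias[channel_names], channel_names)
  coords <- ten_twenty_coords()
  if (!all(nm %in% rownames(coords)))
    stop_eegms(paste("unrecognised electrode name(s):",
                     paste(setdiff(nm, rownames(coords)), collapse = ", "),
                     "- supply a custom reference template set"),
               "eegms_invalid_input")
  xy <- coords[nm, , drop = FALSE]
  x <- xy[, "x"]; y <- xy[, "y"]
  maps <- rbind(A = x + y, B = y - x, C = -y,
                D = exp(-(x^2 + (y - 0.35)^2) / 0.35))
  maps <- center_rows(maps)
  maps <- maps / sqrt(rowSums(maps^2))
  structure(list(maps = maps, labels = c("A", "B", "C", "D"),
                 channels = channel_names), class = "ms_templates")
}

template_maps <- function(x) {
  if (inherits(x, "ms_templates")) x$maps
  else if (inherits(x, "microstates")) x$templates
  else as.matrix(x)
}

template_labels <- function(x, k) {
  if (inherits(x, "ms_templates")) x$labels
  else if (inherits(x, "microstates")) rownames(x$templates)
  else rownames(template_maps(x)) %||% LETTERS[seq_len(k)]
}

# Minimum-cost perfect assignment (Hungarian algorithm with potentials,
# shortest augmenting paths). cost is square; returns column for each row.
hungarian <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L); v <- numeric(n + 1L)
  p <- integer(n + 1L); way <- integer(n + 1L)   # index 1 = virtual column 0
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) if (!used[j + 1L]) {
        cur <- cost[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  match(seq_len(n), p[-1L])   # row -> column
}

#' Match and label templates against a reference
#'
#' Finds the one-to-one assignment between fitted templates and a reference
#' set that maximises the total absolute spatial correlation (optimal
#' assignment, polarity ignored), reorders the templates accordingly,
#' inherits the reference labels, and flips signs so each template
#' correlates positively with its reference map.
#'
#' @param ts fitted templates: a K x N matrix or `"ms_templates"`.
#' @param reference reference templates of the same K and N.
#' @return An `"ms_templates"` object in reference order, with an
#'   `"matching"` attribute giving the permutation and correlations.
#' @export
order_templates <- function(ts, reference) {
  maps <- center_rows(template_maps(ts))
  ref <- center_rows(template_maps(reference))
  if (!all(dim(maps) == dim(ref)))
    stop_eegms("template and reference dimensions differ",
               "eegms_dimension_error")
  maps <- maps / sqrt(rowSums(maps^2))
  refn <- ref / sqrt(rowSums(ref^2))
  s <- maps %*% t(refn)                         # signed correlations
  perm <- hungarian(max(abs(s)) - t(abs(s)))    # ref row -> template row
  ordered <- maps[perm, , drop = FALSE]
  signs <- sign(s[cbind(perm, seq_len(nrow(ref)))])
  signs[signs == 0] <- 1
  ordered <- ordered * signs
  labels <- template_labels(reference, nrow(ref))
  rownames(ordered) <- labels
  structure(list(maps = ordered, labels = labels,
                 channels = if (inherits(reference, "ms_templates"))
                   reference$channels else colnames(ordered)),
            class = "ms_templates",
            matching = list(permutation = perm,
                            correlation = abs(s[cbind(perm,
                                                      seq_len(nrow(ref)))])))
}

#' Global map dissimilarity (diagnostic)
#'
#' Polarity-invariant topographic distance between two maps: both are
#' average-referenced and scaled to unit GFP, and the root-mean-square
#' difference is minimised over the sign of the second map. Ranges 0 (equal
#' up to polarity and scale) to 2 (perfectly inverted is 0 here; orthogonal
#' maps give sqrt(2)).
#'
#' @param u,v electrode-potential vectors of equal length.
#' @return A single dissimilarity value.
#' @export
gmd <- function(u, v) {
  if (length(u) != length(v))
    stop_eegms("maps must have equal length", "eegms_dimension_error")
  un <- (u - mean(u)); vn <- (v - mean(v))
  gu <- sqrt(mean(un^2)); gv <- sqrt(mean(vn^2))
  if (gu == 0 || gv == 0)
    stop_eegms("flat map has undefined GMD", "eegms_degenerate_input")
  un <- un / gu; vn <- vn / gv
  min(sqrt(mean((un - vn)^2)), sqrt(mean((un + vn)^2)))
}

#' Backfit templates to an epoch
#'
#' Assigns every sample to the template with the highest absolute spatial
#' correlation (polarity ignored; ties go to the lowest label index), then
#' applies temporal smoothing: runs shorter than `min_duration` samples are
#' relabelled sample-by-sample to whichever neighbouring run's state
#' correlates better at that sample. Samples with zero spatial variance have
#' undefined correlation and inherit the previous label (leading samples
#' take the first valid label).
#'
#' @param ts templates (K x N matrix, `"ms_templates"`, or a fitted
#'   `"microstates"` object).
#' @param epoch channels x samples matrix.
#' @param min_duration minimum run length in samples (default 3).
#' @return An `"ms_segmentation"`: `labels` (integer classes),
#'   `states` (character labels), `correlations` (per-sample |r| with the
#'   assigned template), `gfp`, `gev`, `per_state_gev`, `k`.
#' @export
backfit <- function(ts, epoch, min_duration = 3L) {
  templ <- template_maps(ts)
  k <- nrow(templ)
  labels_chr <- template_labels(ts, k)
  epoch <- as.matrix(epoch)
  if (ncol(templ) != nrow(epoch))
    stop_eegms("template/channel dimensions disagree",
               "eegms_dimension_error")
  templ <- center_rows(templ)
  templ <- templ / sqrt(rowSums(templ^2))
  xc <- sweep(epoch, 2L, colMeans(epoch))
  norms <- sqrt(colSums(xc^2))
  s <- ncol(xc)
  valid <- norms > 1e-12
  if (!any(valid))
    stop_eegms("every sample is flat; nothing to backfit",
               "eegms_degenerate_input")
  r <- matrix(0, k, s)
  r[, valid] <- (templ %*% xc[, valid, drop = FALSE]) /
    rep(norms[valid], each = k)
  ra <- abs(r)
  lab <- max.col(t(ra), ties.method = "first")
  # zero-variance samples: carry the previous (or first valid) label
  if (!all(valid)) {
    first_valid <- which(valid)[1L]
    lab[seq_len(first_valid - 1L)] <- lab[first_valid]
    for (i in which(!valid)) if (i > first_valid) lab[i] <- lab[i - 1L]
  }
  lab <- smooth_labels(lab, ra, min_duration)
  corr <- ra[cbind(lab, seq_len(s))]
  w <- norms^2                    # GFP^2 up to the common 1/N factor
  denom <- sum(w)
  per_state <- vapply(seq_len(k), function(j) {
    i <- lab == j
    sum(w[i] * corr[i]^2) / denom
  }, 0)
  structure(list(labels = lab, states = labels_chr[lab],
                 state_labels = labels_chr, correlations = corr,
                 gfp = norms / sqrt(nrow(epoch)), gev = sum(per_state),
                 per_state_gev = per_state, k = k),
            class = "ms_segmentation")
}

smooth_labels <- function(lab, ra, min_duration) {
  if (min_duration <= 1L) return(lab)
  for (pass in seq_len(20L)) {
    r <- run_lengths(lab)
    short <- which(r$lengths < min_duration)
    short <- setdiff(short, if (length(r$lengths) == 1L) 1L else integer())
    if (!length(short)) break
    changed <- FALSE
    for (ri in short) {
      left <- if (ri > 1L) r$values[ri - 1L] else NA_integer_
      right <- if (ri < length(r$values)) r$values[ri + 1L] else NA_integer_
      span <- r$starts[ri]:(r$starts[ri] + r$lengths[ri] - 1L)
      for (t in span) {
        new <- if (is.na(left)) right
        else if (is.na(right)) left
        else if (ra[left, t] >= ra[right, t]) left else right
        if (new != lab[t]) { lab[t] <- new; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  lab
}

#' @export
print.ms_segmentation <- function(x, ...) {
  cat(sprintf("<ms_segmentation> %d samples, %d states, GEV %.3f\n",
              length(x$labels), x$k, x$gev))
  cov <- table(factor(x$states, levels = x$state_labels)) / length(x$labels)
  cat("  coverage:", paste(sprintf("%s %.2f", names(cov), cov),
                           collapse = ", "), "\n")
  invisible(x)
}
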