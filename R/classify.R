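feature_columns <- function(table)
  setdiff(names(table), c("subject_id", "group"))

#' Confusion-matrix metrics
#'
#' Counts and derived proportions with Alzheimer's disease (`"AD"`) as the
#' positive class: accuracy `(tp+tn)/n`, sensitivity `tp/(tp+fn)` (AD
#' recall), specificity `tn/(tn+fp)` (HC recall). A zero denominator makes
#' the corresponding rate undefined (`NA` with a warning).
#'
#' @param truth,pred character/factor vectors of `"AD"`/`"HC"` labels.
#' @param scores optional continuous scores (higher = more AD-like) from
#'   which the AUC is computed by the rank (Mann–Whitney) construction with
#'   midrank tie correction.
#' @return A one-row `data.frame`: `tp, fp, fn, tn, accuracy, sensitivity,
#'   specificity, auc`.
#' @export
eval_metrics <- function(truth, pred, scores = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  tp <- sum(truth == "AD" & pred == "AD")
  fp <- sum(truth == "HC" & pred == "AD")
  fn <- sum(truth == "AD" & pred == "HC")
  tn <- sum(truth == "HC" & pred == "HC")
  sens <- if (tp + fn > 0) tp / (tp + fn) else {
    warning("no positive (AD) cases in truth: sensitivity undefined")
    NA_real_
  }
  spec <- if (tn + fp > 0) tn / (tn + fp) else {
    warning("no negative (HC) cases in truth: specificity undefined")
    NA_real_
  }
  data.frame(tp = tp, fp = fp, fn = fn, tn = tn,
             accuracy = (tp + tn) / length(truth),
             sensitivity = sens, specificity = spec,
             auc = if (is.null(scores)) NA_real_ else
               auc_rank(scores, truth == "AD"))
}

#' Rank-based AUC
#'
#' The Mann–Whitney construction: with midranks for ties,
#' `AUC = (sum of positive ranks - n1(n1+1)/2) / (n1 n0)`. Equals the
#' probability a random positive outscores a random negative, counting ties
#' as one half.
#'
#' @param scores numeric scores, higher = more positive-like.
#' @param positive logical vector marking the positive class.
#' @return AUC in `[0, 1]`; `NA` if either class is empty.
#' @export
auc_rank <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

default_hyper <- function() {
  list(svm_cost = 1, knn_k = 5L, rf_ntree = 100L, lr_lambda_scale = 1)
}

#' Train one classifier and evaluate on held-out data
#'
#' Standardises features with training statistics only (z-score; zero-
#' variance columns pass through), fits the requested model and evaluates
#' on the test table. Classifiers: `"svm"` (RBF kernel, cost 1, gamma
#' `1/(p * mean feature variance)` on the scaled data), `"knn"` (k = 5),
#' `"rf"` (100 trees), `"lr"` (ridge logistic regression, unit-strength L2,
#' i.e. lambda = 1/n_train). The positive class is AD.
#'
#' @param train,test feature tables sharing the same columns, both with a
#'   `group` column of `"AD"`/`"HC"`.
#' @param classifier one of `"svm"`, `"knn"`, `"rf"`, `"lr"`.
#' @param seed integer seed (tie-breaking in KNN, bootstrap in RF).
#' @param hyper optional overrides of `default_hyper()` entries.
#' @return A one-row `data.frame` of [eval_metrics()] plus `classifier`,
#'   with the hyperparameters in the `"hyper"` attribute.
#' @export
train_eval <- function(train, test, classifier = c("svm", "knn", "rf", "lr"),
                       seed = 1L, hyper = list()) {
  classifier <- match.arg(classifier)
  hp <- utils::modifyList(default_hyper(), hyper)
  cols <- feature_columns(train)
  if (!identical(cols, feature_columns(test)))
    stop_eegms("train and test feature columns differ",
               "eegms_invalid_input")
  if (length(unique(train$group)) < 2L)
    stop_eegms("training set must contain both classes",
               "eegms_invalid_input")
  xtr <- as.matrix(train[, cols, drop = FALSE])
  xte <- as.matrix(test[, cols, drop = FALSE])
  mu <- colMeans(xtr)
  sg <- apply(xtr, 2L, sd)
  sg[!is.finite(sg) | sg == 0] <- 1
  xtr <- sweep(sweep(xtr, 2L, mu), 2L, sg, "/")
  xte <- sweep(sweep(xte, 2L, mu), 2L, sg, "/")
  ytr <- factor(train$group, levels = c("AD", "HC"))
  yte <- factor(test$group, levels = c("AD", "HC"))
  res <- with_seed(seed, switch(
    classifier,
    svm = {
      gamma <- 1 / (ncol(xtr) * mean(apply(xtr, 2L, var)))
      fit <- e1071::svm(xtr, ytr, kernel = "radial", cost = hp$svm_cost,
                        gamma = gamma, scale = FALSE)
      pr <- predict(fit, xte, decision.values = TRUE)
      dv <- drop(attr(pr, "decision.values"))
      if (!startsWith(colnames(attr(pr, "decision.values"))[1L], "AD"))
        dv <- -dv
      list(pred = pr, scores = dv)
    },
    knn = {
      pr <- class::knn(xtr, xte, ytr, k = hp$knn_k, prob = TRUE)
      p <- attr(pr, "prob")
      list(pred = pr, scores = ifelse(pr == "AD", p, 1 - p))
    },
    rf = {
      fit <- randomForest::randomForest(xtr, ytr, ntree = hp$rf_ntree)
      list(pred = predict(fit, xte),
           scores = predict(fit, xte, type = "prob")[, "AD"])
    },
    lr = {
      y01 <- as.integer(ytr == "AD")
      fit <- glmnet::glmnet(xtr, y01, family = "binomial", alpha = 0,
                            lambda = hp$lr_lambda_scale / nrow(xtr))
      sc <- drop(predict(fit, xte, type = "response"))
      list(pred = factor(ifelse(sc > 0.5, "AD", "HC"),
                         levels = c("AD", "HC")), scores = sc)
    }))
  out <- cbind(data.frame(classifier = classifier),
               eval_metrics(yte, res$pred, res$scores))
  attr(out, "hyper") <- hp
  attr(out, "seed") <- seed
  out
}

#' Band-selection experiment
#'
#' For each frequency band: band-pass filter every epoch, fit a microstate
#' model, extract the microstate feature table, split it, and evaluate one
#' classifier (SVM with RBF kernel by default). Bands are ranked by
#' held-out accuracy and the best band is reported.
#'
#' @param subjects list of subjects, each a list with `id`, `group`, and
#'   `epochs` (channels x samples matrices), e.g. from [simulate_eeg()].
#' @param fs sampling rate (Hz).
#' @param bands data.frame of band definitions (default [eeg_bands()]).
#' @param k number of microstate classes.
#' @param train_fraction,split_mode passed to the split.
#' @param classifier evaluated classifier (default `"svm"`).
#' @param seed integer master seed.
#' @param ... further arguments to [microstates()].
#' @return An `"ms_eval_report"` data.frame, one row per band, with the
#'   winning band in `attr(, "best_band")`.
#' @export
band_selection <- function(subjects, fs, bands = eeg_bands(), k = 4L,
                           train_fraction = 0.7,
                           split_mode = c("epoch", "subject"),
                           classifier = "svm", seed = 1L, ...) {
  split_mode <- match.arg(split_mode)
  seeds <- child_seeds(seed, nrow(bands))
  rows <- vector("list", nrow(bands))
  for (b in seq_len(nrow(bands))) {
    filt <- lapply(subjects, function(s) {
      s$epochs <- lapply(s$epochs, bandpass, low = bands$low[b],
                         high = bands$high[b], fs = fs)
      s
    })
    tab <- subject_feature_table(filt, fs, k = k, seed = seeds[[b]], ...)
    parts <- suppressWarnings(
      split_table(tab, train_fraction, seed = seeds[[b]], mode = split_mode))
    ev <- train_eval(parts$train, parts$test, classifier,
                     seed = seeds[[b]])
    rows[[b]] <- cbind(data.frame(band = bands$name[b]), ev)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "best_band") <- out$band[which.max(out$accuracy)]
  attr(out, "seed") <- seed
  class(out) <- c("ms_eval_report", class(out))
  out
}

# fit a microstate model on all subjects' epochs and return the per-epoch
# microstate feature table with provenance
subject_feature_table <- function(subjects, fs, k = 4L, seed = 1L, ...) {
  epochs <- unlist(lapply(subjects, `[[`, "epochs"), recursive = FALSE)
  subj <- unlist(lapply(subjects, function(s)
    rep(s$id, length(s$epochs))))
  grp <- unlist(lapply(subjects, function(s)
    rep(s$group, length(s$epochs))))
  fit <- microstates(epochs, k = k, fs = fs, subjects = subj, seed = seed,
                     ...)
  segs <- predict(fit, epochs)
  microstate_features(segs, fs, subject_id = subj, group = grp)
}

#' Compare the microstate and conventional feature sets
#'
#' Evaluates each classifier on both feature tables using one shared,
#' paired split (identical train/test rows for the two tables), so that the
#' feature set is the only varying factor.
#'
#' @param ms_table,conv_table feature tables describing the same epochs in
#'   the same row order.
#' @param classifiers classifiers to run (default all four).
#' @param train_fraction fraction of rows used for training.
#' @param split_mode `"epoch"` (replicates the common published design,
#'   leakage-prone) or `"subject"` (leakage-safe).
#' @param seed integer master seed; recorded in the report.
#' @return An `"ms_eval_report"` data.frame with `classifiers x 2` rows and
#'   the per-feature-set mean accuracies in `attr(, "mean_accuracy")`.
#' @export
feature_set_comparison <- function(ms_table, conv_table,
                                   classifiers = c("svm", "knn", "rf", "lr"),
                                   train_fraction = 0.7,
                                   split_mode = c("epoch", "subject"),
                                   seed = 1L) {
  split_mode <- match.arg(split_mode)
  if (nrow(ms_table) != nrow(conv_table))
    stop_eegms("feature tables have different row counts",
               "eegms_invalid_input")
  if (!identical(as.character(ms_table$group),
                 as.character(conv_table$group)))
    stop_eegms("feature tables disagree on group labels",
               "eegms_invalid_input")
  idx <- split_indices(ms_table, train_fraction, seed, split_mode)
  seeds <- child_seeds(seed, length(classifiers))
  rows <- list()
  for (ci in seq_along(classifiers)) {
    for (set in c("microstate", "conventional")) {
      tab <- if (set == "microstate") ms_table else conv_table
      ev <- train_eval(tab[idx$train, , drop = FALSE],
                       tab[idx$test, , drop = FALSE],
                       classifiers[ci], seed = seeds[[ci]])
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(feature_set = set), ev)[, c("classifier", "feature_set",
                                               "tp", "fp", "fn", "tn",
                                               "accuracy", "sensitivity",
                                               "specificity", "auc")]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "mean_accuracy") <- tapply(out$accuracy, out$feature_set, mean)
  attr(out, "split") <- list(mode = split_mode, seed = seed,
                             train_fraction = train_fraction)
  class(out) <- c("ms_eval_report", class(out))
  out
}

#' @export
print.ms_eval_report <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE) &
    names(df) %in% c("accuracy", "sensitivity", "specificity", "auc")
  df[num] <- lapply(df[num], function(v) sprintf("%.4f", v))
  print(df, row.names = FALSE)
  ma <- attr(x, "mean_accuracy")
  if (!is.null(ma))
    cat(sprintf("\nMean accuracy: %s\n",
                paste(sprintf("%s %.4f", names(ma), ma), collapse = ", ")))
  bb <- attr(x, "best_band")
  if (!is.null(bb)) cat(sprintf("\nBest band: %s\n", bb))
  sp <- attr(x, "split")
  if (!is.null(sp) && sp$mode == "epoch")
    cat("Note: epoch-mode split; epochs of one subject may occur on both",
        "sides (leakage-prone).\n")
  invisible(x)
}

#' Serialise an evaluation report to JSON
#'
#' @param report an `"ms_eval_report"`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
report_json <- function(report, path = NULL) {
  payload <- list(rows = as.data.frame(report),
                  mean_accuracy = as.list(attr(report, "mean_accuracy")),
                  best_band = attr(report, "best_band"),
                  split = attr(report, "split"))
  payload <- Filter(Negate(is.null), payload)
  js <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE,
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Render an evaluation report as a Markdown table
#'
#' @param report an `"ms_eval_report"`.
#' @return A character vector of Markdown lines.
#' @export
format_report_md <- function(report) {
  df <- as.data.frame(report)
  pct <- c("accuracy", "sensitivity", "specificity", "auc")
  for (p in intersect(pct, names(df))) df[[p]] <- sprintf("%.2f",
                                                          100 * df[[p]])
  hdr <- names(df)
  lines <- c(paste0("| ", paste(hdr, collapse = " | "), " |"),
             paste0("|", paste(rep("---", length(hdr)), collapse = "|"),
                    "|"),
             vapply(seq_len(nrow(df)), function(i)
               paste0("| ", paste(unlist(df[i, ]), collapse = " | "), " |"),
               ""))
  lines
}
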