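fake_seg <- function(labels, k = max(labels), correlations = NULL,
                     per_state_gev = NULL) {
  structure(list(labels = as.integer(labels),
                 state_labels = LETTERS[seq_len(k)],
                 correlations = correlations %||% rep(1, length(labels)),
                 per_state_gev = per_state_gev %||% numeric(k),
                 gev = sum(per_state_gev %||% numeric(k)), k = k),
            class = "ms_segmentation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("run-length encoding reproduces its input exactly", {
  r <- run_lengths(c(1L, 1L, 2L, 2L, 1L))
  expect_equal(r$values, c(1L, 2L, 1L))
  expect_equal(r$starts, c(1L, 3L, 5L))
  expect_equal(r$lengths, c(2L, 2L, 1L))
  expect_equal(run_lengths(rep(3L, 7))$lengths, 7L)
  set.seed(5)
  for (i in 1:10) {
    lab <- sample.int(4, 200, replace = TRUE)
    r <- run_lengths(lab)
    expect_identical(rep(r$values, r$lengths), lab)
  }
  expect_error(run_lengths(integer()), class = "eegms_invalid_input")
})

test_that("the AABBA toy sequence yields the hand-computed parameters", {
  # 5 samples at 10 Hz: A covers 3/5, two A runs of mean length 1.5 samples
  p <- microstate_parameters(fake_seg(c(1, 1, 2, 2, 1), k = 2), 10)
  expect_equal(p[["coverage_A"]], 0.6)
  expect_equal(p[["coverage_B"]], 0.4)
  expect_equal(p[["occurrence_A"]], 4)     # 2 runs in 0.5 s
  expect_equal(p[["occurrence_B"]], 2)
  expect_equal(p[["duration_A"]], 0.15)    # 1.5 samples at 10 Hz
  expect_equal(p[["duration_B"]], 0.2)
  expect_equal(p[["p_AB"]], 1)
  expect_equal(p[["p_BA"]], 1)
  expect_equal(p[["p_AA"]], 0)
  expect_equal(p[["p_BB"]], 0)
})

test_that("a constant epoch gives full coverage and empty transition rows", {
  p <- microstate_parameters(fake_seg(rep(1L, 50), k = 4), 10)
  expect_equal(p[["coverage_A"]], 1)
  expect_equal(p[["occurrence_A"]], 1 / 5)   # one run in a 5-s epoch
  expect_equal(p[["duration_A"]], 5)
  expect_equal(unname(p[c("coverage_B", "coverage_C", "coverage_D")]),
               rep(0, 3))
  expect_equal(sum(p[grepl("^p_", names(p))]), 0)
})

test_that("duration x occurrence = coverage holds for every state on random sequences", {
  set.seed(9)
  for (i in 1:20) {
    lab <- sample.int(4, 500, replace = TRUE)
    p <- microstate_parameters(fake_seg(lab, k = 4), 250)
    for (s in c("A", "B", "C", "D")) {
      expect_equal(p[[paste0("duration_", s)]] * p[[paste0("occurrence_", s)]],
                   p[[paste0("coverage_", s)]], tolerance = 1e-10)
    }
    expect_equal(sum(p[paste0("coverage_", c("A", "B", "C", "D"))]), 1,
                 tolerance = 1e-12)
    # transition rows are stochastic wherever the state has a successor
    for (s in c("A", "B", "C", "D")) {
      row <- p[paste0("p_", s, c("A", "B", "C", "D"))]
      expect_true(abs(sum(row) - 1) < 1e-10 || sum(row) == 0)
    }
  }
})

test_that("parameters computed from planted sequences equal the generative truth", {
  cfg <- tiny_cfg(n_subjects_per_group = 3L, n_epochs_per_subject = 5L)
  truth <- make_ground_truth(cfg)
  segs <- lapply(truth$subjects[["HC01"]]$states, fake_seg, k = 4)
  dyn <- eegms:::pooled_dynamics(segs, cfg$sampling_rate)
  # same sequences summarised by the independent rle-based truth summary
  ref <- eegms:::truth_summary(truth$subjects["HC01"], cfg)$HC
  expect_equal(unname(dyn$mean_duration), ref$mean_duration,
               tolerance = 1e-12)
  expect_equal(unname(dyn$occurrence), ref$occurrence, tolerance = 1e-12)
  expect_equal(unname(dyn$coverage), ref$coverage, tolerance = 1e-12)
  expect_equal(unname(dyn$transition_matrix), ref$transition_matrix,
               tolerance = 1e-12)
})

test_that("pooled estimates recover the planted dynamics at scale", {
  cfg <- sim_config(n_subjects_per_group = 1L, n_epochs_per_subject = 200L,
                    seed = 31)
  truth <- make_ground_truth(cfg)
  segs <- lapply(truth$subjects[["HC01"]]$states, fake_seg, k = 4)
  dyn <- eegms:::pooled_dynamics(segs, cfg$sampling_rate)
  expect_lt(max(abs(dyn$mean_duration / cfg$mean_duration - 1)), 0.15)
  expect_lt(max(abs(unname(dyn$transition_matrix) - cfg$transition_matrix)),
            0.05)
})

test_that("the feature table has the canonical 36 columns and round-trips through CSV", {
  set.seed(4)
  segs <- lapply(1:10, function(i) fake_seg(sample.int(4, 100, TRUE), k = 4,
                                            correlations = runif(100)))
  tab <- microstate_features(segs, 250, subject_id = "s1", group = "HC")
  expect_equal(dim(tab), c(10L, 38L))
  states <- c("A", "B", "C", "D")
  expected <- c("subject_id", "group",
                paste0("duration_", states), paste0("occurrence_", states),
                paste0("coverage_", states), paste0("mean_corr_", states),
                paste0("gev_", states),
                as.vector(t(outer(states, states,
                                  function(a, b) paste0("p_", a, b)))))
  expect_identical(names(tab), expected)
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- utils::read.csv(path, check.names = FALSE)
  expect_equal(back, tab, tolerance = 1e-12)
})

test_that("microstate features are invariant to polarity flips and amplitude scaling", {
  tm <- make_templates(4, 21, seed = 12)
  ts <- structure(list(maps = tm, labels = LETTERS[1:4], channels = NULL),
                  class = "ms_templates")
  lab <- rep(sample.int(4, 20, replace = TRUE), each = 10)
  epoch <- t(tm[lab, ]) * (1 + 0.2 * sin(seq_along(lab) / 7))
  base <- microstate_parameters(backfit(ts, epoch), 250)
  flip <- microstate_parameters(backfit(ts, -epoch), 250)
  scaled <- microstate_parameters(backfit(ts, 3.7 * epoch), 250)
  expect_equal(base, flip, tolerance = 1e-12)
  expect_equal(base, scaled, tolerance = 1e-12)
})
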