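test_that("GFP matches the per-sample definition and handles edge cases", {
  expect_equal(gfp(matrix(5, 4, 3)), rep(0, 3))
  expect_equal(gfp(matrix(c(1, -1), 2, 1)), 1)
  set.seed(1)
  ep <- matrix(rnorm(21 * 100), 21)
  expect_equal(gfp(ep), gfp_oracle(ep), tolerance = 1e-12)
  expect_error(gfp(matrix(1, 1, 10)), class = "eegms_invalid_input")
})

test_that("GFP smoothing finds bump apices and ignores flat series", {
  expect_length(pick_gfp_peaks(rep(2, 200))$peaks, 0L)
  tri <- c(seq(0, 1, length.out = 100), seq(1, 0, length.out = 100)[-1])
  pk <- pick_gfp_peaks(tri, window = 20)
  expect_length(pk$peaks, 1L)
  expect_lte(abs(pk$peaks - 100L), 1L)
  x <- seq_len(220)
  two <- exp(-(x - 60)^2 / 200) + exp(-(x - 160)^2 / 200)
  pk2 <- pick_gfp_peaks(two, window = 50)
  expect_length(pk2$peaks, 2L)
  expect_lte(max(abs(sort(pk2$peaks) - c(60L, 160L))), 2L)
  expect_error(pick_gfp_peaks(rep(1, 10), window = 50),
               class = "eegms_invalid_input")
})

test_that("modified K-means recovers planted templates from sign-flipped copies", {
  tm <- make_templates(2, 8, seed = 4)
  idx <- rep(1:2, each = 10)
  signs <- rep(c(1, -1), 10)
  maps <- tm[idx, ] * signs
  fit <- microstate_kmeans(maps, 2, n_init = 10, seed = 1)
  r <- abs(fit$templates %*% t(tm))
  expect_gte(min(apply(r, 2, max)), 0.999)
  expect_gte(fit$gev, 0.999)
})

test_that("K equal to the number of maps fits perfectly", {
  set.seed(2)
  maps <- matrix(rnorm(5 * 8), 5)
  fit <- microstate_kmeans(maps, 5, n_init = 20, seed = 1)
  expect_equal(fit$gev, 1, tolerance = 1e-6)
})

test_that("clustering is polarity invariant and GEV ascends monotonically", {
  set.seed(3)
  maps <- matrix(rnorm(30 * 10), 30)
  f1 <- microstate_kmeans(maps, 3, n_init = 10, seed = 7)
  f2 <- microstate_kmeans(-maps, 3, n_init = 10, seed = 7)
  expect_equal(f1$gev, f2$gev, tolerance = 1e-12)
  expect_equal(abs(f1$templates %*% t(f2$templates))[cbind(1:3, 1:3)],
               rep(1, 3), tolerance = 1e-9)
  for (s in 1:5) {
    set.seed(s)
    m <- matrix(rnorm(40 * 12), 40)
    tr <- microstate_kmeans(m, 4, n_init = 5, seed = s)$gev_trace
    expect_true(all(diff(tr) >= -1e-10))
    expect_true(all(tr >= 0 & tr <= 1 + 1e-12))
  }
  expect_error(microstate_kmeans(maps[1:2, ], 3),
               class = "eegms_invalid_input")
  expect_error(microstate_kmeans(matrix(0, 5, 4), 2),
               class = "eegms_degenerate_input")
})

test_that("K-means at K=2 attains the exhaustive 2-partition optimum", {
  for (s in 1:3) {
    set.seed(s)
    maps <- matrix(rnorm(10 * 6), 10)
    fit <- microstate_kmeans(maps, 2, n_init = 50, seed = s)
    expect_equal(fit$gev, kmeans2_oracle(maps), tolerance = 1e-6)
  }
})

test_that("two-level clustering recovers templates shared across subjects", {
  tm <- make_templates(4, 21, seed = 9)
  per_subject <- lapply(1:3, function(s) {
    set.seed(s)
    idx <- sample(rep(1:4, each = 8))
    tm[idx, ] * sample(c(-1, 1), 32, replace = TRUE)
  })
  out <- two_level_cluster(per_subject, 4, n_init = 10, seed = 2)
  r <- abs(out$templates %*% t(tm))
  expect_gte(min(apply(r, 2, max)), 0.99)
  one <- two_level_cluster(per_subject[1], 4, n_init = 10, seed = 2)
  sub <- microstate_kmeans(per_subject[[1]], 4, n_init = 10, seed = 3)
  match <- order_templates(one$templates, sub$templates)
  expect_gte(min(attr(match, "matching")$correlation), 0.999)
  expect_identical(two_level_cluster(per_subject, 4, n_init = 5, seed = 5),
                   two_level_cluster(per_subject, 4, n_init = 5, seed = 5))
})

test_that("template ordering undoes permutations, ignores polarity, and is assignment-optimal", {
  ref <- canonical_templates(eegms:::default_channel_names(21))
  perm <- c(3, 1, 4, 2)
  shuffled <- ref$maps[perm, ]
  out <- order_templates(shuffled, ref)
  expect_equal(unname(out$maps), unname(ref$maps), tolerance = 1e-12)
  expect_identical(out$labels, c("A", "B", "C", "D"))
  flipped <- shuffled * c(-1, 1, -1, 1)
  out2 <- order_templates(flipped, ref)
  expect_equal(unname(out2$maps), unname(ref$maps), tolerance = 1e-12)
  for (s in 1:4) {
    rand <- make_templates(4, 21, seed = s + 100)
    o <- order_templates(rand, ref)
    score <- abs((rand - rowMeans(rand)) %*% t(ref$maps))
    hung_total <- sum(attr(o, "matching")$correlation)
    oracle <- assignment_oracle(t(score))
    expect_equal(hung_total, oracle$value, tolerance = 1e-10)
    expect_gte(hung_total + 1e-10, sum(diag(score)))
  }
  expect_error(order_templates(ref$maps[, 1:10], ref),
               class = "eegms_dimension_error")
})

test_that("backfitting exact template frames gives GEV 1 and is polarity invariant", {
  tm <- make_templates(4, 21, seed = 6)
  ts <- structure(list(maps = tm, labels = LETTERS[1:4],
                       channels = eegms:::default_channel_names(21)),
                  class = "ms_templates")
  lab_true <- rep(rep(1:4, each = 25), 4)
  amp <- 1 + 0.5 * sin(seq_along(lab_true) / 30)
  epoch <- t(tm[lab_true, ] * amp)
  seg <- backfit(ts, epoch, min_duration = 3)
  expect_equal(seg$gev, 1, tolerance = 1e-10)
  expect_identical(seg$labels, lab_true)
  expect_equal(sum(seg$per_state_gev), seg$gev, tolerance = 1e-10)
  neg <- backfit(ts, -epoch, min_duration = 3)
  expect_identical(neg$labels, seg$labels)
  expect_equal(neg$gev, seg$gev, tolerance = 1e-12)
})

test_that("flat samples inherit the previous label instead of failing", {
  tm <- make_templates(2, 6, seed = 2)
  ts <- structure(list(maps = tm, labels = c("A", "B"), channels = NULL),
                  class = "ms_templates")
  epoch <- t(tm[c(1, 1, 1, 1, 2, 2, 2, 2), ])
  epoch[, 3] <- 0
  seg <- backfit(ts, epoch, min_duration = 1)
  expect_identical(seg$labels, c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L))
  all_flat <- matrix(0, 6, 10)
  expect_error(backfit(ts, all_flat), class = "eegms_degenerate_input")
})

test_that("temporal smoothing removes runs shorter than the minimum duration", {
  tm <- make_templates(2, 8, seed = 3)
  ts <- structure(list(maps = tm, labels = c("A", "B"), channels = NULL),
                  class = "ms_templates")
  lab <- c(rep(1, 20), 2, rep(1, 20), rep(2, 20))
  epoch <- t(tm[lab, ])
  seg <- backfit(ts, epoch, min_duration = 3)
  runs <- run_lengths(seg$labels)
  expect_true(all(runs$lengths >= 3))
  expect_identical(seg$labels[21], 1L)   # the singleton was absorbed
})

test_that("noiseless planted sequences are recovered almost exactly", {
  cfg <- tiny_cfg(snr = Inf, n_subjects_per_group = 1L,
                  n_epochs_per_subject = 5L)
  hc <- hc_epochs(cfg)
  ts <- truth_templates(hc$truth)
  agree <- vapply(seq_along(hc$epochs), function(i)
    label_agreement(backfit(ts, hc$epochs[[i]], min_duration = 3)$labels,
                    hc$states[[i]]), 0)
  expect_gte(mean(agree), 0.99)
})

test_that("GMD is zero for polarity-flipped copies and sqrt(2) for orthogonal maps", {
  u <- c(1, -1, 2, -2)
  expect_equal(gmd(u, 3 * u), 0)
  expect_equal(gmd(u, -u), 0)
  a <- c(1, -1, 0, 0); b <- c(0, 0, 1, -1)
  expect_equal(gmd(a, b), sqrt(2), tolerance = 1e-12)
  expect_error(gmd(a, b[1:3]), class = "eegms_dimension_error")
  expect_error(gmd(a, rep(1, 4)), class = "eegms_degenerate_input")
})

test_that("the fitted model carries labelled templates and sensible methods", {
  cfg <- tiny_cfg(n_subjects_per_group = 2L, n_epochs_per_subject = 4L)
  hc <- hc_epochs(cfg)
  fit <- microstates(hc$epochs, k = 4, fs = 250, subjects = hc$subjects,
                     n_init = 10, seed = 5)
  expect_s3_class(fit, "microstates")
  expect_identical(rownames(coef(fit)), c("A", "B", "C", "D"))
  expect_equal(rowSums(coef(fit)^2), rep(1, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_true(fit$gev > 0.5 && fit$gev <= 1)
  expect_output(print(fit), "Microstate model")
  expect_output(print(summary(fit)), "transition")
  seg <- predict(fit, hc$epochs[[1]])
  expect_s3_class(seg, "ms_segmentation")
  sim <- simulate(fit, nsim = 2, seed = 3)
  expect_length(sim, 2L)
  expect_identical(dim(sim[[1]]), dim(hc$epochs[[1]]))
  pdf(NULL)
  expect_no_error(plot(fit))
  dev.off()
})

test_that("the whole segmentation pipeline is invariant to a global polarity flip", {
  cfg <- tiny_cfg(n_subjects_per_group = 1L, n_epochs_per_subject = 4L)
  hc <- hc_epochs(cfg)
  neg <- lapply(hc$epochs, function(e) -e)
  f1 <- microstates(hc$epochs, k = 4, fs = 250, n_init = 10, seed = 8)
  f2 <- microstates(neg, k = 4, fs = 250, n_init = 10, seed = 8)
  expect_equal(f1$gev, f2$gev, tolerance = 1e-10)
  s1 <- predict(f1, hc$epochs)
  s2 <- predict(f2, neg)
  for (i in seq_along(s1)) {
    expect_identical(s1[[i]]$labels, s2[[i]]$labels)
    expect_equal(s1[[i]]$gev, s2[[i]]$gev, tolerance = 1e-10)
  }
  ft1 <- microstate_features(s1, 250)
  ft2 <- microstate_features(s2, 250)
  expect_equal(ft1, ft2, tolerance = 1e-10)
})
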