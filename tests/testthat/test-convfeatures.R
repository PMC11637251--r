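test_that("linear features match hand arithmetic and closed forms", {
  lf <- linear_features(c(1, 2, 3), fs = 10)
  expect_equal(lf[["mean"]], 2)
  expect_equal(lf[["median"]], 2)
  expect_equal(lf[["variance"]], 1)        # n-1 divisor
  expect_equal(lf[["sd"]], 1)
  expect_equal(lf[["rms"]], sqrt(14 / 3))
  fs <- 250
  t <- seq(0, 10, by = 1 / fs)[-1]         # 10 s, many full cycles
  s <- 3.2 * sin(2 * pi * 8 * t)
  expect_lt(abs(linear_features(s, fs)[["rms"]] / (3.2 / sqrt(2)) - 1),
            0.01)
  set.seed(1)
  g <- rnorm(10000)
  lg <- linear_features(g, fs)
  expect_lt(abs(lg[["skewness"]]), 0.1)
  expect_lt(abs(lg[["kurtosis"]] - 3), 0.2)
})

test_that("rms^2 equals population variance plus squared mean", {
  set.seed(2)
  for (i in 1:10) {
    x <- rnorm(500, mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    lf <- linear_features(x, 100)
    pop_var <- mean((x - mean(x))^2)
    expect_equal(lf[["rms"]]^2, pop_var + lf[["mean"]]^2, tolerance = 1e-8)
    expect_equal(lf[["variance"]], lf[["sd"]]^2, tolerance = 1e-10)
  }
})

test_that("spectral flatness separates white noise from a pure tone", {
  set.seed(3)
  w <- linear_features(rnorm(8192), 250)
  expect_gte(w[["spectral_flatness"]], 0.9)
  expect_lte(w[["spectral_flatness"]], 1)
  t <- seq_len(8192) / 250
  s <- linear_features(sin(2 * pi * 10 * t), 250)
  expect_lt(s[["spectral_flatness"]], 0.1)
  expect_gt(s[["spectral_flatness"]], 0)
})

test_that("a constant signal yields zero Hjorth parameters with a warning", {
  expect_warning(lf <- linear_features(rep(2, 100), 50), "constant")
  expect_equal(lf[["hjorth_mobility"]], 0)
  expect_equal(lf[["hjorth_complexity"]], 0)
})

test_that("Petrosian fractal dimension follows its defining formula", {
  expect_equal(pfd(seq_len(50)), 1)                       # monotone
  alt <- rep(c(1, -1), 50)
  expect_equal(pfd(alt),
               log10(100) / (log10(100) + log10(100 / (100 + 0.4 * 98))))
  set.seed(4)
  for (i in 1:5) {
    x <- rnorm(100)
    d <- diff(x)
    if (sum(d[-1] * d[-99] < 0) > 0) expect_gt(pfd(x), 1)
  }
  expect_error(pfd(1), class = "eegms_invalid_input")
})

test_that("Lempel-Ziv complexity matches the hand parsing of a periodic string", {
  alt <- rep(c(1, -1), 50)                 # binarises to 1010...
  expect_equal(lzc(alt), 3 * log2(100) / 100)   # phrases: 1 | 0 | 1010...
  set.seed(5)
  rnd <- rnorm(100)
  expect_gt(lzc(rnd), lzc(alt))
  expect_warning(cz <- lzc(rep(1, 64)), "convention")
  expect_equal(cz, log2(64) / 64)
})

test_that("entropies vanish on constant signals and order periodic below shuffled", {
  const <- rep(1.3, 100)
  expect_equal(apen(const), 0)
  expect_equal(sampen(const), 0)
  expect_equal(fuzzen(const), 0)
  per <- rep(c(1, 2), 100)
  set.seed(6)
  shuf <- sample(per)
  expect_lt(apen(per), apen(shuf))
  expect_lt(sampen(per), sampen(shuf))
  expect_lt(fuzzen(per), fuzzen(shuf))
  expect_lt(lzc(per), lzc(shuf))
  expect_error(apen(c(1, 2, 3)), class = "eegms_invalid_input")
})

test_that("entropy implementations agree exactly with brute-force oracles", {
  cfg <- entropy_config()
  set.seed(7)
  for (i in 1:5) {
    x <- runif(150)
    r_abs <- cfg$r * sd(x)
    expect_equal(apen(x, cfg), apen_oracle(x, cfg$m, r_abs),
                 tolerance = 1e-12)
    expect_equal(sampen(x, cfg), sampen_oracle(x, cfg$m, r_abs),
                 tolerance = 1e-12)
    expect_equal(fuzzen(x, cfg), fuzzen_oracle(x, cfg$m, r_abs, cfg$fuzz_n),
                 tolerance = 1e-12)
  }
  # strict ApEn inequality mode also matches its oracle
  strict_cfg <- entropy_config(strict = TRUE)
  x <- runif(120)
  expect_equal(apen(x, strict_cfg),
               apen_oracle(x, 2, 0.2 * sd(x), strict = TRUE),
               tolerance = 1e-12)
})

test_that("sample entropy is scale invariant and NA when no templates match", {
  set.seed(8)
  x <- rnorm(200)
  expect_equal(sampen(x), sampen(17.3 * x), tolerance = 1e-12)
  spiky <- c(0, 1e3, 1, 2e3, 2, 3e3, 3, 4e3, 4, 5e3)
  expect_warning(v <- sampen(spiky, entropy_config(r = 1e-6)), "undefined")
  expect_true(is.na(v))
})

test_that("fuzzy entropy is continuous in the tolerance", {
  set.seed(9)
  x <- rnorm(200)
  f1 <- fuzzen(x, entropy_config(r = 0.2))
  f2 <- fuzzen(x, entropy_config(r = 0.2 + 1e-6))
  expect_lt(abs(f1 - f2), 1e-3)
})

test_that("the conventional vector averages channels and keeps canonical order", {
  set.seed(10)
  ch <- rnorm(300)
  ep <- rbind(ch, ch, ch)
  v <- conventional_vector(ep, 100)
  expect_equal(v, c(linear_features(ch, 100), pfd = pfd(ch), lzc = lzc(ch),
                    apen = apen(ch), sampen = sampen(ch),
                    fuzzen = fuzzen(ch)), tolerance = 1e-12)
  canonical <- c("mean", "median", "rms", "sd", "variance", "mean_psd",
                 "spectral_flatness", "hjorth_mobility", "hjorth_complexity",
                 "skewness", "kurtosis", "pfd", "lzc", "apen", "sampen",
                 "fuzzen")
  expect_identical(names(v), canonical)
  eps <- lapply(1:4, function(i) matrix(rnorm(3 * 300), 3))
  tab <- conventional_features(eps, fs = 100, group = "HC")
  expect_equal(dim(tab), c(4L, 18L))
  expect_identical(names(tab), c("subject_id", "group", canonical))
  per_ch <- conventional_vector(ep, 100, aggregate = "channel")
  expect_equal(dim(per_ch), c(3L, 16L))
})
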