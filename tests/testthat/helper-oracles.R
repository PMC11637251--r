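# Independent brute-force oracles, written directly from the defining
# formulas. They deliberately share no code with the package internals.

gfp_oracle <- function(epoch) {
  out <- numeric(ncol(epoch))
  for (t in seq_len(ncol(epoch))) {
    u <- epoch[, t]
    ub <- mean(u)
    out[t] <- sqrt(sum((u - ub)^2) / length(u))
  }
  out
}

cheb_oracle <- function(x, i, j, m) max(abs(x[i + 0:(m - 1)] - x[j + 0:(m - 1)]))

apen_oracle <- function(x, m, r_abs, strict = FALSE) {
  phi <- function(mm) {
    nw <- length(x) - mm + 1
    acc <- 0
    for (i in seq_len(nw)) {
      cnt <- 0
      for (j in seq_len(nw)) {
        d <- cheb_oracle(x, i, j, mm)
        if (if (strict) d < r_abs else d <= r_abs) cnt <- cnt + 1
      }
      acc <- acc + log(cnt / nw)
    }
    acc / nw
  }
  phi(m) - phi(m + 1)
}

sampen_oracle <- function(x, m, r_abs) {
  nw <- length(x) - m
  a <- b <- 0
  for (i in seq_len(nw - 1)) {
    for (j in (i + 1):nw) {
      if (cheb_oracle(x, i, j, m) <= r_abs) {
        b <- b + 1
        if (abs(x[i + m] - x[j + m]) <= r_abs) a <- a + 1
      }
    }
  }
  if (a == 0 || b == 0) return(NA_real_)
  -log(a / b)
}

fuzzen_oracle <- function(x, m, r_abs, nfuzz) {
  phi <- function(mm) {
    nw <- length(x) - m
    w <- t(sapply(seq_len(nw), function(i) {
      v <- x[i + 0:(mm - 1)]
      v - mean(v)
    }))
    acc <- 0
    for (i in seq_len(nw)) {
      s <- 0
      for (j in seq_len(nw)) {
        if (j == i) next
        d <- max(abs(w[i, ] - w[j, ]))
        s <- s + exp(-d^nfuzz / r_abs)
      }
      acc <- acc + s / (nw - 1)
    }
    acc / nw
  }
  log(phi(m)) - log(phi(m + 1))
}

# Exhaustive search over all 2-partitions of M maps: for each partition the
# optimal polarity-invariant template is the dominant right singular vector,
# so the attainable GEV is the sum of leading squared singular values over
# the partition, divided by the total squared norm.
kmeans2_oracle <- function(maps) {
  xc <- maps - rowMeans(maps)
  m <- nrow(xc)
  denom <- sum(xc^2)
  best <- 0
  for (code in 1:(2^(m - 1) - 1)) {
    grp <- as.logical(bitwAnd(code, 2^(0:(m - 1))))
    if (!any(grp) || all(grp)) next
    val <- sum(vapply(list(which(grp), which(!grp)), function(idx) {
      svd(xc[idx, , drop = FALSE], nu = 0, nv = 0)$d[1]^2
    }, 0))
    best <- max(best, val)
  }
  best / denom
}

# All-permutations optimum for template matching (K small).
assignment_oracle <- function(score) {
  k <- nrow(score)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      out <- c(out, lapply(perms(v[-i]), function(p) c(v[i], p)))
    out
  }
  best <- -Inf
  best_p <- NULL
  for (p in perms(seq_len(k))) {
    val <- sum(score[cbind(p, seq_len(k))])
    if (val > best) { best <- val; best_p <- p }
  }
  list(value = best, permutation = best_p)
}
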