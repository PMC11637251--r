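#' @useDynLib eegms, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rnorm runif rgeom sd var predict fft dnorm
#' @importFrom stats simulate setNames coef quantile binomial
#' @importFrom utils read.delim write.csv head
NULL

stop_eegms <- function(msg, class) {
  stop(structure(class = c(class, "eegms_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Evaluate expr under a temporary RNG state seeded with `seed`; restores the
# caller's .Random.seed afterwards so library code never disturbs user RNG.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stream of child seeds from one master seed (kept < 2^31).
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a
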