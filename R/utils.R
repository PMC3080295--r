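# Internal helpers shared across the package.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random state. `seed = NULL` leaves the RNG alone.
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Sample standard deviation of each matrix row (denominator n - 1).
.row_sd <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

.is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

# One-sample two-sided t-test against mu = 0 that tolerates degenerate
# inputs: zero spread with zero mean gives t = 0, p = 1; zero spread with a
# non-zero mean gives t = +/-Inf, p = 0.
.t_test_zero <- function(x) {
  n <- length(x)
  if (n < 2L) {
    return(list(t = NA_real_, p = NA_real_, mean = mean(x), n = n))
  }
  m <- mean(x)
  s <- stats::sd(x)
  if (s == 0) {
    tt <- if (m == 0) 0 else sign(m) * Inf
    pp <- if (m == 0) 1 else 0
  } else {
    tt <- m / (s / sqrt(n))
    pp <- 2 * stats::pt(-abs(tt), df = n - 1)
  }
  list(t = tt, p = pp, mean = m, n = n)
}
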