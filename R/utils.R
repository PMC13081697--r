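# internal helpers shared across modules

# z-score a vector; errors on zero variance when strict
zscore <- function(x, label = "vector") {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    stop("cannot standardise constant ", label, call. = FALSE)
  (x - mean(x)) / s
}

# derive a stream-specific 32-bit seed from a base seed
deriveSeed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + stream * 9973) %% 2147483647L)
}

# run expr with a local RNG state seeded by `seed` (NULL = leave RNG alone)
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# multivariate normal draws via Cholesky: n x d matrix
rmvnormChol <- function(n, sigma) {
  d <- nrow(sigma)
  L <- chol(sigma)
  matrix(stats::rnorm(n * d), n, d) %*% L
}

stopifnotScalar <- function(x, name, positive = TRUE) {
  if (length(x) != 1 || !is.finite(x) || (positive && x <= 0))
    stop(name, " must be a single ", if (positive) "positive " else "",
         "finite number", call. = FALSE)
  invisible(x)
}
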