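# Discrete prolate spheroidal (Slepian) sequences via the symmetric
# tridiagonal eigenproblem (Slepian 1978): the tapers are eigenvectors of
# the matrix with diagonal ((N-1)/2 - t)^2 cos(2 pi W), t = 0..N-1, and
# off-diagonal t (N - t) / 2, taken at the k largest eigenvalues. This
# yields the same sequences as the classical concentration problem but is
# numerically stable for the window lengths used in spectral estimation.

dpssCache <- new.env(parent = emptyenv())

#' DPSS (Slepian) tapers
#'
#' Computes the first `k` discrete prolate spheroidal sequences of length
#' `n` at dimensionless time-half-bandwidth product `nw`. Tapers are
#' normalised to unit energy. Sign convention: tapers with nonzero sum are
#' made to sum positive; antisymmetric tapers start positive.
#'
#' @param n taper length in samples.
#' @param nw time-half-bandwidth product (dimensionless, e.g. 4).
#' @param k number of tapers; default `2 * nw - 1`, the standard rule for
#'   well-concentrated tapers.
#' @return n x k matrix, one taper per column, ordered by decreasing
#'   spectral concentration.
#' @examples
#' v <- dpssTapers(500, 4)
#' ncol(v)            # 7 tapers under the 2 * nw - 1 rule
#' colSums(v^2)       # unit energy
#' @export
dpssTapers <- function(n, nw, k = 2 * nw - 1) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (nw <= 0 || nw >= n / 2) stop("nw must lie in (0, n/2)")
  key <- paste(n, nw, k, sep = "_")
  if (!is.null(dpssCache[[key]])) return(dpssCache[[key]])
  W <- nw / n
  t0 <- seq_len(n) - 1
  dg <- ((n - 1) / 2 - t0)^2 * cos(2 * pi * W)
  od <- seq_len(n - 1) * (n - seq_len(n - 1)) / 2
  M <- matrix(0, n, n)
  diag(M) <- dg
  M[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- od
  M[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- od
  e <- eigen(M, symmetric = TRUE)
  v <- e$vectors[, seq_len(k), drop = FALSE]
  # unit energy and deterministic sign
  for (j in seq_len(k)) {
    v[, j] <- v[, j] / sqrt(sum(v[, j]^2))
    s <- sum(v[, j])
    if (abs(s) > 1e-8) {
      if (s < 0) v[, j] <- -v[, j]
    } else {
      i <- which(abs(v[, j]) > 1e-12)[1]
      if (v[i, j] < 0) v[, j] <- -v[, j]
    }
  }
  dpssCache[[key]] <- v
  v
}
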