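#' Time-delay embedding
#'
#' Augments each parcel with time-lagged copies of itself so that the
#' covariance of the embedded data captures spectral structure. With L
#' lags each side, a recording of P parcels becomes `P * (2L + 1)`
#' channels; the 2L boundary samples are trimmed (not zero-padded) to
#' avoid artificial edge covariance. Channels are ordered parcel-major
#' with lags running from -L to +L: output channel `(p - 1) * (2L + 1) +
#' (l + L + 1)` at sample t holds parcel p at input sample `t + l`.
#'
#' @param ts a [ParcelTimeSeries-class] or parcels x samples matrix.
#' @param nLagsEachSide L, the number of lags on each side (default 7,
#'   a +/-28 ms window at 250 Hz).
#' @return embedded matrix, `P * (2L + 1)` channels x `samples - 2L`.
#' @examples
#' tdeChannelCount(52, 7)  # 780
#' @export
tdeEmbed <- function(ts, nLagsEachSide = 7) {
  x <- if (is(ts, "ParcelTimeSeries")) ts@data else as.matrix(ts)
  L <- as.integer(nLagsEachSide)
  if (L < 0) stop("nLagsEachSide must be >= 0")
  P <- nrow(x); T <- ncol(x)
  if (T <= 2 * L)
    stop("input too short: need more than ", 2 * L, " samples, got ", T)
  if (L == 0) return(x)
  Tout <- T - 2L * L
  out <- matrix(0, P * (2L * L + 1L), Tout)
  row <- 0L
  for (p in seq_len(P)) {
    for (l in -L:L) {
      row <- row + 1L
      out[row, ] <- x[p, (L + 1L + l):(T - L + l)]
    }
  }
  out
}

#' Embedded channel count
#'
#' @param nParcels number of parcels.
#' @param nLagsEachSide lags each side.
#' @return `nParcels * (2 * nLagsEachSide + 1)`.
#' @export
tdeChannelCount <- function(nParcels, nLagsEachSide) {
  as.integer(nParcels * (2 * nLagsEachSide + 1))
}

#' Group-level PCA basis from multiple subjects
#'
#' Estimates a principal-component basis of the (embedded) channels from
#' all subjects jointly. The covariance is accumulated subject-by-subject
#' (bounded memory) and is defined to equal the covariance of the
#' concatenated data. Component signs follow a fixed convention (the
#' largest-magnitude loading of each component is made positive) so
#' repeated runs are comparable.
#'
#' @param data list of channels x samples matrices (one per subject).
#' @param nComponents number of components to retain.
#' @return list of class `GroupPCABasis` with `components`
#'   (channels x nComponents, orthonormal columns), `means` (per-channel
#'   mean over pooled samples), `explainedVariance` (fraction per
#'   retained component, nonincreasing) and `totalSamples`.
#' @export
fitGroupPCA <- function(data, nComponents) {
  if (!length(data)) stop("data must be a nonempty list")
  d <- nrow(data[[1]])
  if (nComponents < 1 || nComponents > d)
    stop("nComponents must lie in 1..", d)
  S <- matrix(0, d, d)
  m <- numeric(d)
  n <- 0
  for (x in data) {
    if (nrow(x) != d) stop("all subjects must share the channel count")
    S <- S + tcrossprod(x)
    m <- m + rowSums(x)
    n <- n + ncol(x)
  }
  if (n < d)
    stop("total samples (", n, ") must be at least the channel count (", d, ")")
  mu <- m / n
  cov <- (S - n * tcrossprod(mu)) / (n - 1)
  e <- eigen(cov, symmetric = TRUE)
  ev <- pmax(e$values, 0)
  V <- e$vectors[, seq_len(nComponents), drop = FALSE]
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  structure(list(components = V, means = mu,
                 explainedVariance = ev[seq_len(nComponents)] / sum(ev),
                 totalSamples = n),
            class = "GroupPCABasis")
}

#' Project data onto a group PCA basis
#'
#' @param x channels x samples matrix.
#' @param basis a `GroupPCABasis` from [fitGroupPCA()].
#' @return components x samples matrix of scores.
#' @export
projectPCA <- function(x, basis) {
  stopifnot(inherits(basis, "GroupPCABasis"))
  crossprod(basis$components, x - basis$means)
}

#' Reconstruct channel data from PCA scores
#'
#' @param scores components x samples matrix.
#' @param basis a `GroupPCABasis`.
#' @return channels x samples matrix.
#' @export
backprojectPCA <- function(scores, basis) {
  basis$components %*% scores + basis$means
}

#' Temporal standardisation (z-scoring per channel)
#'
#' Subtracts each channel's temporal mean and divides by its standard
#' deviation, leaving every channel with mean 0 and unit variance.
#'
#' @param x channels x samples matrix, or a [ParcelTimeSeries-class]
#'   (returned with standardised data).
#' @return same type as the input.
#' @export
standardize <- function(x) {
  if (is(x, "ParcelTimeSeries")) {
    x@data <- standardizeRows(x@data)
    return(x)
  }
  standardizeRows(as.matrix(x))
}

standardizeRows <- function(x) {
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad))
    stop("cannot standardise constant channel ", bad[1])
  (x - mu) / s
}

#' Prepare subject data for HMM training
#'
#' The full data-preparation chain: time-delay embedding per subject,
#' group-level PCA across subjects, then temporal standardisation of the
#' projected data.
#'
#' @param tsList list of [ParcelTimeSeries-class] (or matrices).
#' @param nLagsEachSide lags each side (default 7).
#' @param nComponents retained PCA components (default 120, capped at the
#'   embedded channel count).
#' @return list with `prepared` (list of components x samples matrices),
#'   `basis` (the [fitGroupPCA()] result) and `nLagsEachSide`.
#' @export
prepareTrainingData <- function(tsList, nLagsEachSide = 7,
                                nComponents = 120) {
  embedded <- lapply(tsList, tdeEmbed, nLagsEachSide = nLagsEachSide)
  d <- nrow(embedded[[1]])
  nComponents <- min(nComponents, d)
  basis <- fitGroupPCA(embedded, nComponents)
  prepared <- lapply(embedded, function(x) standardizeRows(projectPCA(x, basis)))
  list(prepared = prepared, basis = basis, nLagsEachSide = nLagsEachSide)
}
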