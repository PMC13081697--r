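#' Multitaper configuration
#'
#' Settings of the multitaper power/cross-spectral estimator. Defaults
#' match common resting-state MEG practice: 2 s windows, 0% overlap,
#' time-half-bandwidth product 4 and 7 DPSS tapers (the `2 * nw - 1`
#' rule), retaining 1-45 Hz for time-averaged analysis (state spectra use
#' 1-80 Hz instead).
#'
#' @param windowLengthS window length in seconds (frequency resolution is
#'   its reciprocal).
#' @param overlapFraction fraction of window overlap in `[0, 1)`. A
#'   trailing partial window is dropped, not zero-padded.
#' @param timeHalfBandwidth dimensionless time-half-bandwidth product NW.
#' @param nTapers number of DPSS tapers; default `2 * NW - 1`.
#' @param freqRangeHz retained frequency range in Hz (inclusive bounds).
#' @return list of class `SpectralConfig`.
#' @export
spectralConfig <- function(windowLengthS = 2, overlapFraction = 0,
                           timeHalfBandwidth = 4,
                           nTapers = 2 * timeHalfBandwidth - 1,
                           freqRangeHz = c(1, 45)) {
  if (windowLengthS <= 0) stop("windowLengthS must be positive")
  if (overlapFraction < 0 || overlapFraction >= 1)
    stop("overlapFraction must lie in [0, 1)")
  if (nTapers < 1) stop("nTapers must be >= 1")
  if (length(freqRangeHz) != 2 || freqRangeHz[1] >= freqRangeHz[2])
    stop("freqRangeHz must be an increasing pair")
  structure(list(windowLengthS = windowLengthS,
                 overlapFraction = overlapFraction,
                 timeHalfBandwidth = timeHalfBandwidth,
                 nTapers = as.integer(nTapers), freqRangeHz = freqRangeHz),
            class = "SpectralConfig")
}

#' Multitaper PSD and CSD estimation
#'
#' Averages tapered periodograms over DPSS tapers and non-overlapping (or
#' overlapping) windows to estimate each parcel's power spectral density
#' and every parcel pair's cross-spectral density. Densities are
#' one-sided, normalised so that the PSD integrated over frequency
#' approximates the signal variance. Parcel time courses are z-scored
#' before estimation by default (disable for pre-masked data in dual
#' estimation, where rescaling would distort the occupancy accounting).
#'
#' @param ts a [ParcelTimeSeries-class], or a parcels x samples matrix if
#'   `fs` is given.
#' @param cfg a [spectralConfig()].
#' @param standardize z-score each parcel before estimation (default TRUE).
#' @param fs sampling rate, required when `ts` is a bare matrix.
#' @return a [SpectralEstimate-class].
#' @examples
#' ts <- parcelTimeSeries(matrix(rnorm(2 * 5000), 2), samplingRate = 250)
#' est <- multitaperSpectra(ts)
#' dim(specPsd(est))
#' @export
multitaperSpectra <- function(ts, cfg = spectralConfig(), standardize = TRUE,
                              fs = NULL) {
  if (is(ts, "ParcelTimeSeries")) {
    x <- ts@data
    fs <- ts@samplingRate
  } else {
    if (is.null(fs)) stop("fs required when ts is a matrix")
    x <- as.matrix(ts)
  }
  if (anyNA(x)) stop("input contains NaN/NA values")
  nP <- nrow(x); T <- ncol(x)
  n <- round(cfg$windowLengthS * fs)
  if (T < n)
    stop("recording shorter than one window (", T, " < ", n, " samples)")
  if (standardize) x <- standardizeRows(x)

  step <- max(1L, round(n * (1 - cfg$overlapFraction)))
  starts <- seq(1L, T - n + 1L, by = step)
  tapers <- dpssTapers(n, cfg$timeHalfBandwidth, cfg$nTapers)
  nHalf <- floor(n / 2) + 1L
  freqsAll <- (seq_len(nHalf) - 1) * fs / n
  keep <- which(freqsAll >= cfg$freqRangeHz[1] & freqsAll <= cfg$freqRangeHz[2])
  if (!length(keep)) stop("freqRangeHz retains no frequency bins")
  freqs <- freqsAll[keep]
  # one-sided density scaling: double all bins except DC and Nyquist
  sided <- rep(2, nHalf)
  sided[1] <- 1
  if (n %% 2 == 0) sided[nHalf] <- 1
  sided <- sided[keep]

  nEst <- length(starts) * cfg$nTapers
  # collect tapered FFTs: kept bins x parcels x estimates
  F <- array(complex(real = 0), c(length(keep), nP, nEst))
  e <- 0L
  for (w in starts) {
    seg <- t(x[, w:(w + n - 1L), drop = FALSE])   # n x parcels
    for (m in seq_len(cfg$nTapers)) {
      e <- e + 1L
      F[, , e] <- stats::mvfft(seg * tapers[, m])[keep, , drop = FALSE]
    }
  }
  csd <- array(complex(real = 0), c(nP, nP, length(keep)))
  for (a in seq_len(nP)) {
    for (b in a:nP) {
      s <- rowMeans(F[, a, , drop = FALSE] * Conj(F[, b, , drop = FALSE]),
                    dims = 1)
      s <- s * sided / fs
      csd[a, b, ] <- s
      if (b != a) csd[b, a, ] <- Conj(s)
    }
  }
  psd <- matrix(0, nP, length(keep))
  for (a in seq_len(nP)) {
    p <- Re(csd[a, a, ])
    p[p < 0] <- 0
    psd[a, ] <- p
    csd[a, a, ] <- p
  }
  new("SpectralEstimate", freqs = freqs, psd = psd, csd = csd,
      nEstimates = nEst)
}

#' Coherence from a spectral estimate
#'
#' Magnitude coherence: the absolute cross-spectral density normalised by
#' the square root of the product of the two power spectral densities.
#'
#' @param est a [SpectralEstimate-class] with strictly positive PSD.
#' @return parcels x parcels x freqs array with values in `[0, 1]`, unit
#'   diagonal, symmetric in the parcel indices.
#' @export
coherenceFromSpectra <- function(est) {
  stopifnot(is(est, "SpectralEstimate"))
  psd <- est@psd
  if (any(psd <= 0)) {
    bad <- which(psd <= 0, arr.ind = TRUE)[1, ]
    stop("PSD is zero for parcel ", bad[1], " at ",
         format(est@freqs[bad[2]]), " Hz; coherence undefined")
  }
  nP <- nrow(psd); nf <- length(est@freqs)
  C <- array(0, c(nP, nP, nf))
  for (a in seq_len(nP)) {
    for (b in a:nP) {
      v <- Mod(est@csd[a, b, ]) / sqrt(psd[a, ] * psd[b, ])
      v <- pmin(v, 1)
      C[a, b, ] <- v
      C[b, a, ] <- v
    }
    C[a, a, ] <- 1
  }
  C
}

#' Canonical frequency bands
#'
#' Default band limits: delta 1-4, theta 4-8, alpha 8-13, beta 13-24 and
#' gamma 30-45 Hz. Bands are half-open `[low, high)` so touching limits
#' are not double-counted; the 24-30 Hz gap between beta and gamma is
#' deliberate (a band-limited artefact range excluded from analysis).
#'
#' @return named list of `c(low, high)` pairs in Hz.
#' @export
frequencyBands <- function() {
  list(delta = c(1, 4), theta = c(4, 8), alpha = c(8, 13),
       beta = c(13, 24), gamma = c(30, 45))
}

bandBins <- function(band, freqs) {
  if (band[1] >= band[2]) stop("band limits must be increasing")
  which(freqs >= band[1] & freqs < band[2])
}

#' Number of retained frequency bins per band
#'
#' @param bands named list of band limit pairs.
#' @param freqs retained frequency axis in Hz.
#' @return named integer vector of bin counts.
#' @export
bandBinCounts <- function(bands, freqs) {
  vapply(bands, function(b) length(bandBins(b, freqs)), integer(1))
}

#' Collapse a spectral quantity over frequency bands
#'
#' Simple mean over the frequency bins whose centre lies in
#' `[low, high)`, per band. Accepts a [SpectralEstimate-class] (collapses
#' the PSD into band power) or any array whose last dimension is
#' frequency (e.g. a coherence array, giving band coherence networks).
#'
#' @param x a `SpectralEstimate`, a parcels x freqs matrix, or an array
#'   with frequency as last dimension.
#' @param bands named list of band limit pairs, e.g. [frequencyBands()].
#' @param freqs frequency axis; taken from `x` when it is a
#'   `SpectralEstimate`.
#' @return named list with one collapsed array per band (parcel vector
#'   for a PSD, parcels x parcels matrix for coherence).
#' @export
bandCollapse <- function(x, bands = frequencyBands(), freqs = NULL) {
  if (is(x, "SpectralEstimate")) {
    freqs <- x@freqs
    x <- x@psd
  }
  if (is.null(freqs)) stop("freqs required for a bare array")
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (d[length(d)] != length(freqs))
    stop("last dimension of x must match freqs")
  out <- lapply(bands, function(b) {
    idx <- bandBins(b, freqs)
    if (!length(idx))
      stop("band [", b[1], ", ", b[2], ") contains no retained bins")
    collapseLastDim(x, idx)
  })
  names(out) <- names(bands)
  out
}

# mean over the last dimension at the given indices
collapseLastDim <- function(x, idx) {
  d <- dim(x)
  if (length(d) == 2) {
    rowMeans(x[, idx, drop = FALSE])
  } else if (length(d) == 3) {
    apply(x[, , idx, drop = FALSE], c(1, 2), mean)
  } else {
    mean(x[idx])
  }
}

#' Coherence map: mean edge strength per parcel
#'
#' Averages the off-diagonal entries of a symmetric coherence network for
#' each parcel, yielding a per-parcel connectivity profile. Uses the
#' unreferenced, unthresholded network.
#'
#' @param network symmetric parcels x parcels matrix (diagonal ignored).
#' @param tol asymmetry tolerance.
#' @return numeric vector, one mean edge value per parcel.
#' @export
coherenceMap <- function(network, tol = 1e-9) {
  if (!is.matrix(network) || nrow(network) != ncol(network))
    stop("network must be a square matrix")
  if (max(abs(network - t(network))) > tol)
    stop("network is asymmetric beyond tolerance ", tol)
  nP <- nrow(network)
  if (nP < 2) stop("need at least 2 parcels")
  (rowSums(network) - diag(network)) / (nP - 1)
}

#' Weighted average across frequency bands
#'
#' Element-wise weighted mean of per-band arrays, used as the reference
#' that band-specific maps and networks are displayed against. Weights
#' default to each band's retained bin count (equivalently the band width
#' on a uniform axis) and are normalised to sum to 1.
#'
#' @param values named list of same-shaped numeric arrays, one per band.
#' @param weights numeric weights, one per band; or computed from
#'   `bands` + `freqs` via [bandBinCounts()].
#' @param bands,freqs used to derive bin-count weights when `weights` is
#'   NULL.
#' @return array of the common shape: the weighted average.
#' @export
weightedBandReference <- function(values, weights = NULL, bands = NULL,
                                  freqs = NULL) {
  if (!length(values)) stop("values must be a nonempty list")
  shp <- dim(values[[1]])
  for (v in values) {
    if (!identical(dim(v), shp) || length(v) != length(values[[1]]))
      stop("per-band arrays must share a common shape")
  }
  if (is.null(weights)) {
    weights <- if (!is.null(bands) && !is.null(freqs))
      as.numeric(bandBinCounts(bands, freqs)) else rep(1, length(values))
  }
  if (length(weights) != length(values))
    stop("need one weight per band")
  w <- weights / sum(weights)
  out <- values[[1]] * w[1]
  for (i in seq_along(values)[-1]) out <- out + values[[i]] * w[i]
  out
}

#' Reference and threshold band networks for display
#'
#' Subtracts the (edge-specific) weighted average across bands from each
#' band's network, then keeps the top fraction of edges by absolute
#' referenced value, irrespective of sign. Ties are broken by lower
#' parcel index, then lower partner index, so the mask is deterministic.
#' This is a reporting aid only: statistics are computed on unreferenced
#' values.
#'
#' @param networks named list of symmetric parcels x parcels matrices,
#'   one per band.
#' @param topFraction fraction of edges to keep, in `(0, 1]` (default
#'   0.03); the kept count is `ceiling(topFraction * nEdges)`.
#' @param weights,bands,freqs band weights as in
#'   [weightedBandReference()].
#' @return list with `referenced` (list of referenced networks),
#'   `mask` (list of logical symmetric matrices marking kept edges) and
#'   `reference` (the per-edge reference matrix).
#' @export
referenceAndThreshold <- function(networks, topFraction = 0.03,
                                  weights = NULL, bands = NULL,
                                  freqs = NULL) {
  if (topFraction <= 0 || topFraction > 1)
    stop("topFraction must lie in (0, 1]")
  if (length(networks) < 2)
    stop("need at least 2 bands for referencing")
  ref <- weightedBandReference(networks, weights = weights, bands = bands,
                               freqs = freqs)
  nP <- nrow(ref)
  ut <- which(upper.tri(ref), arr.ind = TRUE)
  nEdges <- nrow(ut)
  nKeep <- ceiling(topFraction * nEdges)
  referenced <- lapply(networks, function(m) m - ref)
  mask <- lapply(referenced, function(m) {
    vals <- abs(m[upper.tri(m)])
    ord <- order(-vals, ut[, 1], ut[, 2])
    keepIdx <- ord[seq_len(nKeep)]
    mk <- matrix(FALSE, nP, nP)
    mk[ut[keepIdx, , drop = FALSE]] <- TRUE
    mk | t(mk)
  })
  list(referenced = referenced, mask = mask, reference = ref)
}

#' Write band networks as an edge list
#'
#' TSV with columns parcel_i, parcel_j, band, value, kept.
#'
#' @param networks named list of referenced networks per band.
#' @param mask list of logical keep masks per band.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeEdgeList <- function(networks, mask, path) {
  rows <- list()
  for (b in names(networks)) {
    m <- networks[[b]]
    ut <- which(upper.tri(m), arr.ind = TRUE)
    rows[[b]] <- data.frame(parcel_i = ut[, 1], parcel_j = ut[, 2],
                            band = b, value = m[ut],
                            kept = mask[[b]][ut])
  }
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
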