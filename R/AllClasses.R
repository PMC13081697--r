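#' @import methods
#' @importFrom stats var sd rnorm runif cor prcomp fft aggregate quantile
#' @importFrom utils write.csv read.csv head tail
NULL

#' Parcellated time series for one subject
#'
#' Container for a single subject's parcellated recording: a numeric
#' matrix with one row per parcel (region of interest) and one column per
#' sample, together with its sampling rate. All pipeline stages consume
#' this class.
#'
#' @slot data numeric matrix, parcels x samples.
#' @slot samplingRate sampling rate in Hz.
#' @slot subjectId character identifier.
#'
#' @export
setClass("ParcelTimeSeries",
  representation(
    data = "matrix",
    samplingRate = "numeric",
    subjectId = "character"
  ),
  prototype(samplingRate = 250, subjectId = "subject")
)

setValidity("ParcelTimeSeries", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be a numeric matrix")
  if (anyNA(object@data)) msg <- c(msg, "data contains NA values")
  if (length(object@samplingRate) != 1 || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a ParcelTimeSeries
#'
#' @param data numeric matrix, parcels x samples.
#' @param samplingRate sampling rate in Hz (default 250).
#' @param subjectId subject identifier.
#' @return A [ParcelTimeSeries-class] object.
#' @examples
#' ts <- parcelTimeSeries(matrix(rnorm(500), nrow = 2), samplingRate = 250)
#' nParcels(ts)
#' @export
parcelTimeSeries <- function(data, samplingRate = 250, subjectId = "subject") {
  new("ParcelTimeSeries", data = as.matrix(data), samplingRate = samplingRate,
      subjectId = as.character(subjectId))
}

#' @describeIn parcelTimeSeries number of parcels (rows).
#' @param x a `ParcelTimeSeries`.
#' @export
nParcels <- function(x) nrow(x@data)

#' @describeIn parcelTimeSeries number of samples (columns).
#' @export
nSamples <- function(x) ncol(x@data)

#' @describeIn parcelTimeSeries sampling rate in Hz.
#' @export
samplingRate <- function(x) x@samplingRate

#' @describeIn parcelTimeSeries the parcels x samples data matrix.
#' @export
tsData <- function(x) x@data

setMethod("show", "ParcelTimeSeries", function(object) {
  cat("ParcelTimeSeries '", object@subjectId, "': ",
      nrow(object@data), " parcels x ", ncol(object@data), " samples @ ",
      object@samplingRate, " Hz\n", sep = "")
})

#' Multitaper spectral estimate
#'
#' Holds the frequency axis, power spectral densities (PSD, one row per
#' parcel) and the complex cross-spectral density array (CSD, Hermitian in
#' the parcel indices) for one subject. The PSD equals the real diagonal
#' of the CSD.
#'
#' @slot freqs frequency axis in Hz, ascending.
#' @slot psd parcels x freqs matrix of one-sided power densities.
#' @slot csd parcels x parcels x freqs complex array.
#' @slot nEstimates number of averaged window-taper estimates.
#'
#' @export
setClass("SpectralEstimate",
  representation(
    freqs = "numeric",
    psd = "matrix",
    csd = "array",
    nEstimates = "numeric"
  )
)

setValidity("SpectralEstimate", function(object) {
  msg <- character()
  if (is.unsorted(object@freqs)) msg <- c(msg, "freqs must be ascending")
  if (ncol(object@psd) != length(object@freqs))
    msg <- c(msg, "psd columns must match freqs")
  if (any(object@psd < 0)) msg <- c(msg, "psd must be nonnegative")
  d <- dim(object@csd)
  if (length(d) != 3 || d[1] != d[2] || d[1] != nrow(object@psd) ||
      d[3] != length(object@freqs))
    msg <- c(msg, "csd must be parcels x parcels x freqs")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SpectralEstimate", function(object) {
  cat("SpectralEstimate: ", nrow(object@psd), " parcels, ",
      length(object@freqs), " frequency bins [",
      min(object@freqs), ", ", max(object@freqs), "] Hz, ",
      object@nEstimates, " averaged estimates\n", sep = "")
})

#' @describeIn SpectralEstimate-class frequency axis in Hz.
#' @param x a `SpectralEstimate` (or `StateSpectra`).
#' @export
specFreqs <- function(x) x@freqs

#' @describeIn SpectralEstimate-class PSD matrix (parcels x freqs).
#' @export
specPsd <- function(x) x@psd

#' @describeIn SpectralEstimate-class complex CSD array.
#' @export
specCsd <- function(x) x@csd

#' Per-state dual-estimated spectra for one subject
#'
#' Result of dual estimation: per state, a PSD (rescaled by the inverse
#' fractional occupancy) and a coherence array on a common frequency
#' axis. States the subject never visited carry all-NA entries, never
#' silent zeros.
#'
#' @slot freqs frequency axis in Hz.
#' @slot psd states x parcels x freqs array (NA for unvisited states).
#' @slot coherence states x parcels x parcels x freqs array.
#' @slot fo fractional occupancy per state used for the rescaling.
#'
#' @export
setClass("StateSpectra",
  representation(
    freqs = "numeric",
    psd = "array",
    coherence = "array",
    fo = "numeric"
  )
)

setValidity("StateSpectra", function(object) {
  msg <- character()
  if (dim(object@psd)[1] != length(object@fo))
    msg <- c(msg, "psd first dimension must match number of states")
  if (any(object@fo < 0 | object@fo > 1)) msg <- c(msg, "fo must lie in [0,1]")
  ok <- !is.na(object@psd)
  if (any(object@psd[ok] < 0)) msg <- c(msg, "psd must be nonnegative")
  if (length(msg)) msg else TRUE
})

setMethod("show", "StateSpectra", function(object) {
  cat("StateSpectra: ", length(object@fo), " states, ",
      dim(object@psd)[2], " parcels, ", length(object@freqs),
      " frequency bins; FO = ",
      paste(sprintf("%.3f", object@fo), collapse = " "), "\n", sep = "")
})

#' Fitted hidden Markov model
#'
#' Parameters, per-subject posteriors and diagnostics of a zero-mean
#' Gaussian-covariance HMM fitted at the group level.
#'
#' @slot K number of states.
#' @slot covariances list of K channel x channel state covariances.
#' @slot transMat K x K transition probability matrix (rows sum to 1).
#' @slot initProb length-K initial state distribution.
#' @slot posteriors per subject: list with elements `gamma` (K x samples
#'   marginal state probabilities), `xi` (K x K expected transition
#'   counts summed over time) and `loglik`.
#' @slot diagnostics list: objective trace (`trace`), `converged`,
#'   `runIndex`, `finalObjective` (negative log-likelihood; lower is
#'   better), `method`.
#'
#' @export
setClass("HMMFit",
  representation(
    K = "numeric",
    covariances = "list",
    transMat = "matrix",
    initProb = "numeric",
    posteriors = "list",
    diagnostics = "list"
  )
)

setValidity("HMMFit", function(object) {
  msg <- character()
  K <- object@K
  if (length(object@covariances) != K)
    msg <- c(msg, "need one covariance per state")
  if (!all(dim(object@transMat) == c(K, K)))
    msg <- c(msg, "transMat must be K x K")
  else if (max(abs(rowSums(object@transMat) - 1)) > 1e-10)
    msg <- c(msg, "transMat rows must sum to 1")
  if (abs(sum(object@initProb) - 1) > 1e-8)
    msg <- c(msg, "initProb must sum to 1")
  for (D in object@covariances) {
    if (max(abs(D - t(D))) > 1e-8) { msg <- c(msg, "covariances must be symmetric"); break }
    if (min(eigen(D, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      msg <- c(msg, "covariances must be positive-definite"); break
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "HMMFit", function(object) {
  d <- object@diagnostics
  cat("HMMFit: K = ", object@K, ", ", nrow(object@covariances[[1]]),
      " channels, ", length(object@posteriors), " subjects\n",
      "  method = ", d$method, ", converged = ", d$converged,
      ", -loglik = ", format(d$finalObjective), "\n", sep = "")
})

#' @describeIn HMMFit-class list of state covariance matrices.
#' @param x an `HMMFit`.
#' @export
stateCovariances <- function(x) x@covariances

#' @describeIn HMMFit-class transition probability matrix.
#' @export
transitionMatrix <- function(x) x@transMat

#' @describeIn HMMFit-class list of per-subject posteriors
#'   (`gamma`, `xi`, `loglik`).
#' @export
statePosteriors <- function(x) x@posteriors

#' Design matrix for group-level GLMs
#'
#' Subjects x regressors matrix with a constant column and z-scored
#' non-constant regressors, plus the name of the regressor of interest.
#'
#' @slot X numeric matrix, subjects x regressors.
#' @slot regressorNames column names.
#' @slot interest name of the regressor of interest.
#'
#' @export
setClass("GLMDesign",
  representation(
    X = "matrix",
    regressorNames = "character",
    interest = "character"
  )
)

setValidity("GLMDesign", function(object) {
  msg <- character()
  if (ncol(object@X) != length(object@regressorNames))
    msg <- c(msg, "regressorNames must match columns of X")
  if (!object@interest %in% object@regressorNames)
    msg <- c(msg, "interest must name a regressor")
  if (qr(object@X)$rank < ncol(object@X))
    msg <- c(msg, "X must have full column rank")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GLMDesign", function(object) {
  cat("GLMDesign: ", nrow(object@X), " subjects x ", ncol(object@X),
      " regressors (interest: ", object@interest, ")\n  columns: ",
      paste(object@regressorNames, collapse = ", "), "\n", sep = "")
})

#' Sign-flip max-statistic permutation result
#'
#' Observed statistics, the shared null distribution of permutation
#' maxima and the resulting family-wise-error-controlled p-values.
#'
#' @slot observed observed statistic per feature (signed).
#' @slot nullMax null distribution of the maximum absolute statistic.
#' @slot pValues per-feature p-values in (0, 1].
#' @slot statistic `"beta"` or `"t"`.
#' @slot interest regressor of interest.
#' @slot seed seed used for the sign flips.
#'
#' @export
setClass("PermResult",
  representation(
    observed = "numeric",
    nullMax = "numeric",
    pValues = "numeric",
    statistic = "character",
    interest = "character",
    seed = "numeric"
  )
)

setValidity("PermResult", function(object) {
  msg <- character()
  if (length(object@pValues) != length(object@observed))
    msg <- c(msg, "one p-value per feature required")
  if (any(object@pValues <= 0 | object@pValues > 1))
    msg <- c(msg, "p-values must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PermResult", function(object) {
  cat("PermResult (", object@statistic, " statistic, interest: ",
      object@interest, "): ", length(object@observed), " features, ",
      length(object@nullMax), " permutations, ",
      sum(object@pValues < 0.05), " significant at p < 0.05\n", sep = "")
})

#' @describeIn PermResult-class per-feature permutation p-values.
#' @param x a `PermResult`.
#' @export
permPValues <- function(x) x@pValues

#' @describeIn PermResult-class observed per-feature statistics.
#' @export
permObserved <- function(x) x@observed
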