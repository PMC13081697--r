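#' Dual estimation of per-state spectra
#'
#' Re-estimates the spectral content of each inferred state from the
#' original (standardised) parcel data: the parcel time courses are
#' multiplied by the state's binary indicator (windows straddling state
#' boundaries are retained, with zeros inserted), the multitaper P/CSD is
#' computed with the same settings as the time-averaged analysis,
#' coherence is formed from the P/CSD, and finally the PSD is rescaled by
#' the inverse fractional occupancy to undo the amplitude bias of the
#' masking. Coherence needs no such correction (its normalisation is
#' scale-free). States with zero occupancy are returned all-NA, never as
#' silent zeros.
#'
#' If the state time course is shorter than the recording by an even
#' number of samples (the time-delay-embedding trim), the recording is
#' aligned by trimming half the difference from each end.
#'
#' @param ts a [ParcelTimeSeries-class] (standardised internally).
#' @param stc integer state time course aligned to `ts` (possibly
#'   shorter by the embedding trim).
#' @param K number of states (default: max observed).
#' @param cfg a [spectralConfig()]; the default retains 1-80 Hz, the
#'   full band-pass of typical recordings.
#' @return a [StateSpectra-class].
#' @export
dualEstimate <- function(ts, stc, K = max(stc),
                         cfg = spectralConfig(freqRangeHz = c(1, 80))) {
  stopifnot(is(ts, "ParcelTimeSeries"))
  x <- ts@data
  fs <- ts@samplingRate
  T <- ncol(x)
  diffT <- T - length(stc)
  if (diffT < 0 || diffT %% 2 != 0)
    stop("state time course length ", length(stc),
         " cannot be aligned to ", T, " samples (need an even, ",
         "nonnegative trim)")
  if (diffT > 0) {
    tr <- diffT / 2
    x <- x[, (tr + 1):(T - tr), drop = FALSE]
  }
  x <- standardizeRows(x)
  if (any(stc < 1 | stc > K)) stop("state label outside 1..", K)
  nP <- nrow(x)
  fo <- vapply(seq_len(K), function(k) mean(stc == k), numeric(1))

  psd <- NULL; coh <- NULL; freqs <- NULL
  psdA <- NULL; cohA <- NULL
  for (k in seq_len(K)) {
    if (fo[k] == 0) next
    masked <- x * rep(as.numeric(stc == k), each = nP)
    est <- multitaperSpectra(masked, cfg, standardize = FALSE, fs = fs)
    if (is.null(freqs)) {
      freqs <- est@freqs
      psdA <- array(NA_real_, c(K, nP, length(freqs)))
      cohA <- array(NA_real_, c(K, nP, nP, length(freqs)))
    }
    psdA[k, , ] <- est@psd / fo[k]
    cohA[k, , , ] <- coherenceFromSpectra(est)
  }
  if (is.null(freqs)) stop("no state was ever active")
  new("StateSpectra", freqs = freqs, psd = psdA, coherence = cohA, fo = fo)
}

#' Broadband collapse of state spectra
#'
#' Averages each state's PSD and coherence over the full retained
#' frequency range (no hand-chosen band: each state carries its own
#' characteristic spectrum), giving per-state power maps, coherence
#' networks and coherence maps. For display, per-state maps are
#' referenced against the uniform mean across states (computed here via
#' [weightedBandReference()] with uniform weights); coherence maps always
#' use the unreferenced, unthresholded networks.
#'
#' @param sse a [StateSpectra-class].
#' @param freqRange frequency range to average over (default the full
#'   retained axis).
#' @return list with `powerMaps` (states x parcels), `coherenceNetworks`
#'   (states x parcels x parcels), `coherenceMaps` (states x parcels),
#'   `referencedPowerMaps` and `referencedCoherenceMaps` (deviation from
#'   the across-state mean; NA rows preserved).
#' @export
stateBandCollapse <- function(sse, freqRange = NULL) {
  stopifnot(is(sse, "StateSpectra"))
  freqs <- sse@freqs
  if (is.null(freqRange)) freqRange <- range(freqs)
  idx <- which(freqs >= freqRange[1] & freqs <= freqRange[2])
  if (!length(idx)) stop("freqRange retains no frequency bins")
  K <- dim(sse@psd)[1]; nP <- dim(sse@psd)[2]
  powerMaps <- matrix(NA_real_, K, nP)
  cohNets <- array(NA_real_, c(K, nP, nP))
  cohMaps <- matrix(NA_real_, K, nP)
  for (k in seq_len(K)) {
    if (anyNA(sse@psd[k, , 1])) next
    powerMaps[k, ] <- rowMeans(sse@psd[k, , idx, drop = FALSE], dims = 1)
    net <- apply(sse@coherence[k, , , idx, drop = FALSE], c(2, 3), mean)
    cohNets[k, , ] <- net
    cohMaps[k, ] <- coherenceMap(net)
  }
  visited <- which(!is.na(powerMaps[, 1]))
  refPower <- weightedBandReference(
    lapply(visited, function(k) powerMaps[k, ]),
    weights = rep(1, length(visited)))
  refCohMap <- weightedBandReference(
    lapply(visited, function(k) cohMaps[k, ]),
    weights = rep(1, length(visited)))
  referencedPowerMaps <- sweep(powerMaps, 2, refPower)
  referencedCoherenceMaps <- sweep(cohMaps, 2, refCohMap)
  list(powerMaps = powerMaps, coherenceNetworks = cohNets,
       coherenceMaps = cohMaps,
       referencedPowerMaps = referencedPowerMaps,
       referencedCoherenceMaps = referencedCoherenceMaps)
}
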