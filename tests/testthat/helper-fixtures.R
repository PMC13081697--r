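# shared fixtures built in code

# AR(1)-correlated covariance with a scale, used as distinct HMM states
ar1Cov <- function(d, rho, scale = 1) {
  scale * outer(seq_len(d), seq_len(d), function(i, j) rho^abs(i - j))
}

# three clearly distinct 5-channel state covariances
distinctCovs3 <- function(d = 5) {
  list(ar1Cov(d, 0.0, 1), ar1Cov(d, 0.7, 3), ar1Cov(d, -0.4, 9))
}

# white-noise recording
whiteTS <- function(nParcels, nSamples, fs = 250, seed = 1) {
  withr::with_seed(seed,
    parcelTimeSeries(matrix(rnorm(nParcels * nSamples), nParcels),
                     samplingRate = fs))
}

# independent run-length oracle for dynamics statistics (plain loops)
oracleDynamics <- function(stc, K, fs) {
  T <- length(stc)
  res <- list()
  for (k in seq_len(K)) {
    lifetimes <- c(); onsets <- c(); ends <- c()
    inRun <- FALSE; runLen <- 0
    for (t in seq_len(T)) {
      if (stc[t] == k) {
        if (!inRun) { onsets <- c(onsets, t); inRun <- TRUE; runLen <- 0 }
        runLen <- runLen + 1
      } else if (inRun) {
        lifetimes <- c(lifetimes, runLen); ends <- c(ends, t - 1)
        inRun <- FALSE
      }
    }
    if (inRun) { lifetimes <- c(lifetimes, runLen); ends <- c(ends, T) }
    fo <- sum(stc == k) / T
    mlt <- if (length(lifetimes)) mean(lifetimes) / fs * 1000 else NA_real_
    gaps <- if (length(onsets) > 1) onsets[-1] - ends[-length(ends)] - 1 else NULL
    mint <- if (!is.null(gaps)) mean(gaps) / fs else NA_real_
    sr <- length(onsets) / (T / fs)
    res[[k]] <- c(fo = fo, mlt = mlt, mint = mint,
                  sr = if (length(onsets)) sr else 0)
  }
  do.call(rbind, res)
}
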