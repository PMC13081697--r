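#' State specification for the oscillatory cohort generator
#'
#' Describes one hidden state of the generator: per-parcel oscillator
#' frequencies and gains, groups of parcels driven by a shared source
#' (inducing inter-parcel coherence) and the observation noise level.
#' Oscillators are realised as damped AR(2) resonators (pole radius 0.95)
#' excited by white noise; a frequency of 0 marks a broadband (unfiltered
#' noise) parcel.
#'
#' @param oscillatorFreqHz numeric vector, one resonance frequency per
#'   parcel (Hz); 0 means broadband noise.
#' @param oscillatorGain nonnegative amplitude per parcel (the filtered,
#'   unit-variance oscillation is multiplied by this gain).
#' @param couplingGroups list of integer vectors; parcels within a group
#'   share the same driving innovation, so they are coherent.
#' @param couplingStrength fraction in (0, 1] of shared innovation
#'   variance within a coupling group (1 = identical driving source).
#' @param noiseSd observation noise standard deviation, signal units.
#' @return A validated list of class `StateSpec`.
#' @export
stateSpec <- function(oscillatorFreqHz, oscillatorGain,
                      couplingGroups = list(), couplingStrength = 1,
                      noiseSd = 0.2) {
  if (length(oscillatorGain) != length(oscillatorFreqHz))
    stop("oscillatorGain and oscillatorFreqHz must have one entry per parcel")
  if (any(oscillatorGain < 0)) stop("gains must be nonnegative")
  if (any(oscillatorFreqHz < 0)) stop("frequencies must be nonnegative")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  if (couplingStrength <= 0 || couplingStrength > 1)
    stop("couplingStrength must lie in (0, 1]")
  nP <- length(oscillatorFreqHz)
  for (g in couplingGroups) {
    if (!all(g %in% seq_len(nP)))
      stop("coupling group references parcel outside 1..", nP)
  }
  structure(list(oscillatorFreqHz = oscillatorFreqHz,
                 oscillatorGain = oscillatorGain,
                 couplingGroups = couplingGroups,
                 couplingStrength = couplingStrength,
                 noiseSd = noiseSd),
            class = "StateSpec")
}

#' Default spectrally distinct state specifications
#'
#' One state per resonance frequency spread over 2-40 Hz, unit gains,
#' one two-parcel coupling group per state (rotating over parcels).
#'
#' @param K number of states.
#' @param nParcels number of parcels.
#' @param noiseSd observation noise sd.
#' @return list of K [stateSpec()] objects.
#' @export
defaultStateSpecs <- function(K, nParcels, noiseSd = 0.2) {
  freqs <- seq(2, 40, length.out = K)
  lapply(seq_len(K), function(k) {
    i <- ((k - 1L) %% nParcels) + 1L
    j <- (k %% nParcels) + 1L
    grp <- if (i != j) list(c(i, j)) else list()
    stateSpec(rep(freqs[k], nParcels), rep(1, nParcels),
              couplingGroups = grp, noiseSd = noiseSd)
  })
}

#' Cohort generator configuration
#'
#' Bundles every knob of the synthetic cohort: cohort size, recording
#' geometry, the hidden-state Markov chain, per-state oscillator specs and
#' the covariate effect map. Defaults emulate a desk-scale resting-state
#' MEG cohort: 250 Hz parcel data, K = 10 states with stay probability
#' 0.94 (mean state lifetime about 67 ms), ages uniform on 18-88 years and
#' 10 positively loaded cognitive task scores whose shared latent factor
#' declines with age.
#'
#' @param nSubjects number of subjects.
#' @param nParcels number of parcels.
#' @param nSamples samples per subject.
#' @param samplingRateHz sampling rate (Hz).
#' @param K number of hidden states.
#' @param baseTransitionMatrix K x K row-stochastic matrix; default has
#'   0.94 on the diagonal, remainder spread uniformly.
#' @param stateSpecs list of K [stateSpec()]s; default [defaultStateSpecs()].
#' @param effectMap list of effects, each a list with elements
#'   `covariate` ("age" or "sex"), `feature` ("stay_prob", "power" or
#'   "coupling"), `state` (for stay_prob/coupling; optional for power),
#'   `parcel` (for power) and `slope`. Stay-probability and coupling
#'   effects act on the logit scale, power effects multiplicatively on the
#'   gain (`gain * exp(slope * z(covariate))`), so rows stay stochastic
#'   and gains nonnegative.
#' @param nCogScores number of cognitive task scores (>= 2).
#' @param latentCogAgeSlope slope of the latent cognitive factor on
#'   z-scored age (default -0.5: performance declines with age).
#' @param cogNoiseSd task-specific score noise sd.
#' @param ageRange sampling range of ages in years.
#' @param confoundAgeCor correlations of (total brain volume, relative
#'   grey volume, relative white volume, head size, head x/y/z) with age.
#' @param gainJitterSd log-normal sd of random per-subject gain
#'   heterogeneity.
#' @param crossfadeSamples width of the linear crossfade applied at state
#'   switches; 0 (default) switches abruptly, matching the piecewise
#'   assumption of the HMM.
#' @param seed integer seed; the same seed reproduces the cohort exactly.
#' @return validated list of class `CohortConfig`.
#' @export
cohortConfig <- function(nSubjects = 100, nParcels = 8, nSamples = 15000,
                         samplingRateHz = 250, K = 10,
                         baseTransitionMatrix = NULL, stateSpecs = NULL,
                         effectMap = list(), nCogScores = 10,
                         latentCogAgeSlope = -0.5, cogNoiseSd = 1,
                         ageRange = c(18, 88),
                         confoundAgeCor = c(tbv = -0.4, gm = -0.5, wm = -0.2,
                                            headsize = 0, hx = 0.1, hy = 0.1,
                                            hz = 0.1),
                         gainJitterSd = 0.1, crossfadeSamples = 0,
                         seed = 1) {
  stopifnotScalar(nSubjects, "nSubjects"); stopifnotScalar(nParcels, "nParcels")
  stopifnotScalar(nSamples, "nSamples"); stopifnotScalar(K, "K")
  stopifnotScalar(samplingRateHz, "samplingRateHz")
  if (is.null(baseTransitionMatrix)) {
    baseTransitionMatrix <- matrix((1 - 0.94) / max(K - 1, 1), K, K)
    diag(baseTransitionMatrix) <- if (K > 1) 0.94 else 1
  }
  checkStochasticMatrix(baseTransitionMatrix, K)
  if (is.null(stateSpecs)) stateSpecs <- defaultStateSpecs(K, nParcels)
  if (length(stateSpecs) != K) stop("need one stateSpec per state")
  for (sp in stateSpecs) {
    if (length(sp$oscillatorFreqHz) != nParcels)
      stop("stateSpec parcel count does not match nParcels")
  }
  for (eff in effectMap) validateEffect(eff, K, nParcels)
  if (nCogScores < 2) stop("nCogScores must be >= 2")
  structure(list(nSubjects = nSubjects, nParcels = nParcels,
                 nSamples = nSamples, samplingRateHz = samplingRateHz, K = K,
                 baseTransitionMatrix = baseTransitionMatrix,
                 stateSpecs = stateSpecs, effectMap = effectMap,
                 nCogScores = nCogScores,
                 latentCogAgeSlope = latentCogAgeSlope,
                 cogNoiseSd = cogNoiseSd, ageRange = ageRange,
                 confoundAgeCor = confoundAgeCor,
                 gainJitterSd = gainJitterSd,
                 crossfadeSamples = crossfadeSamples, seed = seed),
            class = "CohortConfig")
}

checkStochasticMatrix <- function(A, K = nrow(A), tol = 1e-8) {
  if (!is.matrix(A) || nrow(A) != K || ncol(A) != K)
    stop("transition matrix must be ", K, " x ", K)
  if (any(A < 0) || any(A > 1))
    stop("transition probabilities must lie in [0, 1]")
  bad <- which(abs(rowSums(A) - 1) > tol)
  if (length(bad))
    stop("transition matrix rows must sum to 1 (row ", bad[1], " sums to ",
         format(rowSums(A)[bad[1]]), ")")
  invisible(A)
}

validateEffect <- function(eff, K, nParcels) {
  if (!all(c("covariate", "feature", "slope") %in% names(eff)))
    stop("effect must have covariate, feature and slope")
  if (!eff$covariate %in% c("age", "sex"))
    stop("unknown effect covariate '", eff$covariate, "'")
  if (!eff$feature %in% c("stay_prob", "power", "coupling"))
    stop("unknown effect feature '", eff$feature, "'")
  if (eff$feature %in% c("stay_prob", "coupling")) {
    if (is.null(eff$state) || !eff$state %in% seq_len(K))
      stop("effect on ", eff$feature, " references unknown state")
  }
  if (eff$feature == "power") {
    if (is.null(eff$parcel) || !all(eff$parcel %in% seq_len(nParcels)))
      stop("power effect references unknown parcel")
    if (!is.null(eff$state) && !all(eff$state %in% seq_len(K)))
      stop("power effect references unknown state")
  }
  invisible(eff)
}

#' Simulate a Markov state sequence
#'
#' Draws a categorical hidden-state sequence from a first-order Markov
#' chain with transition matrix `A`.
#'
#' @param A K x K row-stochastic transition matrix.
#' @param T sequence length (samples).
#' @param initial length-K initial distribution; default is the stationary
#'   distribution of `A`.
#' @param seed optional integer seed.
#' @return integer vector of length `T` with values in 1..K.
#' @examples
#' A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
#' s <- simulateStateSequence(A, 1000, seed = 1)
#' table(s) / 1000  # close to the stationary distribution (2/3, 1/3)
#' @export
simulateStateSequence <- function(A, T, initial = NULL, seed = NULL) {
  checkStochasticMatrix(A)
  if (T < 1) stop("T must be >= 1")
  K <- nrow(A)
  if (is.null(initial)) initial <- stationaryDistribution(A)
  if (length(initial) != K || abs(sum(initial) - 1) > 1e-8)
    stop("initial must be a length-K probability vector")
  withSeed(seed, {
    u <- stats::runif(T)
    s <- integer(T)
    cumInit <- cumsum(initial)
    cumA <- t(apply(A, 1, cumsum))
    s[1] <- findInterval(u[1], cumInit, left.open = TRUE) + 1L
    for (t in seq_len(T - 1L)) {
      s[t + 1L] <- findInterval(u[t + 1L], cumA[s[t], ], left.open = TRUE) + 1L
    }
    s
  })
}

#' Stationary distribution of a Markov chain
#'
#' Solves pi A = pi via the leading left eigenvector.
#'
#' @param A row-stochastic transition matrix.
#' @return probability vector pi with `pi %*% A = pi`.
#' @export
stationaryDistribution <- function(A) {
  checkStochasticMatrix(A)
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

# damped AR(2) resonator: poles at r * exp(+/- i 2 pi f / fs), unit-variance output
ar2Filter <- function(innovations, freqHz, fs, radius = 0.95) {
  if (freqHz <= 0) return(innovations / stats::sd(innovations))
  w <- 2 * pi * freqHz / fs
  y <- as.numeric(stats::filter(innovations, c(2 * radius * cos(w), -radius^2),
                                method = "recursive"))
  y / stats::sd(y)
}

#' Simulate oscillatory parcel signals for a given state sequence
#'
#' For each state, every parcel is driven by white noise through a damped
#' AR(2) resonator at the state's per-parcel frequency (gain 0 or
#' frequency 0 gives broadband noise); parcels in a coupling group share
#' a fraction `couplingStrength` of their innovation variance, which
#' induces coherence. The per-state signals are switched sample-wise by
#' the state sequence (optionally crossfaded) and observation noise is
#' added.
#'
#' @param states integer state sequence (values in 1..K).
#' @param specs list of K [stateSpec()] objects.
#' @param fs sampling rate in Hz.
#' @param seed optional seed.
#' @param crossfadeSamples linear crossfade width at switches (0 = abrupt).
#' @return a [ParcelTimeSeries-class] (parcels x length(states)).
#' @export
simulateSubjectSignals <- function(states, specs, fs, seed = NULL,
                                   crossfadeSamples = 0) {
  K <- length(specs)
  if (any(states < 1 | states > K)) stop("state index outside 1..", K)
  nP <- length(specs[[1]]$oscillatorFreqHz)
  T <- length(states)
  withSeed(seed, {
    x <- matrix(0, nP, T)
    for (k in seq_len(K)) {
      ind <- as.numeric(states == k)
      if (crossfadeSamples > 0) {
        w <- rep(1 / crossfadeSamples, crossfadeSamples)
        ind <- as.numeric(stats::filter(ind, w, sides = 2))
        ind[is.na(ind)] <- as.numeric(states[is.na(ind)] == k)
      }
      # always synthesise so the RNG stream is invariant to occupancy
      sk <- stateSignal(specs[[k]], nP, T, fs)
      if (any(ind > 0)) x <- x + sk * rep(ind, each = nP)
    }
    noiseSd <- vapply(specs, function(s) s$noiseSd, numeric(1))[states]
    x <- x + matrix(stats::rnorm(nP * T), nP, T) * rep(noiseSd, each = nP)
    parcelTimeSeries(x, samplingRate = fs)
  })
}

# full-length signal for one state: coupled innovations -> AR(2) -> gain
stateSignal <- function(spec, nP, T, fs) {
  own <- matrix(stats::rnorm(nP * T), nP, T)
  innov <- own
  c2 <- spec$couplingStrength
  for (g in spec$couplingGroups) {
    shared <- stats::rnorm(T)
    for (p in g) innov[p, ] <- sqrt(c2) * shared + sqrt(1 - c2) * own[p, ]
  }
  out <- matrix(0, nP, T)
  for (p in seq_len(nP)) {
    if (spec$oscillatorGain[p] == 0) next
    out[p, ] <- spec$oscillatorGain[p] *
      ar2Filter(innov[p, ], spec$oscillatorFreqHz[p], fs)
  }
  out
}

# perturb the stay probability A[k,k] on the logit scale, rescaling the
# off-diagonal mass so the row stays stochastic
perturbStayProb <- function(A, k, delta) {
  a <- A[k, k]
  a <- min(max(a, 1e-12), 1 - 1e-12)
  newA <- stats::plogis(stats::qlogis(a) + delta)
  off <- A[k, -k]
  A[k, -k] <- if (sum(off) > 0) off * (1 - newA) / sum(off)
              else rep((1 - newA) / (ncol(A) - 1), ncol(A) - 1)
  A[k, k] <- newA
  A
}

#' Simulate cognitive task scores driven by a latent factor
#'
#' Scores are generated as positive loadings times a latent performance
#' factor plus independent task noise. The latent factor is
#' `latentSlope * z(age)` plus a residual with sd
#' `sqrt(max(0, 1 - latentSlope^2))`, so it has unit variance for
#' `|latentSlope| <= 1` and is fully age-determined at `|latentSlope| = 1`.
#' All pairwise score correlations are positive in expectation.
#'
#' @param age numeric vector of ages.
#' @param nScores number of task scores (>= 2).
#' @param latentSlope slope of the latent factor on z-scored age.
#' @param noiseSd task noise sd (>= 0).
#' @param seed optional seed.
#' @return list with `scores` (subjects x scores matrix), `loadings`
#'   (positive, per task) and `latent` (the latent factor).
#' @export
simulateCognitiveScores <- function(age, nScores, latentSlope = -0.5,
                                    noiseSd = 1, seed = NULL) {
  if (nScores < 2) stop("nScores must be >= 2")
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  n <- length(age)
  withSeed(seed, {
    residSd <- sqrt(max(0, 1 - latentSlope^2))
    latent <- latentSlope * zscore(age, "age") + residSd * stats::rnorm(n)
    loadings <- stats::runif(nScores, 0.5, 1.5)
    scores <- outer(latent, loadings) +
      noiseSd * matrix(stats::rnorm(n * nScores), n, nScores)
    colnames(scores) <- paste0("cog", seq_len(nScores))
    list(scores = scores, loadings = loadings, latent = latent)
  })
}

#' Simulate a synthetic cohort with known covariate effects
#'
#' Generates per-subject Markov-switching oscillatory parcel time courses
#' (standardised per parcel), a covariate table (age, sex, brain volumes,
#' head size/position, cognitive task scores) and a ground-truth record of
#' the exact per-subject transition matrices, gains and coupling
#' strengths. Covariate effects configured in `config$effectMap` are
#' applied on the logit scale for stay probabilities and coupling and
#' multiplicatively for gains.
#'
#' @param config a [cohortConfig()].
#' @return list with elements `timeSeries` (list of
#'   [ParcelTimeSeries-class]), `covariates` (data.frame, one row per
#'   subject) and `groundTruth` (list: per-subject `transMats`, `gains`
#'   (subject x state x parcel), `couplings`, `stateSequences`).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  cfg <- config
  withSeed(cfg$seed, {
    n <- cfg$nSubjects
    age <- stats::runif(n, cfg$ageRange[1], cfg$ageRange[2])
    sex <- stats::rbinom(n, 1, 0.5)
    zAge <- zscore(age, "age")
    conf <- vapply(cfg$confoundAgeCor, function(r) {
      r * zAge + sqrt(max(0, 1 - r^2)) * stats::rnorm(n)
    }, numeric(n))
    colnames(conf) <- names(cfg$confoundAgeCor)
    cogs <- simulateCognitiveScores(age, cfg$nCogScores,
                                    cfg$latentCogAgeSlope, cfg$cogNoiseSd)
    covariates <- data.frame(subject = paste0("sub-", seq_len(n)),
                             age = age, sex = sex, conf, cogs$scores,
                             check.names = FALSE)
    covValue <- list(age = zAge, sex = as.numeric(scale(sex)[, 1]))

    K <- cfg$K; nP <- cfg$nParcels
    transMats <- vector("list", n)
    gains <- array(NA_real_, c(n, K, nP))
    couplings <- matrix(NA_real_, n, K)
    stateSeqs <- vector("list", n)
    timeSeries <- vector("list", n)
    subjectSeeds <- sample.int(2147483646L, 2L * n)

    for (i in seq_len(n)) {
      A <- cfg$baseTransitionMatrix
      specs <- cfg$stateSpecs
      for (eff in cfg$effectMap) {
        v <- covValue[[eff$covariate]][i]
        if (eff$feature == "stay_prob") {
          A <- perturbStayProb(A, eff$state, eff$slope * v)
        } else if (eff$feature == "power") {
          ks <- if (is.null(eff$state)) seq_len(K) else eff$state
          for (k in ks) {
            g <- specs[[k]]$oscillatorGain
            g[eff$parcel] <- g[eff$parcel] * exp(eff$slope * v)
            specs[[k]]$oscillatorGain <- g
          }
        } else if (eff$feature == "coupling") {
          k <- eff$state
          c0 <- min(max(specs[[k]]$couplingStrength, 1e-6), 1 - 1e-6)
          specs[[k]]$couplingStrength <-
            stats::plogis(stats::qlogis(c0) + eff$slope * v)
        }
      }
      if (cfg$gainJitterSd > 0) {
        for (k in seq_len(K)) {
          specs[[k]]$oscillatorGain <- specs[[k]]$oscillatorGain *
            exp(cfg$gainJitterSd * stats::rnorm(nP))
        }
      }
      transMats[[i]] <- A
      for (k in seq_len(K)) {
        gains[i, k, ] <- specs[[k]]$oscillatorGain
        couplings[i, k] <- specs[[k]]$couplingStrength
      }
      s <- simulateStateSequence(A, cfg$nSamples, seed = subjectSeeds[2 * i - 1])
      stateSeqs[[i]] <- s
      ts <- simulateSubjectSignals(s, specs, cfg$samplingRateHz,
                                   seed = subjectSeeds[2 * i],
                                   crossfadeSamples = cfg$crossfadeSamples)
      ts@data <- standardizeRows(ts@data)
      ts@subjectId <- covariates$subject[i]
      timeSeries[[i]] <- ts
    }
    list(timeSeries = timeSeries, covariates = covariates,
         groundTruth = list(transMats = transMats, gains = gains,
                            couplings = couplings,
                            stateSequences = stateSeqs))
  })
}

#' Simulate data directly from a zero-mean Gaussian HMM
#'
#' Exact draws from the HMM generative model (state-conditional
#' multivariate normals with Markov switching), used for parameter
#' recovery experiments where the ground-truth covariances must be exact.
#'
#' @param covariances list of K channel x channel covariance matrices.
#' @param transMat K x K transition matrix.
#' @param nSubjects number of independent sequences.
#' @param nSamples samples per sequence.
#' @param seed optional seed.
#' @return list with `data` (list of channels x samples matrices) and
#'   `states` (list of integer sequences).
#' @export
simulateHMMData <- function(covariances, transMat, nSubjects, nSamples,
                            seed = NULL) {
  K <- length(covariances)
  checkStochasticMatrix(transMat, K)
  withSeed(seed, {
    seeds <- sample.int(2147483646L, nSubjects)
    data <- vector("list", nSubjects)
    states <- vector("list", nSubjects)
    for (i in seq_len(nSubjects)) {
      s <- simulateStateSequence(transMat, nSamples, seed = seeds[i])
      d <- nrow(covariances[[1]])
      x <- matrix(0, d, nSamples)
      for (k in seq_len(K)) {
        idx <- which(s == k)
        if (length(idx))
          x[, idx] <- t(rmvnormChol(length(idx), covariances[[k]]))
      }
      data[[i]] <- x
      states[[i]] <- s
    }
    list(data = data, states = states)
  })
}

#' Write a simulated cohort to disk
#'
#' One CSV per subject (samples x parcels with a header row), a covariate
#' CSV and a JSON ground-truth record.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if missing).
#' @return invisibly, the directory.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ts in cohort$timeSeries) {
    m <- t(tsData(ts))
    colnames(m) <- paste0("parcel", seq_len(ncol(m)))
    utils::write.csv(m, file.path(dir, paste0(ts@subjectId, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(cohort$covariates, file.path(dir, "covariates.csv"),
                   row.names = FALSE)
  gt <- cohort$groundTruth
  jsonlite::write_json(
    list(transMats = gt$transMats, gains = gt$gains,
         couplings = gt$couplings),
    file.path(dir, "ground_truth.json"), digits = NA, auto_unbox = TRUE)
  invisible(dir)
}
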