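#' Pipeline configuration
#'
#' Bundles the settings of the static (time-averaged) and transient
#' (HMM) workflows: spectral estimation, canonical bands, embedding,
#' HMM training and group-level statistics. One global seed propagates
#' to every stochastic stage.
#'
#' @param spectral a [spectralConfig()] for the time-averaged analysis.
#' @param stateSpectral a [spectralConfig()] for dual estimation
#'   (default: same settings over 1-80 Hz).
#' @param bands named band list, default [frequencyBands()].
#' @param nLagsEachSide time-delay embedding lags (default 7).
#' @param nComponents group-PCA components (default 120, capped at the
#'   embedded channel count).
#' @param train a [trainConfig()].
#' @param interest regressor of interest (default "age").
#' @param confounds confound column names; `"cog"` refers to the
#'   PCA-reduced cognitive score computed from the `cog*` columns.
#' @param nPerm permutations for the sign-flip test (default 1000).
#' @param outDir optional output directory; when set, feature tables,
#'   reports and a JSON manifest are written there.
#' @param seed global integer seed.
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(spectral = spectralConfig(),
                           stateSpectral = spectralConfig(freqRangeHz = c(1, 80)),
                           bands = frequencyBands(), nLagsEachSide = 7,
                           nComponents = 120, train = trainConfig(),
                           interest = "age",
                           confounds = c("sex", "tbv", "gm", "wm",
                                         "headsize", "hx", "hy", "hz", "cog"),
                           nPerm = 1000, outDir = NULL, seed = 1) {
  structure(list(spectral = spectral, stateSpectral = stateSpectral,
                 bands = bands, nLagsEachSide = nLagsEachSide,
                 nComponents = nComponents, train = train,
                 interest = interest, confounds = confounds, nPerm = nPerm,
                 outDir = outDir, seed = seed),
            class = "PipelineConfig")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file; top-level keys mirror the [pipelineConfig()]
#'   arguments (nested `spectral` and `train` blocks are passed to their
#'   constructors).
#' @return a `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- raw
  if (!is.null(raw$spectral)) args$spectral <- do.call(spectralConfig, raw$spectral)
  if (!is.null(raw$stateSpectral))
    args$stateSpectral <- do.call(spectralConfig, raw$stateSpectral)
  if (!is.null(raw$train)) args$train <- do.call(trainConfig, raw$train)
  if (!is.null(raw$bands)) args$bands <- lapply(raw$bands, unlist)
  do.call(pipelineConfig, args)
}

# FNV-1a hash of a serialised object, for manifest config fingerprints
configHash <- function(obj) {
  bytes <- as.integer(serialize(obj, NULL, version = 2))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# augment a covariate table with the PCA-reduced cognitive score
addCognitiveScore <- function(covariates) {
  cogCols <- grep("^cog[0-9]+$", names(covariates), value = TRUE)
  if (length(cogCols) >= 2 && !"cog" %in% names(covariates)) {
    covariates$cog <- reduceScoresPCA(as.matrix(covariates[cogCols]))$pc1
  }
  covariates
}

writeManifest <- function(outDir, cfg, extra = list()) {
  manifest <- c(list(configHash = configHash(cfg), seed = cfg$seed,
                     package = "netdyn",
                     version = as.character(utils::packageVersion("netdyn")),
                     timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
                extra)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
}

#' Run the time-averaged (static) network pipeline
#'
#' Per subject: multitaper P/CSD, coherence, band collapse into power
#' maps, coherence networks and coherence maps; then group-level
#' sign-flip max-statistic permutation GLMs of the configured interest
#' regressor on band power and band coherence features (statistics run on
#' unreferenced values).
#'
#' @param cohort list with `timeSeries` (list of
#'   [ParcelTimeSeries-class]) and `covariates` (data.frame), e.g. from
#'   [simulateCohort()].
#' @param cfg a [pipelineConfig()].
#' @return list with `power` (subjects x bands x parcels array),
#'   `coherence` (subjects x bands x parcels x parcels), `coherenceMaps`,
#'   `tests` (list of [PermResult-class]: `power`, `coherence`),
#'   `featureNames`, `design` and `covariates` (with the reduced
#'   cognitive score added).
#' @export
runStaticPipeline <- function(cohort, cfg = pipelineConfig()) {
  tsList <- cohort$timeSeries
  covariates <- addCognitiveScore(cohort$covariates)
  if (length(tsList) != nrow(covariates))
    stop("subject count mismatch between signals (", length(tsList),
         ") and covariates (", nrow(covariates), ")")
  nSub <- length(tsList)
  nP <- nParcels(tsList[[1]])
  bands <- cfg$bands
  nB <- length(bands)
  power <- array(NA_real_, c(nSub, nB, nP),
                 dimnames = list(NULL, names(bands), NULL))
  coh <- array(NA_real_, c(nSub, nB, nP, nP),
               dimnames = list(NULL, names(bands), NULL, NULL))
  cohMap <- array(NA_real_, c(nSub, nB, nP),
                  dimnames = list(NULL, names(bands), NULL))
  for (i in seq_len(nSub)) {
    est <- multitaperSpectra(tsList[[i]], cfg$spectral)
    bandPow <- bandCollapse(est, bands)
    C <- coherenceFromSpectra(est)
    bandCoh <- bandCollapse(C, bands, freqs = est@freqs)
    for (b in seq_len(nB)) {
      power[i, b, ] <- bandPow[[b]]
      net <- bandCoh[[b]]
      diag(net) <- 0
      coh[i, b, , ] <- net
      cohMap[i, b, ] <- coherenceMap(net)
    }
  }
  design <- buildDesign(covariates, cfg$interest,
                        intersect(cfg$confounds, names(covariates)))
  powerY <- matrix(power, nSub)
  powerNames <- as.vector(outer(names(bands), seq_len(nP),
                                function(b, p) paste0(b, "_parcel", p)))
  nE <- nP * (nP - 1) / 2
  cohY <- matrix(NA_real_, nSub, nB * nE)
  for (b in seq_len(nB)) {
    for (i in seq_len(nSub)) {
      m <- matrix(coh[i, b, , ], nP)
      cohY[i, (b - 1) * nE + seq_len(nE)] <- m[upper.tri(m)]
    }
  }
  cohNames <- paste0(rep(names(bands), each = nE), "_edge",
                     rep(seq_len(nE), nB))
  tests <- list(
    power = maxstatSignflipTest(powerY, design, nPerm = cfg$nPerm,
                                statistic = "beta",
                                seed = deriveSeed(cfg$seed, 101)),
    coherence = maxstatSignflipTest(cohY, design, nPerm = cfg$nPerm,
                                    statistic = "beta",
                                    seed = deriveSeed(cfg$seed, 102)))
  result <- list(power = power, coherence = coh, coherenceMaps = cohMap,
                 tests = tests,
                 featureNames = list(power = powerNames, coherence = cohNames),
                 design = design, covariates = covariates)
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    powLong <- data.frame(subject = rep(seq_len(nSub), nB * nP),
                          feature = rep(powerNames, each = nSub),
                          value = as.vector(powerY))
    utils::write.csv(powLong, file.path(cfg$outDir, "static_power.csv"),
                     row.names = FALSE)
    utils::write.csv(permReport(tests$power, powerNames),
                     file.path(cfg$outDir, "static_power_glm.csv"),
                     row.names = FALSE)
    utils::write.csv(permReport(tests$coherence, cohNames),
                     file.path(cfg$outDir, "static_coherence_glm.csv"),
                     row.names = FALSE)
    writeManifest(cfg$outDir, cfg,
                  list(stage = "static", nSubjects = nSub, nParcels = nP))
  }
  result
}

#' Run the transient (HMM) network pipeline
#'
#' Chain: time-delay embedding + group PCA + standardisation; HMM
#' training with multi-run selection; MAP state time courses; dynamics
#' summary statistics and subject transition matrices; dual-estimated
#' state spectra collapsed to broadband state maps; sign-flip
#' max-statistic permutation GLMs of the interest regressor on the
#' dynamics statistics (t-statistic, as feature scales differ) and on
#' state power (regression coefficient). Subjects missing a statistic
#' (never-visited state) are dropped per feature, with counts reported.
#'
#' @param cohort list with `timeSeries` and `covariates`.
#' @param cfg a [pipelineConfig()].
#' @return list with `hmm` ([HMMFit-class]), `stateTimeCourses`,
#'   `summaryStats` (long data.frame), `transitionMatrices`, `statePower`
#'   (subjects x states x parcels), `stateCoherence`, `dynamicsY`,
#'   `tests` (list of [PermResult-class]: `dynamics`, `statePower`),
#'   `design`, `covariates`.
#' @export
runTransientPipeline <- function(cohort, cfg = pipelineConfig()) {
  tsList <- cohort$timeSeries
  covariates <- addCognitiveScore(cohort$covariates)
  if (length(tsList) != nrow(covariates))
    stop("subject count mismatch between signals (", length(tsList),
         ") and covariates (", nrow(covariates), ")")
  nSub <- length(tsList)
  fs <- samplingRate(tsList[[1]])
  nP <- nParcels(tsList[[1]])
  prep <- prepareTrainingData(tsList, cfg$nLagsEachSide, cfg$nComponents)
  train <- cfg$train
  train$seed <- deriveSeed(cfg$seed, 7)
  fit <- fitHMM(prep$prepared, train)
  K <- fit@K
  stcs <- mapStates(fit)
  stats <- cohortSummaryStats(stcs, K = K, fs = fs)
  transMats <- lapply(stcs, function(s)
    suppressWarnings(subjectTransitionMatrix(s, K = K)))

  statePower <- array(NA_real_, c(nSub, K, nP))
  stateCoh <- array(NA_real_, c(nSub, K, nP, nP))
  for (i in seq_len(nSub)) {
    sse <- dualEstimate(tsList[[i]], stcs[[i]], K = K, cfg = cfg$stateSpectral)
    maps <- stateBandCollapse(sse)
    statePower[i, , ] <- maps$powerMaps
    stateCoh[i, , , ] <- maps$coherenceNetworks
  }

  # dynamics features: subjects x (state x statistic)
  statCols <- c("fractional_occupancy", "mean_lifetime_ms",
                "mean_interval_s", "switching_rate_hz")
  dynY <- matrix(NA_real_, nSub, K * length(statCols))
  dynNames <- as.vector(outer(statCols, seq_len(K),
                              function(s, k) paste0("state", k, "_", s)))
  for (i in seq_len(nSub)) {
    si <- stats[stats$subject == i, ]
    dynY[i, ] <- as.vector(t(as.matrix(si[statCols])))
  }
  colnames(dynY) <- dynNames

  design <- buildDesign(covariates, cfg$interest,
                        intersect(cfg$confounds, names(covariates)))
  powY <- matrix(statePower, nSub)
  powNames <- as.vector(outer(seq_len(K), seq_len(nP),
                              function(k, p) paste0("state", k, "_parcel", p)))
  tests <- list(
    dynamics = maxstatSignflipTest(dynY, design, nPerm = cfg$nPerm,
                                   statistic = "t",
                                   seed = deriveSeed(cfg$seed, 201)),
    statePower = maxstatSignflipTest(powY, design, nPerm = cfg$nPerm,
                                     statistic = "beta",
                                     seed = deriveSeed(cfg$seed, 202)))
  result <- list(hmm = fit, stateTimeCourses = stcs, summaryStats = stats,
                 transitionMatrices = transMats, statePower = statePower,
                 stateCoherence = stateCoh, dynamicsY = dynY,
                 tests = tests,
                 featureNames = list(dynamics = dynNames,
                                     statePower = powNames),
                 design = design, covariates = covariates,
                 pcaBasis = prep$basis)
  if (!is.null(cfg$outDir)) {
    dir.create(cfg$outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(stats, file.path(cfg$outDir, "dynamics_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(permReport(tests$dynamics, dynNames),
                     file.path(cfg$outDir, "dynamics_glm.csv"),
                     row.names = FALSE)
    utils::write.csv(permReport(tests$statePower, powNames),
                     file.path(cfg$outDir, "state_power_glm.csv"),
                     row.names = FALSE)
    writeManifest(cfg$outDir, cfg,
                  list(stage = "transient", nSubjects = nSub, K = K,
                       selectedRun = fit@diagnostics$runIndex,
                       droppedPerFeature = unname(colSums(is.na(dynY)))))
  }
  result
}
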