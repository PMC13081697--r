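test_that("Markov state sequences follow the generating chain", {
  # absorbing chain stays put
  s <- simulateStateSequence(diag(2), 100, initial = c(1, 0), seed = 1)
  expect_true(all(s == 1))

  # uniform chain is symmetric in occupancy
  K <- 4
  A <- matrix(1 / K, K, K)
  s <- simulateStateSequence(A, 1e5, seed = 2)
  expect_true(all(abs(table(s) / 1e5 - 0.25) < 0.01))

  # occupancies converge to the stationary distribution (eigenvector oracle)
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, 2, byrow = TRUE)
  e <- eigen(t(A))
  piOracle <- Re(e$vectors[, which.min(abs(e$values - 1))])
  piOracle <- piOracle / sum(piOracle)
  expect_equal(piOracle, c(2 / 3, 1 / 3), tolerance = 1e-12)
  s <- simulateStateSequence(A, 2e5, seed = 3)
  occ <- as.numeric(table(factor(s, 1:2)) / 2e5)
  expect_true(all(abs(occ - piOracle) < 0.01))

  # empirical transition matrix converges to the generator
  Ahat <- subjectTransitionMatrix(s, K = 2)
  expect_lt(max(rowSums(abs(Ahat - A))), 0.02)

  expect_error(simulateStateSequence(matrix(c(0.5, 0.6, 0.2, 0.8), 2, 2),
                                     10), "sum to 1")
})

test_that("subject signals carry the configured spectral content", {
  # all gains zero: pure white observation noise, flat multitaper PSD
  spec0 <- stateSpec(c(0, 0), c(0, 0), noiseSd = 1)
  ts <- simulateSubjectSignals(rep(1L, 60000), list(spec0), fs = 250, seed = 4)
  est <- multitaperSpectra(ts, spectralConfig(freqRangeHz = c(1, 100)))
  level <- 2 / 250  # one-sided density of unit-variance white noise
  se <- level / sqrt(est@nEstimates)
  expect_true(all(abs(specPsd(est) - level) < 4 * se))

  # strong 10 Hz resonator peaks within one bin of 10 Hz
  spec10 <- stateSpec(c(10), c(20), noiseSd = 0.1)
  ts <- simulateSubjectSignals(rep(1L, 20000), list(spec10), fs = 250, seed = 5)
  est <- multitaperSpectra(ts)
  peak <- specFreqs(est)[which.max(specPsd(est)[1, ])]
  expect_lte(abs(peak - 10), diff(specFreqs(est))[1])

  # coupled parcels with no observation noise are fully coherent
  specC <- stateSpec(c(12, 12), c(1, 1), couplingGroups = list(c(1, 2)),
                     couplingStrength = 1, noiseSd = 0)
  ts <- simulateSubjectSignals(rep(1L, 20000), list(specC), fs = 250, seed = 6)
  C <- coherenceFromSpectra(multitaperSpectra(ts))
  f12 <- which.min(abs(specFreqs(multitaperSpectra(ts)) - 12))
  expect_gt(C[1, 2, f12], 0.99)

  expect_error(simulateSubjectSignals(c(1L, 3L), list(spec0, spec0), 250),
               "state index")
})

test_that("cohort simulation is deterministic and honours its config", {
  cfg <- cohortConfig(nSubjects = 4, nParcels = 3, nSamples = 1500, K = 2,
                      seed = 7)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(lapply(a$timeSeries, tsData), lapply(b$timeSeries, tsData))
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$groundTruth, b$groundTruth)

  # standardised outputs
  for (ts in a$timeSeries) {
    expect_lt(max(abs(rowMeans(tsData(ts)))), 1e-10)
    expect_lt(max(abs(apply(tsData(ts), 1, var) - 1)), 1e-10)
  }
  expect_equal(nrow(a$covariates), 4)
  expect_true(all(a$covariates$age >= 18 & a$covariates$age <= 88))
  expect_false(anyNA(a$covariates))

  # effect map validation
  expect_error(cohortConfig(K = 2, nParcels = 3, effectMap = list(
    list(covariate = "age", feature = "stay_prob", state = 5, slope = 1))),
    "unknown state")
  expect_error(cohortConfig(K = 2, nParcels = 3, effectMap = list(
    list(covariate = "age", feature = "power", parcel = 9, slope = 1))),
    "unknown parcel")
})

test_that("planted stay-probability effects reach the ground truth record", {
  cfg <- cohortConfig(nSubjects = 30, nParcels = 3, nSamples = 500, K = 2,
                      effectMap = list(list(covariate = "age",
                                            feature = "stay_prob",
                                            state = 2, slope = -1)),
                      seed = 8)
  coh <- simulateCohort(cfg)
  stay <- vapply(coh$groundTruth$transMats, function(A) A[2, 2], numeric(1))
  expect_lt(cor(stay, coh$covariates$age), -0.9)
  # rows remain stochastic after the logit perturbation
  for (A in coh$groundTruth$transMats)
    expect_equal(rowSums(A), rep(1, 2), tolerance = 1e-12)
})

test_that("cognitive scores expose the latent age factor", {
  set.seed(9)
  age <- runif(200, 18, 88)
  # fully age-determined latent factor, no task noise: rank-1 structure
  cs <- simulateCognitiveScores(age, 5, latentSlope = -1, noiseSd = 0, seed = 10)
  p <- reduceScoresPCA(cs$scores)
  expect_equal(abs(cor(p$pc1, age)), 1, tolerance = 1e-8)
  expect_equal(p$varianceExplained, 1, tolerance = 1e-8)

  # no age slope: PC1 uncorrelated with age
  cs0 <- simulateCognitiveScores(age, 5, latentSlope = 0, noiseSd = 1, seed = 11)
  p0 <- reduceScoresPCA(cs0$scores)
  expect_lt(abs(cor(p0$pc1, age)), 2 / sqrt(200) * 2)

  # moderate negative slope: sign recovered across seeds
  signs <- vapply(1:20, function(s) {
    cs <- simulateCognitiveScores(age, 6, latentSlope = -0.5, noiseSd = 1,
                                  seed = 100 + s)
    sign(cor(reduceScoresPCA(cs$scores)$pc1, age))
  }, numeric(1))
  expect_gte(mean(signs < 0), 0.95)

  expect_error(simulateCognitiveScores(age, 5, noiseSd = -1), "nonnegative")
  expect_error(simulateCognitiveScores(age, 1), "nScores")
})

test_that("cohorts round-trip through the CSV/JSON writer", {
  cfg <- cohortConfig(nSubjects = 2, nParcels = 2, nSamples = 400, K = 2,
                      seed = 12)
  coh <- simulateCohort(cfg)
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  expect_true(file.exists(file.path(dir, "sub-1.csv")))
  expect_true(file.exists(file.path(dir, "covariates.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
  back <- as.matrix(read.csv(file.path(dir, "sub-1.csv")))
  expect_equal(unname(t(back)), unname(tsData(coh$timeSeries[[1]])),
               tolerance = 1e-12)
})
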