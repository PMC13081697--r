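test_that("DPSS tapers match the reference implementation and theory", {
  v <- dpssTapers(16, 4, 7)
  # frozen reference values (scipy.signal.windows.dpss(16, 4, 7))
  expect_equal(v[1:4, 1],
               c(0.000839443, 0.0065515295, 0.0269425302, 0.0761717523),
               tolerance = 1e-7)
  expect_equal(v[1:4, 2],
               c(0.0044223139, 0.0282940524, 0.0946090707, 0.2124981382),
               tolerance = 1e-7)
  # orthonormal, unit energy
  expect_equal(crossprod(v), diag(7), tolerance = 1e-8)
  # default taper count follows the 2 NW - 1 rule
  expect_identical(ncol(dpssTapers(500, 4)), 7L)
  # concentration ordering: in-band energy is nonincreasing over tapers
  n <- 128; W <- 4 / n
  freqs <- seq(0, 0.5, length.out = 2049)
  conc <- apply(dpssTapers(n, 4, 5), 2, function(tp) {
    spec <- abs(vapply(freqs, function(f)
      sum(tp * exp(-2i * pi * f * seq_len(n))), complex(1)))^2
    sum(spec[freqs <= W]) / sum(spec)
  })
  expect_true(all(diff(conc) < 1e-6))
})

test_that("multitaper PSD matches the white-noise and sinusoid oracles", {
  ts <- whiteTS(2, 60000, seed = 21)
  cfg <- spectralConfig(freqRangeHz = c(1, 100))
  est <- multitaperSpectra(ts, cfg)
  expect_equal(diff(specFreqs(est))[1], 1 / cfg$windowLengthS)
  level <- 2 / 250
  se <- level / sqrt(est@nEstimates)
  expect_true(all(abs(specPsd(est) - level) < 4 * se))

  # Parseval: one-sided density integrates to the (unit) variance
  full <- multitaperSpectra(ts, spectralConfig(freqRangeHz = c(0, 125)))
  integral <- sum(specPsd(full)[1, ]) * diff(specFreqs(full))[1]
  expect_lt(abs(integral - 1), 0.05)

  # pure sinusoid: argmax at its frequency bin
  x <- rbind(sin(2 * pi * 10 * seq_len(5000) / 250))
  e <- multitaperSpectra(parcelTimeSeries(x, 250))
  expect_equal(specFreqs(e)[which.max(specPsd(e)[1, ])], 10)

  # auto-spectrum definition: csd diagonal equals psd, CSD Hermitian
  expect_equal(Re(specCsd(est)[1, 1, ]), specPsd(est)[1, ], tolerance = 1e-12)
  expect_equal(specCsd(est)[2, 1, ], Conj(specCsd(est)[1, 2, ]),
               tolerance = 1e-12)

  expect_error(multitaperSpectra(whiteTS(1, 100), cfg), "shorter than")
  bad <- matrix(c(1, NA, 3, 4), 2)
  expect_error(multitaperSpectra(bad, cfg, fs = 250), "NaN/NA")
})

test_that("coherence respects its bounds and trivial identities", {
  ts <- whiteTS(2, 20000, seed = 22)
  x <- tsData(ts)
  # duplicated parcel and scaled parcel are perfectly coherent
  dup <- multitaperSpectra(rbind(x[1, ], x[1, ], 3 * x[1, ]),
                           fs = 250, standardize = FALSE)
  C <- coherenceFromSpectra(dup)
  expect_true(all(abs(C[1, 2, ] - 1) < 1e-10))
  expect_true(all(abs(C[1, 3, ] - 1) < 1e-10))
  # bounds and symmetry on random input
  C2 <- coherenceFromSpectra(multitaperSpectra(ts))
  expect_true(all(C2 >= 0 & C2 <= 1))
  expect_equal(C2[2, 1, ], C2[1, 2, ], tolerance = 1e-12)
  expect_true(all(C2[1, 1, ] == 1))
})

test_that("coherence of a noisy mixture matches the closed form", {
  # y = a x + noise, all white: C = a sx / sqrt(a^2 sx^2 + sn^2)
  set.seed(23)
  for (draw in 1:20) {
    a <- runif(1, 0.3, 3)
    sx <- runif(1, 0.5, 2)
    sn <- runif(1, 0.5, 2)
    x <- sx * rnorm(51000)
    y <- a * x + sn * rnorm(51000)
    est <- multitaperSpectra(rbind(x, y), fs = 250)
    C <- coherenceFromSpectra(est)
    oracle <- a * sx / sqrt(a^2 * sx^2 + sn^2)
    expect_lt(abs(mean(C[1, 2, ]) - oracle), 0.02)
  }
})

test_that("band collapse averages bins whose centre lies in [low, high)", {
  freqs <- seq(1, 45, by = 0.5)
  psd <- matrix(3, 2, length(freqs))
  bands <- frequencyBands()
  bp <- bandCollapse(psd, bands, freqs = freqs)
  for (b in names(bands)) expect_equal(unname(bp[[b]]), c(3, 3))

  # 3-bin hand example: mean of (1, 2, 6) is 3
  psd2 <- matrix(c(1, 2, 6), 1, 3)
  expect_equal(unname(bandCollapse(psd2, list(all = c(0, 4)),
                                   freqs = c(1, 2, 3))$all), 3)

  # half-open bands: a bin at 4 Hz belongs to theta, not delta
  psd3 <- matrix(c(1, 1, 1, 9), 1, 4)
  bp3 <- bandCollapse(psd3, list(delta = c(1, 4), theta = c(4, 8)),
                      freqs = c(1, 2, 3, 4))
  expect_equal(unname(bp3$delta), 1)
  expect_equal(unname(bp3$theta), 9)

  # coherence array constant 0.4 in alpha, 0.1 elsewhere
  nf <- length(freqs)
  C <- array(0.1, c(3, 3, nf))
  C[, , freqs >= 8 & freqs < 13] <- 0.4
  bc <- bandCollapse(C, bands, freqs = freqs)
  expect_true(all(abs(bc$alpha - 0.4) < 1e-12))
  expect_true(all(abs(bc$delta - 0.1) < 1e-12))

  expect_error(bandCollapse(psd, list(hi = c(200, 300)), freqs = freqs),
               "no retained bins")
})

test_that("coherence maps average the off-diagonal edges per parcel", {
  m <- matrix(0, 3, 3)
  m[1, 2] <- m[2, 1] <- 0.6
  m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.4
  expect_equal(coherenceMap(m), c(0.4, 0.5, 0.3))
  expect_equal(coherenceMap(matrix(0, 4, 4)), rep(0, 4))
  cm <- matrix(0.7, 5, 5)
  expect_equal(coherenceMap(cm), rep(0.7, 5))
  asym <- m; asym[1, 2] <- 0.61
  expect_error(coherenceMap(asym), "asymmetric")
})

test_that("weighted band reference uses bin-count weights", {
  # widths 3 and 6 Hz with values 1 and 4: (3*1 + 6*4)/9 = 3
  ref <- weightedBandReference(list(a = matrix(1, 2, 2), b = matrix(4, 2, 2)),
                               weights = c(3, 6))
  expect_equal(ref, matrix(3, 2, 2))
  # equal widths reduce to the simple mean
  ref2 <- weightedBandReference(list(matrix(1, 2, 2), matrix(5, 2, 2)),
                                weights = c(2, 2))
  expect_equal(ref2, matrix(3, 2, 2))
  # single band: the reference is the band itself
  expect_equal(weightedBandReference(list(matrix(7, 2, 2)), weights = 1),
               matrix(7, 2, 2))
  # weights derived from the frequency axis
  freqs <- seq(1, 12.5, by = 0.5)
  w <- bandBinCounts(list(delta = c(1, 4), alpha = c(8, 13)), freqs)
  expect_identical(unname(w), c(6L, 10L))
  expect_error(weightedBandReference(list(matrix(1, 2, 2), matrix(1, 3, 3))),
               "common shape")
})

test_that("edge thresholding keeps the ceiling count with deterministic ties", {
  set.seed(24)
  p <- 15  # 105 unique-magnitude edges
  mkNet <- function() {
    m <- matrix(0, p, p)
    m[upper.tri(m)] <- sample(seq_len(p * (p - 1) / 2))
    m + t(m)
  }
  nets <- list(a = mkNet(), b = mkNet())
  out <- referenceAndThreshold(nets, topFraction = 0.03)
  expect_identical(sum(out$mask$a[upper.tri(out$mask$a)]),
                   as.integer(ceiling(0.03 * 105)))
  # the kept edges are those of largest absolute referenced value
  vals <- abs(out$referenced$a[upper.tri(out$referenced$a)])
  kept <- out$mask$a[upper.tri(out$mask$a)]
  expect_gte(min(vals[kept]), max(vals[!kept]))

  # topFraction 1 keeps everything
  all1 <- referenceAndThreshold(nets, topFraction = 1)
  expect_true(all(all1$mask$a[upper.tri(all1$mask$a)]))

  # identical networks across bands reference to zero
  same <- list(a = nets$a, b = nets$a)
  z <- referenceAndThreshold(same, topFraction = 0.5)
  expect_equal(z$referenced$a, matrix(0, p, p))

  expect_error(referenceAndThreshold(nets, topFraction = 0), "0, 1")
  expect_error(referenceAndThreshold(nets["a"], topFraction = 0.5),
               "at least 2 bands")
})
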