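test_that("cognitive-score PCA reduction follows the positive-loading rule", {
  set.seed(81)
  # two perfectly correlated tasks: equal loadings, all variance on PC1
  base <- rnorm(50)
  scores <- cbind(a = base, b = 2 * base + 5)
  p <- reduceScoresPCA(scores)
  expect_equal(unname(p$loadings[1]), unname(p$loadings[2]), tolerance = 1e-10)
  expect_equal(p$varianceExplained, 1, tolerance = 1e-10)

  # generator ground truth: negative latent age slope shows in PC1
  age <- runif(150, 18, 88)
  cs <- simulateCognitiveScores(age, 6, latentSlope = -0.8, noiseSd = 0.5,
                                seed = 82)
  p2 <- reduceScoresPCA(cs$scores)
  expect_lt(cor(p2$pc1, age), 0)
  expect_true(all(p2$loadings > 0))

  # flipping every task flips PC1's external correlation, not the loadings
  p3 <- reduceScoresPCA(-cs$scores)
  expect_true(all(p3$loadings > 0))
  expect_equal(cor(p3$pc1, age), -cor(p2$pc1, age), tolerance = 1e-8)

  expect_error(reduceScoresPCA(cbind(rep(1, 10), rnorm(10))), "constant task")
  expect_error(reduceScoresPCA(matrix(rnorm(5), 5, 1)), "at least 2 tasks")
})

test_that("design matrices are standardised, named and rank-checked", {
  set.seed(83)
  cov <- data.frame(age = runif(100, 18, 88), sex = rbinom(100, 1, 0.5),
                    tbv = rnorm(100), gm = rnorm(100), wm = rnorm(100),
                    headsize = rnorm(100), hx = rnorm(100), hy = rnorm(100),
                    hz = rnorm(100), cog = rnorm(100))
  d <- buildDesign(cov, "age")
  expect_identical(dim(d@X), c(100L, 2L))
  expect_equal(unname(d@X[, 1]), rep(1, 100))
  expect_lt(abs(mean(d@X[, "age"])), 1e-10)
  expect_equal(sd(d@X[, "age"]), 1, tolerance = 1e-10)

  # the full confound set: constant + age + 9 confounds = 11 columns
  full <- buildDesign(cov, "age", c("sex", "tbv", "gm", "wm", "headsize",
                                    "hx", "hy", "hz", "cog"))
  expect_identical(ncol(full@X), 11L)

  cov$tbv2 <- cov$tbv
  expect_error(buildDesign(cov, "age", c("tbv", "tbv2")),
               "perfectly correlated")
  expect_error(buildDesign(cov, "age", "nope"), "not found")
})

test_that("the GLM reproduces exact and pseudo-inverse solutions", {
  set.seed(84)
  cov <- data.frame(age = rnorm(50), sex = rbinom(50, 1, 0.5),
                    tbv = rnorm(50))
  d <- buildDesign(cov, "age", c("sex", "tbv"))
  # exact linear target
  y <- matrix(2 * d@X[, "age"], 50, 1)
  f <- fitGLM(y, d)
  expect_equal(unname(f$beta["age", 1]), 2, tolerance = 1e-10)
  expect_lt(max(abs(crossprod(d@X, f$residuals))), 1e-8)

  # random problem vs normal-equations oracle
  d8 <- buildDesign(data.frame(age = rnorm(50), sex = rbinom(50, 1, 0.5),
                               a = rnorm(50), b = rnorm(50), c = rnorm(50),
                               e = rnorm(50), g = rnorm(50)),
                    "age", c("sex", "a", "b", "c", "e", "g"))
  Y <- matrix(rnorm(50 * 6), 50)
  f8 <- fitGLM(Y, d8)
  oracle <- solve(t(d8@X) %*% d8@X) %*% t(d8@X) %*% Y
  expect_equal(unname(f8$beta), unname(oracle), tolerance = 1e-8)

  # per-feature subject dropping for missing values
  Yna <- Y
  Yna[3, 2] <- NA
  fna <- fitGLM(Yna, d8)
  expect_identical(unname(fna$droppedSubjects[2]), 1)
  ok <- !is.na(Yna[, 2])
  oracle2 <- qr.solve(d8@X[ok, ], Yna[ok, 2])
  expect_equal(unname(fna$beta[, 2]), unname(oracle2), tolerance = 1e-8)
  expect_equal(unname(fna$beta[, 1]), unname(oracle[, 1]), tolerance = 1e-10)

  expect_error(fitGLM(Y[1:5, ], d8), "differ")
})

test_that("a planted effect is detected and the constant case degenerates", {
  set.seed(85)
  n <- 60
  d <- buildDesign(data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5)),
                   "age", "sex")
  y <- matrix(rnorm(n * 20), n)
  y[, 1] <- 5 * d@X[, "age"] + rnorm(n, sd = 0.5)
  pr <- maxstatSignflipTest(y, d, nPerm = 500, seed = 86)
  expect_lt(permPValues(pr)[1], 0.05)
  expect_lte(sum(permPValues(pr)[-1] < 0.05), 1)
  expect_length(pr@nullMax, 500)
  expect_true(all(permPValues(pr) > 0 & permPValues(pr) <= 1))

  # constant target: all statistics 0, all p-values 1
  yc <- matrix(1, n, 3)
  pc <- maxstatSignflipTest(yc, d, nPerm = 50, seed = 87)
  expect_equal(permObserved(pc), rep(0, 3))
  expect_equal(permPValues(pc), rep(1, 3))

  # determinism given the seed
  pr2 <- maxstatSignflipTest(y, d, nPerm = 500, seed = 86)
  expect_identical(pr@nullMax, pr2@nullMax)
})

test_that("the max-statistic null is calibrated under a global null", {
  set.seed(88)
  n <- 40
  d <- buildDesign(data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5)),
                   "age", "sex")
  rej <- vapply(1:60, function(r) {
    y <- withr::with_seed(1000 + r, matrix(rnorm(n * 25), n))
    any(permPValues(maxstatSignflipTest(y, d, nPerm = 200, seed = r)) < 0.05)
  }, logical(1))
  # expected 5%; allow the exact binomial 99% range for 60 repeats
  expect_gte(sum(rej), qbinom(0.005, 60, 0.05))
  expect_lte(sum(rej), qbinom(0.995, 60, 0.05))
})

test_that("confound regression removes a pure confound signal", {
  set.seed(89)
  n <- 80
  cleared <- vapply(1:10, function(r) {
    withr::with_seed(2000 + r, {
      age <- rnorm(n)
      tbv <- 0.4 * age + sqrt(1 - 0.16) * rnorm(n)  # confound tracks age
      cov <- data.frame(age = age, tbv = tbv)
      y <- matrix(tbv + 0.2 * rnorm(n), n, 1)       # target is confound-driven
      dNo <- buildDesign(cov, "age")
      dYes <- buildDesign(cov, "age", "tbv")
      bNo <- abs(fitGLM(y, dNo)$beta["age", 1])
      bYes <- abs(fitGLM(y, dYes)$beta["age", 1])
      p <- permPValues(maxstatSignflipTest(y, dYes, nPerm = 200, seed = r))
      (bYes < bNo) && (p > 0.05)
    })
  }, logical(1))
  expect_gte(mean(cleared), 0.9)
})

test_that("beta and t statistics agree on homoscedastic features", {
  set.seed(90)
  n <- 70
  d <- buildDesign(data.frame(age = rnorm(n), sex = rbinom(n, 1, 0.5)),
                   "age", "sex")
  y <- matrix(rnorm(n * 10), n)
  y[, 4] <- y[, 4] + 1.2 * d@X[, "age"]
  pb <- maxstatSignflipTest(y, d, nPerm = 300, statistic = "beta", seed = 91)
  pt <- maxstatSignflipTest(y, d, nPerm = 300, statistic = "t", seed = 91)
  expect_identical(permPValues(pb) < 0.05, permPValues(pt) < 0.05)
  expect_identical(pt@statistic, "t")
})
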