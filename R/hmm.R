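#' HMM training configuration
#'
#' @param K number of states (default 10, the usual choice for
#'   resting-state MEG network modelling).
#' @param nRuns independent training runs from random initialisations;
#'   the run with the lowest final objective is selected (default 5).
#' @param maxIter maximum EM iterations per run.
#' @param tol relative objective-change convergence tolerance.
#' @param covReg diagonal covariance regularisation, as a fraction of the
#'   mean state variance added to the diagonal (default 1e-5). Guards
#'   against singular accumulated covariances.
#' @param method `"em"` (full-batch Baum-Welch EM, deterministic given
#'   the seed; the default) or `"stochastic"` (mini-batch stochastic EM
#'   with Robbins-Monro averaging of the sufficient statistics).
#' @param batchSize subjects per mini-batch in stochastic mode.
#' @param forgetRate,delay stochastic step-size schedule
#'   `rho_i = (i + delay)^(-forgetRate)`.
#' @param seed integer seed controlling initialisation (and batching).
#' @return list of class `TrainConfig`.
#' @export
trainConfig <- function(K = 10, nRuns = 5, maxIter = 100, tol = 1e-6,
                        covReg = 1e-5, method = c("em", "stochastic"),
                        batchSize = 2, forgetRate = 0.7, delay = 5,
                        seed = 1) {
  method <- match.arg(method)
  if (K < 1) stop("K must be >= 1")
  if (nRuns < 1) stop("nRuns must be >= 1")
  if (covReg < 0) stop("covReg must be >= 0")
  structure(list(K = as.integer(K), nRuns = as.integer(nRuns),
                 maxIter = as.integer(maxIter), tol = tol, covReg = covReg,
                 method = method, batchSize = as.integer(batchSize),
                 forgetRate = forgetRate, delay = delay, seed = seed),
            class = "TrainConfig")
}

# per-state Gaussian log-densities: K x T matrix for data x (d x T)
stateLogDensities <- function(x, covariances) {
  d <- nrow(x); T <- ncol(x); K <- length(covariances)
  logB <- matrix(0, K, T)
  for (k in seq_len(K)) {
    L <- tryCatch(chol(covariances[[k]]), error = function(e)
      stop("state covariance ", k, " is singular; increase covReg ",
           "(diagonal regularisation) above zero", call. = FALSE))
    logdet <- 2 * sum(log(diag(L)))
    Q <- backsolve(L, x, transpose = TRUE)
    logB[k, ] <- -0.5 * (d * log(2 * pi) + logdet + colSums(Q^2))
  }
  logB
}

# E-step over a list of subjects; returns posteriors and pooled stats
eStep <- function(data, covariances, A, pi0) {
  K <- length(covariances)
  d <- nrow(data[[1]])
  posteriors <- vector("list", length(data))
  scatter <- lapply(seq_len(K), function(k) matrix(0, d, d))
  gammaSum <- numeric(K)
  xiSum <- matrix(0, K, K)
  gamma1 <- numeric(K)
  loglik <- 0
  for (i in seq_along(data)) {
    x <- data[[i]]
    logB <- stateLogDensities(x, covariances)
    fb <- .forwardBackwardC(logB, A, pi0)
    g <- fb$gamma
    posteriors[[i]] <- list(gamma = g, xi = fb$xi, loglik = fb$loglik)
    loglik <- loglik + fb$loglik
    xiSum <- xiSum + fb$xi
    gamma1 <- gamma1 + g[, 1]
    for (k in seq_len(K)) {
      scatter[[k]] <- scatter[[k]] + tcrossprod(sweep(x, 2, g[k, ], "*"), x)
      gammaSum[k] <- gammaSum[k] + sum(g[k, ])
    }
  }
  list(posteriors = posteriors, scatter = scatter, gammaSum = gammaSum,
       xiSum = xiSum, gamma1 = gamma1 / length(data), loglik = loglik)
}

# M-step from pooled sufficient statistics
mStep <- function(stats, covReg, K, d) {
  covariances <- vector("list", K)
  for (k in seq_len(K)) {
    if (stats$gammaSum[k] < sqrt(.Machine$double.eps)) {
      # dead state: fall back to pooled covariance scale
      pooled <- Reduce(`+`, stats$scatter) / sum(stats$gammaSum)
      covariances[[k]] <- pooled
    } else {
      covariances[[k]] <- stats$scatter[[k]] / stats$gammaSum[k]
    }
    covariances[[k]] <- (covariances[[k]] + t(covariances[[k]])) / 2
    if (covReg > 0) {
      eps <- covReg * mean(diag(covariances[[k]]))
      covariances[[k]] <- covariances[[k]] + diag(eps, d)
    }
  }
  rs <- rowSums(stats$xiSum)
  A <- stats$xiSum
  for (k in seq_len(K)) {
    A[k, ] <- if (rs[k] > 0) A[k, ] / rs[k] else rep(1 / K, K)
  }
  pi0 <- stats$gamma1 / sum(stats$gamma1)
  list(covariances = covariances, A = A, pi0 = pi0)
}

# one training run from a random initialisation
fitHMMRun <- function(data, cfg, runSeed) {
  K <- cfg$K
  d <- nrow(data[[1]])
  withSeed(runSeed, {
    # random soft assignment -> initial covariances; diagonal-dominant A
    init <- list(scatter = lapply(seq_len(K), function(k) matrix(0, d, d)),
                 gammaSum = numeric(K),
                 xiSum = matrix(1, K, K) + diag(9, K),
                 gamma1 = rep(1 / K, K))
    for (x in data) {
      g <- matrix(stats::runif(K * ncol(x)), K)
      g <- sweep(g, 2, colSums(g), "/")
      for (k in seq_len(K)) {
        init$scatter[[k]] <- init$scatter[[k]] +
          tcrossprod(sweep(x, 2, g[k, ], "*"), x)
        init$gammaSum[k] <- init$gammaSum[k] + sum(g[k, ])
      }
    }
    params <- mStep(init, max(cfg$covReg, 1e-8), K, d)

    if (cfg$method == "em") {
      trace <- numeric(0)
      converged <- FALSE
      es <- NULL
      for (it in seq_len(cfg$maxIter)) {
        es <- eStep(data, params$covariances, params$A, params$pi0)
        trace <- c(trace, -es$loglik)
        if (it > 1 && abs(trace[it] - trace[it - 1]) <=
              cfg$tol * abs(trace[it - 1])) {
          converged <- TRUE
          break
        }
        params <- mStep(es, cfg$covReg, K, d)
      }
    } else {
      # stochastic mini-batch EM: blend batch statistics scaled to the
      # full cohort into a running average with a decaying step size
      nSub <- length(data)
      run <- NULL
      for (it in seq_len(cfg$maxIter)) {
        idx <- sample.int(nSub, min(cfg$batchSize, nSub))
        es <- eStep(data[idx], params$covariances, params$A, params$pi0)
        scale <- nSub / length(idx)
        batch <- list(scatter = lapply(es$scatter, `*`, scale),
                      gammaSum = es$gammaSum * scale,
                      xiSum = es$xiSum * scale, gamma1 = es$gamma1)
        rho <- (it + cfg$delay)^(-cfg$forgetRate)
        run <- if (is.null(run)) batch else {
          list(scatter = Map(function(a, b) (1 - rho) * a + rho * b,
                             run$scatter, batch$scatter),
               gammaSum = (1 - rho) * run$gammaSum + rho * batch$gammaSum,
               xiSum = (1 - rho) * run$xiSum + rho * batch$xiSum,
               gamma1 = (1 - rho) * run$gamma1 + rho * batch$gamma1)
        }
        params <- mStep(run, cfg$covReg, K, d)
      }
      es <- eStep(data, params$covariances, params$A, params$pi0)
      trace <- -es$loglik
      converged <- FALSE
    }
    # final posteriors under the final parameters
    final <- eStep(data, params$covariances, params$A, params$pi0)
    list(params = params, posteriors = final$posteriors,
         trace = trace, converged = converged,
         finalObjective = -final$loglik)
  })
}

#' Fit a zero-mean Gaussian-covariance HMM
#'
#' Group-level hidden Markov model in which each state emits zero-mean
#' multivariate normal observations with a state-specific covariance, so
#' states are recurring covariance (hence spectral/connectivity)
#' patterns. Subjects are treated as independent sequences sharing one
#' set of parameters. Training runs Baum-Welch EM (or stochastic
#' mini-batch EM) from `nRuns` random initialisations and keeps the run
#' with the lowest final objective (negative log-likelihood; lower is
#' better).
#'
#' @param data list of channels x samples matrices, one per subject
#'   (typically the output of [prepareTrainingData()]).
#' @param cfg a [trainConfig()].
#' @return an [HMMFit-class].
#' @export
fitHMM <- function(data, cfg = trainConfig()) {
  stopifnot(inherits(cfg, "TrainConfig"))
  data <- lapply(data, function(x)
    if (is(x, "ParcelTimeSeries")) x@data else as.matrix(x))
  d <- nrow(data[[1]])
  for (x in data) {
    if (nrow(x) != d) stop("all subjects must share the channel count")
    if (ncol(x) < cfg$K) stop("each subject needs at least K samples")
  }
  runSeeds <- vapply(seq_len(cfg$nRuns), function(r)
    deriveSeed(cfg$seed, r), integer(1))
  runs <- lapply(runSeeds, function(s) fitHMMRun(data, cfg, s))
  best <- selectBestRun(runs)
  run <- runs[[best]]
  new("HMMFit", K = cfg$K, covariances = run$params$covariances,
      transMat = run$params$A, initProb = run$params$pi0,
      posteriors = run$posteriors,
      diagnostics = list(trace = run$trace, converged = run$converged,
                         runIndex = best,
                         finalObjective = run$finalObjective,
                         allObjectives = vapply(runs, `[[`, numeric(1),
                                                "finalObjective"),
                         method = cfg$method, seed = cfg$seed))
}

#' Model selection objective (negative log-likelihood)
#'
#' Evaluates the selection objective of fitted HMM parameters on data:
#' the negative log-likelihood under the model, the quantity minimised
#' across training restarts (lower is better). Additive over independent
#' sequences.
#'
#' @param fit an [HMMFit-class], or a list with `covariances`,
#'   `transMat`/`A` and `initProb`/`pi0`.
#' @param data list of channels x samples matrices.
#' @return scalar objective value.
#' @export
freeEnergy <- function(fit, data) {
  if (is(fit, "HMMFit")) {
    covs <- fit@covariances; A <- fit@transMat; pi0 <- fit@initProb
  } else {
    covs <- fit$covariances
    A <- if (!is.null(fit$transMat)) fit$transMat else fit$A
    pi0 <- if (!is.null(fit$initProb)) fit$initProb else fit$pi0
  }
  d <- nrow(covs[[1]])
  total <- 0
  for (x in data) {
    x <- if (is(x, "ParcelTimeSeries")) x@data else as.matrix(x)
    if (nrow(x) != d)
      stop("channel count mismatch: model has ", d, ", data has ", nrow(x))
    logB <- stateLogDensities(x, covs)
    total <- total + .forwardBackwardC(logB, A, pi0)$loglik
  }
  -total
}

#' Select the best of several training runs
#'
#' Returns the index of the run with the lowest final objective; ties go
#' to the lowest run index.
#'
#' @param runs list of fitted runs, each with a `finalObjective` element
#'   (or a `diagnostics$finalObjective` for [HMMFit-class] objects).
#' @return integer index of the selected run.
#' @export
selectBestRun <- function(runs) {
  if (!length(runs)) stop("no runs to select from")
  obj <- vapply(runs, function(r) {
    if (is(r, "HMMFit")) r@diagnostics$finalObjective else r$finalObjective
  }, numeric(1))
  which.min(obj)
}

#' Match estimated states to reference states
#'
#' Finds the state permutation maximising the summed Pearson correlation
#' between vectorised estimated and reference covariances (exhaustive for
#' K <= 8, greedy beyond).
#'
#' @param estimated,reference lists of K covariance matrices.
#' @return list with `perm` (index such that `estimated[perm[k]]` matches
#'   `reference[k]`) and `correlations` (matched per-state correlation).
#' @export
matchStates <- function(estimated, reference) {
  K <- length(reference)
  if (length(estimated) != K) stop("state counts differ")
  cc <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      a <- as.numeric(reference[[i]])
      b <- as.numeric(estimated[[j]])
      cc[i, j] <- if (length(a) > 1 && stats::sd(a) > 0 && stats::sd(b) > 0) {
        stats::cor(a, b)
      } else {
        # scalar covariances: similarity by log-variance closeness
        -abs(log(mean(diag(estimated[[j]])) / mean(diag(reference[[i]]))))
      }
    }
  }
  perm <- if (K <= 8) {
    perms <- permutations(K)
    scores <- apply(perms, 1, function(p) sum(cc[cbind(seq_len(K), p)]))
    perms[which.max(scores), ]
  } else {
    greedyAssign(cc)
  }
  perm <- unname(as.integer(perm))
  list(perm = perm, correlations = unname(cc[cbind(seq_len(K), perm)]))
}

permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    out <- rbind(out, cbind(i, matrix(rest[sub], nrow(sub))))
  }
  out
}

greedyAssign <- function(cc) {
  K <- nrow(cc)
  perm <- integer(K)
  used <- logical(K)
  for (i in order(-apply(cc, 1, max))) {
    j <- order(-cc[i, ])
    j <- j[!used[j]][1]
    perm[i] <- j
    used[j] <- TRUE
  }
  perm
}
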