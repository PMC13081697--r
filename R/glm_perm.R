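#' PCA reduction of cognitive task scores
#'
#' Z-scores each task column, applies PCA across subjects and returns the
#' first principal component as a single cognitive-performance measure.
#' The component sign is fixed so that the mean loading is positive: an
#' increase in the score then means an increase across the tasks.
#'
#' @param scores subjects x tasks numeric matrix, no missing values.
#' @return list with `pc1` (per-subject score), `loadings` (per task),
#'   `varianceExplained` (fraction explained by PC1).
#' @export
reduceScoresPCA <- function(scores) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 2) stop("need at least 2 tasks")
  if (nrow(scores) < 3) stop("need at least 3 subjects")
  if (anyNA(scores)) stop("scores contain missing values")
  sds <- apply(scores, 2, stats::sd)
  if (any(sds == 0))
    stop("constant task column: ",
         paste(colnames(scores)[sds == 0], collapse = ", "))
  z <- scale(scores)
  p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  loadings <- p$rotation[, 1]
  pc1 <- p$x[, 1]
  if (mean(loadings) < 0) {
    loadings <- -loadings
    pc1 <- -pc1
  }
  list(pc1 = as.numeric(pc1), loadings = loadings,
       varianceExplained = p$sdev[1]^2 / sum(p$sdev^2))
}

#' Build a confound-aware design matrix
#'
#' Constructs `constant + interest + confounds` from a covariate table.
#' Non-constant columns are z-scored across subjects. For cognition
#' analyses, include `"age"` among the confounds so any cognitive effect
#' is not an indirect age effect.
#'
#' @param covariates data.frame, one row per subject.
#' @param interest name of the regressor of interest.
#' @param confounds character vector of confound column names.
#' @return a [GLMDesign-class].
#' @examples
#' cov <- data.frame(age = rnorm(20), sex = rbinom(20, 1, 0.5))
#' design <- buildDesign(cov, "age", "sex")
#' @export
buildDesign <- function(covariates, interest, confounds = character()) {
  cols <- c(interest, confounds)
  missing <- setdiff(cols, names(covariates))
  if (length(missing))
    stop("covariate columns not found: ", paste(missing, collapse = ", "))
  n <- nrow(covariates)
  if (n <= length(cols) + 1)
    stop("need more subjects than regressors")
  X <- cbind(constant = rep(1, n),
             vapply(cols, function(cn)
               zscore(as.numeric(covariates[[cn]]), cn), numeric(n)))
  colnames(X) <- c("constant", cols)
  # name the offending pair on exact collinearity
  if (ncol(X) > 2) {
    cc <- stats::cor(X[, -1, drop = FALSE])
    diag(cc) <- 0
    if (any(abs(cc) > 1 - 1e-12)) {
      ij <- which(abs(cc) > 1 - 1e-12, arr.ind = TRUE)[1, ]
      stop("design is rank deficient: regressors '", cols[ij[1]],
           "' and '", cols[ij[2]], "' are perfectly correlated")
    }
  }
  new("GLMDesign", X = X, regressorNames = colnames(X), interest = interest)
}

# core OLS for a fixed design: beta (p x F), residuals, sigma2, t-stats
olsFit <- function(X, y, interestIdx = NULL) {
  XtX <- crossprod(X)
  XtXinv <- chol2inv(chol(XtX))
  beta <- XtXinv %*% crossprod(X, y)
  resid <- y - X %*% beta
  dof <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / dof
  out <- list(beta = beta, residuals = resid, sigma2 = sigma2, dof = dof)
  if (!is.null(interestIdx)) {
    se <- sqrt(sigma2 * XtXinv[interestIdx, interestIdx])
    out$tInterest <- ifelse(se > 0, beta[interestIdx, ] / se, 0)
  }
  out
}

#' Fit a group-level GLM across all features
#'
#' Ordinary least squares of `y = X beta + eps`, all features jointly.
#' Features containing missing values are fitted on their complete
#' subjects only (the per-feature subject-dropping rule), with the
#' dropped counts reported.
#'
#' @param y subjects x features matrix (may contain NA).
#' @param design a [GLMDesign-class].
#' @return list with `beta` (regressors x features), `residuals`
#'   (subjects x features, NA where y was NA), `sigma2`, `dof`,
#'   `tInterest` (t-statistic of the interest regressor per feature) and
#'   `droppedSubjects` (per feature).
#' @export
fitGLM <- function(y, design) {
  stopifnot(is(design, "GLMDesign"))
  y <- as.matrix(y)
  X <- design@X
  if (nrow(y) != nrow(X)) stop("y and design subject counts differ")
  if (nrow(X) < ncol(X) + 1) stop("fewer subjects than regressors")
  iIdx <- match(design@interest, design@regressorNames)
  dropped <- colSums(is.na(y))
  complete <- which(dropped == 0)
  p <- ncol(X); Fn <- ncol(y)
  beta <- matrix(NA_real_, p, Fn,
                 dimnames = list(design@regressorNames, colnames(y)))
  residuals <- matrix(NA_real_, nrow(y), Fn)
  sigma2 <- numeric(Fn)
  tInterest <- numeric(Fn)
  if (length(complete)) {
    f <- olsFit(X, y[, complete, drop = FALSE], iIdx)
    beta[, complete] <- f$beta
    residuals[, complete] <- f$residuals
    sigma2[complete] <- f$sigma2
    tInterest[complete] <- f$tInterest
  }
  for (j in which(dropped > 0)) {
    ok <- !is.na(y[, j])
    if (sum(ok) < p + 1)
      stop("feature ", j, " has fewer complete subjects than regressors")
    f <- olsFit(X[ok, , drop = FALSE], y[ok, j, drop = FALSE], iIdx)
    beta[, j] <- f$beta
    residuals[ok, j] <- f$residuals
    sigma2[j] <- f$sigma2
    tInterest[j] <- f$tInterest
  }
  list(beta = beta, residuals = residuals, sigma2 = sigma2,
       dof = nrow(X) - p, tInterest = tInterest,
       droppedSubjects = dropped)
}

#' Sign-flip max-statistic permutation test
#'
#' Tests whether the regressor of interest explains any feature, with
#' family-wise error control across all features. Each permutation flips
#' the sign of every entry of the interest regressor independently with
#' probability 1/2, refits the GLM once for all features jointly, and
#' records the maximum absolute statistic across features; the shared
#' null of these maxima gives each feature a FWE-corrected p-value
#' `(1 + #{null >= observed}) / (1 + nPerm)`. The statistic is the raw
#' regression coefficient (`"beta"`) or the t-statistic (`"t"`, useful
#' when feature scales differ, as across dynamics statistics).
#'
#' @param y subjects x features matrix (NA handled per feature).
#' @param design a [GLMDesign-class].
#' @param nPerm number of sign-flip permutations (default 1000).
#' @param statistic `"beta"` or `"t"`.
#' @param seed integer seed for the sign flips.
#' @param alpha significance level used for the `significant` flag.
#' @return a [PermResult-class].
#' @export
maxstatSignflipTest <- function(y, design, nPerm = 1000,
                                statistic = c("beta", "t"), seed = 1,
                                alpha = 0.05) {
  statistic <- match.arg(statistic)
  stopifnot(is(design, "GLMDesign"))
  if (nPerm < 1) stop("nPerm must be >= 1")
  y <- as.matrix(y)
  X <- design@X
  iIdx <- match(design@interest, design@regressorNames)
  obsFit <- fitGLM(y, design)
  observed <- if (statistic == "beta") obsFit$beta[iIdx, ] else obsFit$tInterest
  # zap solver noise so features the design cannot explain score exactly 0
  eps <- 1e-12 * max(abs(y), 1)
  zap <- function(v) ifelse(abs(v) < eps, 0, v)
  observed <- zap(as.numeric(observed))

  nullMax <- withSeed(seed, {
    vapply(seq_len(nPerm), function(b) {
      flips <- sample(c(-1, 1), nrow(X), replace = TRUE)
      Xp <- X
      # re-standardise the flipped column: every regressor in a design is
      # z-scored, and an unstandardised permuted column would inflate the
      # null coefficients relative to the observed ones
      v <- X[, iIdx] * flips
      Xp[, iIdx] <- (v - mean(v)) / stats::sd(v)
      designP <- design
      designP@X <- Xp
      f <- fitGLM(y, designP)
      s <- zap(if (statistic == "beta") f$beta[iIdx, ] else f$tInterest)
      max(abs(s), na.rm = TRUE)
    }, numeric(1))
  })
  p <- vapply(abs(observed), function(o)
    (1 + sum(nullMax >= o)) / (1 + nPerm), numeric(1))
  new("PermResult", observed = observed, nullMax = nullMax, pValues = p,
      statistic = statistic, interest = design@interest, seed = seed)
}

#' Tidy permutation-test report
#'
#' @param perm a [PermResult-class].
#' @param featureNames optional feature names.
#' @param alpha significance level (default 0.05).
#' @return data.frame: feature, observed statistic, p-value, significance.
#' @export
permReport <- function(perm, featureNames = NULL, alpha = 0.05) {
  n <- length(perm@observed)
  data.frame(feature = featureNames %||% paste0("feature", seq_len(n)),
             statistic = perm@statistic, observed = perm@observed,
             p_value = perm@pValues,
             significant = perm@pValues < alpha)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
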