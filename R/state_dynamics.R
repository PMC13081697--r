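#' Maximum a posteriori state time course
#'
#' Collapses marginal state probabilities to a mutually exclusive state
#' sequence by taking the most probable state at each sample; ties go to
#' the lowest state index.
#'
#' @param gamma K x samples matrix of marginal state probabilities (one
#'   subject), or an [HMMFit-class] (returns a list over subjects).
#' @return integer vector of states in 1..K (or a list of them).
#' @export
mapStates <- function(gamma) {
  if (is(gamma, "HMMFit"))
    return(lapply(gamma@posteriors, function(p) mapStates(p$gamma)))
  if (anyNA(gamma)) stop("gamma contains NaN/NA values")
  max.col(t(gamma), ties.method = "first")
}

# run-length view of a state sequence
stateRuns <- function(stc) {
  r <- rle(stc)
  ends <- cumsum(r$lengths)
  data.frame(state = r$values, length = r$lengths,
             start = ends - r$lengths + 1L, end = ends)
}

#' Summary statistics of state dynamics
#'
#' Per state: fractional occupancy (fraction of samples spent in the
#' state), mean lifetime (mean visit duration, ms), mean interval (mean
#' gap between the end of one visit and the start of the next, s; or
#' onset-to-onset with `intervalMode = "onset"`) and switching rate
#' (visit onsets per second, the first visit counting as an onset).
#' States never visited get FO 0, switching rate 0 and NA lifetime and
#' interval; a single visit gives an NA interval.
#'
#' @param stc integer state sequence (values in 1..K).
#' @param K number of states (default: max observed).
#' @param fs sampling rate in Hz.
#' @param intervalMode `"gap"` (default, exclusive end-to-next-onset gap)
#'   or `"onset"` (onset-to-onset).
#' @param censorEdges drop the first and last (possibly censored) visits
#'   from the lifetime mean (default FALSE: include them).
#' @return data.frame, one row per state: `state`,
#'   `fractional_occupancy`, `mean_lifetime_ms`, `mean_interval_s`,
#'   `switching_rate_hz`, `n_visits`.
#' @examples
#' summaryStats(c(1, 1, 1, 2, 1, 1, 2, 2), K = 2, fs = 250)
#' @export
summaryStats <- function(stc, K = max(stc), fs,
                         intervalMode = c("gap", "onset"),
                         censorEdges = FALSE) {
  intervalMode <- match.arg(intervalMode)
  if (!length(stc)) stop("empty state sequence")
  if (fs <= 0) stop("fs must be positive")
  if (any(stc < 1 | stc > K)) stop("state label outside 1..", K)
  T <- length(stc)
  runs <- stateRuns(stc)
  out <- data.frame(state = seq_len(K), fractional_occupancy = 0,
                    mean_lifetime_ms = NA_real_, mean_interval_s = NA_real_,
                    switching_rate_hz = 0, n_visits = 0L)
  for (k in seq_len(K)) {
    rk <- runs[runs$state == k, , drop = FALSE]
    if (!nrow(rk)) next
    out$fractional_occupancy[k] <- sum(rk$length) / T
    out$n_visits[k] <- nrow(rk)
    lt <- rk$length
    if (censorEdges) {
      drop <- c(if (rk$start[1] == 1L) 1L,
                if (rk$end[nrow(rk)] == T) nrow(rk))
      if (length(drop) && nrow(rk) > length(unique(drop)))
        lt <- lt[-unique(drop)]
    }
    out$mean_lifetime_ms[k] <- mean(lt) / fs * 1000
    if (nrow(rk) > 1) {
      gaps <- if (intervalMode == "gap") {
        rk$start[-1] - rk$end[-nrow(rk)] - 1L
      } else {
        rk$start[-1] - rk$start[-nrow(rk)]
      }
      out$mean_interval_s[k] <- mean(gaps) / fs
    }
    out$switching_rate_hz[k] <- nrow(rk) / (T / fs)
  }
  out
}

#' Summary statistics for a cohort of state time courses
#'
#' @param stcList list of state sequences (e.g. from [mapStates()] on an
#'   [HMMFit-class]).
#' @param K number of states.
#' @param fs sampling rate in Hz.
#' @param ... passed to [summaryStats()].
#' @return long data.frame with a `subject` column.
#' @export
cohortSummaryStats <- function(stcList, K, fs, ...) {
  out <- lapply(seq_along(stcList), function(i) {
    s <- summaryStats(stcList[[i]], K = K, fs = fs, ...)
    cbind(subject = i, s)
  })
  do.call(rbind, out)
}

#' Subject-specific transition probability matrix
#'
#' Counts pairwise transitions (including self-transitions, so the
#' diagonal holds the stay probabilities) in a state time course and
#' row-normalises. Rows of never-visited states are set uniform and
#' flagged via the `"uniformRows"` attribute, with a warning.
#'
#' @param stc integer state sequence, length >= 2.
#' @param K number of states (default: max observed).
#' @return K x K row-stochastic matrix; attribute `uniformRows` lists the
#'   states whose rows were unobserved.
#' @export
subjectTransitionMatrix <- function(stc, K = max(stc)) {
  if (length(stc) < 2) stop("need a sequence of length >= 2")
  if (any(stc < 1 | stc > K)) stop("state label outside 1..", K)
  from <- stc[-length(stc)]
  to <- stc[-1]
  counts <- unclass(table(factor(from, levels = seq_len(K)),
                          factor(to, levels = seq_len(K))))
  dimnames(counts) <- NULL
  counts <- matrix(as.numeric(counts), K, K)
  rs <- rowSums(counts)
  uniform <- which(rs == 0)
  A <- counts
  for (k in seq_len(K)) {
    A[k, ] <- if (rs[k] > 0) counts[k, ] / rs[k] else rep(1 / K, K)
  }
  if (length(uniform)) {
    warning("states never left from: ", paste(uniform, collapse = ", "),
            "; rows set uniform")
    attr(A, "uniformRows") <- uniform
  }
  A
}
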