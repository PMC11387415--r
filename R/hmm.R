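## transient_hmm module: two-state Gaussian hidden Markov model fitting,
## transformation-time extraction under the minimum-dwell rule,
## fluctuation classification and photobleach truncation.

## deterministic 2-means split (Lloyd iterations from quantile centers)
twoMeansSplit <- function(x, iter = 25L) {
  c1 <- quantile(x, 0.25, names = FALSE)
  c2 <- quantile(x, 0.75, names = FALSE)
  if (c2 - c1 < .Machine$double.eps) c2 <- c1 + 1
  for (i in seq_len(iter)) {
    assign2 <- abs(x - c2) < abs(x - c1)
    if (!any(assign2) || all(assign2)) break
    n1 <- mean(x[!assign2]); n2 <- mean(x[assign2])
    if (isTRUE(all.equal(c(n1, n2), c(c1, c2)))) break
    c1 <- n1; c2 <- n2
  }
  assign2 <- abs(x - c2) < abs(x - c1)
  list(centers = c(c1, c2), cluster = assign2 + 1L)
}

#' Fit a two-state Gaussian-emission HMM to a transient
#'
#' Parameters are estimated by expectation-maximization (Baum-Welch)
#' initialized from a deterministic 2-means split of the intensities;
#' convergence at a log-likelihood change below \code{tol} or
#' \code{maxIter} iterations. The decoded path is the Viterbi path.
#' States are ordered by emission mean: state 1 = untransformed (low),
#' state 2 = transformed (high). If the fitted level separation is below
#' one pooled noise sigma the trace is declared single-state at the
#' dominant level and flagged.
#'
#' @param transient a \linkS4class{Transient} (>= 10 finite frames).
#' @param seed integer; kept for interface stability (the fit itself is
#'   deterministic).
#' @param tol log-likelihood convergence tolerance.
#' @param maxIter EM iteration cap.
#' @return a \linkS4class{StatePath}.
#' @export
fitTwoStateHMM <- function(transient, seed = 1L, tol = 1e-4,
                           maxIter = 500L) {
  x <- intensities(transient)
  times <- timestamps(transient)
  if (length(x) < 10) stop("at least 10 frames required")
  if (any(!is.finite(x))) stop("intensities must be finite")
  set.seed(as.integer(seed))

  sigmaFloor <- max(1e-6, 0.02 * (diff(range(x)) + 1e-9), 1e-3 * sd(x))
  emRun <- function(mu) {
    grp <- (abs(x - mu[2]) < abs(x - mu[1])) + 1L
    sig <- pmax(c(sd(x[grp == 1L]), sd(x[grp == 2L])), sigmaFloor)
    sig[is.na(sig)] <- max(sd(x), sigmaFloor)
    pi0 <- c(0.5, 0.5)
    A <- matrix(c(0.98, 0.02, 0.02, 0.98), 2, 2, byrow = TRUE)
    ll0 <- -Inf
    for (it in seq_len(maxIter)) {
      fb <- .hmm_forward_backward(x, pi0, A, mu, sig)
      g <- fb$gamma
      xi <- fb$xi
      pi0 <- pmax(g[1, ], 1e-12); pi0 <- pi0 / sum(pi0)
      A <- xi / pmax(rowSums(xi), 1e-12)
      A <- pmax(A, 1e-8); A <- A / rowSums(A)
      wsum <- colSums(g)
      mu <- colSums(g * x) / pmax(wsum, 1e-12)
      sig <- sqrt(colSums(g * (outer(x, mu, "-")^2)) / pmax(wsum, 1e-12))
      sig <- pmax(sig, sigmaFloor)
      if (abs(fb$logLik - ll0) < tol) { ll0 <- fb$logLik; break }
      ll0 <- fb$logLik
    }
    list(mu = mu, sig = sig, pi0 = pi0, A = A, logLik = ll0)
  }

  ## three deterministic starts: a central 2-means split, an extreme
  ## split, and a baseline-anchored split (turn-on traces start dark and
  ## may spend almost the whole record at the on level)
  km <- twoMeansSplit(x)
  xs <- sort(x)
  k5 <- min(5L, length(x))
  fits <- list(emRun(sort(km$centers)),
               emRun(sort(quantile(x, c(0.01, 0.99), names = FALSE))),
               emRun(sort(c(median(head(x, 10)),
                            quantile(x, 0.9, names = FALSE)))),
               emRun(sort(c(mean(xs[seq_len(k5)]), median(x)))),
               emRun(sort(c(median(x), mean(tail(xs, k5))))))
  fit <- fits[[which.max(vapply(fits, `[[`, 0, "logLik"))]]
  mu <- fit$mu; sig <- fit$sig; pi0 <- fit$pi0; A <- fit$A
  ll0 <- fit$logLik
  if (mu[2] < mu[1]) {   # keep state 2 = high level
    mu <- rev(mu); sig <- rev(sig); pi0 <- rev(pi0)
    A <- A[2:1, 2:1]
  }

  ## degenerate fits: separation below the noise, or no support for two
  ## levels at all (a single Gaussian explains the data as well, by BIC)
  ll1 <- sum(dnorm(x, mean(x), max(sd(x), sigmaFloor), log = TRUE))
  bicOne <- -2 * ll1 + 2 * log(length(x))
  bicTwo <- -2 * ll0 + 7 * log(length(x))
  pooled <- sqrt(mean(sig^2))
  if ((mu[2] - mu[1]) < pooled || bicOne <= bicTwo) {
    lvl <- if (mean(x) > mean(mu)) 2L else {
      if (abs(mean(x) - mu[2]) < abs(mean(x) - mu[1])) 2L else 1L
    }
    path <- rep(lvl, length(x))
    return(new("StatePath", states = as.integer(path), times = times,
               levelMeans = mu, levelSds = sig,
               transitions = integer(), logLik = ll0,
               truncationFrame = NA_integer_, singleState = TRUE))
  }
  path <- .hmm_viterbi(x, log(pi0), log(A), mu, sig)
  trans <- which(diff(path) != 0) + 1L
  new("StatePath", states = as.integer(path), times = times,
      levelMeans = mu, levelSds = sig, transitions = as.integer(trans),
      logLik = ll0, truncationFrame = NA_integer_, singleState = FALSE)
}

#' Viterbi decoding with fixed parameters
#'
#' Decodes the most probable state path of a two-state Gaussian-emission
#' HMM with given parameters (no fitting). Exposed mainly for validation
#' against exhaustive path enumeration.
#'
#' @param x numeric observations.
#' @param pi0 initial state probabilities (length 2).
#' @param A 2 x 2 transition matrix (rows sum to 1).
#' @param mu,sigma per-state emission means and sds.
#' @return integer path (1/2).
#' @export
viterbiPath <- function(x, pi0, A, mu, sigma) {
  .hmm_viterbi(x, log(pi0), log(A), mu, sigma)
}

## dwell time of the level segment starting at frame `from` (1-based):
## time to the next transition, or to the last timestamp for the final
## segment
segmentDwell <- function(path, from) {
  nxt <- path@transitions[path@transitions > from]
  end <- if (length(nxt)) path@times[nxt[1]] else path@times[length(path@times)]
  end - path@times[from]
}

#' Transformation time under the minimum-dwell rule
#'
#' The transformation time is the time of the first
#' untransformed-to-transformed transition that is followed by at least
#' \code{minDwell} seconds of uninterrupted transformed occupancy. A
#' transition too close to the end of the record to accumulate the dwell
#' cannot qualify. Single-state paths never yield a call.
#'
#' @param path a \linkS4class{StatePath} (photobleach-truncated paths are
#'   evaluated up to their truncation frame).
#' @param minDwell minimum transformed dwell (s).
#' @return a \linkS4class{TransformationCall} (time NA if none).
#' @export
transformationTime <- function(path, minDwell = 10) {
  none <- new("TransformationCall", time = NA_real_, dwell = NA_real_,
              channel = NA_character_)
  if (isTRUE(path@singleState)) return(none)
  lim <- if (is.na(path@truncationFrame)) length(path@states)
         else path@truncationFrame - 1L
  ups <- path@transitions[path@states[path@transitions] == 2L &
                          path@transitions <= lim]
  for (fr in ups) {
    nxt <- path@transitions[path@transitions > fr]
    endFrame <- if (length(nxt)) nxt[1] else lim + 1L
    endFrame <- min(endFrame, lim + 1L)
    dwell <- path@times[min(endFrame, length(path@times))] - path@times[fr]
    if (endFrame > lim) {  # dwell runs to end of (truncated) record
      dwell <- path@times[lim] - path@times[fr]
      if (!is.na(path@truncationFrame))  # bleach interrupts observation,
        dwell <- max(dwell, 0)           # dwell counted to truncation
    }
    if (dwell >= minDwell)
      return(new("TransformationCall", time = path@times[fr],
                 dwell = dwell, channel = NA_character_))
  }
  none
}

#' Classify a trace as fluctuating
#'
#' TRUE iff the decoded path contains at least one
#' transformed-to-untransformed transition before the photobleach
#' truncation, i.e. at least one reversal of the transformation.
#'
#' @param path a \linkS4class{StatePath}.
#' @return logical flag.
#' @export
classifyFluctuating <- function(path) {
  lim <- if (is.na(path@truncationFrame)) length(path@states)
         else path@truncationFrame - 1L
  downs <- path@transitions[path@states[path@transitions] == 1L &
                            path@transitions <= lim]
  length(downs) >= 1L
}

#' Detect single-step photobleaching
#'
#' A terminal drop from the transformed level to background that
#' persists to the end of the record is labeled photobleaching; the
#' returned frame is the first frame of that final dark segment. A drop
#' followed by recovery is a reversal, not bleaching.
#'
#' @param transient the source \linkS4class{Transient} (unused beyond
#'   interface symmetry; the decision is made on the decoded path).
#' @param path a \linkS4class{StatePath}.
#' @param minFrames minimum length (frames) of the terminal dark segment
#'   to call bleaching.
#' @return integer truncation frame (1-based) or NA.
#' @export
detectBleach <- function(transient, path, minFrames = 3L) {
  s <- path@states
  n <- length(s)
  if (isTRUE(path@singleState) || length(path@transitions) == 0)
    return(NA_integer_)
  last <- path@transitions[length(path@transitions)]
  if (s[n] != 1L) return(NA_integer_)       # record ends transformed
  if (s[last] != 1L) return(NA_integer_)
  ## segment before the final drop must be the transformed level
  if (last == 1L || s[last - 1L] != 2L) return(NA_integer_)
  if ((n - last + 1L) < minFrames) return(NA_integer_)
  as.integer(last)
}

#' Apply a photobleach truncation to a path
#'
#' @param path a \linkS4class{StatePath}.
#' @param frame truncation frame from \code{\link{detectBleach}} (NA
#'   leaves the path unchanged).
#' @return the path with \code{truncationFrame} set.
#' @export
truncateAtBleach <- function(path, frame) {
  if (is.na(frame)) return(path)
  path@truncationFrame <- as.integer(frame)
  path
}

#' Dual-color keep filter
#'
#' A structure is analyzed further only if both fluorophores turned into
#' their fluorescent state, i.e. both decoded paths contain at least one
#' untransformed-to-transformed transition.
#'
#' @param pathRed,pathGreen \linkS4class{StatePath} objects.
#' @return logical keep flag.
#' @export
filterDualOn <- function(pathRed, pathGreen) {
  on <- function(p) {
    !isTRUE(p@singleState) &&
      any(p@states[p@transitions] == 2L)
  }
  on(pathRed) && on(pathGreen)
}
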