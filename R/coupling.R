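## coupling_stats module: the coupling parameter C, transformation time
## differences, population fractions and transformation yield.

#' The coupling parameter C of one structure
#'
#' C compares the time two monitored anti-junctions spend in the same
#' conformation with the time they spend in differing conformations:
#' \code{C = same / (same + differing)}, counted over aligned frames.
#' A maximum of C = 1 corresponds to maximally coupled junctions; values
#' near 0 indicate junctions that mostly occupy differing conformations.
#'
#' Both channels are truncated at the earlier photobleach. Because the
#' two colors are recorded with a half-period lag, each green frame is
#' aligned to the nearest red frame (exact half-period ties round down).
#' For every decoded transition in either channel the frame pair flanking
#' the jump (last frame of the old level, first frame of the new level)
#' is excluded so that the interleaved sampling does not artificially
#' weaken the coupling.
#'
#' The published definition of C comes from supplementary material that
#' only constrains its range and endpoints; the normalization window used
#' here is therefore a documented reconstruction. By default the whole
#' shared record is counted; \code{window = "first_transition"} instead
#' starts counting at the first transition of either channel (frames
#' before any transformation are trivially "same" and inflate C).
#'
#' @param pathRed,pathGreen \linkS4class{StatePath} objects with
#'   timestamps on the interleaved two-color grid.
#' @param window "record" (default) or "first_transition".
#' @return a \linkS4class{CouplingResult}; C is NA (structure dropped
#'   from coupling histograms) when no countable frames remain.
#' @export
coupling <- function(pathRed, pathGreen,
                     window = c("record", "first_transition")) {
  window <- match.arg(window)
  tR <- pathRed@times; tG <- pathGreen@times

  ## nearest red frame for each green frame; half-way ties round down
  lo <- pmin(pmax(findInterval(tG, tR), 1L), length(tR))
  hi <- pmin(lo + 1L, length(tR))
  useHi <- (tR[hi] - tG) < (tG - tR[lo])   # strict: ties stay at lo
  gMap <- ifelse(useHi, hi, lo)

  m <- min(length(tR), length(tG))
  idxG <- seq_len(m)                       # green frames used
  idxR <- gMap[idxG]                       # their aligned red frames

  limR <- if (is.na(pathRed@truncationFrame)) length(tR)
          else pathRed@truncationFrame - 1L
  limG <- if (is.na(pathGreen@truncationFrame)) length(tG)
          else pathGreen@truncationFrame - 1L
  ok <- idxR <= limR & idxG <= limG
  idxG <- idxG[ok]; idxR <- idxR[ok]

  excl <- rep(FALSE, length(idxG))
  for (tr in pathRed@transitions) {
    hit <- idxR %in% c(tr - 1L, tr)
    excl <- excl | hit
  }
  for (tr in pathGreen@transitions) {
    hit <- idxG %in% c(tr - 1L, tr)
    excl <- excl | hit
  }

  start <- 1L
  if (window == "first_transition") {
    firsts <- c(if (length(pathRed@transitions))
                  min(match(pathRed@transitions, idxR), na.rm = TRUE),
                if (length(pathGreen@transitions))
                  min(match(pathGreen@transitions, idxG), na.rm = TRUE))
    firsts <- firsts[is.finite(firsts)]
    if (length(firsts)) start <- min(firsts)
  }
  inWin <- seq_along(idxG) >= start
  winN <- sum(inWin)

  sR <- pathRed@states[idxR]
  sG <- pathGreen@states[idxG]
  counted <- inWin & !excl
  nSame <- sum(counted & sR == sG)
  nDiff <- sum(counted & sR != sG)
  nExcl <- sum(inWin & excl)
  Cval <- if (nSame + nDiff > 0) nSame / (nSame + nDiff) else NA_real_
  ## note: the slot cannot be set via new() because "C" partially
  ## matches new()'s Class argument
  out <- new("CouplingResult", nSame = as.integer(nSame),
             nDiff = as.integer(nDiff), nExcluded = as.integer(nExcl),
             windowFrames = as.integer(winN))
  out@C <- Cval
  validObject(out)
  out
}

#' Fraction of fully coupled structures
#'
#' Structures with C above the threshold (default 0.95) are considered
#' fully coupled.
#'
#' @param C numeric vector of coupling values (NAs dropped).
#' @param threshold full-coupling threshold.
#' @return list with \code{fraction}, binomial \code{se}, \code{n}.
#' @export
fractionFullyCoupled <- function(C, threshold = 0.95) {
  C <- C[!is.na(C)]
  if (!length(C)) stop("at least one defined C value required")
  p <- mean(C > threshold)
  list(fraction = p, se = sqrt(p * (1 - p) / length(C)), n = length(C))
}

#' Transformation time difference of one structure
#'
#' \code{delta t = t_green - t_red} on the frame grid. If either channel
#' has no qualifying transformation the structure is excluded from
#' delta-t statistics (NA returned; callers tally it as
#' "no transformation").
#'
#' @param callRed,callGreen \linkS4class{TransformationCall} objects.
#' @return numeric seconds or NA.
#' @export
deltaT <- function(callRed, callGreen) {
  if (is.na(callRed@time) || is.na(callGreen@time)) return(NA_real_)
  callGreen@time - callRed@time
}

#' Gaussian fit of a sample of time differences
#'
#' Maximum-likelihood Gaussian parameters (sample mean and sigma) with
#' standard error \code{sigma/sqrt(n)}. For designs in which most
#' structures transform simultaneously, exact zeros can be excluded
#' first (\code{excludeZero}), as done when quantifying the delayed
#' subpopulation.
#'
#' @param values numeric sample (s).
#' @param excludeZero drop exact-zero values before fitting.
#' @return list with \code{mean}, \code{sigma}, \code{se}, \code{n},
#'   \code{ok} (FALSE when fewer than 2 values remain; no fit then),
#'   \code{degenerate} (TRUE when sigma is 0).
#' @export
fitGaussian <- function(values, excludeZero = FALSE) {
  v <- values[!is.na(values)]
  if (excludeZero) v <- v[v != 0]
  if (length(v) < 2)
    return(list(mean = NA_real_, sigma = NA_real_, se = NA_real_,
                n = length(v), ok = FALSE, degenerate = NA))
  m <- mean(v); s <- sd(v)
  list(mean = m, sigma = s, se = s / sqrt(length(v)), n = length(v),
       ok = TRUE, degenerate = s == 0)
}

#' Fraction of fluctuating structures with standard error
#'
#' @param flags logical vector (fluctuating yes/no).
#' @return list with \code{fraction}, \code{se} =
#'   \code{sqrt(p(1-p)/n)}, \code{n}.
#' @export
fractionFluctuating <- function(flags) {
  flags <- flags[!is.na(flags)]
  if (!length(flags)) stop("at least one flag required")
  p <- mean(flags)
  list(fraction = p, se = sqrt(p * (1 - p) / length(flags)),
       n = length(flags))
}

#' Transformation yield
#'
#' Percentage of reference-localized structures whose probe turned on,
#' with an exact binomial confidence interval.
#'
#' @param nTurnedOn number of turned-on colocalized structures.
#' @param nReference number of reference-localized structures (> 0).
#' @param conf confidence level.
#' @return list with \code{percent}, \code{ci} (percent), \code{n}.
#' @export
transformationYield <- function(nTurnedOn, nReference, conf = 0.95) {
  if (nReference <= 0) stop("reference count must be positive")
  if (nTurnedOn > nReference)
    stop("turned-on count cannot exceed the reference count")
  bt <- binom.test(nTurnedOn, nReference, conf.level = conf)
  list(percent = 100 * nTurnedOn / nReference,
       ci = 100 * as.numeric(bt$conf.int), n = nReference)
}
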