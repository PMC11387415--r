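## synthetic_data module, part 1: the lattice energy-landscape model and
## its kinetic Monte Carlo dynamics.

#' Default anti-junction occupancy mask
#'
#' The model array is drawn with the five-junction trigger edge as the
#' rightmost column. The fractional width of the array (5 x 2.5
#' anti-junctions) is represented by tapering the mask away from the
#' trigger edge: the middle column carries three junctions and the far
#' column two. The taper also shapes the kinetics: the reconfiguration
#' nucleates against the full interface penalty at the top of the middle
#' column and then runs downhill, reproducing the observed
#' single-step-then-zip transformation.
#'
#' @param nrow,ncol lattice dimensions (default 5 x 3).
#' @return logical matrix.
#' @export
defaultMask <- function(nrow = 5L, ncol = 3L) {
  m <- matrix(FALSE, nrow, ncol)
  m[, ncol] <- TRUE
  if (ncol >= 2) m[seq_len(min(3L, nrow)), ncol - 1L] <- TRUE
  if (ncol >= 3) m[seq_len(min(2L, nrow)), ncol - 2L] <- TRUE
  m
}

#' Construct a LatticeModel
#'
#' The default geometry is a 5-row x 3-column lattice of anti-junctions
#' (the 5 x 2.5 array drawn with the long trigger edge vertical), with the
#' five trigger strands on the right-edge column and an asymmetric trigger
#' design: stabilization decreases from the topmost trigger downwards, so
#' the cascade reliably nucleates at the top-right corner and sweeps
#' diagonally. Defaults are calibrated so that the five-trigger cascade
#' completes within the first minutes of a 25 min recording while the
#' fully transformed state stays quiet, and reversible fluctuations emerge
#' when the bottom trigger is withheld.
#'
#' @param nrow,ncol lattice dimensions.
#' @param mask logical matrix marking which lattice positions carry an
#'   anti-junction; defaults to \code{\link{defaultMask}}.
#' @param J interface penalty per discordant adjacent pair (kcal/mol).
#' @param triggerSites integer matrix (n x 2; row, col). Default: the whole
#'   rightmost column.
#' @param h per-trigger stabilization of the transformed state (kcal/mol);
#'   recycled to the number of triggers. The default decreasing profile
#'   encodes the asymmetric trigger design.
#' @param hTopBonus extra stabilization (kcal/mol) added to the first
#'   (topmost) trigger site, on top of \code{h}.
#' @param strain penalty per transformed non-trigger site while the field is
#'   active (kcal/mol); see \linkS4class{LatticeModel}.
#' @param triggerOnTime field switch-on time (s), default 0 (trigger strands
#'   added at the start of the recording).
#' @param bindingRate per-trigger exponential binding rate (1/s) for the
#'   trigger strands added in excess at t = 0; \code{Inf} = instantaneous
#'   switch-on. The default corresponds to a mean binding time of 50 s.
#' @param lockBarriers either a numeric matrix (same dim as mask) or a named
#'   list like \code{list("2,1" = 4.7)} mapping "row,col" to a barrier
#'   (kcal/mol) applied to moves flipping that site out of the untransformed
#'   conformation.
#' @param removedSites integer matrix (n x 2) of deleted anti-junctions.
#' @param k0 attempt rate (1/s).
#' @param temperature temperature (K).
#' @return a validated \linkS4class{LatticeModel}.
#' @examples
#' m <- latticeModel()
#' configurationEnergy(m, matrix(0L, 5, 3))
#' @export
latticeModel <- function(nrow = 5L, ncol = 3L, mask = NULL,
                         J = 3.7,
                         triggerSites = NULL,
                         h = c(12, 6, 5, 4.5, 8), hTopBonus = 0,
                         strain = 1.0,
                         triggerOnTime = 0,
                         bindingRate = c(0.5, 0.1, 0.1, 0.1, 0.05),
                         lockBarriers = NULL,
                         removedSites = NULL,
                         k0 = 8,
                         temperature = 310.15) {
  if (is.null(mask)) {
    mask <- if (nrow == 5L && ncol == 3L) defaultMask(nrow, ncol)
            else matrix(TRUE, nrow, ncol)
  }
  nrow <- base::nrow(mask); ncol <- base::ncol(mask)
  if (is.null(triggerSites))
    triggerSites <- cbind(seq_len(nrow), ncol)
  triggerSites <- asSiteMatrix(triggerSites)
  nTrig <- base::nrow(triggerSites)
  hVec <- rep_len(h, nTrig)
  if (nTrig > 0 && hTopBonus != 0)
    hVec[1] <- hVec[1] + hTopBonus
  bindingRate <- if (nTrig > 0) rep_len(bindingRate, nTrig) else numeric()
  if (is.null(removedSites))
    removedSites <- matrix(integer(), 0, 2)
  removedSites <- asSiteMatrix(removedSites)
  lb <- matrix(0, nrow, ncol)
  if (!is.null(lockBarriers)) {
    if (is.matrix(lockBarriers)) {
      lb <- lockBarriers
    } else if (is.list(lockBarriers)) {
      for (key in names(lockBarriers)) {
        rc <- as.integer(strsplit(key, ",")[[1]])
        lb[rc[1], rc[2]] <- lockBarriers[[key]]
      }
    } else stop("lockBarriers must be a matrix or a named list")
  }
  new("LatticeModel", mask = mask, J = J, triggerSites = triggerSites,
      h = hVec, strain = strain, triggerOnTime = triggerOnTime,
      bindingRate = bindingRate, lockBarriers = lb,
      removedSites = removedSites, k0 = as.numeric(k0),
      temperature = temperature)
}

asSiteMatrix <- function(x) {
  x <- matrix(as.integer(x), ncol = 2,
              dimnames = list(NULL, c("row", "col")))
  x
}

## gas constant in kcal/(mol K)
RGAS <- 0.0019872041

rtOf <- function(model) RGAS * model@temperature

## logical matrix of sites actually present (mask minus removals)
presentMask <- function(model) {
  p <- model@mask
  if (nrow(model@removedSites) > 0) p[model@removedSites] <- FALSE
  p
}

## linear indices and neighbor table over present sites
latticeGraph <- function(model) {
  p <- presentMask(model)
  dims <- dim(p)
  idx <- which(p)                        # linear indices, column-major
  pos <- arrayInd(idx, dims)
  lookup <- rep(NA_integer_, prod(dims))
  lookup[idx] <- seq_along(idx)
  nbrList <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    r <- pos[k, 1]; c <- pos[k, 2]
    cand <- rbind(c(r - 1, c), c(r + 1, c), c(r, c - 1), c(r, c + 1))
    ok <- cand[, 1] >= 1 & cand[, 1] <= dims[1] &
          cand[, 2] >= 1 & cand[, 2] <= dims[2]
    cand <- cand[ok, , drop = FALSE]
    li <- cand[, 1] + (cand[, 2] - 1) * dims[1]
    nbrList[[k]] <- lookup[li][!is.na(lookup[li])]
  }
  maxDeg <- max(1L, vapply(nbrList, length, 1L))
  nbr <- matrix(-1L, length(idx), maxDeg)
  for (k in seq_along(idx)) {
    nb <- nbrList[[k]]
    if (length(nb)) nbr[k, seq_along(nb)] <- nb - 1L  # 0-based for C++
  }
  list(pos = pos, nbr = nbr, lookup = lookup, dims = dims)
}

## per-present-site field vectors (h, strain) aligned with latticeGraph order
siteFields <- function(model, graph) {
  n <- nrow(graph$pos)
  h <- numeric(n); strain <- numeric(n)
  bindRate <- rep(Inf, n)
  isTrig <- logical(n)
  if (nrow(model@triggerSites) > 0) {
    li <- model@triggerSites[, 1] + (model@triggerSites[, 2] - 1) * graph$dims[1]
    ki <- graph$lookup[li]
    if (any(is.na(ki)))
      stop("trigger site removed or outside the mask")
    h[ki] <- model@h
    bindRate[ki] <- model@bindingRate
    isTrig[ki] <- TRUE
  }
  strain[!isTrig] <- model@strain
  lock <- model@lockBarriers[graph$pos]
  list(h = h, strain = strain, lock = lock, isTrigger = isTrig,
       bindRate = bindRate, triggerIdx = if (nrow(model@triggerSites) > 0)
         ki else integer())
}

#' Configuration energy of a lattice state
#'
#' Energy of one conformation assignment:
#' \code{J * (# discordant adjacent pairs, adjacency excluding removed
#' sites) - sum(h over transformed trigger sites) + strain * (# transformed
#' non-trigger sites)}, field terms counted only when the trigger field is
#' active. With the field off any uniform state has energy exactly 0.
#'
#' @param model a \linkS4class{LatticeModel}.
#' @param state integer/logical matrix of the same dimensions as the grid
#'   (0 = untransformed, 1 = transformed); values at removed positions are
#'   ignored. Alternatively a vector over present sites in column-major
#'   order.
#' @param fieldActive is the trigger field on? Default TRUE.
#' @return energy in kcal/mol.
#' @examples
#' m <- latticeModel(h = 3, hTopBonus = 0, strain = 0)
#' configurationEnergy(m, matrix(1L, 5, 3))  # -15: five triggers at h = 3
#' @export
configurationEnergy <- function(model, state, fieldActive = TRUE) {
  graph <- latticeGraph(model)
  s <- stateVector(model, state, graph)
  fld <- siteFields(model, graph)
  ## each discordant pair counted once (nbr table lists both directions)
  d <- 0L
  for (k in seq_len(nrow(graph$nbr))) {
    nb <- graph$nbr[k, ]
    nb <- nb[nb >= 0] + 1L
    d <- d + sum(s[nb] != s[k])
  }
  e <- model@J * d / 2
  if (isTRUE(fieldActive))
    e <- e - sum(fld$h * s) + sum(fld$strain * s)
  e
}

## normalize a user-supplied state to a 0/1 vector over present sites
stateVector <- function(model, state, graph = latticeGraph(model)) {
  if (is.matrix(state)) {
    if (!identical(dim(state), graph$dims))
      stop("state shape mismatch with grid")
    s <- as.integer(state[graph$pos] != 0)
  } else {
    if (length(state) != nrow(graph$pos))
      stop("state shape mismatch with grid")
    s <- as.integer(state != 0)
  }
  if (any(is.na(s))) stop("state must assign a conformation to every site")
  s
}

#' Simulate the transformation cascade by kinetic Monte Carlo
#'
#' Continuous-time (Gillespie) simulation over single-site flips with
#' Metropolis-style barriers \code{k = k0 * exp(-(max(dE, 0) + lock)/RT)};
#' the lock barrier applies only to moves taking a locked site out of the
#' untransformed conformation. The initial state is all-untransformed. With
#' a finite \code{bindingRate} each trigger's field switches on after an
#' independent exponential binding delay.
#'
#' @param model a \linkS4class{LatticeModel}.
#' @param duration simulated time (s), > 0.
#' @param seed integer RNG seed; the trajectory is reproducible from it.
#' @param maxEvents safety cap on the number of recorded events.
#' @param stopWhenComplete stop as soon as every present site is
#'   transformed (useful for first-passage studies).
#' @return a \linkS4class{LatticeTrajectory}.
#' @examples
#' m <- latticeModel()
#' traj <- simulateCascade(m, duration = 1500, seed = 1)
#' head(events(traj))
#' @export
simulateCascade <- function(model, duration, seed,
                            maxEvents = 2e6, stopWhenComplete = FALSE) {
  stopifnot(duration > 0)
  validObject(model)
  graph <- latticeGraph(model)
  fld <- siteFields(model, graph)
  set.seed(as.integer(seed))
  actTime <- rep(model@triggerOnTime, nrow(graph$pos))
  if (length(fld$triggerIdx) > 0 && any(is.finite(model@bindingRate))) {
    ## one binding delay per trigger, drawn in trigger-list order
    delays <- ifelse(is.finite(model@bindingRate),
                     rexp(length(model@bindingRate)) / model@bindingRate, 0)
    actTime[fld$triggerIdx] <- model@triggerOnTime + delays
  }
  res <- .kmc_run(graph$nbr, fld$h, actTime, fld$strain,
                  model@triggerOnTime, fld$lock,
                  model@J, model@k0, rtOf(model),
                  duration, as.integer(maxEvents),
                  isTRUE(stopWhenComplete))
  pos <- graph$pos
  ev <- data.frame(time = res$time,
                   row = pos[res$site + 1L, 1],
                   col = pos[res$site + 1L, 2],
                   state = as.integer(res$state))
  new("LatticeTrajectory", events = ev, duration = as.numeric(duration),
      seed = as.integer(seed), dims = as.integer(graph$dims),
      removedSites = model@removedSites)
}

#' Sample the conformation of one site at a set of frame times
#'
#' Piecewise-constant replay of a trajectory: the state at frame time t is
#' the state after all events with event time <= t (a frame whose start
#' coincides with an event already sees the new conformation).
#'
#' @param traj a \linkS4class{LatticeTrajectory}.
#' @param site integer(2) (row, col); must not be a removed site.
#' @param frameTimes sorted numeric vector of frame times (s).
#' @return integer vector of conformations (0/1), one per frame.
#' @export
junctionStateSeries <- function(traj, site, frameTimes) {
  if (is.unsorted(frameTimes)) stop("frameTimes must be sorted")
  rem <- traj@removedSites
  if (nrow(rem) > 0 && any(rem[, 1] == site[1] & rem[, 2] == site[2]))
    stop("site was removed from the design; it has no conformation series")
  ev <- traj@events
  sel <- ev$row == site[1] & ev$col == site[2]
  tEv <- ev$time[sel]; sEv <- ev$state[sel]
  if (length(tEv) == 0) return(rep(0L, length(frameTimes)))
  idx <- findInterval(frameTimes, tEv)   # 0 = before first event
  out <- ifelse(idx == 0, 0L, sEv[pmax(idx, 1L)])
  as.integer(out)
}

#' First sustained transformation time of one site
#'
#' Ground-truth analogue of the minimum-dwell rule used in transient
#' analysis: the time of the first untransformed-to-transformed event that
#' is followed by at least \code{minDwell} seconds of uninterrupted
#' transformed occupancy (occupancy persisting to the end of the record
#' counts with dwell = duration - event time).
#'
#' @param traj a \linkS4class{LatticeTrajectory}.
#' @param site integer(2) (row, col).
#' @param minDwell minimum transformed dwell (s), default 10.
#' @return time in seconds, or NA if the site never qualifies.
#' @export
trueTransformationTime <- function(traj, site, minDwell = 10) {
  ev <- traj@events
  sel <- ev$row == site[1] & ev$col == site[2]
  tEv <- ev$time[sel]; sEv <- ev$state[sel]
  up <- which(sEv == 1L)
  for (i in up) {
    tNext <- if (i < length(tEv)) tEv[i + 1L] else traj@duration
    if (tNext - tEv[i] >= minDwell) return(tEv[i])
  }
  NA_real_
}

#' Number of transformed-to-untransformed reversals of one site
#'
#' @param traj a \linkS4class{LatticeTrajectory}.
#' @param site integer(2) (row, col).
#' @param minDwell only count reversals out of a transformed dwell at least
#'   this long (s); 0 counts every down-flip.
#' @return integer count.
#' @export
countReversals <- function(traj, site, minDwell = 0) {
  ev <- traj@events
  sel <- ev$row == site[1] & ev$col == site[2]
  tEv <- ev$time[sel]; sEv <- ev$state[sel]
  down <- which(sEv == 0L)
  if (minDwell <= 0) return(length(down))
  n <- 0L
  for (i in down) {
    # dwell in transformed before this down-flip
    if (i == 1L) next
    if (tEv[i] - tEv[i - 1L] >= minDwell) n <- n + 1L
  }
  n
}

#' Default FRET probe position map
#'
#' The lattice coordinates of the probed anti-junctions (Positions 1-5) are
#' a documented modeling assumption: the cascade nucleates at the top-right
#' corner next to the strongest trigger, so Position 1 sits adjacent to that
#' corner, Positions 2 and 4 lie progressively further along the diagonal
#' sweep in the middle column, Position 3 is the far-column junction used by
#' the lock/deletion designs, and Position 5 is the same-cascade-step
#' partner of Position 1. \code{edge} is the bottom trigger-edge junction
#' whose trigger strand is withheld in the four-trigger regime.
#'
#' @return named list of integer(2) (row, col) sites.
#' @export
probePositions <- function() {
  list(P1 = c(1L, 2L),
       P2 = c(3L, 2L),
       P3 = c(2L, 1L),
       P4 = c(2L, 2L),
       P5 = c(1L, 1L),
       edge = c(5L, 3L))
}
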