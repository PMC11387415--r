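## synthetic_data module, part 2: rendering cascades into dual-color
## turn-on FRET time-lapse movies.

#' Construct an OpticsConfig
#'
#' Defaults emulate alternating-laser TIRF time-lapse imaging of
#' surface-immobilized origami: 100 ms exposure, one frame per second and
#' color, 0.5 s between the red and green excitation, 25 min total. The
#' default photon budget gives a peak-pixel signal-to-noise ratio of about
#' 5 for an unquenched probe.
#'
#' @param imageSize integer(2), image height and width (px).
#' @param pixelSizeNm pixel size (nm).
#' @param psfSigma named numeric(2), Gaussian PSF sigma per channel (px).
#' @param photonRate photons per frame from an unquenched on-state probe.
#' @param residualFraction relative emission of the quenched state.
#' @param background photons per pixel per frame.
#' @param exposure exposure time (s).
#' @param channelPeriod frame period per color (s).
#' @param interChannelLag green-after-red excitation lag (s).
#' @param duration total measurement time (s).
#' @param bleachRate single-step photobleach rate per second of illuminated
#'   on-time (1/s).
#' @param driftVelocity numeric(2), stage drift in px/s (x, y).
#' @param driftJitter per-frame random-walk drift step sigma (px).
#' @param chromaticOffset numeric(2), green-channel offset relative to red
#'   (px).
#' @param nFiducials number of always-on fiducial structures.
#' @return a validated \linkS4class{OpticsConfig}.
#' @export
opticsConfig <- function(imageSize = c(128L, 128L),
                         pixelSizeNm = 100,
                         psfSigma = c(red = 1.1, green = 1.0),
                         photonRate = 300,
                         residualFraction = 0.02,
                         background = 20,
                         exposure = 0.1,
                         channelPeriod = 1.0,
                         interChannelLag = 0.5,
                         duration = 1500,
                         bleachRate = 0.005,
                         driftVelocity = c(0.002, 0.001),
                         driftJitter = 0.01,
                         chromaticOffset = c(1.5, -0.8),
                         nFiducials = 5L) {
  new("OpticsConfig", imageSize = as.integer(imageSize),
      pixelSizeNm = pixelSizeNm, psfSigma = psfSigma,
      photonRate = photonRate, residualFraction = residualFraction,
      background = background, exposure = exposure,
      channelPeriod = channelPeriod, interChannelLag = interChannelLag,
      duration = duration, bleachRate = bleachRate,
      driftVelocity = driftVelocity, driftJitter = driftJitter,
      chromaticOffset = chromaticOffset, nFiducials = as.integer(nFiducials))
}

## frame start times for one channel
frameTimes <- function(optics, channel) {
  n <- floor(optics@duration / optics@channelPeriod)
  t0 <- if (channel == "green") optics@interChannelLag else 0
  t0 + optics@channelPeriod * (seq_len(n) - 1)
}

## pixel-integrated Gaussian PSF stamp centered at (x, y) (0-based pixel
## centers at integers); returns list(rows, cols, val) of the footprint
psfStamp <- function(x, y, sigma, amplitude, imgDim, halfWidth = 4) {
  r0 <- max(0L, floor(y - halfWidth * sigma))
  r1 <- min(imgDim[1] - 1L, ceiling(y + halfWidth * sigma))
  c0 <- max(0L, floor(x - halfWidth * sigma))
  c1 <- min(imgDim[2] - 1L, ceiling(x + halfWidth * sigma))
  if (r0 > r1 || c0 > c1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  wy <- pnorm(rows + 0.5, y, sigma) - pnorm(rows - 0.5, y, sigma)
  wx <- pnorm(cols + 0.5, x, sigma) - pnorm(cols - 0.5, x, sigma)
  list(rows = rows + 1L, cols = cols + 1L,
       val = amplitude * outer(wy, wx))
}

## cumulative stage drift sampled at arbitrary times; random-walk jitter is
## generated on the red frame grid and linearly interpolated
makeDriftTrace <- function(optics, times) {
  grid <- frameTimes(optics, "red")
  nG <- length(grid)
  stepSd <- optics@driftJitter
  wx <- cumsum(c(0, rnorm(nG - 1, 0, stepSd)))
  wy <- cumsum(c(0, rnorm(nG - 1, 0, stepSd)))
  dx <- optics@driftVelocity[1] * times +
    approx(grid, wx, xout = times, rule = 2)$y
  dy <- optics@driftVelocity[2] * times +
    approx(grid, wy, xout = times, rule = 2)$y
  cbind(dx = dx, dy = dy)
}

#' Render simulated cascades into a dual-color movie dataset
#'
#' Each structure carries one probe per channel on a chosen anti-junction.
#' Per frame a probe emits Poisson photons at the full rate if its site is
#' in the transformed conformation (sampled at the frame start) and the
#' dye has not photobleached, and at a small residual rate otherwise.
#' Emitters are rendered as pixel-integrated 2-D Gaussian PSFs on a
#' Poisson background; fiducials emit in both channels from frame 0;
#' global stage drift plus a chromatic offset of the green channel are
#' applied; all ground truth is recorded.
#'
#' @param structures list; each element a list with components
#'   \code{trajectory} (a \linkS4class{LatticeTrajectory}), \code{sites}
#'   (list with \code{red} and \code{green} integer(2) lattice sites) and
#'   \code{x}, \code{y} (position in px, frame-0 coordinates).
#' @param optics an \linkS4class{OpticsConfig}.
#' @param seed integer seed for all rendering randomness.
#' @param fiducialXY optional n x 2 matrix of fiducial positions; default
#'   random placement.
#' @param scenario label stored in the dataset.
#' @return a \linkS4class{SyntheticDataset}.
#' @export
renderMovie <- function(structures, optics, seed, fiducialXY = NULL,
                        scenario = "custom") {
  validObject(optics)
  set.seed(as.integer(seed))
  dimHW <- optics@imageSize
  nStruct <- length(structures)

  xy <- cbind(vapply(structures, `[[`, 0, "x"),
              vapply(structures, `[[`, 0, "y"))
  if (nStruct > 0) {
    if (any(xy[, 1] < 0 | xy[, 1] > dimHW[2] - 1 |
            xy[, 2] < 0 | xy[, 2] > dimHW[1] - 1))
      stop("structure positions outside the field of view")
    minSep <- 4 * max(optics@psfSigma)
    if (nStruct > 1) {
      d <- as.matrix(dist(xy))
      diag(d) <- Inf
      if (any(d < minSep))
        warning("structures closer than 4 PSF sigma: detection may be ambiguous")
    }
  }
  if (is.null(fiducialXY)) {
    margin <- 6
    fiducialXY <- cbind(
      runif(optics@nFiducials, margin, dimHW[2] - 1 - margin),
      runif(optics@nFiducials, margin, dimHW[1] - 1 - margin))
  }

  tsRed <- frameTimes(optics, "red")
  tsGreen <- frameTimes(optics, "green")
  allT <- sort(unique(c(tsRed, tsGreen)))
  driftAll <- makeDriftTrace(optics, allT)
  rownames(driftAll) <- as.character(allT)

  gt <- data.frame(
    structure_id = if (nStruct) sprintf("S%03d", seq_len(nStruct)) else character(),
    site_red = character(nStruct), site_green = character(nStruct),
    x_px = numeric(nStruct), y_px = numeric(nStruct),
    t_transform_red_s = numeric(nStruct),
    t_transform_green_s = numeric(nStruct),
    t_bleach_red_s = numeric(nStruct),
    t_bleach_green_s = numeric(nStruct),
    stringsAsFactors = FALSE)

  stateSeries <- vector("list", nStruct)
  ## per-channel on/off series and bleach frames, drawn before rendering so
  ## the photon draws follow in a fixed order
  chanData <- list(red = list(), green = list())
  for (ch in c("red", "green")) {
    ts <- if (ch == "red") tsRed else tsGreen
    for (i in seq_len(nStruct)) {
      st <- structures[[i]]
      series <- junctionStateSeries(st$trajectory, st$sites[[ch]], ts)
      ## single-step photobleaching in cumulative illuminated on-time
      onIdx <- which(series == 1L)
      bleachFrame <- NA_integer_
      if (length(onIdx) && optics@bleachRate > 0) {
        budget <- rexp(1, optics@bleachRate)
        k <- which(cumsum(rep(optics@exposure, length(onIdx))) >= budget)
        if (length(k)) bleachFrame <- onIdx[k[1]]
      } else if (optics@bleachRate > 0) {
        invisible(rexp(1, optics@bleachRate))  # keep draw order fixed
      }
      ## the dye still emits during the exposure in which it bleaches and
      ## is dark from the next frame onward
      emit <- series == 1L
      if (!is.na(bleachFrame) && bleachFrame < length(emit))
        emit[(bleachFrame + 1L):length(emit)] <- FALSE
      chanData[[ch]][[i]] <- list(series = series, emit = emit,
                                  bleachFrame = bleachFrame)
      if (ch == "red") {
        stateSeries[[i]] <- list(red = series)
      } else stateSeries[[i]]$green <- series
      gt[i, paste0("t_bleach_", ch, "_s")] <-
        if (is.na(bleachFrame)) NA_real_ else ts[bleachFrame]
      gt[i, paste0("t_transform_", ch, "_s")] <-
        trueTransformationTime(st$trajectory, st$sites[[ch]])
      gt[i, paste0("site_", ch)] <- paste(st$sites[[ch]], collapse = ",")
    }
  }
  if (nStruct) { gt$x_px <- xy[, 1]; gt$y_px <- xy[, 2] }

  movies <- list()
  for (ch in c("red", "green")) {
    ts <- if (ch == "red") tsRed else tsGreen
    sigma <- optics@psfSigma[[ch]]
    off <- if (ch == "green") optics@chromaticOffset else c(0, 0)
    nFrames <- length(ts)
    stack <- array(0L, dim = c(dimHW[1], dimHW[2], nFrames))
    dIdx <- match(as.character(ts), rownames(driftAll))
    for (f in seq_len(nFrames)) {
      lam <- matrix(optics@background, dimHW[1], dimHW[2])
      dx <- driftAll[dIdx[f], 1]; dy <- driftAll[dIdx[f], 2]
      for (i in seq_len(nStruct)) {
        cd <- chanData[[ch]][[i]]
        amp <- if (cd$emit[f]) optics@photonRate
               else if (!is.na(cd$bleachFrame) && f >= cd$bleachFrame) 0
               else optics@photonRate * optics@residualFraction
        if (amp <= 0) next
        s <- psfStamp(xy[i, 1] + off[1] + dx, xy[i, 2] + off[2] + dy,
                      sigma, amp, dimHW)
        if (!is.null(s)) lam[s$rows, s$cols] <- lam[s$rows, s$cols] + s$val
      }
      for (i in seq_len(nrow(fiducialXY))) {
        s <- psfStamp(fiducialXY[i, 1] + off[1] + dx,
                      fiducialXY[i, 2] + off[2] + dy,
                      sigma, optics@photonRate, dimHW)
        if (!is.null(s)) lam[s$rows, s$cols] <- lam[s$rows, s$cols] + s$val
      }
      stack[, , f] <- rpois(length(lam), lam)
    }
    movies[[ch]] <- new("Movie", frames = stack, timestamps = ts,
                        channel = ch)
  }

  driftRed <- driftAll[match(as.character(tsRed), rownames(driftAll)), ,
                       drop = FALSE]
  new("SyntheticDataset",
      red = movies$red, green = movies$green,
      groundTruth = gt,
      trajectories = lapply(structures, `[[`, "trajectory"),
      stateSeries = stateSeries,
      fiducials = data.frame(x = fiducialXY[, 1], y = fiducialXY[, 2]),
      drift = data.frame(t = tsRed, dx = driftRed[, 1], dy = driftRed[, 2]),
      scenario = scenario, seed = as.integer(seed))
}
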