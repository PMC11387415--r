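## imaging module: drift correction, channel registration, appearing-spot
## detection, transient extraction and dual-color colocalization.
## Coordinates are 0-based with pixel centers at integers; x = column,
## y = row; subpixel positions are continuous. Frames are never resampled:
## drift is applied to extraction coordinates instead.

## separable Gaussian blur with reflected edges
gaussBlur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- dnorm(-r:r, 0, sigma)
  k <- k / sum(k)
  pad <- function(v) c(rev(v[seq_len(r)]), v, rev(v[length(v) - seq_len(r) + 1]))
  conv1 <- function(v) {
    out <- stats::filter(pad(v), k, sides = 2)
    out[(r + 1):(length(v) + r)]
  }
  tmp <- apply(img, 2, conv1)
  t(apply(tmp, 1, conv1))
}

## difference-of-Gaussians band-pass, sigma ratio 1.6
dogFilter <- function(img, sigma) {
  gaussBlur(img, sigma) - gaussBlur(img, 1.6 * sigma)
}

## local maxima of img above threshold (8-neighborhood)
localMaxima <- function(img, threshold) {
  h <- nrow(img); w <- ncol(img)
  out <- NULL
  core <- img[2:(h - 1), 2:(w - 1)]
  isMax <- core >= threshold
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    isMax <- isMax & core >= img[2:(h - 1) + dr, 2:(w - 1) + dc]
  }
  idx <- which(isMax, arr.ind = TRUE)
  if (nrow(idx) == 0) return(matrix(numeric(), 0, 2))
  cbind(row = idx[, 1] + 1L, col = idx[, 2] + 1L)
}

## background-subtracted Gaussian-weighted centroid in a window around
## (x, y) (0-based); returns refined c(x, y)
weightedCentroid <- function(img, x, y, halfWin = 3L, sigma = 2,
                             iterations = 3L) {
  h <- nrow(img); w <- ncol(img)
  for (it in seq_len(iterations)) {
    r0 <- max(1L, round(y) + 1L - halfWin)
    r1 <- min(h, round(y) + 1L + halfWin)
    c0 <- max(1L, round(x) + 1L - halfWin)
    c1 <- min(w, round(x) + 1L + halfWin)
    win <- img[r0:r1, c0:c1, drop = FALSE]
    bg <- median(win)
    v <- pmax(win - bg, 0)
    ys <- (r0:r1) - 1L; xs <- (c0:c1) - 1L
    ## re-centering the weights on each new estimate removes the pull
    ## of the weight window toward its (integer) seed position
    wgt <- outer(dnorm(ys, y, sigma), dnorm(xs, x, sigma)) * v
    s <- sum(wgt)
    if (s <= 0) return(c(x, y))
    xNew <- sum(t(wgt) * xs) / s
    yNew <- sum(wgt * ys) / s
    if (abs(xNew - x) < 1e-3 && abs(yNew - y) < 1e-3) {
      x <- xNew; y <- yNew
      break
    }
    x <- xNew; y <- yNew
  }
  c(x, y)
}

## disk and annulus pixel offsets (0-based, relative to center pixel)
diskOffsets <- function(radius) {
  g <- expand.grid(dr = -ceiling(radius):ceiling(radius),
                   dc = -ceiling(radius):ceiling(radius))
  g[sqrt(g$dr^2 + g$dc^2) <= radius, , drop = FALSE]
}

annulusOffsets <- function(rIn, rOut) {
  g <- expand.grid(dr = -ceiling(rOut):ceiling(rOut),
                   dc = -ceiling(rOut):ceiling(rOut))
  d <- sqrt(g$dr^2 + g$dc^2)
  g[d >= rIn & d <= rOut, , drop = FALSE]
}

## disk-sum minus annulus-median background at a (possibly drifting)
## position, vectorized over frames
diskMinusAnnulus <- function(stack, xs, ys, radius = 3, annulus = c(5, 8)) {
  h <- dim(stack)[1]; w <- dim(stack)[2]; nF <- dim(stack)[3]
  dsk <- diskOffsets(radius)
  ann <- annulusOffsets(annulus[1], annulus[2])
  out <- rep(NA_real_, nF)
  for (f in seq_len(nF)) {
    rc <- round(ys[f]) + 1L; cc <- round(xs[f]) + 1L
    rr <- rc + dsk$dr; ccD <- cc + dsk$dc
    okD <- rr >= 1 & rr <= h & ccD >= 1 & ccD <= w
    if (!all(okD)) next                   # spot (partially) out of frame
    ra <- rc + ann$dr; ca <- cc + ann$dc
    okA <- ra >= 1 & ra <= h & ca >= 1 & ca <= w
    img <- stack[, , f]
    annv <- img[cbind(ra[okA], ca[okA])]
    ## robust background: mean over a symmetric window around the median,
    ## which rejects bleed-through from neighboring spots while staying
    ## unbiased on counting noise (unlike a discrete median)
    med <- median(annv)
    halfWidth <- 4 * sqrt(max(med, 0) + 1) + 1
    inWin <- abs(annv - med) <= halfWidth
    bg <- mean(annv[inWin])
    out[f] <- sum(img[cbind(rr, ccD)]) - bg * nrow(dsk)
  }
  out
}

#' Detect always-on fiducial structures
#'
#' Fiducials are spots that are fluorescent from frame 0 and remain above
#' the detection threshold in at least \code{presentFraction} of all
#' frames. Candidates are found by difference-of-Gaussians filtering of
#' the average of the first frames; each candidate is then tracked with a
#' Gaussian-weighted centroid and its per-frame presence checked.
#'
#' @param movie a \linkS4class{Movie} (>= 10 frames).
#' @param psfSigma expected PSF sigma (px).
#' @param threshold detection threshold in robust-noise units.
#' @param presentFraction minimum fraction of frames above threshold.
#' @param nInit number of initial frames averaged for candidate detection.
#' @return data.frame (spot_id, channel, x, y, first_frame, is_fiducial).
#' @export
detectFiducials <- function(movie, psfSigma = 1.1, threshold = 5,
                            presentFraction = 0.95, nInit = 10L) {
  fr <- frames(movie)
  nF <- dim(fr)[3]
  if (nF < 10) stop("at least 10 frames required")
  init <- apply(fr[, , seq_len(min(nInit, nF)), drop = FALSE], c(1, 2), mean)
  dog <- dogFilter(init, psfSigma)
  noise <- mad(dog)
  cand <- localMaxima(dog, threshold * noise)
  spots <- list()
  for (i in seq_len(nrow(cand))) {
    xy <- weightedCentroid(init, cand[i, "col"] - 1L, cand[i, "row"] - 1L,
                           sigma = 2 * psfSigma)
    ## presence check on a subsample of frames (always incl. frame 0),
    ## tracking the spot so stage drift does not fail the check
    checkIdx <- unique(c(1L, round(seq(1, nF, length.out = min(nF, 150L)))))
    x <- xy[1]; y <- xy[2]
    ints <- rep(NA_real_, length(checkIdx))
    for (k in seq_along(checkIdx)) {
      f <- checkIdx[k]
      cxy <- weightedCentroid(fr[, , f], x, y, sigma = 2 * psfSigma)
      if (sqrt((cxy[1] - x)^2 + (cxy[2] - y)^2) < 3) { x <- cxy[1]; y <- cxy[2] }
      ints[k] <- diskMinusAnnulus(fr[, , f, drop = FALSE], x, y)
    }
    lvl <- median(ints, na.rm = TRUE)
    present <- mean(ints > lvl / 2, na.rm = TRUE)
    if (!is.na(ints[1]) && ints[1] > lvl / 2 && lvl > 0 &&
        present >= presentFraction)
      spots[[length(spots) + 1]] <- data.frame(
        x = xy[1], y = xy[2], stringsAsFactors = FALSE)
  }
  if (!length(spots))
    return(data.frame(spot_id = character(), channel = character(),
                      x = numeric(), y = numeric(),
                      first_frame = integer(), is_fiducial = logical()))
  out <- do.call(rbind, spots)
  data.frame(spot_id = sprintf("%s_fid%02d", channelName(movie),
                               seq_len(nrow(out))),
             channel = channelName(movie), x = out$x, y = out$y,
             first_frame = 0L, is_fiducial = TRUE,
             stringsAsFactors = FALSE)
}

#' Estimate per-frame stage drift from fiducials
#'
#' Each fiducial is tracked by a Gaussian-weighted centroid in a window
#' that follows its previous position; the per-frame translation is the
#' robust (median) average of fiducial displacements, smoothed with a
#' running mean. Gaps (lost fiducials) are interpolated.
#'
#' @param movie a \linkS4class{Movie}.
#' @param fiducials data.frame from \code{\link{detectFiducials}}. With
#'   zero rows, an identity trace is returned with a warning.
#' @param smoothWindow running-mean window (frames).
#' @param psfSigma PSF sigma used for centroid weighting (px).
#' @return a \linkS4class{DriftTrace}; residual RMS in
#'   \code{residualRms}.
#' @export
estimateDrift <- function(movie, fiducials, smoothWindow = 9L,
                          psfSigma = 1.1) {
  fr <- frames(movie)
  nF <- dim(fr)[3]
  if (nrow(fiducials) == 0) {
    warning("no fiducials: drift correction downgraded to identity")
    return(new("DriftTrace", dx = rep(0, nF), dy = rep(0, nF),
               residualRms = NA_real_))
  }
  nFid <- nrow(fiducials)
  dxm <- matrix(NA_real_, nF, nFid)
  dym <- matrix(NA_real_, nF, nFid)
  for (j in seq_len(nFid)) {
    x <- fiducials$x[j]; y <- fiducials$y[j]
    x0 <- x; y0 <- y
    for (f in seq_len(nF)) {
      xy <- weightedCentroid(fr[, , f], x, y, sigma = 2 * psfSigma)
      ## reject jumps (likely a lost fiducial in this frame)
      if (sqrt((xy[1] - x)^2 + (xy[2] - y)^2) < 3) {
        x <- xy[1]; y <- xy[2]
        dxm[f, j] <- x - x0; dym[f, j] <- y - y0
      }
    }
  }
  dx <- apply(dxm, 1, median, na.rm = TRUE)
  dy <- apply(dym, 1, median, na.rm = TRUE)
  if (anyNA(dx)) {
    idx <- seq_len(nF)
    dx <- approx(idx[!is.na(dx)], dx[!is.na(dx)], idx, rule = 2)$y
    dy <- approx(idx[!is.na(dy)], dy[!is.na(dy)], idx, rule = 2)$y
    message("fiducial gaps interpolated")
  }
  smooth <- function(v) {
    as.numeric(stats::filter(c(rep(v[1], smoothWindow), v,
                               rep(v[length(v)], smoothWindow)),
                             rep(1 / smoothWindow, smoothWindow),
                             sides = 2))[smoothWindow + seq_along(v)]
  }
  dxs <- smooth(dx); dys <- smooth(dy)
  dxs <- dxs - dxs[1]; dys <- dys - dys[1]
  resid <- sqrt(mean((sweep(dxm, 1, dxs))^2 + (sweep(dym, 1, dys))^2,
                     na.rm = TRUE))
  new("DriftTrace", dx = dxs, dy = dys, residualRms = resid)
}

#' Register the green channel onto red coordinates
#'
#' Matches fiducials across channels (nearest neighbor within
#' \code{matchRadius}) and fits a least-squares transform mapping green
#' coordinates into red coordinates: affine with >= 3 non-collinear
#' pairs, translation-only with 1-2 pairs, identity (with a warning)
#' otherwise.
#'
#' @param fiducialsRed,fiducialsGreen data.frames from
#'   \code{\link{detectFiducials}}.
#' @param matchRadius maximum pairing distance (px).
#' @param type "auto" (affine when >= 3 non-collinear pairs, translation
#'   otherwise), or force "translation"/"affine". A pure chromatic shift
#'   is best estimated translation-only.
#' @return list with \code{A} (2 x 2), \code{b} (length 2; map is
#'   \code{A \%*\% xy + b}), \code{residuals} (per-pair px), \code{type}.
#' @export
registerChannels <- function(fiducialsRed, fiducialsGreen,
                             matchRadius = 4,
                             type = c("auto", "translation", "affine")) {
  type <- match.arg(type)
  if (nrow(fiducialsRed) == 0 || nrow(fiducialsGreen) == 0) {
    warning("no fiducial pairs: using identity channel transform")
    return(list(A = diag(2), b = c(0, 0), residuals = numeric(),
                type = "identity"))
  }
  ## match mutually nearest pairs within the chromatic search radius
  d2 <- outer(fiducialsRed$x, fiducialsGreen$x, "-")^2 +
        outer(fiducialsRed$y, fiducialsGreen$y, "-")^2
  pairs <- which(d2 <= matchRadius^2, arr.ind = TRUE)
  if (nrow(pairs)) {
    keep <- logical(nrow(pairs))
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      keep[k] <- which.min(d2[i, ]) == j && which.min(d2[, j]) == i
    }
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (nrow(pairs) == 0) {
    warning("no fiducial pairs: using identity channel transform")
    return(list(A = diag(2), b = c(0, 0), residuals = numeric(),
                type = "identity"))
  }
  R <- cbind(fiducialsRed$x[pairs[, 1]], fiducialsRed$y[pairs[, 1]])
  G <- cbind(fiducialsGreen$x[pairs[, 2]], fiducialsGreen$y[pairs[, 2]])
  collinear <- nrow(G) >= 3 &&
    abs(det(cov(G))) < 1e-8
  useAffine <- switch(type,
    auto = nrow(pairs) >= 3 && !collinear,
    translation = FALSE,
    affine = {
      if (nrow(pairs) < 3 || collinear)
        stop("affine registration needs >= 3 non-collinear pairs")
      TRUE
    })
  if (useAffine) {
    fx <- lm.fit(cbind(1, G), R[, 1])
    fy <- lm.fit(cbind(1, G), R[, 2])
    A <- rbind(fx$coefficients[2:3], fy$coefficients[2:3])
    b <- c(fx$coefficients[1], fy$coefficients[1])
    type <- "affine"
  } else {
    A <- diag(2)
    b <- c(mean(R[, 1] - G[, 1]), mean(R[, 2] - G[, 2]))
    type <- "translation"
  }
  mapped <- t(A %*% t(G) + b)
  res <- sqrt(rowSums((mapped - R)^2))
  list(A = unname(A), b = unname(b), residuals = res, type = type)
}

#' Apply a channel transform to coordinates
#' @param transform list from \code{\link{registerChannels}}.
#' @param x,y coordinates (green channel).
#' @return matrix with columns x, y in red coordinates.
#' @export
applyTransform <- function(transform, x, y) {
  out <- t(transform$A %*% rbind(x, y) + transform$b)
  colnames(out) <- c("x", "y")
  out
}

#' Detect spots appearing during the measurement
#'
#' Works on drift-corrected (integer-shifted) temporal block averages:
#' the movie is split into blocks, each block mean is shifted back by the
#' rounded drift, and the detection image is the pixelwise maximum of
#' (block mean - early baseline mean), band-pass filtered
#' (difference-of-Gaussians). Spots already present in the early baseline
#' (fiducials, pre-transformed structures) are excluded. The
#' first-appearance frame is the first frame whose extracted intensity
#' exceeds half the fitted on-level.
#'
#' @param movie a \linkS4class{Movie}.
#' @param drift a \linkS4class{DriftTrace}.
#' @param psfSigma PSF sigma (px).
#' @param threshold threshold in robust-noise units of the detection
#'   image.
#' @param baselineFrames number of initial frames forming the baseline.
#' @param blockLength frames per temporal block.
#' @return data.frame (spot_id, channel, x, y, first_frame, is_fiducial).
#' @export
detectAppearingSpots <- function(movie, drift, psfSigma = 1.1,
                                 threshold = 5, baselineFrames = 10L,
                                 blockLength = 100L) {
  fr <- frames(movie)
  h <- dim(fr)[1]; w <- dim(fr)[2]; nF <- dim(fr)[3]
  dxy <- driftXY(drift)

  shiftSum <- function(idx) {
    acc <- matrix(0, h, w)
    cnt <- matrix(0, h, w)
    for (f in idx) {
      sr <- round(dxy$dy[f]); sc <- round(dxy$dx[f])
      rSrc <- max(1, 1 + sr):min(h, h + sr)
      cSrc <- max(1, 1 + sc):min(w, w + sc)
      rDst <- rSrc - sr; cDst <- cSrc - sc
      acc[rDst, cDst] <- acc[rDst, cDst] + fr[rSrc, cSrc, f]
      cnt[rDst, cDst] <- cnt[rDst, cDst] + 1
    }
    acc / pmax(cnt, 1)
  }

  nBase <- min(baselineFrames, nF)
  baseline <- shiftSum(seq_len(nBase))
  starts <- seq(nBase + 1L, nF, by = blockLength)
  proj <- matrix(-Inf, h, w)
  for (s in starts) {
    idx <- s:min(nF, s + blockLength - 1L)
    proj <- pmax(proj, shiftSum(idx) - baseline)
  }
  dog <- dogFilter(proj, psfSigma)
  noise <- mad(dog)
  cand <- localMaxima(dog, threshold * noise)
  baseDog <- dogFilter(baseline, psfSigma)

  out <- list()
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, "row"]; cc <- cand[i, "col"]
    ## present in baseline already -> not an appearing spot
    if (baseDog[r, cc] > 0.5 * dog[r, cc] &&
        baseDog[r, cc] > threshold * mad(baseDog)) next
    xy <- weightedCentroid(proj, cc - 1L, r - 1L, sigma = 2 * psfSigma)
    ints <- diskMinusAnnulus(fr, xy[1] + dxy$dx, xy[2] + dxy$dy)
    onLevel <- quantile(ints, 0.9, na.rm = TRUE)
    if (!is.finite(onLevel) || onLevel <= 0) next
    ff <- which(ints > onLevel / 2)[1]
    if (is.na(ff)) next
    out[[length(out) + 1]] <- data.frame(x = xy[1], y = xy[2],
                                         first_frame = ff - 1L)
  }
  if (!length(out))
    return(data.frame(spot_id = character(), channel = character(),
                      x = numeric(), y = numeric(),
                      first_frame = integer(), is_fiducial = logical()))
  o <- do.call(rbind, out)
  data.frame(spot_id = sprintf("%s_spot%03d", channelName(movie),
                               seq_len(nrow(o))),
             channel = channelName(movie), x = o$x, y = o$y,
             first_frame = o$first_frame, is_fiducial = FALSE,
             stringsAsFactors = FALSE)
}

#' Extract a background-subtracted intensity transient
#'
#' Per frame, the intensity is the pixel sum over a fixed-radius disk
#' centered on the drift-corrected spot position minus the disk area
#' times the median of a surrounding annulus. Frames where the disk
#' leaves the image are dropped (transient truncated) with a message.
#'
#' @param movie a \linkS4class{Movie}.
#' @param drift a \linkS4class{DriftTrace}.
#' @param spot one row of a spot data.frame.
#' @param radius disk radius (px).
#' @param annulus inner/outer annulus radii (px).
#' @return a \linkS4class{Transient}.
#' @export
extractTransient <- function(movie, drift, spot, radius = 3,
                             annulus = c(5, 8)) {
  fr <- frames(movie)
  dxy <- driftXY(drift)
  ints <- diskMinusAnnulus(fr, spot$x + dxy$dx, spot$y + dxy$dy,
                           radius, annulus)
  times <- timestamps(movie)
  if (anyNA(ints)) {
    keep <- seq_len(max(which(!is.na(ints))))
    if (any(is.na(ints[keep])))
      keep <- keep[keep < which(is.na(ints))[1]]
    message("spot ", spot$spot_id, " leaves the frame: transient truncated")
    ints <- ints[keep]; times <- times[keep]
  }
  new("Transient", times = times, intensities = ints,
      channel = channelName(movie), spotId = as.character(spot$spot_id),
      x = spot$x, y = spot$y)
}

#' Pair colocalized red and green spots
#'
#' Green positions are mapped into red coordinates with the channel
#' transform; mutual nearest neighbors within \code{radius} are paired.
#' Ambiguous many-to-one candidates are resolved by distance, ties by
#' earlier first appearance.
#'
#' @param spotsRed,spotsGreen spot data.frames.
#' @param transform from \code{\link{registerChannels}}.
#' @param radius pairing radius (px) in red coordinates.
#' @return list with \code{pairs} (data.frame: red_id, green_id,
#'   distance_px) and \code{unpairedRed}, \code{unpairedGreen}
#'   (character ids).
#' @export
pairColocalized <- function(spotsRed, spotsGreen, transform,
                            radius = 1.5) {
  if (nrow(spotsRed) == 0 || nrow(spotsGreen) == 0)
    return(list(pairs = data.frame(red_id = character(),
                                   green_id = character(),
                                   distance_px = numeric()),
                unpairedRed = spotsRed$spot_id,
                unpairedGreen = spotsGreen$spot_id))
  g <- applyTransform(transform, spotsGreen$x, spotsGreen$y)
  d <- sqrt(outer(spotsRed$x, g[, "x"], "-")^2 +
            outer(spotsRed$y, g[, "y"], "-")^2)
  cand <- which(d <= radius, arr.ind = TRUE)
  if (nrow(cand)) {
    ord <- order(d[cand],
                 spotsRed$first_frame[cand[, 1]] +
                   spotsGreen$first_frame[cand[, 2]])
    cand <- cand[ord, , drop = FALSE]
  }
  usedR <- logical(nrow(spotsRed)); usedG <- logical(nrow(spotsGreen))
  pairs <- list()
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (usedR[i] || usedG[j]) next
    usedR[i] <- TRUE; usedG[j] <- TRUE
    pairs[[length(pairs) + 1]] <- data.frame(
      red_id = spotsRed$spot_id[i], green_id = spotsGreen$spot_id[j],
      distance_px = d[i, j], stringsAsFactors = FALSE)
  }
  list(pairs = if (length(pairs)) do.call(rbind, pairs)
       else data.frame(red_id = character(), green_id = character(),
                       distance_px = numeric()),
       unpairedRed = spotsRed$spot_id[!usedR],
       unpairedGreen = spotsGreen$spot_id[!usedG])
}
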