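# Drift correction, registration, detection, extraction, colocalization

fidOptics <- function(...) {
  args <- utils::modifyList(
    list(imageSize = c(64L, 64L), duration = 200,
         chromaticOffset = c(0, 0), nFiducials = 0L,
         bleachRate = 0, residualFraction = 0),
    list(...))
  do.call(opticsConfig, args)
}

stepStructure <- function(x, y, tOn, duration = 200) {
  traj <- madeTrajectory(data.frame(time = tOn, row = 1L, col = 2L,
                                    state = 1L), duration = duration)
  list(trajectory = traj, sites = list(red = c(1, 2), green = c(1, 2)),
       x = x, y = y)
}

test_that("fiducials are found to subpixel accuracy, turn-ons excluded", {
  opt <- fidOptics(driftVelocity = c(0, 0), driftJitter = 0)
  truth <- cbind(c(12.3, 40.7, 22.2), c(50.1, 18.4, 30.6))
  ds <- renderMovie(list(stepStructure(52, 52, tOn = 100)), opt,
                    seed = 21, fiducialXY = truth)
  fid <- detectFiducials(channelMovie(ds, "red"))
  expect_equal(nrow(fid), 3)
  for (i in 1:3) {
    d <- min(sqrt((fid$x - truth[i, 1])^2 + (fid$y - truth[i, 2])^2))
    expect_lt(d, 0.3)
  }
  # the turn-on emitter at (52, 52) is not a fiducial
  expect_gt(min(sqrt((fid$x - 52)^2 + (fid$y - 52)^2)), 5)
})

test_that("a background-only movie has no fiducials and no spots", {
  opt <- fidOptics(photonRate = 0)
  ds <- renderMovie(list(), opt, seed = 22)
  mv <- channelMovie(ds, "red")
  expect_equal(nrow(detectFiducials(mv)), 0)
  drift <- suppressWarnings(estimateDrift(mv, detectFiducials(mv)))
  expect_equal(nrow(detectAppearingSpots(mv, drift)), 0)
})

test_that("injected linear drift is recovered within 0.2 px RMS", {
  opt <- fidOptics(driftVelocity = c(2 / 200, -1 / 200), driftJitter = 0)
  truth <- cbind(c(15, 45, 25, 50), c(45, 15, 28, 50))
  ds <- renderMovie(list(), opt, seed = 23, fiducialXY = truth)
  mv <- channelMovie(ds, "red")
  drift <- estimateDrift(mv, detectFiducials(mv))
  d <- driftXY(drift)
  tGrid <- timestamps(mv)
  errx <- d$dx - 2 / 200 * tGrid
  erry <- d$dy - (-1 / 200) * tGrid
  expect_lt(sqrt(mean(errx^2 + erry^2)), 0.2)
})

test_that("a drift-free movie yields a near-zero drift trace", {
  opt <- fidOptics(driftVelocity = c(0, 0), driftJitter = 0)
  ds <- renderMovie(list(), opt, seed = 24,
                    fiducialXY = cbind(c(20, 40), c(20, 40)))
  drift <- estimateDrift(channelMovie(ds, "red"),
                         detectFiducials(channelMovie(ds, "red")))
  d <- driftXY(drift)
  expect_lt(sqrt(mean(d$dx^2 + d$dy^2)), 0.1)
  expect_equal(c(d$dx[1], d$dy[1]), c(0, 0))
})

test_that("channel registration recovers a pure translation to 0.1 px", {
  fr <- data.frame(x = c(10, 40, 20, 50), y = c(12, 18, 44, 40))
  fg <- data.frame(x = fr$x - 1.5, y = fr$y + 0.8)
  tf <- registerChannels(fr, fg)
  mapped <- applyTransform(tf, fg$x, fg$y)
  expect_lt(max(abs(mapped[, "x"] - fr$x)), 0.1)
  expect_lt(max(abs(mapped[, "y"] - fr$y)), 0.1)

  # identical coordinates give the identity
  tf0 <- registerChannels(fr, fr)
  expect_equal(applyTransform(tf0, fr$x, fr$y)[, "x"], fr$x,
               tolerance = 1e-8)

  # an exact affine warp on 3 non-collinear pairs is recovered exactly
  A <- matrix(c(1.01, 0.02, -0.015, 0.99), 2, 2)
  b <- c(1.2, -0.7)
  g3 <- data.frame(x = c(10, 40, 15), y = c(10, 20, 45))
  r3xy <- t(A %*% t(as.matrix(g3)) + b)
  r3 <- data.frame(x = r3xy[, 1], y = r3xy[, 2])
  tf3 <- registerChannels(r3, g3)
  expect_equal(tf3$type, "affine")
  expect_equal(tf3$A, A, tolerance = 1e-8)
  expect_equal(tf3$b, b, tolerance = 1e-8)

  expect_warning(tfEmpty <- registerChannels(fr[0, ], fg), "identity")
  expect_equal(tfEmpty$A, diag(2))
})

test_that("appearing turn-on spots are detected with few false positives", {
  set.seed(31)
  n <- 20
  xy <- dominoArray:::placeStructures(n, c(96L, 96L), 6)
  tOn <- runif(n, 30, 180)
  structures <- lapply(seq_len(n), function(i)
    stepStructure(xy[i, 1], xy[i, 2], tOn[i], duration = 250))
  opt <- opticsConfig(imageSize = c(96L, 96L), duration = 250,
                      chromaticOffset = c(0, 0), nFiducials = 2L,
                      bleachRate = 0)
  ds <- renderMovie(structures, opt, seed = 32)
  mv <- channelMovie(ds, "red")
  drift <- estimateDrift(mv, detectFiducials(mv))
  spots <- detectAppearingSpots(mv, drift)
  matched <- vapply(seq_len(n), function(i)
    any(sqrt((spots$x - xy[i, 1])^2 + (spots$y - xy[i, 2])^2) < 1.5), NA)
  expect_gte(mean(matched), 0.95)
  falsePos <- sum(vapply(seq_len(nrow(spots)), function(k)
    min(sqrt((xy[, 1] - spots$x[k])^2 + (xy[, 2] - spots$y[k])^2)) >= 1.5,
    NA))
  expect_lte(falsePos, 1)
  # fiducials are never reported as appearing
  for (i in seq_len(nrow(ds@fiducials)))
    expect_gt(min(sqrt((spots$x - ds@fiducials$x[i])^2 +
                       (spots$y - ds@fiducials$y[i])^2)), 1.5)
})

test_that("detection is equivariant under integer image shifts", {
  opt <- fidOptics(driftVelocity = c(0, 0), driftJitter = 0)
  st <- stepStructure(30.2, 25.7, tOn = 60)
  ds <- renderMovie(list(st), opt, seed = 33)
  mv <- channelMovie(ds, "red")
  fr <- frames(mv)
  shifted <- array(0, dim = dim(fr))
  shifted[4:64, 7:64, ] <- fr[1:61, 1:58, ]
  mvS <- new("Movie", frames = shifted, timestamps = timestamps(mv),
             channel = "red")
  drift0 <- new("DriftTrace", dx = rep(0, dim(fr)[3]),
                dy = rep(0, dim(fr)[3]), residualRms = 0)
  s1 <- detectAppearingSpots(mv, drift0)
  s2 <- detectAppearingSpots(mvS, drift0)
  expect_equal(nrow(s1), 1)
  expect_equal(nrow(s2), 1)
  expect_equal(s2$x - s1$x, 6, tolerance = 0.05)
  expect_equal(s2$y - s1$y, 3, tolerance = 0.05)
})

test_that("transient extraction cancels the background", {
  opt <- fidOptics(driftVelocity = c(0, 0), driftJitter = 0,
                   background = 15, photonRate = 400)
  st <- stepStructure(32.4, 30.1, tOn = 80)
  ds <- renderMovie(list(st), opt, seed = 34)
  mv <- channelMovie(ds, "red")
  nF <- dim(frames(mv))[3]
  drift0 <- new("DriftTrace", dx = rep(0, nF), dy = rep(0, nF),
                residualRms = 0)
  spot <- data.frame(spot_id = "s", x = 32.4, y = 30.1)
  tr <- extractTransient(mv, drift0, spot)
  ints <- intensities(tr)
  pre <- ints[seq_len(78)]
  post <- ints[83:nF]
  expect_lt(abs(mean(pre)), 3 * sd(pre) / sqrt(length(pre)))
  expect_equal(mean(post), 400, tolerance = 0.05)
  # dark position: mean consistent with zero
  dark <- extractTransient(mv, drift0,
                           data.frame(spot_id = "d", x = 10, y = 50))
  di <- intensities(dark)
  expect_lt(abs(mean(di)), 3 * sd(di) / sqrt(length(di)))
})

test_that("extraction on drifting data matches the undrifted scene", {
  st <- stepStructure(30, 30, tOn = 40)
  opt0 <- fidOptics(driftVelocity = c(0, 0), driftJitter = 0,
                    photonRate = 4000)
  optD <- fidOptics(driftVelocity = c(3 / 200, 1.5 / 200), driftJitter = 0,
                    photonRate = 4000)
  truthFid <- cbind(c(12, 50), c(12, 50))
  ds0 <- renderMovie(list(st), opt0, seed = 35, fiducialXY = truthFid)
  dsD <- renderMovie(list(st), optD, seed = 35, fiducialXY = truthFid)
  mv0 <- channelMovie(ds0, "red"); mvD <- channelMovie(dsD, "red")
  nF <- dim(frames(mv0))[3]
  drift0 <- new("DriftTrace", dx = rep(0, nF), dy = rep(0, nF),
                residualRms = 0)
  driftD <- estimateDrift(mvD, detectFiducials(mvD))
  spot <- data.frame(spot_id = "s", x = 30, y = 30)
  i0 <- intensities(extractTransient(mv0, drift0, spot))
  iD <- intensities(extractTransient(mvD, driftD, spot))
  on <- 45:nF
  rel <- sqrt(mean((iD[on] - i0[on])^2)) / mean(i0[on])
  expect_lt(rel, 0.05)
})

test_that("colocalization pairs mutual nearest neighbors only", {
  tf <- list(A = diag(2), b = c(0, 0), residuals = numeric(),
             type = "identity")
  r <- data.frame(spot_id = paste0("r", 1:3), channel = "red",
                  x = c(10, 30, 50), y = c(10, 30, 50),
                  first_frame = 1L, is_fiducial = FALSE)
  g <- r; g$spot_id <- paste0("g", 1:3); g$channel <- "green"
  res <- pairColocalized(r, g, tf)
  expect_equal(nrow(res$pairs), 3)

  gFar <- g; gFar$x <- gFar$x + 5
  resFar <- pairColocalized(r, gFar, tf)
  expect_equal(nrow(resFar$pairs), 0)
  expect_equal(length(resFar$unpairedRed), 3)

  # 50 structures with a realistic chromatic offset and localization noise
  set.seed(36)
  xy <- dominoArray:::placeStructures(50, c(96L, 96L), 5)
  r50 <- data.frame(spot_id = sprintf("r%02d", 1:50), channel = "red",
                    x = xy[, 1], y = xy[, 2], first_frame = 1L,
                    is_fiducial = FALSE)
  g50 <- r50
  g50$spot_id <- sprintf("g%02d", 1:50)
  g50$x <- g50$x - 1.5 + rnorm(50, 0, 0.1)
  g50$y <- g50$y + 0.8 + rnorm(50, 0, 0.1)
  tf50 <- list(A = diag(2), b = c(1.5, -0.8), residuals = numeric(),
               type = "translation")
  res50 <- pairColocalized(r50, g50, tf50)
  expect_gte(nrow(res50$pairs), 48)
  idx <- match(res50$pairs$red_id, r50$spot_id)
  expect_identical(sub("g", "r", res50$pairs$green_id),
                   res50$pairs$red_id)
})

test_that("background subtraction is unbiased over many dark disks", {
  opt <- fidOptics(photonRate = 0, background = 12, duration = 40)
  ds <- renderMovie(list(), opt, seed = 37)
  mv <- channelMovie(ds, "red")
  nF <- dim(frames(mv))[3]
  drift0 <- new("DriftTrace", dx = rep(0, nF), dy = rep(0, nF),
                residualRms = 0)
  set.seed(38)
  vals <- replicate(40, {
    spot <- data.frame(spot_id = "d", x = runif(1, 10, 54),
                       y = runif(1, 10, 54))
    intensities(extractTransient(mv, drift0, spot))
  })
  vals <- as.vector(vals)   # > 1000 dark disk measurements
  expect_gt(length(vals), 1000)
  expect_lt(abs(mean(vals)), 3 * sd(vals) / sqrt(length(vals)))
})
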