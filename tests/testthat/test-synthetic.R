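# Movie rendering and scenario presets

smallOptics <- function(...) {
  args <- utils::modifyList(
    list(imageSize = c(48L, 48L), duration = 60,
         driftVelocity = c(0, 0), driftJitter = 0,
         chromaticOffset = c(0, 0), nFiducials = 0L, bleachRate = 0),
    list(...))
  do.call(opticsConfig, args)
}

test_that("zero photon rates leave pure Poisson background", {
  opt <- smallOptics(photonRate = 0, background = 7)
  ds <- renderMovie(list(), opt, seed = 1)
  px <- as.vector(frames(channelMovie(ds, "red")))
  expect_equal(mean(px), 7, tolerance = 0.02)
  expect_equal(var(px), 7, tolerance = 0.05)     # Poisson: var = mean
})

test_that("a rendered emitter sits within 0.1 px of its true position", {
  opt <- smallOptics(photonRate = 2e4, background = 0)
  ds <- renderMovie(list(), opt, seed = 2,
                    fiducialXY = cbind(20.37, 25.81))
  img <- frames(channelMovie(ds, "red"))[, , 1]
  tot <- sum(img)
  xs <- 0:(ncol(img) - 1); ys <- 0:(nrow(img) - 1)
  cx <- sum(t(img) * xs) / tot
  cy <- sum(img * ys) / tot
  expect_lt(abs(cx - 20.37), 0.1)
  expect_lt(abs(cy - 25.81), 0.1)
})

test_that("an immediately bleaching emitter is dark after one on-frame", {
  opt <- smallOptics(photonRate = 5000, background = 0,
                     bleachRate = 1e9)
  traj <- madeTrajectory(data.frame(time = 10.1, row = 1L, col = 2L,
                                    state = 1L), duration = 60)
  st <- list(trajectory = traj, sites = list(red = c(1, 2), green = c(1, 2)),
             x = 24, y = 24)
  ds <- renderMovie(list(st), opt, seed = 3)
  perFrame <- apply(frames(channelMovie(ds, "red")), 3, sum)
  on <- which(perFrame > 1000)
  expect_equal(on, 12L)   # frame at t = 11 s only (turn-on at 10.1 s)
  expect_equal(groundTruth(ds)$t_bleach_red_s, 11)
})

test_that("five_trigger dataset bookkeeping is consistent", {
  opt <- opticsConfig(imageSize = c(64L, 64L), duration = 120)
  ds <- generateDataset("five_trigger", seed = 5, nStructures = 8,
                        optics = opt)
  gt <- groundTruth(ds)
  expect_equal(nrow(gt), 8)
  expect_equal(length(ds@trajectories), 8)
  expect_equal(dim(frames(channelMovie(ds, "red")))[3], 120)
  expect_equal(dim(frames(channelMovie(ds, "green")))[3], 120)
  # ground-truth transformation times agree with the trajectories
  P <- probePositions()
  for (i in seq_len(8)) {
    tt <- trueTransformationTime(ds@trajectories[[i]], P$P1)
    expect_equal(gt$t_transform_red_s[i], tt)
  }
  expect_error(generateDataset("no_such_preset", seed = 1), "arg")
  expect_error(generateDataset("five_trigger", seed = 1, nStructures = 3,
                               optics = opt,
                               overrides = list(bogus = 1)), "override")
})

test_that("four-trigger cascades are reversible, five-trigger ones are not", {
  P <- probePositions()
  m5 <- scenarioPreset("five_trigger")$model
  m4 <- scenarioPreset("four_trigger")$model
  n <- 80
  rev5 <- vapply(seq_len(n), function(i)
    countReversals(simulateCascade(m5, 1500, seed = 200 + i), P$edge) >= 2,
    NA)
  rev4 <- vapply(seq_len(n), function(i)
    countReversals(simulateCascade(m4, 1500, seed = 200 + i), P$edge) >= 2,
    NA)
  expect_gt(mean(rev4), 0.5)
  # one-sided binomial comparison of the two fractions
  tst <- prop.test(c(sum(rev4), sum(rev5)), c(n, n),
                   alternative = "greater")
  expect_lt(tst$p.value, 0.01)
})

test_that("the lock preset injects its documented mean delay", {
  preset <- scenarioPreset("lock_design_2")
  frameT <- 0:1499
  n <- 200
  dt <- vapply(seq_len(n), function(i) {
    tr <- simulateCascade(preset$model, 1500, seed = 3000 + i)
    sR <- junctionStateSeries(tr, preset$probes$red, frameT) + 1L
    sG <- junctionStateSeries(tr, preset$probes$green, frameT + 0.5) + 1L
    tR <- transformationTime(madePath(sR, frameT))@time
    tG <- transformationTime(madePath(sG, frameT + 0.5))@time
    tG - tR
  }, 0)
  se <- sd(dt, na.rm = TRUE) / sqrt(sum(!is.na(dt)))
  expect_lt(abs(mean(dt, na.rm = TRUE) - preset$lockDelayMean), 3 * se)
})

test_that("design 4 never transforms downstream of the deleted junction", {
  P <- probePositions()
  m <- scenarioPreset("lock_design_4")$model
  for (i in 1:60) {
    tr <- simulateCascade(m, 1500, seed = 400 + i)
    expect_true(is.na(trueTransformationTime(tr, P$P3)))
  }
})

test_that("the cascade initiates at the top-right trigger corner", {
  P <- probePositions()
  m <- latticeModel()
  n <- 60
  ok <- vapply(seq_len(n), function(i) {
    tr <- simulateCascade(m, 1500, seed = 700 + i)
    tc <- trueTransformationTime(tr, c(1L, 3L))
    tp <- vapply(P[c("P1", "P2", "P3", "P4", "P5")],
                 function(s) trueTransformationTime(tr, s), 0)
    !is.na(tc) && all(tc <= tp + 1e-9, na.rm = TRUE)
  }, NA)
  expect_gte(mean(ok), 0.95)
})

test_that("structures too close together trigger a warning", {
  opt <- smallOptics()
  traj <- madeTrajectory(data.frame(time = 1, row = 1L, col = 2L,
                                    state = 1L), duration = 60)
  mk <- function(x, y) list(trajectory = traj,
                            sites = list(red = c(1, 2), green = c(1, 2)),
                            x = x, y = y)
  expect_warning(renderMovie(list(mk(20, 20), mk(21, 20)), opt, seed = 1),
                 "4 PSF sigma")
  expect_error(renderMovie(list(mk(200, 20)), opt, seed = 1),
               "field of view")
})

test_that("dataset generation is deterministic in the master seed", {
  opt <- opticsConfig(imageSize = c(48L, 48L), duration = 60)
  d1 <- generateDataset("five_trigger", seed = 9, nStructures = 3,
                        optics = opt)
  d2 <- generateDataset("five_trigger", seed = 9, nStructures = 3,
                        optics = opt)
  expect_identical(frames(channelMovie(d1, "red")),
                   frames(channelMovie(d2, "red")))
  expect_identical(groundTruth(d1), groundTruth(d2))
})

test_that("datasets round-trip through the TIFF + sidecar contract", {
  opt <- opticsConfig(imageSize = c(32L, 32L), duration = 20,
                      nFiducials = 2L)
  ds <- generateDataset("five_trigger", seed = 13, nStructures = 2,
                        optics = opt)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  red <- readMovieTiff(file.path(dir, "movie_red.tif"),
                       file.path(dir, "timestamps.csv"), "red")
  expect_equal(frames(red), frames(channelMovie(ds, "red")))
  expect_equal(timestamps(red), timestamps(channelMovie(ds, "red")))
  gt <- read.csv(file.path(dir, "ground_truth.csv"))
  expect_equal(nrow(gt), 2)
})
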