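# Coupling parameter C, delta-t statistics, population fractions, yield

redGreen <- function(sR, sG) {
  list(red = madePath(sR, times = seq_along(sR) - 1),
       green = madePath(sG, times = seq_along(sG) - 1 + 0.5))
}

test_that("identical paths are fully coupled", {
  s <- c(rep(1, 40), rep(2, 60))
  p <- redGreen(s, s)
  r <- coupling(p$red, p$green)
  expect_equal(couplingValue(r), 1)
  # C of a path with itself (no lag) is also 1
  expect_equal(couplingValue(coupling(p$red, p$red)), 1)
})

test_that("anti-phase paths give C = 0", {
  sR <- c(rep(1, 5), rep(2, 95))
  sG <- c(rep(2, 5), rep(1, 95))
  p <- redGreen(sR, sG)
  expect_equal(couplingValue(coupling(p$red, p$green)), 0)
})

test_that("the hand-counted ten-frame example gives C = 4/6", {
  # red switches between (0-based) frames 3/4, green between 7/8;
  # states chosen so counted frames are same at 0,1,2,9, differing at 5,6
  sR <- c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2)
  sG <- c(1, 1, 1, 1, 1, 1, 1, 1, 2, 2)
  p <- redGreen(sR, sG)
  r <- coupling(p$red, p$green)
  expect_equal(r@nExcluded, 4L)
  expect_equal(r@nSame + r@nDiff, 6L)
  expect_equal(couplingValue(r), 4 / 6)
})

test_that("C is symmetric and insensitive to time origin and padding", {
  set.seed(201)
  for (i in 1:10) {
    sR <- simulateSwitcher(200, 0.05, 0.05)
    sG <- simulateSwitcher(200, 0.05, 0.05)
    p <- redGreen(sR, sG)
    c1 <- couplingValue(coupling(p$red, p$green))
    # symmetry under swapping the two channels
    pSwap <- list(red = madePath(sG, seq_along(sG) - 1),
                  green = madePath(sR, seq_along(sR) - 1 + 0.5))
    c2 <- couplingValue(coupling(pSwap$red, pSwap$green))
    expect_equal(c1, c2)
    # shifting the time origin changes nothing
    pShift <- list(red = madePath(sR, seq_along(sR) - 1 + 500),
                   green = madePath(sG, seq_along(sG) - 1 + 500.5))
    expect_equal(couplingValue(coupling(pShift$red, pShift$green)), c1)
  }
})

test_that("appending frames excluded in both channels leaves C alone", {
  sR <- c(rep(1, 10), rep(2, 30))
  sG <- c(rep(1, 12), rep(2, 28))
  p <- redGreen(sR, sG)
  c1 <- couplingValue(coupling(p$red, p$green))
  # pad both channels with a trailing segment cut off by bleach truncation
  pR <- madePath(c(sR, rep(2, 10)), times = 0:49, truncation = 41L)
  pG <- madePath(c(sG, rep(2, 10)), times = 0:49 + 0.5, truncation = 41L)
  expect_equal(couplingValue(coupling(pR, pG)), c1)
})

test_that("independent switchers are rarely fully coupled, common-driver pairs are", {
  set.seed(202)
  nPair <- 200
  cInd <- vapply(seq_len(nPair), function(i) {
    sR <- simulateSwitcher(500, 1 / 20, 1 / 20)
    sG <- simulateSwitcher(500, 1 / 20, 1 / 20)
    p <- redGreen(sR, sG)
    couplingValue(coupling(p$red, p$green))
  }, 0)
  expect_lt(median(cInd, na.rm = TRUE), 0.95)

  cCom <- vapply(seq_len(nPair), function(i) {
    s <- simulateSwitcher(500, 1 / 20, 1 / 20)
    flipR <- runif(500) < 0.01           # per-channel decoding noise
    flipG <- runif(500) < 0.01
    sR <- ifelse(flipR, 3L - s, s)
    sG <- ifelse(flipG, 3L - s, s)
    p <- redGreen(sR, sG)
    couplingValue(coupling(p$red, p$green))
  }, 0)
  expect_gt(fractionFullyCoupled(cCom)$fraction, 0.8)
})

test_that("fraction fully coupled counts C above the threshold", {
  expect_equal(fractionFullyCoupled(rep(1, 5))$fraction, 1)
  r <- fractionFullyCoupled(c(0.99, 0.90, 0.96, 0.50))
  expect_equal(r$fraction, 0.5)
  expect_equal(r$se, sqrt(0.5 * 0.5 / 4))
  expect_error(fractionFullyCoupled(NA_real_), "defined")
})

test_that("delta t follows the green-minus-red sign convention", {
  call <- function(t) new("TransformationCall", time = t, dwell = 100,
                          channel = "x")
  expect_equal(deltaT(call(100), call(100)), 0)
  expect_equal(deltaT(call(100), call(300)), 200)
  expect_true(is.na(deltaT(call(NA_real_), call(300))))
})

test_that("Gaussian fits return ML parameters with SE sigma over root n", {
  r <- fitGaussian(c(5, 5, 5, 5))
  expect_equal(r$mean, 5)
  expect_equal(r$sigma, 0)
  expect_equal(r$se, 0)
  expect_true(r$degenerate)

  set.seed(203)
  v <- rnorm(1000, 10, 2)
  f <- fitGaussian(v)
  expect_lt(abs(f$mean - 10), 3 * f$se)
  expect_equal(f$se, f$sigma / sqrt(1000))

  z <- fitGaussian(c(0, 0, 120, 180, 240), excludeZero = TRUE)
  expect_equal(z$n, 3)
  expect_equal(z$mean, 180)

  expect_false(fitGaussian(c(0, 0, 7), excludeZero = TRUE)$ok)
})

test_that("fluctuating fractions carry the binomial standard error", {
  expect_equal(fractionFluctuating(rep(FALSE, 10))$fraction, 0)
  expect_equal(fractionFluctuating(rep(FALSE, 10))$se, 0)
  flags <- rep(c(TRUE, FALSE), c(24, 56))     # p = 0.3, n = 80
  r <- fractionFluctuating(flags)
  expect_equal(r$fraction, 0.3)
  expect_equal(r$se, sqrt(0.3 * 0.7 / 80))
  expect_equal(round(r$se, 4), 0.0512)
})

test_that("transformation yield is a percentage with binomial CI", {
  expect_equal(transformationYield(50, 50)$percent, 100)
  y <- transformationYield(43, 50)
  expect_equal(y$percent, 86)
  expect_true(y$ci[1] < 86 && y$ci[2] > 86)
  expect_equal(transformationYield(0, 50)$percent, 0)
  expect_error(transformationYield(51, 50), "exceed")
  expect_error(transformationYield(1, 0), "positive")
})

# nearest-neighbor duplex energetics -------------------------------------

# manual table sums (unified NN dG37, kcal/mol):
#   stacks: AT/AT -0.88, AC -1.44, CG -2.17, GT -1.44, GG -1.84,
#           GA -1.30, AA -1.00, CA -1.45, TG -1.45
#   init per terminal G.C +0.98, per terminal A.T +1.03; symmetry +0.43
test_that("NN duplex energies match manual table sums", {
  # AT: one AT/AT stack, two A.T ends, self-complementary
  expect_equal(as.numeric(nnHybridizationEnergy("AT")),
               -0.88 + 2 * 1.03 + 0.43)
  # ACGT: AC + CG + GT, two A.T ends, self-complementary
  expect_equal(as.numeric(nnHybridizationEnergy("ACGT")),
               (-1.44 - 2.17 - 1.44) + 2 * 1.03 + 0.43)
  # GGAA: GG + GA + AA, one G.C and one A.T end, not self-complementary
  expect_equal(as.numeric(nnHybridizationEnergy("GGAA")),
               (-1.84 - 1.30 - 1.00) + 0.98 + 1.03)
  # CATG: CA + AT + TG, two G.C... ends are C (G.C) and G (G.C)
  expect_equal(as.numeric(nnHybridizationEnergy("CATG")),
               (-1.45 - 0.88 - 1.45) + 2 * 0.98 + 0.43)
  # GCGC: GC + CG + GC, two G.C ends, self-complementary
  expect_equal(as.numeric(nnHybridizationEnergy("GCGC")),
               (-2.24 - 2.17 - 2.24) + 2 * 0.98 + 0.43)
})

test_that("a duplex and its reverse complement have the same energy", {
  for (s in c("ACGTTGCA", "GATTACA", "CCCGGA", "ATGCATTTGG")) {
    rc <- dominoArray:::reverseComplement(s)
    expect_equal(as.numeric(nnHybridizationEnergy(s)),
                 as.numeric(nnHybridizationEnergy(rc)))
  }
  expect_error(nnHybridizationEnergy("ACGU"), "A, C, G, T")
  expect_error(nnHybridizationEnergy("A"), "length")
})

test_that("the transport-efficiency midpoint is recovered", {
  # symmetric points around 16 kcal/mol
  f <- transportEfficiencyFit(c(14, 16, 18), c(0.9, 0.5, 0.1))
  expect_equal(f$midpoint, 16, tolerance = 0.01)

  # seeded binomial samples from a logistic with midpoint 16
  set.seed(204)
  dG <- seq(12, 20, by = 1)
  pTrue <- 1 / (1 + exp((dG - 16) / 1.2))
  n <- rep(80, length(dG))
  frac <- rbinom(length(dG), n, pTrue) / n
  fit <- transportEfficiencyFit(dG, frac, n = n)
  expect_lt(abs(fit$midpoint - 16), 3 * fit$se)

  expect_error(transportEfficiencyFit(c(14, 16, 18), c(1, 1, 1)),
               "crossing")
})
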