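# Shared fixtures built in code: tiny lattice models, hand-made
# trajectories and state paths, and direct two-state switcher simulators.

# a bare lattice model with no triggers (all-field-free), full mask
freeLattice <- function(nrow, ncol, J, strain = 0, k0 = 1,
                        temperature = 310.15) {
  latticeModel(nrow = nrow, ncol = ncol,
               mask = matrix(TRUE, nrow, ncol),
               J = J, triggerSites = matrix(integer(), 0, 2),
               h = numeric(0), hTopBonus = 0, strain = strain,
               bindingRate = Inf, k0 = k0, temperature = temperature)
}

# hand-made trajectory from an event table
madeTrajectory <- function(events, duration = 100, dims = c(5L, 3L)) {
  new("LatticeTrajectory",
      events = events, duration = duration, seed = 0L,
      dims = as.integer(dims))
}

# StatePath from a 1/2 state vector on a given time grid
madePath <- function(states, times = seq_along(states) - 1,
                     truncation = NA_integer_) {
  new("StatePath", states = as.integer(states), times = times,
      levelMeans = c(0, 100), levelSds = c(5, 5),
      transitions = as.integer(which(diff(states) != 0) + 1L),
      logLik = 0, truncationFrame = as.integer(truncation),
      singleState = FALSE)
}

# two-state Markov switcher sampled on a frame grid (1 = down, 2 = up);
# rates per second, frame period 1 s, exact per-frame transition kernel
simulateSwitcher <- function(nFrames, kUp, kDown, start = 1L) {
  pUp <- 1 - exp(-kUp)     # P(down -> up within one frame)
  pDown <- 1 - exp(-kDown)
  s <- integer(nFrames)
  s[1] <- start
  for (i in seq_len(nFrames - 1L)) {
    s[i + 1L] <- if (s[i] == 1L) {
      if (runif(1) < pUp) 2L else 1L
    } else {
      if (runif(1) < pDown) 1L else 2L
    }
  }
  s
}

# noisy turn-on transient with a known step frame
turnOnTransient <- function(nFrames, stepFrame, low = 0, high = 100,
                            noiseSd = 20, channel = "red") {
  x <- rnorm(nFrames, low, noiseSd)
  if (stepFrame <= nFrames)
    x[stepFrame:nFrames] <- rnorm(nFrames - stepFrame + 1, high, noiseSd)
  new("Transient", times = seq_len(nFrames) - 1, intensities = x,
      channel = channel, spotId = "t1", x = 0, y = 0)
}

# brute-force joint log-probability maximum over all 2^n paths of a
# two-state Gaussian HMM; returns the maximal score (oracle for Viterbi)
bruteForceBestScore <- function(x, pi0, A, mu, sigma) {
  n <- length(x)
  paths <- as.matrix(expand.grid(rep(list(1:2), n)))
  logB <- rbind(dnorm(x, mu[1], sigma[1], log = TRUE),
                dnorm(x, mu[2], sigma[2], log = TRUE))
  emis <- matrix(logB[cbind(as.vector(paths),
                            rep(seq_len(n), each = nrow(paths)))],
                 nrow = nrow(paths))
  score <- log(pi0)[paths[, 1]] + rowSums(emis)
  if (n > 1) {
    logA <- log(A)
    for (t in seq_len(n - 1))
      score <- score + logA[cbind(paths[, t], paths[, t + 1])]
  }
  max(score)
}

pathScore <- function(path, x, pi0, A, mu, sigma) {
  n <- length(x)
  s <- log(pi0)[path[1]] +
    sum(dnorm(x, mu[path], sigma[path], log = TRUE))
  if (n > 1) s <- s + sum(log(A)[cbind(path[-n], path[-1])])
  s
}
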