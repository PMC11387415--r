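## synthetic_data module, part 3: scenario presets, dataset generation and
## on-disk interchange (TIFF stacks + sidecar CSV/JSON).

scenarioNames <- c("five_trigger", "four_trigger",
                   paste0("lock_design_", 1:4))

#' Scenario presets
#'
#' Returns the model, probe assignment and structure count of one named
#' scenario. Presets mirror the study regimes:
#' \describe{
#'   \item{five_trigger}{all five trigger strands; probes on two
#'     mid-array junctions that transform quasi-simultaneously.}
#'   \item{four_trigger}{only the upper four trigger strands; the green
#'     probe sits on the bottom edge junction whose trigger is withheld
#'     and which fluctuates reversibly between its conformations.}
#'   \item{lock_design_1}{unmodified reference for the lock series;
#'     probes on the relay junction and the terminal far-column junction.}
#'   \item{lock_design_2}{a lock unit on the terminal junction adds an
#'     activation barrier, injecting an exponential delay (mean about
#'     50 s) before that junction transforms.}
#'   \item{lock_design_3}{the central relay junction is deleted
#'     (staples left out), cutting the terminal junction off from the
#'     cascade; it only flickers thermally and never sustains the
#'     transformed state.}
#'   \item{lock_design_4}{as design 3 with the terminal junction itself
#'     additionally disabled (its switching barrier is effectively
#'     infinite): the transformation never progresses there at all.}
#' }
#'
#' @param scenario one of \code{"five_trigger"}, \code{"four_trigger"},
#'   \code{"lock_design_1"} ... \code{"lock_design_4"}.
#' @return list with components \code{model} (\linkS4class{LatticeModel}),
#'   \code{probes} (list with red/green lattice sites), \code{nStructures},
#'   \code{lockDelayMean} (s; lock designs only).
#' @export
scenarioPreset <- function(scenario) {
  scenario <- match.arg(scenario, scenarioNames)
  P <- probePositions()
  lockSite <- "2,1"
  switch(scenario,
    five_trigger = list(
      model = latticeModel(),
      probes = list(red = P$P1, green = P$P3),
      nStructures = 50L),
    four_trigger = list(
      model = latticeModel(triggerSites = cbind(1:4, 3L),
                           h = c(12, 6, 5, 4.5), bindingRate = 0.1),
      probes = list(red = P$P2, green = P$edge),
      nStructures = 50L),
    lock_design_1 = list(
      model = latticeModel(),
      probes = list(red = P$P2, green = P$P3),
      nStructures = 50L),
    lock_design_2 = {
      ## barrier calibrated so the lock injects a mean delay of about
      ## one minute between the relay and the locked junction (the
      ## reference value below is the large-sample simulation mean)
      m <- latticeModel(lockBarriers = setNames(list(2.8), lockSite))
      list(model = m,
           probes = list(red = P$P2, green = P$P3),
           nStructures = 50L,
           lockDelayMean = 59.9)
    },
    lock_design_3 = list(
      model = latticeModel(removedSites = rbind(c(2L, 2L))),
      probes = list(red = P$P2, green = P$P3),
      nStructures = 50L),
    lock_design_4 = list(
      model = latticeModel(removedSites = rbind(c(2L, 2L)),
                           lockBarriers = setNames(list(15), lockSite)),
      probes = list(red = P$P2, green = P$P3),
      nStructures = 50L))
}

## random non-overlapping positions in the field of view
placeStructures <- function(n, imageSize, minSep, margin = 5) {
  xy <- matrix(NA_real_, n, 2)
  placed <- 0
  tries <- 0
  while (placed < n && tries < 20000) {
    cand <- c(runif(1, margin, imageSize[2] - 1 - margin),
              runif(1, margin, imageSize[1] - 1 - margin))
    ok <- placed == 0 ||
      min(sqrt((xy[seq_len(placed), 1] - cand[1])^2 +
               (xy[seq_len(placed), 2] - cand[2])^2)) >= minSep
    tries <- tries + 1
    if (ok) {
      placed <- placed + 1
      xy[placed, ] <- cand
    }
  }
  if (placed < n) stop("could not place structures without overlap; ",
                       "reduce the count or enlarge the field")
  xy
}

#' Generate a complete synthetic dataset for a named scenario
#'
#' Simulates one cascade trajectory per structure under the scenario's
#' lattice model, places the structures in the field of view, and renders
#' both channels. Deterministic given (scenario, overrides, seed): the
#' master seed drives structure placement and per-structure child seeds.
#'
#' @param scenario preset name, see \code{\link{scenarioPreset}}.
#' @param seed integer master seed.
#' @param nStructures number of structures (default from the preset).
#' @param optics an \linkS4class{OpticsConfig}.
#' @param overrides named list overriding preset components: \code{model}
#'   (a LatticeModel) and/or \code{probes}.
#' @return a \linkS4class{SyntheticDataset}.
#' @examples
#' \donttest{
#' ds <- generateDataset("five_trigger", seed = 1, nStructures = 5)
#' groundTruth(ds)
#' }
#' @export
generateDataset <- function(scenario, seed, nStructures = NULL,
                            optics = opticsConfig(), overrides = list()) {
  preset <- scenarioPreset(scenario)
  bad <- setdiff(names(overrides), c("model", "probes"))
  if (length(bad))
    stop("unknown override(s): ", paste(bad, collapse = ", "))
  model <- if (!is.null(overrides$model)) overrides$model else preset$model
  probes <- if (!is.null(overrides$probes)) overrides$probes else preset$probes
  n <- if (!is.null(nStructures)) as.integer(nStructures)
       else preset$nStructures

  set.seed(as.integer(seed))
  childSeeds <- sample.int(.Machine$integer.max - 1L, n)
  ## keep structures clear of each other's background annuli
  minSep <- max(4 * max(optics@psfSigma), 7)
  xy <- placeStructures(n, optics@imageSize, minSep)
  renderSeed <- sample.int(.Machine$integer.max - 1L, 1)

  structures <- lapply(seq_len(n), function(i) {
    traj <- simulateCascade(model, duration = optics@duration,
                            seed = childSeeds[i])
    list(trajectory = traj, sites = probes, x = xy[i, 1], y = xy[i, 2])
  })
  ds <- renderMovie(structures, optics, seed = renderSeed,
                    scenario = scenario)
  ds@seed <- as.integer(seed)
  ds
}

#' Write a SyntheticDataset to disk
#'
#' Movies are written as 16-bit multi-page TIFF stacks (pixel values are
#' photon counts), frame timestamps as a sidecar CSV with columns
#' frame_index, channel, t_start_s, the ground truth as CSV, and the full
#' trajectory event lists as JSON.
#'
#' @param ds a \linkS4class{SyntheticDataset}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(red = file.path(dir, "movie_red.tif"),
             green = file.path(dir, "movie_green.tif"),
             timestamps = file.path(dir, "timestamps.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"),
             trajectories = file.path(dir, "trajectories.json"),
             fiducials = file.path(dir, "fiducials.csv"),
             drift = file.path(dir, "drift.csv"))
  writeMovieTiff(ds@red, paths["red"])
  writeMovieTiff(ds@green, paths["green"])
  tsr <- data.frame(frame_index = seq_along(ds@red@timestamps) - 1L,
                    channel = "red", t_start_s = ds@red@timestamps)
  tsg <- data.frame(frame_index = seq_along(ds@green@timestamps) - 1L,
                    channel = "green", t_start_s = ds@green@timestamps)
  write.csv(rbind(tsr, tsg), paths["timestamps"], row.names = FALSE)
  write.csv(ds@groundTruth, paths["ground_truth"], row.names = FALSE)
  jsonlite::write_json(
    lapply(ds@trajectories, function(tr) events(tr)),
    paths["trajectories"], digits = NA)
  write.csv(ds@fiducials, paths["fiducials"], row.names = FALSE)
  write.csv(ds@drift, paths["drift"], row.names = FALSE)
  invisible(paths)
}

## 16-bit TIFF writer; counts are stored as count/65535 in [0, 1]
writeMovieTiff <- function(movie, path) {
  fr <- frames(movie)
  pages <- lapply(seq_len(dim(fr)[3]), function(f)
    pmin(fr[, , f], 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  invisible(path)
}

#' Read a movie written by \code{\link{writeDataset}}
#'
#' @param path TIFF stack path.
#' @param timestampCsv sidecar timestamp CSV path.
#' @param channel "red" or "green".
#' @return a \linkS4class{Movie}.
#' @export
readMovieTiff <- function(path, timestampCsv, channel) {
  pages <- tiff::readTIFF(path, all = TRUE)
  stack <- array(0, dim = c(nrow(pages[[1]]), ncol(pages[[1]]),
                            length(pages)))
  for (f in seq_along(pages)) stack[, , f] <- round(pages[[f]] * 65535)
  ts <- read.csv(timestampCsv)
  ts <- ts[ts$channel == channel, ]
  ts <- ts[order(ts$frame_index), ]
  new("Movie", frames = stack, timestamps = ts$t_start_s, channel = channel)
}
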