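## S4 classes for the domino-array analysis chain.
## Sites are addressed as (row, col) pairs, row 1 at the top, col 1 at the
## left; the trigger edge is the rightmost column by default.

#' LatticeModel: energetics and kinetics of an anti-junction array
#'
#' The cascade is modeled on a rectangular lattice of two-state
#' anti-junctions (0 = untransformed, 1 = transformed). The configuration
#' energy is ranked by the number of "open" anti-junction interfaces,
#' realized as discordant adjacent pairs:
#' \deqn{E = J D - \sum_{i \in triggers} h_i s_i + \epsilon \sum_{i \notin triggers} s_i}
#' where \eqn{D} is the number of adjacent site pairs in differing
#' conformations, \eqn{h_i} the hybridization stabilization of transformed
#' trigger sites (active once the trigger field is on) and \eqn{\epsilon}
#' (\code{strain}) a small penalty for the transformed conformation of
#' untriggered junctions. With the field off every uniform state has energy
#' zero.
#'
#' @slot mask logical matrix; which lattice positions carry an anti-junction
#'   (supports the half-row geometry of the 5 x 2.5 array).
#' @slot J numeric; interface penalty per discordant adjacent pair
#'   (kcal/mol), \code{J >= 0}.
#' @slot triggerSites integer matrix (n x 2, row/col) of edge sites carrying
#'   the trigger bias field.
#' @slot h numeric; per-trigger stabilization of the transformed state
#'   (kcal/mol), recycled to the number of trigger sites.
#' @slot strain numeric; penalty per transformed non-trigger site while the
#'   field is active (kcal/mol). Default 0.
#' @slot triggerOnTime numeric; time (s) at which the trigger field
#'   activates (trigger strand addition), default 0.
#' @slot bindingRate numeric; per-trigger exponential binding rate (1/s),
#'   recycled to the number of triggers. \code{Inf} means that trigger's
#'   field switches on instantaneously at \code{triggerOnTime}.
#' @slot lockBarriers numeric matrix (same dim as mask); additional
#'   activation barrier (kcal/mol) for moves flipping that site out of the
#'   untransformed conformation. 0 where no lock.
#' @slot removedSites integer matrix (n x 2); anti-junctions deleted from
#'   the design (left-out staples). Never overlaps trigger sites.
#' @slot k0 numeric; attempt rate (1/s), \code{k0 > 0}.
#' @slot temperature numeric; temperature in K (default 310.15).
#' @export
setClass("LatticeModel",
  representation(
    mask = "matrix",
    J = "numeric",
    triggerSites = "matrix",
    h = "numeric",
    strain = "numeric",
    triggerOnTime = "numeric",
    bindingRate = "numeric",
    lockBarriers = "matrix",
    removedSites = "matrix",
    k0 = "numeric",
    temperature = "numeric"
  )
)

setValidity("LatticeModel", function(object) {
  msg <- character()
  m <- object@mask
  if (!is.logical(m) || any(is.na(m)))
    msg <- c(msg, "mask must be a logical matrix without NAs")
  if (length(object@J) != 1L || object@J < 0)
    msg <- c(msg, "J must be a single value >= 0")
  if (length(object@k0) != 1L || object@k0 <= 0)
    msg <- c(msg, "k0 must be a single value > 0")
  if (object@strain < 0)
    msg <- c(msg, "strain must be >= 0")
  if (any(object@lockBarriers < 0))
    msg <- c(msg, "all lock barriers must be >= 0")
  if (!identical(dim(object@lockBarriers), dim(m)))
    msg <- c(msg, "lockBarriers must have the same dimensions as mask")
  ts <- object@triggerSites
  if (nrow(ts) > 0) {
    if (any(ts[, 1] < 1 | ts[, 1] > nrow(m) | ts[, 2] < 1 | ts[, 2] > ncol(m)))
      msg <- c(msg, "trigger sites outside the grid")
    else if (any(!m[ts]))
      msg <- c(msg, "trigger sites must lie on masked-in lattice positions")
  }
  if (length(object@h) != nrow(ts))
    msg <- c(msg, "h must have one value per trigger site")
  rs <- object@removedSites
  if (nrow(rs) > 0 && nrow(ts) > 0) {
    key <- function(s) paste(s[, 1], s[, 2])
    if (any(key(rs) %in% key(ts)))
      msg <- c(msg, "removed sites may not include trigger sites")
  }
  if (length(msg)) msg else TRUE
})

#' LatticeTrajectory: one kinetic Monte Carlo realization of the cascade
#'
#' @slot events data.frame with columns \code{time} (s, strictly
#'   increasing), \code{row}, \code{col}, \code{state} (0/1 conformation the
#'   site switched to). The initial state is all-untransformed.
#' @slot duration numeric; simulated time span (s).
#' @slot seed integer; RNG seed that produced the trajectory.
#' @slot dims integer(2); lattice dimensions.
#' @slot removedSites integer matrix; deleted sites of the generating model
#'   (they never appear in events).
#' @export
setClass("LatticeTrajectory",
  representation(
    events = "data.frame",
    duration = "numeric",
    seed = "integer",
    dims = "integer",
    removedSites = "matrix"
  ),
  prototype(removedSites = matrix(integer(), 0, 2))
)

setValidity("LatticeTrajectory", function(object) {
  ev <- object@events
  need <- c("time", "row", "col", "state")
  if (!all(need %in% names(ev)))
    return("events must have columns time, row, col, state")
  if (nrow(ev) > 1 && any(diff(ev$time) <= 0))
    return("event times must be strictly increasing")
  TRUE
})

#' OpticsConfig: camera, illumination and timing of the synthetic microscope
#'
#' Defaults mirror alternating-laser TIRF time-lapse imaging: 100 ms
#' exposure once per second per color, a 0.5 s lag between the two
#' excitation colors, 25 min total.
#'
#' @slot imageSize integer(2); image height and width in pixels.
#' @slot pixelSizeNm numeric; pixel size (nm).
#' @slot psfSigma numeric(2), named red/green; Gaussian PSF sigma (px).
#' @slot photonRate numeric; photons per frame emitted by an unquenched
#'   probe in its on state.
#' @slot residualFraction numeric; relative emission of the quenched state.
#' @slot background numeric; background photons per pixel per frame.
#' @slot exposure numeric; exposure time (s), must be < channelPeriod.
#' @slot channelPeriod numeric; time between frames of one color (s).
#' @slot interChannelLag numeric; green-after-red lag (s), < channelPeriod.
#' @slot duration numeric; total measurement time (s).
#' @slot bleachRate numeric; single-step photobleach rate per second of
#'   cumulative on-time (1/s).
#' @slot driftVelocity numeric(2); stage drift (px/s, x then y).
#' @slot driftJitter numeric; per-frame random drift jitter sigma (px).
#' @slot chromaticOffset numeric(2); translation of the green channel
#'   relative to red (px).
#' @slot nFiducials integer; number of always-on fiducial structures.
#' @export
setClass("OpticsConfig",
  representation(
    imageSize = "integer",
    pixelSizeNm = "numeric",
    psfSigma = "numeric",
    photonRate = "numeric",
    residualFraction = "numeric",
    background = "numeric",
    exposure = "numeric",
    channelPeriod = "numeric",
    interChannelLag = "numeric",
    duration = "numeric",
    bleachRate = "numeric",
    driftVelocity = "numeric",
    driftJitter = "numeric",
    chromaticOffset = "numeric",
    nFiducials = "integer"
  )
)

setValidity("OpticsConfig", function(object) {
  msg <- character()
  if (object@exposure >= object@channelPeriod)
    msg <- c(msg, "exposure must be shorter than the channel period")
  if (object@interChannelLag >= object@channelPeriod)
    msg <- c(msg, "inter-channel lag must be shorter than the channel period")
  rates <- c(object@photonRate, object@background, object@bleachRate,
             object@residualFraction, object@driftJitter)
  if (any(rates < 0)) msg <- c(msg, "all rates must be >= 0")
  if (any(object@imageSize < 8L)) msg <- c(msg, "imageSize too small")
  if (length(msg)) msg else TRUE
})

#' Movie: one-channel time-lapse stack with per-frame timestamps
#'
#' @slot frames numeric array (height x width x frames) of pixel counts.
#' @slot timestamps numeric; exposure start times (s), strictly increasing.
#' @slot channel character; "red" or "green".
#' @export
setClass("Movie",
  representation(
    frames = "array",
    timestamps = "numeric",
    channel = "character"
  )
)

setValidity("Movie", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3-d array (h x w x t)")
  if (length(object@timestamps) != d[3])
    return("one timestamp per frame required")
  if (d[3] > 1 && any(diff(object@timestamps) <= 0))
    return("timestamps must be strictly increasing")
  TRUE
})

#' SyntheticDataset: rendered dual-color movies plus ground truth
#'
#' @slot red,green Movie objects for the two channels.
#' @slot groundTruth data.frame, one row per rendered structure
#'   (structure_id, sites, positions, true transformation/bleach times).
#' @slot trajectories list of LatticeTrajectory, one per structure.
#' @slot stateSeries list; per structure, per channel true per-frame
#'   conformation series.
#' @slot fiducials data.frame of fiducial positions.
#' @slot drift data.frame of the injected per-frame drift (red frame grid).
#' @slot scenario character; preset name.
#' @slot seed integer; master seed.
#' @export
setClass("SyntheticDataset",
  representation(
    red = "Movie",
    green = "Movie",
    groundTruth = "data.frame",
    trajectories = "list",
    stateSeries = "list",
    fiducials = "data.frame",
    drift = "data.frame",
    scenario = "character",
    seed = "integer"
  )
)

setValidity("SyntheticDataset", function(object) {
  if (length(object@trajectories) != nrow(object@groundTruth))
    return("every rendered structure needs a ground-truth row")
  TRUE
})

#' DriftTrace: per-frame lateral stage drift relative to frame 0
#'
#' @slot dx,dy numeric; shift in px per frame, (0, 0) at frame 0.
#' @slot residualRms numeric; RMS of fiducial residuals after correction.
#' @export
setClass("DriftTrace",
  representation(
    dx = "numeric",
    dy = "numeric",
    residualRms = "numeric"
  )
)

setValidity("DriftTrace", function(object) {
  if (length(object@dx) != length(object@dy))
    return("dx and dy must have equal length")
  if (length(object@dx) > 0 &&
      (abs(object@dx[1]) > 1e-9 || abs(object@dy[1]) > 1e-9))
    return("drift at frame 0 must be (0, 0)")
  if (any(!is.finite(object@dx)) || any(!is.finite(object@dy)))
    return("drift values must be finite")
  TRUE
})

#' Transient: background-subtracted intensity-versus-time trace of one spot
#'
#' @slot times numeric; frame times (s), strictly increasing.
#' @slot intensities numeric; background-subtracted counts per frame.
#' @slot channel character; "red" or "green".
#' @slot spotId character; identifier of the source spot.
#' @slot x,y numeric; spot position (px, frame-0 coordinates).
#' @export
setClass("Transient",
  representation(
    times = "numeric",
    intensities = "numeric",
    channel = "character",
    spotId = "character",
    x = "numeric",
    y = "numeric"
  )
)

setValidity("Transient", function(object) {
  if (length(object@times) != length(object@intensities))
    return("times and intensities must have equal length")
  if (length(object@times) > 1 && any(diff(object@times) <= 0))
    return("times must be strictly increasing")
  TRUE
})

#' StatePath: decoded two-level trajectory of one transient
#'
#' @slot states integer; per-frame state, 1 = untransformed, 2 = transformed.
#' @slot times numeric; frame times (s).
#' @slot levelMeans,levelSds numeric(2); emission level parameters, ordered
#'   so that the transformed level mean is the larger one.
#' @slot transitions integer; frame index (1-based) of the first frame of
#'   each new level.
#' @slot logLik numeric; fitted log-likelihood.
#' @slot truncationFrame integer; photobleach truncation frame or NA.
#' @slot singleState logical; TRUE when the fit degenerated to one level.
#' @export
setClass("StatePath",
  representation(
    states = "integer",
    times = "numeric",
    levelMeans = "numeric",
    levelSds = "numeric",
    transitions = "integer",
    logLik = "numeric",
    truncationFrame = "integer",
    singleState = "logical"
  )
)

setValidity("StatePath", function(object) {
  if (length(object@states) != length(object@times))
    return("states and times must have equal length")
  s <- object@states
  if (length(s) > 1) {
    chg <- which(diff(s) != 0) + 1L
    if (!identical(as.integer(chg), object@transitions))
      return("states must only change at listed transitions")
  }
  TRUE
})

#' TransformationCall: transformation time of one channel of one structure
#'
#' @slot time numeric; transformation time (s) or NA if the structure never
#'   qualified under the minimum-dwell rule.
#' @slot dwell numeric; length (s) of the qualifying transformed dwell.
#' @slot channel character.
#' @export
setClass("TransformationCall",
  representation(
    time = "numeric",
    dwell = "numeric",
    channel = "character"
  )
)

#' CouplingResult: the coupling parameter C for one structure
#'
#' @slot C numeric in [0, 1], or NA when the counted window is empty.
#' @slot nSame,nDiff,nExcluded integer frame tallies.
#' @slot windowFrames integer; total frames in the analysis window.
#' @export
setClass("CouplingResult",
  representation(
    C = "numeric",
    nSame = "integer",
    nDiff = "integer",
    nExcluded = "integer",
    windowFrames = "integer"
  ),
  prototype(C = NA_real_, nSame = 0L, nDiff = 0L, nExcluded = 0L,
            windowFrames = 0L)
)

setValidity("CouplingResult", function(object) {
  if (length(object@C) != 1)
    return("C must be a single value (possibly NA)")
  if (!is.na(object@C) && (object@C < 0 || object@C > 1))
    return("C must lie in [0, 1]")
  if (object@nSame + object@nDiff + object@nExcluded != object@windowFrames)
    return("same + differing + excluded must equal the window frame count")
  TRUE
})

#' RunConfig: a reproducible pipeline run configuration
#'
#' @slot scenario character; preset name.
#' @slot overrides list; preset overrides (model/optics parameters,
#'   structure count).
#' @slot seed integer; master seed.
#' @slot analysis list; detection/HMM/coupling parameters.
#' @slot outDir character; output directory ("" = no files written).
#' @slot version character; package version stamp.
#' @export
setClass("RunConfig",
  representation(
    scenario = "character",
    overrides = "list",
    seed = "integer",
    analysis = "list",
    outDir = "character",
    version = "character"
  )
)

#' RunReport: summary of one end-to-end pipeline run
#'
#' @slot config RunConfig that produced the report.
#' @slot configHash character; hash of the serialized configuration.
#' @slot counts named integer; structures surviving each filtering stage.
#' @slot structures data.frame; per-structure results (transformation
#'   times, delta t, C, fluctuation flags).
#' @slot summary list; per-design summary statistics.
#' @slot warnings character.
#' @export
setClass("RunReport",
  representation(
    config = "RunConfig",
    configHash = "character",
    counts = "integer",
    structures = "data.frame",
    summary = "list",
    warnings = "character"
  )
)

setValidity("RunReport", function(object) {
  cnt <- object@counts
  chain <- intersect(c("detected", "colocalized", "dualOn"), names(cnt))
  if (length(chain) > 1 && any(diff(cnt[chain]) > 0))
    return("stage counts must be non-increasing along the filter chain")
  TRUE
})
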