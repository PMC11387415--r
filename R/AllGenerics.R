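## Generics and accessors. Slots are never reached into from user code;
## these accessors are the supported surface.

#' Event table accessor
#'
#' The ordered flip events (time, row, col, new state) of a simulated
#' cascade trajectory.
#'
#' @param object a LatticeTrajectory
#' @return data.frame of events.
#' @export
setGeneric("events", function(object) standardGeneric("events"))

#' @rdname events
setMethod("events", "LatticeTrajectory", function(object) object@events)

#' Frame stack accessor
#' @param object a Movie
#' @export
setGeneric("frames", function(object) standardGeneric("frames"))

#' @rdname frames
setMethod("frames", "Movie", function(object) object@frames)

#' Frame timestamp accessor
#' @param object a Movie or Transient
#' @export
setGeneric("timestamps", function(object) standardGeneric("timestamps"))

#' @rdname timestamps
setMethod("timestamps", "Movie", function(object) object@timestamps)

#' @rdname timestamps
setMethod("timestamps", "Transient", function(object) object@times)

#' Channel label accessor
#' @param object a Movie, Transient or StatePath
#' @export
setGeneric("channelName", function(object) standardGeneric("channelName"))

#' @rdname channelName
setMethod("channelName", "Movie", function(object) object@channel)

#' @rdname channelName
setMethod("channelName", "Transient", function(object) object@channel)

#' Intensity accessor
#' @param object a Transient
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))

#' @rdname intensities
setMethod("intensities", "Transient", function(object) object@intensities)

#' Decoded per-frame states (1 = untransformed, 2 = transformed)
#' @param object a StatePath
#' @export
setGeneric("statePath", function(object) standardGeneric("statePath"))

#' @rdname statePath
setMethod("statePath", "StatePath", function(object) object@states)

#' Transition frame indices (first frame of each new level)
#' @param object a StatePath
#' @export
setGeneric("transitions", function(object) standardGeneric("transitions"))

#' @rdname transitions
setMethod("transitions", "StatePath", function(object) object@transitions)

#' Emission level means, ordered untransformed then transformed
#' @param object a StatePath
#' @export
setGeneric("levelMeans", function(object) standardGeneric("levelMeans"))

#' @rdname levelMeans
setMethod("levelMeans", "StatePath", function(object) object@levelMeans)

#' Per-frame drift accessor
#' @param object a DriftTrace
#' @export
setGeneric("driftXY", function(object) standardGeneric("driftXY"))

#' @rdname driftXY
setMethod("driftXY", "DriftTrace", function(object)
  data.frame(dx = object@dx, dy = object@dy))

#' Coupling parameter accessor
#' @param object a CouplingResult
#' @export
setGeneric("couplingValue", function(object) standardGeneric("couplingValue"))

#' @rdname couplingValue
setMethod("couplingValue", "CouplingResult", function(object) object@C)

#' Ground-truth table accessor
#' @param object a SyntheticDataset
#' @export
setGeneric("groundTruth", function(object) standardGeneric("groundTruth"))

#' @rdname groundTruth
setMethod("groundTruth", "SyntheticDataset", function(object) object@groundTruth)

#' Channel movie accessor
#' @param object a SyntheticDataset
#' @param channel "red" or "green"
#' @export
setGeneric("channelMovie", function(object, channel)
  standardGeneric("channelMovie"))

#' @rdname channelMovie
setMethod("channelMovie", "SyntheticDataset", function(object, channel) {
  channel <- match.arg(channel, c("red", "green"))
  if (channel == "red") object@red else object@green
})

#' Per-structure result table accessor
#' @param object a RunReport
#' @export
setGeneric("structureTable", function(object) standardGeneric("structureTable"))

#' @rdname structureTable
setMethod("structureTable", "RunReport", function(object) object@structures)

#' Stage count accessor
#' @param object a RunReport
#' @export
setGeneric("stageCounts", function(object) standardGeneric("stageCounts"))

#' @rdname stageCounts
setMethod("stageCounts", "RunReport", function(object) object@counts)

#' Summary statistics accessor
#' @param object a RunReport
#' @export
setGeneric("reportSummary", function(object) standardGeneric("reportSummary"))

#' @rdname reportSummary
setMethod("reportSummary", "RunReport", function(object) object@summary)

## show methods -------------------------------------------------------------

setMethod("show", "LatticeModel", function(object) {
  d <- dim(object@mask)
  cat("LatticeModel:", d[1], "x", d[2], "anti-junction lattice\n")
  cat("  present sites:", sum(presentMask(object)),
      "| triggers:", nrow(object@triggerSites),
      "| removed:", nrow(object@removedSites), "\n")
  cat(sprintf("  J = %.3g, h = [%s], strain = %.3g kcal/mol; k0 = %.3g /s; T = %.2f K\n",
      object@J, paste(signif(object@h, 3), collapse = ", "),
      object@strain, object@k0, object@temperature))
  nlock <- sum(object@lockBarriers > 0)
  if (nlock) cat("  lock barriers on", nlock, "site(s)\n")
})

setMethod("show", "LatticeTrajectory", function(object) {
  cat("LatticeTrajectory:", nrow(object@events), "events over",
      object@duration, "s (seed", object@seed, ")\n")
})

setMethod("show", "Movie", function(object) {
  d <- dim(object@frames)
  cat(sprintf("Movie [%s]: %d frames of %d x %d px, t = %.1f..%.1f s\n",
      object@channel, d[3], d[1], d[2],
      min(object@timestamps), max(object@timestamps)))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset (scenario:", object@scenario, ", seed",
      object@seed, ")\n")
  cat("  structures:", nrow(object@groundTruth),
      "| fiducials:", nrow(object@fiducials), "\n")
  show(object@red); show(object@green)
})

setMethod("show", "DriftTrace", function(object) {
  cat(sprintf("DriftTrace: %d frames, max |shift| = %.2f px, residual RMS = %.3f px\n",
      length(object@dx), max(sqrt(object@dx^2 + object@dy^2)),
      object@residualRms))
})

setMethod("show", "Transient", function(object) {
  cat(sprintf("Transient [%s] spot %s: %d frames, mean %.1f counts\n",
      object@channel, object@spotId, length(object@times),
      mean(object@intensities)))
})

setMethod("show", "StatePath", function(object) {
  cat(sprintf("StatePath: %d frames, %d transition(s), levels %.1f / %.1f%s\n",
      length(object@states), length(object@transitions),
      object@levelMeans[1], object@levelMeans[2],
      if (isTRUE(object@singleState)) " [single-state]" else ""))
  if (!is.na(object@truncationFrame))
    cat("  photobleach truncation at frame", object@truncationFrame, "\n")
})

setMethod("show", "CouplingResult", function(object) {
  cat(sprintf("CouplingResult: C = %s (same %d, differing %d, excluded %d)\n",
      format(object@C, digits = 3), object@nSame, object@nDiff,
      object@nExcluded))
})

setMethod("show", "RunReport", function(object) {
  cat("RunReport for scenario", object@config@scenario, "\n")
  cat("  counts:", paste(names(object@counts), object@counts,
                         sep = "=", collapse = ", "), "\n")
  if (length(object@warnings))
    cat("  warnings:", length(object@warnings), "\n")
})
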