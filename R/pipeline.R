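## pipeline_cli module: reproducible end-to-end runs
## (simulate -> render -> analyze -> couple -> report).

#' Default analysis parameters
#'
#' Detection, HMM and coupling parameters of the analysis chain, exposed
#' in one place. These defaults are used by \code{\link{runEndToEnd}}
#' and can be overridden per run.
#'
#' @return named list.
#' @export
analysisParams <- function() {
  list(psfSigma = c(red = 1.1, green = 1.0),
       detectThreshold = 5,
       baselineFrames = 10L,
       blockLength = 100L,
       diskRadius = 3,
       annulus = c(5, 8),
       colocRadius = 1.5,
       minDwell = 10,
       hmmTol = 1e-4,
       hmmMaxIter = 500L,
       couplingWindow = "record",
       deltaTExcludeZero = FALSE)
}

#' Construct a RunConfig
#'
#' @param scenario preset name (see \code{\link{scenarioPreset}}).
#' @param seed integer master seed.
#' @param nStructures structure count (NULL = preset default).
#' @param overrides preset overrides passed to
#'   \code{\link{generateDataset}}.
#' @param analysis named list of overrides of
#'   \code{\link{analysisParams}}; unknown keys are a configuration
#'   error.
#' @param outDir output directory ("" writes nothing).
#' @return a \linkS4class{RunConfig}.
#' @export
runConfig <- function(scenario, seed, nStructures = NULL,
                      overrides = list(), analysis = list(),
                      outDir = "") {
  scenario <- match.arg(scenario, scenarioNames)
  bad <- setdiff(names(analysis), names(analysisParams()))
  if (length(bad))
    stop("unknown analysis parameter(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(names(overrides),
                 c("model", "probes", "optics", "nStructures"))
  if (length(bad))
    stop("unknown override(s): ", paste(bad, collapse = ", "))
  if (!is.null(nStructures))
    overrides$nStructures <- as.integer(nStructures)
  new("RunConfig", scenario = scenario, overrides = overrides,
      seed = as.integer(seed),
      analysis = modifyList(analysisParams(), analysis),
      outDir = outDir,
      version = as.character(utils::packageVersion("dominoArray")))
}

## FNV-1a 32-bit hash of the serialized configuration
configHash <- function(config) {
  js <- jsonlite::toJSON(list(scenario = config@scenario,
                              seed = config@seed,
                              overrides = names(config@overrides),
                              analysis = config@analysis,
                              version = config@version),
                         auto_unbox = TRUE)
  bytes <- utf8ToInt(as.character(js))
  ## polynomial rolling hash mod 2^31 - 1 (stays exact in doubles)
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

## analyze one dual-color dataset; the core of run_end_to_end
#' Analyze a rendered dataset
#'
#' Runs the full image-analysis and transient-analysis chain on a
#' dual-color dataset: fiducial detection, drift estimation, channel
#' registration, appearing-spot detection, colocalization, dual-color
#' transient extraction, HMM fitting with photobleach truncation, the
#' dual-on filter, transformation times, fluctuation classification and
#' the coupling parameter. Structures detected in only one channel still
#' get a transient extracted at the registered position in the other
#' channel, so that dark or never-transforming partners are accounted
#' for.
#'
#' @param ds a \linkS4class{SyntheticDataset} (or any object with red
#'   and green \linkS4class{Movie}s in those slots).
#' @param params list from \code{\link{analysisParams}}.
#' @return list with \code{structures} (data.frame), \code{counts},
#'   \code{spots}, \code{drift}, \code{transform}, \code{warnings}.
#' @export
analyzeDataset <- function(ds, params = analysisParams()) {
  warnLog <- character()
  wrap <- function(expr) withCallingHandlers(expr, warning = function(w) {
    warnLog <<- c(warnLog, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  red <- channelMovie(ds, "red"); green <- channelMovie(ds, "green")

  fidR <- wrap(detectFiducials(red, params$psfSigma[["red"]],
                               params$detectThreshold))
  fidG <- wrap(detectFiducials(green, params$psfSigma[["green"]],
                               params$detectThreshold))
  driftR <- wrap(estimateDrift(red, fidR, psfSigma = params$psfSigma[["red"]]))
  driftG <- wrap(estimateDrift(green, fidG,
                               psfSigma = params$psfSigma[["green"]]))
  transform <- wrap(registerChannels(fidR, fidG))

  spotsR <- detectAppearingSpots(red, driftR, params$psfSigma[["red"]],
                                 params$detectThreshold,
                                 params$baselineFrames, params$blockLength)
  spotsG <- detectAppearingSpots(green, driftG, params$psfSigma[["green"]],
                                 params$detectThreshold,
                                 params$baselineFrames, params$blockLength)
  pairing <- pairColocalized(spotsR, spotsG, transform, params$colocRadius)

  ## inverse map red -> green coordinates for partner extraction
  Ainv <- solve(transform$A)
  toGreen <- function(x, y) {
    out <- Ainv %*% (rbind(x, y) - transform$b)
    c(out[1], out[2])
  }

  candidates <- list()
  for (k in seq_len(nrow(pairing$pairs))) {
    rid <- pairing$pairs$red_id[k]; gid <- pairing$pairs$green_id[k]
    candidates[[length(candidates) + 1]] <- list(
      red = spotsR[spotsR$spot_id == rid, ],
      green = spotsG[spotsG$spot_id == gid, ],
      colocalized = TRUE)
  }
  for (rid in pairing$unpairedRed) {
    sp <- spotsR[spotsR$spot_id == rid, ]
    gxy <- toGreen(sp$x, sp$y)
    candidates[[length(candidates) + 1]] <- list(
      red = sp,
      green = data.frame(spot_id = paste0(rid, "_g"), channel = "green",
                         x = gxy[1], y = gxy[2], first_frame = NA_integer_,
                         is_fiducial = FALSE, stringsAsFactors = FALSE),
      colocalized = FALSE)
  }
  for (gid in pairing$unpairedGreen) {
    sp <- spotsG[spotsG$spot_id == gid, ]
    rxy <- applyTransform(transform, sp$x, sp$y)
    candidates[[length(candidates) + 1]] <- list(
      red = data.frame(spot_id = paste0(gid, "_r"), channel = "red",
                       x = rxy[1, "x"], y = rxy[1, "y"],
                       first_frame = NA_integer_,
                       is_fiducial = FALSE, stringsAsFactors = FALSE),
      green = sp, colocalized = FALSE)
  }

  rows <- list()
  for (k in seq_along(candidates)) {
    cd <- candidates[[k]]
    trR <- wrap(extractTransient(red, driftR, cd$red,
                                 params$diskRadius, params$annulus))
    trG <- wrap(extractTransient(green, driftG, cd$green,
                                 params$diskRadius, params$annulus))
    if (length(intensities(trR)) < 10 || length(intensities(trG)) < 10)
      next
    pR <- fitTwoStateHMM(trR, tol = params$hmmTol,
                         maxIter = params$hmmMaxIter)
    pG <- fitTwoStateHMM(trG, tol = params$hmmTol,
                         maxIter = params$hmmMaxIter)
    pR <- truncateAtBleach(pR, detectBleach(trR, pR))
    pG <- truncateAtBleach(pG, detectBleach(trG, pG))
    keep <- filterDualOn(pR, pG)
    callR <- transformationTime(pR, params$minDwell)
    callG <- transformationTime(pG, params$minDwell)
    C <- if (keep) couplingValue(coupling(pR, pG, params$couplingWindow))
         else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      structure_id = sprintf("X%03d", k),
      red_id = cd$red$spot_id, green_id = cd$green$spot_id,
      x_px = cd$red$x, y_px = cd$red$y,
      colocalized = cd$colocalized,
      dual_on = keep,
      t_red_s = callR@time, t_green_s = callG@time,
      delta_t_s = deltaT(callR, callG),
      C = C,
      fluctuating_red = classifyFluctuating(pR),
      fluctuating_green = classifyFluctuating(pG),
      bleach_red = pR@truncationFrame, bleach_green = pG@truncationFrame,
      stringsAsFactors = FALSE)
  }
  structures <- if (length(rows)) do.call(rbind, rows) else
    data.frame(structure_id = character(), red_id = character(),
               green_id = character(), x_px = numeric(), y_px = numeric(),
               colocalized = logical(), dual_on = logical(),
               t_red_s = numeric(), t_green_s = numeric(),
               delta_t_s = numeric(), C = numeric(),
               fluctuating_red = logical(), fluctuating_green = logical(),
               bleach_red = integer(), bleach_green = integer())

  counts <- c(detected = nrow(structures),
              colocalized = sum(structures$colocalized),
              dualOn = sum(structures$colocalized & structures$dual_on),
              transformed = sum(structures$colocalized & structures$dual_on &
                                !is.na(structures$delta_t_s)),
              cDefined = sum(!is.na(structures$C)))
  list(structures = structures, counts = counts,
       spots = list(red = spotsR, green = spotsG,
                    fiducialsRed = fidR, fiducialsGreen = fidG),
       drift = list(red = driftR, green = driftG),
       transform = transform, warnings = warnLog)
}

summarizeStructures <- function(structures, params) {
  kept <- structures[structures$dual_on, , drop = FALSE]
  dt <- fitGaussian(kept$delta_t_s,
                    excludeZero = isTRUE(params$deltaTExcludeZero))
  fc <- if (any(!is.na(kept$C)))
    fractionFullyCoupled(kept$C) else list(fraction = NA, se = NA, n = 0)
  flR <- if (nrow(kept)) fractionFluctuating(kept$fluctuating_red)
         else list(fraction = NA, se = NA, n = 0)
  flG <- if (nrow(kept)) fractionFluctuating(kept$fluctuating_green)
         else list(fraction = NA, se = NA, n = 0)
  yield <- if (nrow(structures))
    transformationYield(sum(!is.na(structures$t_red_s) &
                            !is.na(structures$t_green_s)),
                        nrow(structures))
    else list(percent = NA, ci = c(NA, NA), n = 0)
  list(n = nrow(structures), nKept = nrow(kept),
       deltaT = dt, fullyCoupled = fc,
       fluctuatingRed = flR, fluctuatingGreen = flG,
       yield = yield)
}

#' Run the complete pipeline for one configuration
#'
#' Generates the scenario dataset, runs the analysis chain, summarizes,
#' and (when \code{outDir} is set) writes the fixed file contract:
#' structures.csv, spots CSVs, drift.csv, summary.json (with the config
#' hash embedded). Identical configuration and seed give identical
#' outputs.
#'
#' @param config a \linkS4class{RunConfig}.
#' @return a \linkS4class{RunReport}.
#' @export
runEndToEnd <- function(config) {
  stopifnot(is(config, "RunConfig"))
  optics <- if (!is.null(config@overrides$optics)) config@overrides$optics
            else opticsConfig()
  ds <- generateDataset(config@scenario, seed = config@seed,
                        nStructures = config@overrides$nStructures,
                        optics = optics,
                        overrides = config@overrides[
                          intersect(names(config@overrides),
                                    c("model", "probes"))])
  res <- analyzeDataset(ds, config@analysis)
  summ <- summarizeStructures(res$structures, config@analysis)
  hash <- configHash(config)
  report <- new("RunReport", config = config, configHash = hash,
                counts = res$counts, structures = res$structures,
                summary = summ, warnings = res$warnings)
  if (nzchar(config@outDir)) {
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$structures,
              file.path(config@outDir, "structures.csv"), row.names = FALSE)
    write.csv(rbind(res$spots$red, res$spots$green),
              file.path(config@outDir, "spots.csv"), row.names = FALSE)
    dxy <- driftXY(res$drift$red)
    write.csv(cbind(frame = seq_len(nrow(dxy)) - 1L, dxy),
              file.path(config@outDir, "drift.csv"), row.names = FALSE)
    jsonlite::write_json(
      c(list(config_hash = hash, scenario = config@scenario,
             seed = config@seed, counts = as.list(res$counts)),
        summ),
      file.path(config@outDir, "summary.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  report
}

#' Compare design runs
#'
#' Aligns the per-design summary statistics of several pipeline runs
#' into one table (delta-t Gaussian mean and SE, fully-coupled fraction,
#' fluctuating fractions). Metrics absent in a report are NA.
#'
#' @param reports list of \linkS4class{RunReport}s (>= 2).
#' @return data.frame, one row per report.
#' @export
compareDesigns <- function(reports) {
  if (length(reports) < 1) stop("at least one report required")
  rows <- lapply(reports, function(r) {
    s <- reportSummary(r)
    grab <- function(x) if (is.null(x) || !length(x)) NA_real_ else
      as.numeric(x)
    data.frame(design = r@config@scenario,
               n_kept = grab(s$nKept),
               delta_t_mean_s = grab(s$deltaT$mean),
               delta_t_se_s = grab(s$deltaT$se),
               fully_coupled = grab(s$fullyCoupled$fraction),
               fully_coupled_se = grab(s$fullyCoupled$se),
               fluctuating_red = grab(s$fluctuatingRed$fraction),
               fluctuating_green = grab(s$fluctuatingGreen$fraction),
               yield_pct = grab(s$yield$percent),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
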