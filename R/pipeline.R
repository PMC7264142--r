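# End-to-end glue: from a trajectory + presentation log to the tables the
# statistical layer consumes.

#' Summarise presentations into analysis tables
#'
#' Runs the full per-presentation pipeline: pre-stimulus window metrics
#' (individual and group), response detection and arrival events, and a
#' per-presentation summary row (first responder, first-response latency,
#' first arriver).
#'
#' @param traj a smoothed [TrajectorySet-class].
#' @param presentations a presentation table (see
#'   [runPresentationProtocol()]); only rows with `valid == TRUE` are
#'   scored.
#' @param vision optional [VisionConfig-class] to include the occlusion
#'   metric (slower).
#' @param criteria a [ResponseCriteria-class].
#' @param speedFloor heading-validity floor passed to
#'   [headingsFromDisplacement()].
#' @return list with `individual` and `group` metric tables (see
#'   [presentationMetrics()]), `arrivals` (long: one row per arriving fish
#'   with `arrivalOrder`), `responses` (long: one row per responding fish),
#'   and `summary` (one row per presentation: `presentationId,
#'   firstResponder, firstResponseLatency, firstArriver, firstArrivalLatency,
#'   nArrived`).
#' @export
presentationSummary <- function(traj, presentations, vision = NULL,
                                criteria = responseCriteria(),
                                speedFloor = 0.3) {
  headings <- headingsFromDisplacement(traj, speedFloor = speedFloor)
  pres <- presentations[presentations$valid, , drop = FALSE]
  pm <- presentationMetrics(traj, headings, pres, vision = vision)
  arr <- list(); resp <- list(); summ <- list()
  for (r in seq_len(nrow(pres))) {
    pid <- pres$presentationId[r]
    on <- pres$onsetFrame[r]; po <- pres$portId[r]
    a <- arrivalEvents(traj, on, po, maxWindowFrames = criteria@maxWindowFrames)
    e <- detectResponses(traj, headings, on, po, criteria)
    if (nrow(a)) { a$presentationId <- pid; arr[[r]] <- a }
    if (nrow(e)) { e$presentationId <- pid; resp[[r]] <- e }
    summ[[r]] <- data.frame(
      presentationId = pid,
      firstResponder = if (nrow(e)) e$fishId[1] else NA_character_,
      firstResponseLatency = if (nrow(e)) e$responseLatency[1] else NA_real_,
      firstArriver = if (nrow(a)) a$fishId[1] else NA_character_,
      firstArrivalLatency = if (nrow(a)) a$arrivalLatency[1] else NA_real_,
      nArrived = nrow(a))
  }
  list(individual = pm$individual, group = pm$group,
       arrivals = do.call(rbind, arr), responses = do.call(rbind, resp),
       summary = do.call(rbind, summ))
}

#' Arrival-latency analysis table
#'
#' Joins arrival events with the group window metrics into the long table
#' for the polarization x arrival-order analysis (one row per arriving fish
#' per presentation).
#'
#' @param ps a [presentationSummary()] result.
#' @param groupId group identifier added to the rows.
#' @param day cumulative days of testing added to the rows.
#' @return data.frame with columns `group, fish, presentationId,
#'   arrivalOrder, arrivalLatency, polarization, groupBearingStimulus,
#'   centroidDistStimulus, hullArea, centroidSpeed, bearingSD, minBearing,
#'   day`.
#' @export
arrivalAnalysisTable <- function(ps, groupId = "g1", day = 1) {
  if (is.null(ps$arrivals)) return(NULL)
  m <- merge(ps$arrivals, ps$group, by = "presentationId")
  data.frame(group = groupId, fish = paste(groupId, m$fishId, sep = "_"),
             presentationId = m$presentationId,
             arrivalOrder = m$arrivalOrder,
             arrivalLatency = m$arrivalLatency,
             polarization = m$polarization,
             groupBearingStimulus = m$groupBearingStimulus,
             centroidDistStimulus = m$centroidDistStimulus,
             hullArea = m$hullArea, centroidSpeed = m$centroidSpeed,
             bearingSD = m$bearingSD, minBearing = m$minBearing,
             day = day)
}

#' First-response analysis table
#'
#' One row per presentation with a detected response: the first-response
#' latency and the group-level window metrics (the predictors of the
#' group-level latency analysis).
#'
#' @param ps a [presentationSummary()] result.
#' @param groupId group identifier added to the rows.
#' @param day cumulative days of testing added to the rows.
#' @return data.frame with one row per responding presentation.
#' @export
firstResponseTable <- function(ps, groupId = "g1", day = 1) {
  s <- ps$summary[!is.na(ps$summary$firstResponseLatency), , drop = FALSE]
  if (nrow(s) == 0) return(NULL)
  m <- merge(s, ps$group, by = "presentationId")
  data.frame(group = groupId, fish = paste(groupId, m$firstResponder, sep = "_"),
             presentationId = m$presentationId,
             firstResponseLatency = m$firstResponseLatency,
             polarization = m$polarization,
             groupBearingStimulus = m$groupBearingStimulus,
             centroidDistStimulus = m$centroidDistStimulus,
             hullArea = m$hullArea, centroidSpeed = m$centroidSpeed,
             day = day)
}
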