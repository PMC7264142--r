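#' @import methods
#' @importFrom stats median sd cor coef logLik pchisq qnorm rnorm runif
#'   setNames complete.cases update as.formula simulate quantile
#' @importFrom utils read.csv write.csv head
#' @useDynLib shoalsight, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Unit conventions of a tracking session
#'
#' Records the temporal and spatial resolution of the source video so that
#' pixel/frame quantities can be converted to mm/seconds and back exactly.
#'
#' @slot fps frames per second of the video (default 25).
#' @slot pxPerMM pixels per millimetre of the calibrated image (default 2.7).
#' @export
setClass("UnitSystem",
  representation(fps = "numeric", pxPerMM = "numeric"),
  prototype(fps = 25, pxPerMM = 2.7))

setValidity("UnitSystem", function(object) {
  if (length(object@fps) != 1 || object@fps <= 0) return("fps must be a positive scalar")
  if (length(object@pxPerMM) != 1 || object@pxPerMM <= 0) return("pxPerMM must be a positive scalar")
  TRUE
})

#' Construct a UnitSystem
#'
#' @param fps frames per second.
#' @param pxPerMM pixels per millimetre.
#' @return A [UnitSystem-class] object.
#' @examples
#' unitSystem()             # 25 fps, 2.7 px/mm
#' @export
unitSystem <- function(fps = 25, pxPerMM = 2.7) {
  new("UnitSystem", fps = fps, pxPerMM = pxPerMM)
}

#' Arena geometry
#'
#' An oval experimental arena, modelled either as a stadium (rectangle with
#' semicircular caps, the default — matching ovals built from flat sheet
#' walls) or an ellipse. Coordinates are Cartesian millimetres with the
#' origin at the arena centre and the long axis along x. Stimulus ports sit
#' on the wall; each carries an inward-pointing unit normal.
#'
#' @slot lengthMM long-axis extent in mm.
#' @slot widthMM short-axis extent in mm.
#' @slot shape `"stadium"` or `"ellipse"`.
#' @slot ports data.frame with columns `id, x, y, nx, ny` (inward normal).
#' @export
setClass("ArenaGeometry",
  representation(lengthMM = "numeric", widthMM = "numeric",
                 shape = "character", ports = "data.frame"))

setValidity("ArenaGeometry", function(object) {
  if (!(object@shape %in% c("stadium", "ellipse")))
    return("shape must be 'stadium' or 'ellipse'")
  if (!(object@lengthMM > object@widthMM && object@widthMM > 0))
    return("need lengthMM > widthMM > 0")
  np <- nrow(object@ports)
  if (np < 1 || np > 8) return("need between 1 and 8 ports")
  need <- c("id", "x", "y", "nx", "ny")
  if (!all(need %in% names(object@ports)))
    return("ports must have columns id, x, y, nx, ny")
  bd <- abs(distanceToWall(object, cbind(object@ports$x, object@ports$y)))
  if (any(bd > 1)) return("every port must lie on the arena boundary (within 1 mm)")
  nn <- sqrt(object@ports$nx^2 + object@ports$ny^2)
  if (any(abs(nn - 1) > 1e-6)) return("port normals must be unit vectors")
  inside <- pointInArena(object, cbind(object@ports$x + 5 * object@ports$nx,
                                       object@ports$y + 5 * object@ports$ny))
  if (!all(inside)) return("port normals must point into the arena")
  TRUE
})

#' A set of tracked trajectories for one group
#'
#' Per-frame centre-of-mass positions for every individual of a group, in
#' Cartesian mm (origin at arena centre, y up). Frames are a strictly
#' increasing integer index; untracked (fish, frame) entries are `NA` and are
#' never interpolated.
#'
#' @slot groupId group identifier.
#' @slot fishIds character vector of individual identifiers (columns of the
#'   position matrices).
#' @slot frames integer frame index (rows).
#' @slot x,y numeric matrices `length(frames) x length(fishIds)` in mm.
#' @slot bodyLengthMM per-fish standard body length in mm.
#' @slot units the [UnitSystem-class] of the source recording.
#' @slot arena the [ArenaGeometry-class] the fish were tracked in.
#' @slot sourceUnits `"px"` or `"mm"` — the units of the ingested file.
#' @export
setClass("TrajectorySet",
  representation(groupId = "character", fishIds = "character",
                 frames = "integer", x = "matrix", y = "matrix",
                 bodyLengthMM = "numeric", units = "UnitSystem",
                 arena = "ArenaGeometry", sourceUnits = "character"))

setValidity("TrajectorySet", function(object) {
  n <- length(object@fishIds)
  if (n < 2) return("a group needs at least 2 individuals")
  if (any(diff(object@frames) <= 0)) return("frame index must be strictly increasing")
  if (!all(dim(object@x) == c(length(object@frames), n)) ||
      !all(dim(object@y) == dim(object@x)))
    return("x and y must be frames x fish matrices")
  if (length(object@bodyLengthMM) != n) return("one body length per fish")
  ok <- is.na(object@x) | is.na(object@y)
  p <- cbind(as.vector(object@x[!ok]), as.vector(object@y[!ok]))
  if (nrow(p) > 0) {
    d <- distanceToWall(object@arena, p)
    if (any(d < -20)) return("positions must lie inside the arena (20 mm tolerance)")
  }
  TRUE
})

#' Per-frame heading estimates
#'
#' Unit heading vectors derived from displacement (central differences of a
#' smoothed trajectory). Frames where a fish moves slower than the speed
#' floor carry no direction and are flagged invalid.
#'
#' @slot hx,hy matrices of unit-heading components (frames x fish); `NA`
#'   where invalid.
#' @slot speed matrix of speeds in mm/frame.
#' @slot valid logical matrix; `TRUE` where a direction is defined.
#' @slot speedFloor the mm/frame floor below which direction is undefined.
#' @export
setClass("HeadingField",
  representation(hx = "matrix", hy = "matrix", speed = "matrix",
                 valid = "matrix", speedFloor = "numeric"))

#' Visual-field configuration
#'
#' Geometry of the planar (cyclopean) visual model: a binocular sector about
#' the heading, a wider full field including the monocular regions, a ray
#' budget, and the occluder body model (an ellipse per neighbour, major axis
#' = body length along the heading).
#'
#' @slot binocularHalfAngle half-angle of the binocular sector, degrees.
#' @slot totalField total angular width of the full field, degrees.
#' @slot nRays number of rays cast across the chosen field.
#' @slot maxRange maximum sight range in mm (`NA` = arena diagonal).
#' @slot eyeOffset eye position ahead of the centre-of-mass, in body lengths.
#' @slot aspectRatio occluder ellipse minor/major axis ratio.
#' @export
setClass("VisionConfig",
  representation(binocularHalfAngle = "numeric", totalField = "numeric",
                 nRays = "numeric", maxRange = "numeric",
                 eyeOffset = "numeric", aspectRatio = "numeric"),
  prototype(binocularHalfAngle = 15, totalField = 300, nRays = 720,
            maxRange = NA_real_, eyeOffset = 0.4, aspectRatio = 0.2))

setValidity("VisionConfig", function(object) {
  if (!(object@binocularHalfAngle > 0 && object@binocularHalfAngle < 90))
    return("binocularHalfAngle must be in (0, 90)")
  if (object@totalField > 360 || object@totalField <= 0)
    return("totalField must be in (0, 360]")
  if (object@nRays < 90) return("need at least 90 rays")
  TRUE
})

#' Construct a VisionConfig
#'
#' @param binocularHalfAngle half-angle of the binocular sector (degrees).
#' @param totalField total field of view including monocular regions (degrees).
#' @param nRays rays per cast field.
#' @param maxRange maximum sight range, mm (`NA` = arena diagonal).
#' @param eyeOffset eye advance along the heading, in body lengths.
#' @param aspectRatio occluder ellipse aspect ratio.
#' @return A [VisionConfig-class].
#' @export
visionConfig <- function(binocularHalfAngle = 15, totalField = 300,
                         nRays = 720, maxRange = NA_real_,
                         eyeOffset = 0.4, aspectRatio = 0.2) {
  new("VisionConfig", binocularHalfAngle = binocularHalfAngle,
      totalField = totalField, nRays = nRays, maxRange = maxRange,
      eyeOffset = eyeOffset, aspectRatio = aspectRatio)
}

#' Shoal simulation configuration
#'
#' Parameters of the zonal (repulsion / alignment / attraction) agent model
#' used by [simulateShoal()]. Defaults emulate the study conditions: groups
#' of 8 three-spined sticklebacks (body length 27 +/- 2.4 mm) tracked at
#' 25 fps in a 1335 x 720 mm oval arena, cruising at about 2 body lengths
#' per second.
#'
#' @slot nFish group size.
#' @slot fps frames per second.
#' @slot arena the [ArenaGeometry-class].
#' @slot rRep,rAli,rAtt zone radii in mm (repulsion < alignment < attraction).
#' @slot wAlign,wAttract,wWall steering weights.
#' @slot wWander weight of the per-frame random steering direction; the
#'   alignment weight competes against it, so `wAlign / wWander` controls
#'   the group's order smoothly (negative `wAlign` = active anti-alignment).
#' @slot wallDist wall-avoidance onset distance, mm.
#' @slot headingNoiseSD per-frame heading noise SD, degrees.
#' @slot turnMax maximum turn per frame, degrees.
#' @slot speedMeanMM,speedSDMM per-fish base speed distribution, mm/frame.
#' @slot bodyLengthMeanMM,bodyLengthSDMM body length distribution, mm.
#' @export
setClass("SimConfig",
  representation(nFish = "numeric", fps = "numeric", arena = "ArenaGeometry",
                 rRep = "numeric", rAli = "numeric", rAtt = "numeric",
                 wAlign = "numeric", wAttract = "numeric", wWall = "numeric",
                 wWander = "numeric",
                 wallDist = "numeric", headingNoiseSD = "numeric",
                 turnMax = "numeric", speedMeanMM = "numeric",
                 speedSDMM = "numeric", bodyLengthMeanMM = "numeric",
                 bodyLengthSDMM = "numeric"))

setValidity("SimConfig", function(object) {
  if (!(object@rRep < object@rAli && object@rAli < object@rAtt))
    return("zone radii must satisfy repulsion < alignment < attraction")
  if (object@headingNoiseSD < 0) return("heading noise SD must be >= 0")
  if (object@nFish < 2) return("need at least 2 fish")
  TRUE
})

#' Construct a SimConfig
#'
#' @param nFish group size (default 8).
#' @param fps frames per second (default 25).
#' @param arena arena geometry (default [defaultArena()]).
#' @param rRep,rAli,rAtt zone radii, mm.
#' @param wAlign,wAttract,wWall steering weights.
#' @param wWander random-steering weight (the order-control denominator).
#' @param wallDist wall-avoidance onset distance, mm.
#' @param headingNoiseSD per-frame heading noise SD, degrees.
#' @param turnMax maximum turn per frame, degrees.
#' @param speedMeanMM,speedSDMM base speed distribution, mm/frame.
#' @param bodyLengthMeanMM,bodyLengthSDMM body length distribution, mm.
#' @return A [SimConfig-class].
#' @export
simConfig <- function(nFish = 8, fps = 25, arena = defaultArena(),
                      rRep = 60, rAli = 220, rAtt = 450,
                      wAlign = 2, wAttract = 0.6, wWall = 2.5, wWander = 1,
                      wallDist = 80, headingNoiseSD = 3, turnMax = 30,
                      speedMeanMM = 2.2, speedSDMM = 0.35,
                      bodyLengthMeanMM = 27, bodyLengthSDMM = 2.4) {
  new("SimConfig", nFish = nFish, fps = fps, arena = arena,
      rRep = rRep, rAli = rAli, rAtt = rAtt, wAlign = wAlign,
      wAttract = wAttract, wWall = wWall, wWander = wWander,
      wallDist = wallDist,
      headingNoiseSD = headingNoiseSD, turnMax = turnMax,
      speedMeanMM = speedMeanMM, speedSDMM = speedSDMM,
      bodyLengthMeanMM = bodyLengthMeanMM, bodyLengthSDMM = bodyLengthSDMM)
}

#' Two-channel detection model
#'
#' Hazard model used by [applyDetectionModel()]. A non-responding fish draws
#' private detection each frame the stimulus lies inside its binocular
#' sector with an unoccluded line of sight, with hazard
#' `h0 * exp(-d / lambda)`; otherwise it draws a social response with hazard
#' `s0 * k * (1 + gamma * P)` where `k` is the number of visible responding
#' neighbours and `P` the group's pre-stimulus polarization. Responders
#' steer straight to the port at `goalSpeedMult` times their base speed.
#'
#' @slot h0 private hazard scale, per frame.
#' @slot lambdaMM private hazard distance decay, mm.
#' @slot s0 social hazard scale per visible responding neighbour, per frame.
#' @slot gamma alignment gain slope (gain `= 1 + gamma * P`, increasing in P).
#' @slot goalSpeedMult speed multiplier after responding.
#' @export
setClass("DetectionModel",
  representation(h0 = "numeric", lambdaMM = "numeric", s0 = "numeric",
                 gamma = "numeric", goalSpeedMult = "numeric"))

setValidity("DetectionModel", function(object) {
  if (object@h0 < 0 || object@s0 < 0) return("hazard scales must be >= 0")
  if (object@gamma < 0) return("gamma must be >= 0 (gain increasing in polarization)")
  TRUE
})

#' Construct a DetectionModel
#'
#' @param h0 private hazard scale per frame.
#' @param lambdaMM private hazard distance decay, mm.
#' @param s0 social hazard scale per visible responding neighbour.
#' @param gamma alignment gain slope.
#' @param goalSpeedMult post-response speed multiplier.
#' @return A [DetectionModel-class].
#' @export
detectionModel <- function(h0 = 0.6, lambdaMM = 1000, s0 = 0.03,
                           gamma = 4, goalSpeedMult = 1.8) {
  new("DetectionModel", h0 = h0, lambdaMM = lambdaMM, s0 = s0,
      gamma = gamma, goalSpeedMult = goalSpeedMult)
}

# ---- show methods ---------------------------------------------------------

setMethod("show", "UnitSystem", function(object) {
  cat("UnitSystem:", object@fps, "fps,", object@pxPerMM, "px/mm\n")
})

setMethod("show", "ArenaGeometry", function(object) {
  cat(sprintf("ArenaGeometry (%s): %.1f x %.1f mm, %d ports\n",
              object@shape, object@lengthMM, object@widthMM,
              nrow(object@ports)))
})

setMethod("show", "TrajectorySet", function(object) {
  cat(sprintf("TrajectorySet '%s': %d fish x %d frames (%.1f s at %g fps)\n",
              object@groupId, length(object@fishIds), length(object@frames),
              length(object@frames) / object@units@fps, object@units@fps))
  miss <- mean(is.na(object@x))
  cat(sprintf("  missing entries: %.2f%%; body length %.1f mm (mean)\n",
              100 * miss, mean(object@bodyLengthMM)))
})

setMethod("show", "HeadingField", function(object) {
  cat(sprintf("HeadingField: %d frames x %d fish, %.1f%% valid (floor %g mm/frame)\n",
              nrow(object@hx), ncol(object@hx),
              100 * mean(object@valid, na.rm = TRUE), object@speedFloor))
})

setMethod("show", "VisionConfig", function(object) {
  cat(sprintf("VisionConfig: binocular +/-%g deg, full field %g deg, %d rays\n",
              object@binocularHalfAngle, object@totalField, as.integer(object@nRays)))
})

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d fish, zones %g/%g/%g mm, wAlign %g, noise %g deg\n",
              as.integer(object@nFish), object@rRep, object@rAli, object@rAtt,
              object@wAlign, object@headingNoiseSD))
})

setMethod("show", "DetectionModel", function(object) {
  cat(sprintf("DetectionModel: h0 %g, lambda %g mm, s0 %g, gamma %g, goal x%g\n",
              object@h0, object@lambdaMM, object@s0, object@gamma,
              object@goalSpeedMult))
})

# ---- accessors ------------------------------------------------------------

#' Number of fish in a trajectory set
#' @param traj a [TrajectorySet-class].
#' @return integer count of individuals.
#' @export
nFish <- function(traj) length(traj@fishIds)

#' Frame index of a trajectory set
#' @param traj a [TrajectorySet-class].
#' @return integer vector of frame numbers.
#' @export
frameIndex <- function(traj) traj@frames

#' Fish identifiers
#' @param traj a [TrajectorySet-class].
#' @return character vector.
#' @export
fishIds <- function(traj) traj@fishIds

#' Body lengths
#' @param traj a [TrajectorySet-class].
#' @return numeric vector, mm.
#' @export
bodyLengths <- function(traj) traj@bodyLengthMM

#' Positions of all fish at one frame
#' @param traj a [TrajectorySet-class].
#' @param frame a frame number present in `frameIndex(traj)`.
#' @return an `nFish x 2` matrix of mm coordinates (may contain `NA`).
#' @export
positionsAt <- function(traj, frame) {
  i <- match(frame, traj@frames)
  if (is.na(i)) stop("frame ", frame, " not in trajectory")
  cbind(x = traj@x[i, ], y = traj@y[i, ])
}
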