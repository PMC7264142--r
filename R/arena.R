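# Arena geometry, trajectory ingestion and smoothing.
#
# Coordinate convention: Cartesian mm, origin at the arena centre, long axis
# along x, y up. Image-style pixel input (y down) is flipped on ingestion.

stadiumParams <- function(arena) {
  r <- arena@widthMM / 2
  list(a = (arena@lengthMM - arena@widthMM) / 2, r = r,
       A = arena@lengthMM / 2, B = r)
}

#' Signed distance from points to the arena wall
#'
#' Positive inside, negative outside. Exact for the stadium; for the ellipse
#' a scaled-radial approximation adequate for wall-proximity logic.
#'
#' @param arena an [ArenaGeometry-class].
#' @param p an `n x 2` matrix of points (mm).
#' @return numeric vector of signed distances, mm.
#' @export
distanceToWall <- function(arena, p) {
  p <- rbind(p)
  sp <- stadiumParams(arena)
  if (arena@shape == "stadium") {
    qx <- pmin(pmax(p[, 1], -sp$a), sp$a)
    sp$r - sqrt((p[, 1] - qx)^2 + p[, 2]^2)
  } else {
    rho <- sqrt((p[, 1] / sp$A)^2 + (p[, 2] / sp$B)^2)
    (1 - rho) * min(sp$A, sp$B)
  }
}

#' Test whether points lie strictly inside the arena
#'
#' @param arena an [ArenaGeometry-class].
#' @param p an `n x 2` matrix of points (mm).
#' @return logical vector.
#' @examples
#' pointInArena(defaultArena(), cbind(0, 0))        # centre: TRUE
#' pointInArena(defaultArena(), cbind(1667.5, 0))   # 1 m outside: FALSE
#' @export
pointInArena <- function(arena, p) {
  distanceToWall(arena, p) > 0
}

#' Polygonal approximation of the arena boundary
#'
#' @param arena an [ArenaGeometry-class].
#' @param n number of vertices.
#' @return an `n x 2` matrix tracing the wall counter-clockwise.
#' @export
arenaBoundary <- function(arena, n = 512) {
  sp <- stadiumParams(arena)
  if (arena@shape == "ellipse") {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    return(cbind(sp$A * cos(th), sp$B * sin(th)))
  }
  # stadium: right cap, top edge, left cap, bottom edge
  nc <- max(8, floor(n / 2 - 2))
  th1 <- seq(-pi / 2, pi / 2, length.out = nc)
  th2 <- seq(pi / 2, 3 * pi / 2, length.out = nc)
  rbind(cbind(sp$a + sp$r * cos(th1), sp$r * sin(th1)),
        cbind(-sp$a + sp$r * cos(th2), sp$r * sin(th2)))
}

#' Arena area
#' @param arena an [ArenaGeometry-class].
#' @return area in mm^2.
#' @export
arenaArea <- function(arena) {
  sp <- stadiumParams(arena)
  if (arena@shape == "stadium") 2 * sp$a * arena@widthMM + pi * sp$r^2
  else pi * sp$A * sp$B
}

arenaDiagonal <- function(arena) {
  sqrt(arena@lengthMM^2 + arena@widthMM^2)
}

# place a port on the wall at the boundary point nearest (x, ySign * Inf)
portOnWall <- function(arena, x, ySign) {
  sp <- stadiumParams(arena)
  if (arena@shape == "stadium") {
    if (abs(x) <= sp$a) {
      y <- ySign * sp$r
      nrm <- c(0, -ySign)
    } else {
      cx <- sign(x) * sp$a
      y <- ySign * sqrt(max(0, sp$r^2 - (x - cx)^2))
      v <- c(x - cx, y)
      nrm <- -v / sqrt(sum(v^2))
    }
  } else {
    y <- ySign * sp$B * sqrt(max(0, 1 - (x / sp$A)^2))
    g <- c(x / sp$A^2, y / sp$B^2)
    nrm <- -g / sqrt(sum(g^2))
  }
  c(x = x, y = y, nx = nrm[1], ny = nrm[2])
}

#' Construct an arena
#'
#' @param lengthMM long axis, mm (default 1335).
#' @param widthMM short axis, mm (default 720).
#' @param shape `"stadium"` (default) or `"ellipse"`.
#' @param ports optional data.frame `id, x, y, nx, ny`; by default four ports
#'   are placed on the wall, two per long side at +/-25% of the long axis.
#' @return An [ArenaGeometry-class].
#' @examples
#' defaultArena()
#' @export
makeArena <- function(lengthMM = 1335, widthMM = 720,
                      shape = c("stadium", "ellipse"), ports = NULL) {
  shape <- match.arg(shape)
  tmp <- new("ArenaGeometry", lengthMM = lengthMM, widthMM = widthMM,
             shape = shape,
             ports = data.frame(id = 1L, x = 0, y = widthMM / 2,
                                nx = 0, ny = -1))
  if (is.null(ports)) {
    xs <- c(0.25, 0.25, -0.25, -0.25) * lengthMM
    ss <- c(1, -1, 1, -1)
    ports <- do.call(rbind, lapply(1:4, function(i) {
      p <- portOnWall(tmp, xs[i], ss[i])
      data.frame(id = i, x = p["x"], y = p["y"], nx = p["nx"], ny = p["ny"])
    }))
    rownames(ports) <- NULL
  }
  new("ArenaGeometry", lengthMM = lengthMM, widthMM = widthMM,
      shape = shape, ports = ports)
}

#' The study arena: 1335 x 720 mm oval with four wall ports
#' @param shape `"stadium"` (default) or `"ellipse"`.
#' @return An [ArenaGeometry-class].
#' @export
defaultArena <- function(shape = "stadium") makeArena(shape = shape)

#' Stimulus port position
#' @param arena an [ArenaGeometry-class].
#' @param portId port identifier.
#' @return length-2 numeric (x, y) in mm.
#' @export
portPosition <- function(arena, portId) {
  i <- match(portId, arena@ports$id)
  if (is.na(i)) stop("no port with id ", portId)
  c(arena@ports$x[i], arena@ports$y[i])
}

#' Read an arena / units configuration from YAML
#'
#' Expected keys: `arena: {length_mm, width_mm, shape, ports: [{id,x,y}]}`,
#' `units: {fps, px_per_mm}`. Ports given without normals are projected onto
#' the wall and get computed inward normals.
#'
#' @param path YAML file path.
#' @return list with elements `arena` ([ArenaGeometry-class]) and `units`
#'   ([UnitSystem-class]).
#' @export
readArenaConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  a <- cfg$arena
  shape <- if (is.null(a$shape)) "stadium" else a$shape
  ports <- NULL
  if (!is.null(a$ports)) {
    base <- makeArena(a$length_mm, a$width_mm, shape)
    ports <- do.call(rbind, lapply(a$ports, function(pp) {
      # YAML 1.1 parses a bare `y` key as boolean TRUE; accept both spellings
      py <- if (!is.null(pp[["y"]])) pp[["y"]] else pp[["TRUE"]]
      ySign <- if (py >= 0) 1 else -1
      p <- portOnWall(base, pp$x, ySign)
      data.frame(id = pp$id, x = p["x"], y = p["y"], nx = p["nx"], ny = p["ny"])
    }))
    rownames(ports) <- NULL
  }
  arena <- makeArena(a$length_mm, a$width_mm, shape, ports)
  u <- cfg$units
  units <- unitSystem(fps = if (is.null(u$fps)) 25 else u$fps,
                      pxPerMM = if (is.null(u$px_per_mm)) 2.7 else u$px_per_mm)
  list(arena = arena, units = units)
}

# ---- trajectory IO --------------------------------------------------------

#' Read multi-animal trajectories from an idTracker-style CSV
#'
#' Expects long-format columns `frame, id, x, y` (an optional `prob` column
#' is ignored). Pixel coordinates are converted to mm via `units@pxPerMM`,
#' with the image origin translated to the arena centre and the y axis
#' flipped to Cartesian (y up). Missing (fish, frame) entries become `NA`
#' and are never interpolated.
#'
#' @param path CSV path.
#' @param units a [UnitSystem-class].
#' @param arena an [ArenaGeometry-class].
#' @param sourceUnits `"px"` (convert and flip) or `"mm"` (already Cartesian
#'   mm, taken as-is).
#' @param originPx length-2 pixel coordinates of the arena centre in the
#'   image (default `c(0, 0)`).
#' @param groupId group identifier stored on the object.
#' @param bodyLengthMM per-fish body length in mm, recycled; default 27.
#' @return A [TrajectorySet-class]. Fish with more than 5% missing frames
#'   trigger a warning.
#' @export
readTrajectories <- function(path, units = unitSystem(), arena = defaultArena(),
                             sourceUnits = c("px", "mm"), originPx = c(0, 0),
                             groupId = "group1", bodyLengthMM = 27) {
  sourceUnits <- match.arg(sourceUnits)
  d <- read.csv(path)
  need <- c("frame", "id", "x", "y")
  if (!all(need %in% names(d)))
    stop("trajectory file must have columns frame, id, x, y")
  if (anyDuplicated(d[, c("frame", "id")]))
    stop("duplicate (fish, frame) rows in ", path)
  if (sourceUnits == "px") {
    d$x <- (d$x - originPx[1]) / units@pxPerMM
    d$y <- -(d$y - originPx[2]) / units@pxPerMM
  }
  ids <- sort(unique(as.character(d$id)))
  frames <- seq(min(d$frame), max(d$frame))
  xm <- matrix(NA_real_, length(frames), length(ids),
               dimnames = list(NULL, ids))
  ym <- xm
  ri <- match(d$frame, frames)
  ci <- match(as.character(d$id), ids)
  xm[cbind(ri, ci)] <- d$x
  ym[cbind(ri, ci)] <- d$y
  missFrac <- colMeans(is.na(xm))
  if (any(missFrac > 0.05))
    warning(sprintf("fish %s have >5%% missing frames",
                    paste(ids[missFrac > 0.05], collapse = ", ")))
  new("TrajectorySet", groupId = groupId, fishIds = ids,
      frames = as.integer(frames), x = xm, y = ym,
      bodyLengthMM = rep_len(bodyLengthMM, length(ids)),
      units = units, arena = arena, sourceUnits = sourceUnits)
}

#' Write trajectories as a tidy CSV with a JSON provenance sidecar
#'
#' Output is long-format `frame, id, x, y` in Cartesian mm; a `<path>.json`
#' sidecar records units and arena settings.
#'
#' @param traj a [TrajectorySet-class].
#' @param path output CSV path.
#' @param sidecar write the JSON sidecar? Default `TRUE`.
#' @return `path`, invisibly.
#' @export
writeTrajectories <- function(traj, path, sidecar = TRUE) {
  nf <- length(traj@frames)
  d <- data.frame(frame = rep(traj@frames, times = nFish(traj)),
                  id = rep(traj@fishIds, each = nf),
                  x = as.vector(traj@x), y = as.vector(traj@y))
  d <- d[!is.na(d$x), ]
  d$x <- sprintf("%.9f", d$x)
  d$y <- sprintf("%.9f", d$y)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  if (sidecar) {
    meta <- list(group_id = traj@groupId, units = "mm",
                 fps = traj@units@fps, px_per_mm = traj@units@pxPerMM,
                 arena = list(length_mm = traj@arena@lengthMM,
                              width_mm = traj@arena@widthMM,
                              shape = traj@arena@shape),
                 body_length_mm = traj@bodyLengthMM,
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}

# ---- smoothing ------------------------------------------------------------

#' Savitzky-Golay trajectory smoothing
#'
#' Polynomial least-squares smoothing applied independently per fish and per
#' coordinate. The default window of 13 frames spans ~0.5 s at 25 fps with a
#' cubic polynomial, so any trajectory that is locally cubic in time passes
#' through unchanged. Contiguous tracked runs shorter than the window are
#' passed through unsmoothed.
#'
#' @param traj a [TrajectorySet-class].
#' @param windowFrames odd window length, frames (default 13).
#' @param degree polynomial degree (default 3).
#' @return A smoothed [TrajectorySet-class]; runs too short to smooth are
#'   listed in `attr(, "unsmoothedRuns")`.
#' @export
smoothSavGol <- function(traj, windowFrames = 13, degree = 3) {
  if (windowFrames %% 2 == 0)
    stop("windowFrames must be odd; use ", windowFrames + 1, " or ",
         windowFrames - 1)
  if (windowFrames <= degree)
    stop("windowFrames must exceed the polynomial degree")
  skipped <- list()
  smooth1 <- function(v, fish) {
    ok <- !is.na(v)
    r <- rle(ok)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (k in seq_along(r$values)) {
      if (!r$values[k]) next
      idx <- starts[k]:ends[k]
      if (length(idx) < windowFrames) {
        skipped[[length(skipped) + 1]] <<- c(fish = fish, start = starts[k],
                                             len = length(idx))
        next
      }
      v[idx] <- signal::sgolayfilt(v[idx], p = degree, n = windowFrames)
    }
    v
  }
  for (j in seq_len(nFish(traj))) {
    traj@x[, j] <- smooth1(traj@x[, j], traj@fishIds[j])
    traj@y[, j] <- smooth1(traj@y[, j], traj@fishIds[j])
  }
  attr(traj, "unsmoothedRuns") <- skipped
  attr(traj, "smoothing") <- c(window = windowFrames, degree = degree)
  traj
}

# internal: build a TrajectorySet from matrices (used by the simulator & tests)
makeTrajectorySet <- function(x, y, arena = defaultArena(),
                              units = unitSystem(), groupId = "sim",
                              bodyLengthMM = 27, frames = NULL,
                              fishIds = NULL) {
  n <- ncol(x)
  if (is.null(frames)) frames <- seq_len(nrow(x))
  if (is.null(fishIds)) fishIds <- sprintf("f%d", seq_len(n))
  colnames(x) <- fishIds
  colnames(y) <- fishIds
  new("TrajectorySet", groupId = groupId, fishIds = fishIds,
      frames = as.integer(frames), x = x, y = y,
      bodyLengthMM = rep_len(bodyLengthMM, n), units = units,
      arena = arena, sourceUnits = "mm")
}
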