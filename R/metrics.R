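# Individual- and group-level position/movement parameters.
#
# Six individual parameters: swimming speed, distance to stimulus, bearing
# to stimulus, proportion of time on the convex-hull edge, distance to the
# group centroid, visual occlusion (the last from the vision module).
# Five group parameters: convex hull area, bearing of the group heading to
# the stimulus, distance of the centroid to the stimulus, centroid speed,
# polarization. Window summaries use the median over the 13 frames (0.5 s)
# before stimulus onset, except the hull-edge proportion which is a
# proportion of window frames.

degPerRad <- 180 / pi

#' Headings from displacement
#'
#' Heading at frame t is the unit central-difference displacement
#' `(p[t+1] - p[t-1]) / 2`; one-sided differences are used at run ends.
#' Frames where the speed falls below `speedFloor` (or where positions are
#' missing) carry no direction and are flagged invalid.
#'
#' @param traj a (smoothed) [TrajectorySet-class].
#' @param speedFloor mm/frame below which direction is undefined (default 0.3).
#' @return A [HeadingField-class].
#' @export
headingsFromDisplacement <- function(traj, speedFloor = 0.3) {
  nf <- length(traj@frames)
  n <- nFish(traj)
  vx <- matrix(NA_real_, nf, n)
  vy <- vx
  for (j in seq_len(n)) {
    x <- traj@x[, j]; y <- traj@y[, j]
    dx <- rep(NA_real_, nf); dy <- dx
    if (nf >= 3) {
      dx[2:(nf - 1)] <- (x[3:nf] - x[1:(nf - 2)]) / 2
      dy[2:(nf - 1)] <- (y[3:nf] - y[1:(nf - 2)]) / 2
    }
    if (nf >= 2) {
      dx[1] <- x[2] - x[1]; dy[1] <- y[2] - y[1]
      dx[nf] <- x[nf] - x[nf - 1]; dy[nf] <- y[nf] - y[nf - 1]
    }
    # interior frames adjacent to a gap: fall back to one-sided differences
    bad <- is.na(dx) & !is.na(x)
    if (any(bad)) {
      i <- which(bad)
      fwd <- i[i < nf & !is.na(x[pmin(i + 1, nf)])]
      dx[fwd] <- x[fwd + 1] - x[fwd]; dy[fwd] <- y[fwd + 1] - y[fwd]
      still <- i[is.na(dx[i])]
      bwd <- still[still > 1 & !is.na(x[pmax(still - 1, 1)])]
      dx[bwd] <- x[bwd] - x[bwd - 1]; dy[bwd] <- y[bwd] - y[bwd - 1]
    }
    vx[, j] <- dx; vy[, j] <- dy
  }
  sp <- sqrt(vx^2 + vy^2)
  valid <- !is.na(sp) & sp >= speedFloor
  hx <- ifelse(valid, vx / sp, NA_real_)
  hy <- ifelse(valid, vy / sp, NA_real_)
  new("HeadingField", hx = hx, hy = hy, speed = sp,
      valid = valid & !is.na(valid), speedFloor = speedFloor)
}

#' Group polarization
#'
#' The standard order parameter `| sum(u_i) | / n` over unit headings:
#' 0 means complete directional cancellation, 1 perfect alignment.
#'
#' @param headings an `n x 2` matrix of unit heading vectors (rows with `NA`
#'   are dropped).
#' @return polarization in `[0, 1]`; `NA` (with a warning) when fewer than
#'   two valid headings remain.
#' @examples
#' polarization(matrix(rep(c(1, 0), each = 8), ncol = 2))  # 1
#' polarization(rbind(c(1, 0), c(-1, 0)))                  # 0
#' @export
polarization <- function(headings) {
  h <- rbind(headings)
  h <- h[stats::complete.cases(h), , drop = FALSE]
  if (nrow(h) < 2) {
    warning("fewer than 2 valid headings; polarization undefined")
    return(NA_real_)
  }
  sqrt(sum(colSums(h)^2)) / nrow(h)
}

#' Bearing to a target
#'
#' Unsigned angle in degrees, in `[0, 180]`, between a heading and the line
#' from `position` to `target`; 0 means facing the target.
#'
#' @param position length-2 point, mm.
#' @param heading length-2 unit vector.
#' @param target length-2 point, mm.
#' @return bearing in degrees.
#' @export
bearingToTarget <- function(position, heading, target) {
  v <- target - position
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) stop("target coincides with position; bearing undefined")
  nh <- sqrt(sum(heading^2))
  if (!is.finite(nh) || nh < 1e-12) stop("invalid heading")
  acos(pmin(1, pmax(-1, sum(heading * v) / (nh * nv)))) * degPerRad
}

# vectorised bearings for many fish at once; NA-safe
bearingsToTarget <- function(pos, hx, hy, target) {
  vx <- target[1] - pos[, 1]
  vy <- target[2] - pos[, 2]
  nv <- sqrt(vx^2 + vy^2)
  acos(pmin(1, pmax(-1, (hx * vx + hy * vy) / nv))) * degPerRad
}

#' Convex hull area and edge membership
#'
#' @param p an `n x 2` matrix of positions.
#' @param tol distance tolerance (mm) for lying on the hull boundary.
#' @return list with `area` (mm^2, shoelace) and `onEdge` (logical per row;
#'   collinear configurations flag every point).
#' @export
convexHullInfo <- function(p, tol = 1e-6) {
  n <- nrow(p)
  h <- grDevices::chull(p)
  hp <- p[h, , drop = FALSE]
  m <- nrow(hp)
  area <- if (m < 3) 0 else
    abs(sum(hp[, 1] * hp[c(2:m, 1), 2] - hp[c(2:m, 1), 1] * hp[, 2])) / 2
  onEdge <- rep(FALSE, n)
  onEdge[h] <- TRUE
  # points lying on a hull edge segment (incl. all points of a collinear set)
  if (m >= 2 && any(!onEdge)) {
    for (i in which(!onEdge)) {
      for (k in seq_len(max(m - 1, 1))) {
        a <- hp[k, ]; b <- hp[if (k == m) 1 else k + 1, ]
        if (m == 2 && k == 2) break
        ab <- b - a
        L2 <- sum(ab^2)
        t <- if (L2 < 1e-18) 0 else sum((p[i, ] - a) * ab) / L2
        t <- min(1, max(0, t))
        q <- a + t * ab
        if (sqrt(sum((p[i, ] - q)^2)) <= tol) { onEdge[i] <- TRUE; break }
      }
    }
  }
  list(area = area, onEdge = onEdge)
}

#' Group metrics at a single frame
#'
#' Computes the group-level parameters at frame `t`: convex hull area,
#' centroid position and speed (central-difference displacement of the
#' centroid), group heading (direction of the vector sum of unit headings),
#' bearing of the group heading to the stimulus, polarization, and per-fish
#' hull-edge membership.
#'
#' @param traj a [TrajectorySet-class].
#' @param headings a [HeadingField-class] for `traj`.
#' @param stimulus length-2 stimulus position, mm.
#' @param t frame number.
#' @return list of scalars plus `onEdge` (logical per fish); `NULL` if any
#'   fish is untracked at `t`.
#' @export
groupMetricsFrame <- function(traj, headings, stimulus, t) {
  i <- match(t, traj@frames)
  if (is.na(i)) return(NULL)
  p <- cbind(traj@x[i, ], traj@y[i, ])
  if (anyNA(p)) return(NULL)
  hull <- convexHullInfo(p)
  centroid <- colMeans(p)
  nf <- length(traj@frames)
  i0 <- max(1, i - 1); i1 <- min(nf, i + 1)
  c0 <- c(mean(traj@x[i0, ]), mean(traj@y[i0, ]))
  c1 <- c(mean(traj@x[i1, ]), mean(traj@y[i1, ]))
  centroidSpeed <- sqrt(sum((c1 - c0)^2)) / (i1 - i0)
  hx <- headings@hx[i, ]; hy <- headings@hy[i, ]
  ok <- headings@valid[i, ]
  pol <- polarization(cbind(hx[ok], hy[ok]))
  gh <- c(sum(hx[ok]), sum(hy[ok]))
  ghn <- sqrt(sum(gh^2))
  groupBearing <- if (ghn > 1e-9)
    bearingToTarget(centroid, gh / ghn, stimulus) else NA_real_
  list(hullArea = hull$area,
       centroid = centroid,
       centroidSpeed = centroidSpeed,
       centroidDistStimulus = sqrt(sum((stimulus - centroid)^2)),
       groupBearingStimulus = groupBearing,
       polarization = pol,
       onEdge = hull$onEdge)
}

#' Median summary over a pre-stimulus window
#'
#' Summarises a per-frame series over the `windowFrames` frames immediately
#' before `onset` (frames `onset - windowFrames` to `onset - 1`), by default
#' with the median to blunt outliers.
#'
#' @param series numeric vector indexed by `frames`.
#' @param frames integer frame index aligned with `series`.
#' @param onset stimulus onset frame.
#' @param windowFrames window length (default 13, i.e. 0.5 s at 25 fps).
#' @param stat summary function (default [stats::median]).
#' @return the summary value, or `NA` if the window has missing frames.
#' @export
windowSummary <- function(series, frames, onset, windowFrames = 13,
                          stat = stats::median) {
  want <- (onset - windowFrames):(onset - 1)
  i <- match(want, frames)
  if (anyNA(i)) return(NA_real_)
  v <- series[i]
  if (anyNA(v)) return(NA_real_)
  stat(v)
}

#' Relative (group-normalised) individual values
#'
#' Divides each fish's per-window summary by the group mean of those
#' summaries, so relative values average to 1 within a group. This is the
#' normalisation used for all individual parameters, including the
#' hull-edge proportion (divided by the group mean proportion).
#'
#' @param values numeric vector, one value per fish.
#' @return relative values; `NA` with a warning if the group mean is zero.
#' @export
relativizeGroup <- function(values) {
  m <- mean(values, na.rm = TRUE)
  if (!is.finite(m) || abs(m) < 1e-12) {
    warning("group mean is zero; relative values undefined")
    return(rep(NA_real_, length(values)))
  }
  values / m
}

#' Dispersion of individual bearings to the stimulus
#'
#' Sample standard deviation and minimum of the unsigned bearings (degrees
#' in `[0, 180]`, which live on a line segment, so the linear SD applies).
#' High polarization concentrates bearings (low SD) and lifts the minimum.
#'
#' @param bearings numeric vector of per-fish bearings, degrees.
#' @return list with `sd` and `min`.
#' @export
bearingDispersion <- function(bearings) {
  b <- bearings[!is.na(bearings)]
  if (length(b) < 2) stop("need at least 2 valid bearings")
  list(sd = stats::sd(b), min = min(b))
}

#' Heading difference to the nearest neighbour
#'
#' For each fish at frame `t`, the unsigned angle (degrees) between its
#' heading and the heading of its Euclidean nearest neighbour. Distance ties
#' resolve to the lower fish index.
#'
#' @param traj a [TrajectorySet-class].
#' @param headings a [HeadingField-class].
#' @param t frame number.
#' @return numeric vector, one entry per fish (`NA` where either heading is
#'   invalid or positions are missing).
#' @export
nnHeadingDifference <- function(traj, headings, t) {
  i <- match(t, traj@frames)
  if (is.na(i)) return(rep(NA_real_, nFish(traj)))
  p <- cbind(traj@x[i, ], traj@y[i, ])
  n <- nrow(p)
  out <- rep(NA_real_, n)
  for (f in seq_len(n)) {
    if (is.na(p[f, 1]) || !headings@valid[i, f]) next
    d <- sqrt((p[, 1] - p[f, 1])^2 + (p[, 2] - p[f, 2])^2)
    d[f] <- Inf
    d[is.na(d)] <- Inf
    nn <- which.min(d)   # which.min takes the first (lowest index) on ties
    if (!is.finite(d[nn]) || !headings@valid[i, nn]) next
    dotp <- headings@hx[i, f] * headings@hx[i, nn] +
            headings@hy[i, f] * headings@hy[i, nn]
    out[f] <- acos(pmin(1, pmax(-1, dotp))) * degPerRad
  }
  out
}

#' Mean nearest-neighbour heading difference over a frame range
#'
#' @param traj a [TrajectorySet-class].
#' @param headings a [HeadingField-class].
#' @param frames frame numbers to average over.
#' @return per-fish mean difference in degrees.
#' @export
meanNNHeadingDifference <- function(traj, headings, frames) {
  acc <- matrix(NA_real_, length(frames), nFish(traj))
  for (k in seq_along(frames))
    acc[k, ] <- nnHeadingDifference(traj, headings, frames[k])
  colMeans(acc, na.rm = TRUE)
}

#' Per-presentation window metrics
#'
#' Summarises the 0.5-s pre-stimulus window of each presentation into the
#' individual and group parameter tables used by the statistical layer.
#' Individual parameters (speed, distance and bearing to the stimulus,
#' hull-edge proportion, distance to centroid, and — when `vision` is
#' supplied — visual occlusion) are medians over the window (the hull-edge
#' value is a proportion of frames) and are also returned relative to the
#' group mean. Group parameters are medians of the per-frame group metrics,
#' plus the bearing SD and minimum bearing across fish.
#'
#' @param traj a smoothed [TrajectorySet-class].
#' @param headings a [HeadingField-class].
#' @param presentations data.frame with columns `presentationId`,
#'   `onsetFrame`, `portId` (e.g. from [runPresentationProtocol()]).
#' @param windowFrames pre-stimulus window length (default 13).
#' @param vision optional [VisionConfig-class]; when supplied the occlusion
#'   index is computed per fish per frame (slower).
#' @return list of two data.frames, `individual` (one row per fish per
#'   presentation) and `group` (one row per presentation). Presentations
#'   whose window has tracking gaps yield `NA` rows.
#' @export
presentationMetrics <- function(traj, headings, presentations,
                                windowFrames = 13, vision = NULL) {
  indiv <- list()
  grp <- list()
  n <- nFish(traj)
  for (r in seq_len(nrow(presentations))) {
    pid <- presentations$presentationId[r]
    onset <- presentations$onsetFrame[r]
    stim <- portPosition(traj@arena, presentations$portId[r])
    want <- (onset - windowFrames):(onset - 1)
    ii <- match(want, traj@frames)
    gap <- anyNA(ii) || anyNA(traj@x[ii, ])
    if (gap) {
      grp[[r]] <- data.frame(presentationId = pid, hullArea = NA_real_,
                             groupBearingStimulus = NA_real_,
                             centroidDistStimulus = NA_real_,
                             centroidSpeed = NA_real_, polarization = NA_real_,
                             bearingSD = NA_real_, minBearing = NA_real_)
      next
    }
    speedW <- matrix(NA_real_, windowFrames, n)
    distW <- speedW; bearW <- speedW; centW <- speedW; occW <- speedW
    edgeW <- matrix(NA, windowFrames, n)
    gm <- matrix(NA_real_, windowFrames, 5,
                 dimnames = list(NULL, c("hullArea", "groupBearingStimulus",
                                         "centroidDistStimulus",
                                         "centroidSpeed", "polarization")))
    for (k in seq_along(want)) {
      t <- want[k]; i <- ii[k]
      g <- groupMetricsFrame(traj, headings, stim, t)
      gm[k, ] <- c(g$hullArea, g$groupBearingStimulus, g$centroidDistStimulus,
                   g$centroidSpeed, g$polarization)
      edgeW[k, ] <- g$onEdge
      p <- cbind(traj@x[i, ], traj@y[i, ])
      speedW[k, ] <- headings@speed[i, ]
      distW[k, ] <- sqrt((stim[1] - p[, 1])^2 + (stim[2] - p[, 2])^2)
      bearW[k, ] <- bearingsToTarget(p, headings@hx[i, ], headings@hy[i, ], stim)
      centW[k, ] <- sqrt((p[, 1] - g$centroid[1])^2 + (p[, 2] - g$centroid[2])^2)
      if (!is.null(vision)) {
        st <- fishStates(traj, headings, t)
        occW[k, ] <- vapply(seq_len(n), function(f)
          occlusionIndex(f, st, traj@arena, vision), numeric(1))
      }
    }
    med <- function(m) apply(m, 2, stats::median, na.rm = TRUE)
    bmed <- med(bearW)
    bd <- bearingDispersion(bmed)
    id <- data.frame(presentationId = pid, fishId = traj@fishIds,
                     speed = med(speedW), distStimulus = med(distW),
                     bearingStimulus = bmed,
                     propHullEdge = colMeans(edgeW),
                     distCentroid = med(centW),
                     occlusion = if (is.null(vision)) NA_real_ else med(occW),
                     bodyLengthMM = traj@bodyLengthMM)
    for (cc in c("speed", "distStimulus", "bearingStimulus", "propHullEdge",
                 "distCentroid", "occlusion", "bodyLengthMM")) {
      id[[paste0("rel_", cc)]] <-
        if (all(is.na(id[[cc]]))) NA_real_ else relativizeGroup(id[[cc]])
    }
    indiv[[r]] <- id
    grp[[r]] <- data.frame(presentationId = pid,
                           hullArea = stats::median(gm[, "hullArea"]),
                           groupBearingStimulus = stats::median(gm[, "groupBearingStimulus"]),
                           centroidDistStimulus = stats::median(gm[, "centroidDistStimulus"]),
                           centroidSpeed = stats::median(gm[, "centroidSpeed"]),
                           polarization = stats::median(gm[, "polarization"]),
                           bearingSD = bd$sd, minBearing = bd$min)
  }
  list(individual = do.call(rbind, indiv), group = do.call(rbind, grp))
}
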