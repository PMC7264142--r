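# 2D ray-cast visual fields with neighbour-body occlusion.
#
# Each fish is a cyclopean viewer: the eye sits eyeOffset body lengths ahead
# of the tracked centre-of-mass along the heading. Rays fan across either
# the binocular sector or the full field (binocular + monocular), stopping
# at the first of: a neighbour's body ellipse, the arena wall, or maxRange.
# The visible region is the star-shaped polygon of ray endpoints.

#' Fish states at one frame
#'
#' Collects position, unit heading and body length per fish at frame `t`,
#' the per-frame input of the vision functions.
#'
#' @param traj a [TrajectorySet-class].
#' @param headings a [HeadingField-class].
#' @param t frame number.
#' @return data.frame with columns `fish, x, y, hx, hy, bl, valid`.
#' @export
fishStates <- function(traj, headings, t) {
  i <- match(t, traj@frames)
  if (is.na(i)) stop("frame ", t, " not in trajectory")
  data.frame(fish = seq_len(nFish(traj)), x = traj@x[i, ], y = traj@y[i, ],
             hx = headings@hx[i, ], hy = headings@hy[i, ],
             bl = traj@bodyLengthMM,
             valid = headings@valid[i, ] & !is.na(traj@x[i, ]),
             row.names = NULL)
}

fieldHalfAngle <- function(config, field) {
  switch(field,
         binocular = config@binocularHalfAngle,
         full = config@totalField / 2,
         stop("field must be 'binocular' or 'full'")) * pi / 180
}

# distance along rays (origin e, unit directions dx/dy) to the arena wall;
# e must be inside the arena (convex: unique exit per ray)
rayWallDistance <- function(arena, e, dx, dy) {
  sp <- stadiumParams(arena)
  n <- length(dx)
  tb <- rep(Inf, n)
  if (arena@shape == "stadium") {
    for (s in c(1, -1)) {           # flat edges y = +/- r
      dok <- s * dy > 1e-12
      t <- (s * sp$r - e[2]) / dy
      hx <- e[1] + t * dx
      ok <- dok & t > 0 & abs(hx) <= sp$a
      tb[ok] <- pmin(tb[ok], t[ok])
    }
    for (s in c(1, -1)) {           # cap circles centred (+/- a, 0)
      cx <- s * sp$a
      ex <- e[1] - cx; ey <- e[2]
      b <- ex * dx + ey * dy
      cc <- ex^2 + ey^2 - sp$r^2
      disc <- b^2 - cc
      sq <- sqrt(pmax(disc, 0))
      for (root in list(-b - sq, -b + sq)) {
        hx <- e[1] + root * dx
        ok <- disc >= 0 & root > 1e-9 & s * hx >= s * cx - 1e-9
        tb[ok] <- pmin(tb[ok], root[ok])
      }
    }
  } else {
    ex <- e[1] / sp$A; ey <- e[2] / sp$B
    ddx <- dx / sp$A; ddy <- dy / sp$B
    a2 <- ddx^2 + ddy^2
    b <- ex * ddx + ey * ddy
    cc <- ex^2 + ey^2 - 1
    disc <- pmax(b^2 - a2 * cc, 0)
    t <- (-b + sqrt(disc)) / a2
    tb <- ifelse(t > 0, t, Inf)
  }
  tb
}

# distance along rays to a body ellipse (centre c, heading angle phi,
# semi-axes sa >= sb); Inf where missed
rayEllipseDistance <- function(e, dx, dy, cx, cy, phi, sa, sb) {
  cp <- cos(phi); sp_ <- sin(phi)
  rx <- e[1] - cx; ry <- e[2] - cy
  px <- (cp * rx + sp_ * ry) / sa
  py <- (-sp_ * rx + cp * ry) / sb
  qx <- (cp * dx + sp_ * dy) / sa
  qy <- (-sp_ * dx + cp * dy) / sb
  a2 <- qx^2 + qy^2
  b <- px * qx + py * qy
  cc <- px^2 + py^2 - 1
  disc <- b^2 - a2 * cc
  sq <- sqrt(pmax(disc, 0))
  t1 <- (-b - sq) / a2
  t2 <- (-b + sq) / a2
  t <- ifelse(t1 > 1e-9, t1, ifelse(t2 > 1e-9, t2, Inf))
  ifelse(disc >= 0, t, Inf)
}

# is the open segment from e to q blocked by any listed neighbour body?
segmentOccluded <- function(e, q, states, exclude, aspect) {
  v <- q - e
  L <- sqrt(sum(v^2))
  if (L < 1e-12) return(FALSE)
  d <- v / L
  for (j in seq_len(nrow(states))) {
    if (j %in% exclude || is.na(states$x[j])) next
    phi <- atan2(states$hy[j], states$hx[j])
    if (is.na(phi)) phi <- 0
    t <- rayEllipseDistance(e, d[1], d[2], states$x[j], states$y[j], phi,
                            0.5 * states$bl[j], 0.5 * aspect * states$bl[j])
    if (t < L - 1e-6) return(TRUE)
  }
  FALSE
}

eyePoint <- function(arena, st, config) {
  e <- c(st$x + config@eyeOffset * st$bl * st$hx,
         st$y + config@eyeOffset * st$bl * st$hy)
  d <- distanceToWall(arena, rbind(e))
  if (d <= 1) {
    # pull the eye just inside the wall
    bnd <- arenaBoundary(arena, 1024)
    k <- which.min((bnd[, 1] - e[1])^2 + (bnd[, 2] - e[2])^2)
    inward <- -c(bnd[k, 1], bnd[k, 2])
    inward <- inward / max(sqrt(sum(inward^2)), 1e-9)
    e <- e + (2 - d) * inward
  }
  e
}

#' Cast a visual field for one fish
#'
#' Shoots `nRays` rays from the eye point across the chosen angular field
#' centred on the heading; each ray terminates at the nearest of the arena
#' wall, the first neighbour-body ellipse, or `maxRange`. Returns the
#' star-shaped visible polygon and summary fractions.
#'
#' @param focal index (row of `states`) of the focal fish.
#' @param states a [fishStates()] data.frame.
#' @param arena an [ArenaGeometry-class].
#' @param config a [VisionConfig-class].
#' @param field `"binocular"` or `"full"`.
#' @param stimulus optional length-2 point; if given, `stimulusVisible` is
#'   evaluated (inside the field angle, within range, unoccluded).
#' @return list with `polygon` (matrix of vertices, eye point included when
#'   the field is narrower than 360 degrees), `coverageFraction`,
#'   `blockedRayFraction` and `stimulusVisible` (`NA` if no stimulus given);
#'   `NULL` if the focal fish has no valid heading.
#' @export
castField <- function(focal, states, arena, config,
                      field = c("binocular", "full"), stimulus = NULL) {
  field <- match.arg(field)
  st <- states[focal, ]
  if (!isTRUE(st$valid)) return(NULL)
  half <- fieldHalfAngle(config, field)
  maxR <- if (is.na(config@maxRange)) arenaDiagonal(arena) else config@maxRange
  e <- eyePoint(arena, st, config)
  th0 <- atan2(st$hy, st$hx)
  nr <- as.integer(config@nRays)
  full360 <- abs(2 * half - 2 * pi) < 1e-9
  ang <- if (full360) th0 + seq(0, 2 * pi, length.out = nr + 1)[-(nr + 1)]
         else seq(th0 - half, th0 + half, length.out = nr)
  dx <- cos(ang); dy <- sin(ang)
  tW <- rayWallDistance(arena, e, dx, dy)
  tFin <- pmin(tW, maxR)
  blocked <- rep(FALSE, nr)
  others <- setdiff(which(states$valid | !is.na(states$x)), focal)
  for (j in others) {
    if (is.na(states$x[j])) next
    phi <- atan2(states$hy[j], states$hx[j])
    if (is.na(phi)) phi <- 0
    tE <- rayEllipseDistance(e, dx, dy, states$x[j], states$y[j], phi,
                             0.5 * states$bl[j], 0.5 * config@aspectRatio * states$bl[j])
    hit <- tE < tFin
    blocked[hit] <- TRUE
    tFin[hit] <- tE[hit]
  }
  pts <- cbind(e[1] + tFin * dx, e[2] + tFin * dy)
  poly <- if (full360) pts else rbind(e, pts)
  m <- nrow(poly)
  area <- abs(sum(poly[, 1] * poly[c(2:m, 1), 2] -
                  poly[c(2:m, 1), 1] * poly[, 2])) / 2
  sv <- NA
  if (!is.null(stimulus)) {
    v <- stimulus - e
    L <- sqrt(sum(v^2))
    inAngle <- {
      a <- atan2(v[2], v[1])
      da <- atan2(sin(a - th0), cos(a - th0))
      abs(da) <= half + 1e-9
    }
    sv <- inAngle && L <= maxR &&
      !segmentOccluded(e, stimulus, states, focal, config@aspectRatio)
  }
  list(polygon = poly, coverageFraction = area / arenaArea(arena),
       blockedRayFraction = mean(blocked), stimulusVisible = sv,
       eye = e)
}

#' Can any group member see the stimulus?
#'
#' @param states a [fishStates()] data.frame.
#' @param stimulus length-2 point, mm.
#' @param arena an [ArenaGeometry-class].
#' @param config a [VisionConfig-class].
#' @param field `"binocular"` or `"full"`.
#' @return list with `any` (logical) and `seeing` (indices of fish whose
#'   field contains the stimulus unoccluded).
#' @export
stimulusVisibleAny <- function(states, stimulus, arena, config,
                               field = c("binocular", "full")) {
  field <- match.arg(field)
  half <- fieldHalfAngle(config, field)
  maxR <- if (is.na(config@maxRange)) arenaDiagonal(arena) else config@maxRange
  seeing <- integer(0)
  for (f in which(states$valid)) {
    st <- states[f, ]
    e <- eyePoint(arena, st, config)
    v <- stimulus - e
    L <- sqrt(sum(v^2))
    if (L > maxR) next
    th0 <- atan2(st$hy, st$hx)
    a <- atan2(v[2], v[1])
    da <- atan2(sin(a - th0), cos(a - th0))
    if (abs(da) > half + 1e-9) next
    if (!segmentOccluded(e, stimulus, states, f, config@aspectRatio))
      seeing <- c(seeing, f)
  }
  list(any = length(seeing) > 0, seeing = seeing)
}

#' Collective visual coverage of the arena
#'
#' Fraction of the arena area covered by the union of the group's visible
#' polygons, evaluated on a regular grid of points inside the arena
#' (point-in-polygon via `mgcv::in.out`).
#'
#' @param states a [fishStates()] data.frame.
#' @param arena an [ArenaGeometry-class].
#' @param config a [VisionConfig-class].
#' @param field `"binocular"` or `"full"`.
#' @param gridStep grid spacing in mm (default 10).
#' @return covered area fraction in `[0, 1]`.
#' @export
collectiveCoverage <- function(states, arena, config,
                               field = c("binocular", "full"),
                               gridStep = 10) {
  field <- match.arg(field)
  gx <- seq(-arena@lengthMM / 2 + gridStep / 2, arena@lengthMM / 2, by = gridStep)
  gy <- seq(-arena@widthMM / 2 + gridStep / 2, arena@widthMM / 2, by = gridStep)
  g <- as.matrix(expand.grid(x = gx, y = gy))
  g <- g[pointInArena(arena, g), , drop = FALSE]
  covered <- rep(FALSE, nrow(g))
  for (f in which(states$valid)) {
    cf <- castField(f, states, arena, config, field)
    if (is.null(cf)) next
    todo <- which(!covered)
    if (length(todo) == 0) break
    covered[todo] <- mgcv::in.out(cf$polygon, g[todo, , drop = FALSE])
  }
  mean(covered)
}

#' Visual occlusion index
#'
#' Fraction of the focal fish's full visual field intercepted by neighbour
#' bodies before the wall or the maximum range — an estimate of visual
#' interference by near neighbours. 0 for an isolated fish; approaches 1
#' when the focal fish is ringed by close neighbours.
#'
#' @param focal focal fish index.
#' @param states a [fishStates()] data.frame.
#' @param arena an [ArenaGeometry-class].
#' @param config a [VisionConfig-class].
#' @return blocked-ray fraction in `[0, 1]` (`NA` if the focal heading is
#'   invalid).
#' @export
occlusionIndex <- function(focal, states, arena, config) {
  cf <- castField(focal, states, arena, config, "full")
  if (is.null(cf)) return(NA_real_)
  cf$blockedRayFraction
}
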