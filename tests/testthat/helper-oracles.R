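# Independent brute-force oracles used to check the implementation by a
# different route. These deliberately avoid the package's own geometry
# helpers.

# dense polygonal approximation of the arena wall (stadium or ellipse),
# built directly from the parametric definition
oracleBoundary <- function(lengthMM, widthMM, shape, n = 4096) {
  r <- widthMM / 2
  a <- (lengthMM - widthMM) / 2
  if (shape == "ellipse") {
    th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
    return(cbind((lengthMM / 2) * cos(th), r * sin(th)))
  }
  nc <- floor(n / 2)
  th1 <- seq(-pi / 2, pi / 2, length.out = nc)
  th2 <- seq(pi / 2, 3 * pi / 2, length.out = nc)
  rbind(cbind(a + r * cos(th1), r * sin(th1)),
        cbind(-a + r * cos(th2), r * sin(th2)))
}

# even-odd ray-crossing point-in-polygon test (scalar, textbook form)
oraclePointInPolygon <- function(poly, px, py) {
  n <- nrow(poly)
  j <- n
  inside <- FALSE
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    if ((yi > py) != (yj > py) &&
        px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- !inside
    j <- i
  }
  inside
}

# does the open segment p -> q cross the ellipse (centre c, angle phi,
# semi-axes sa, sb)? quadratic in the ellipse frame
oracleSegmentHitsEllipse <- function(p, q, cx, cy, phi, sa, sb) {
  R <- rbind(c(cos(phi), sin(phi)), c(-sin(phi), cos(phi)))
  P <- R %*% (p - c(cx, cy)) / c(sa, sb)
  Q <- R %*% (q - c(cx, cy)) / c(sa, sb)
  D <- Q - P
  a <- sum(D^2)
  b <- sum(P * D)
  cc <- sum(P^2) - 1
  if (cc < 0) return(TRUE)
  disc <- b^2 - a * cc
  if (disc < 0 || a < 1e-14) return(FALSE)
  sq <- sqrt(disc)
  t1 <- (-b - sq) / a; t2 <- (-b + sq) / a
  (t1 > 1e-6 && t1 < 1 - 1e-6) || (t2 > 1e-6 && t2 < 1 - 1e-6)
}

# grid-based visibility oracle for one focal fish: classify every grid
# point inside the arena as visible/not by direct segment tests (the arena
# is convex, so the wall never blocks interior segments)
oracleCoverage <- function(focal, states, arena, config, field,
                           gridStep = 2) {
  halfDeg <- if (field == "binocular") config@binocularHalfAngle
             else config@totalField / 2
  half <- halfDeg * pi / 180
  st <- states[focal, ]
  e <- c(st$x + config@eyeOffset * st$bl * st$hx,
         st$y + config@eyeOffset * st$bl * st$hy)
  maxR <- if (is.na(config@maxRange))
    sqrt(arena@lengthMM^2 + arena@widthMM^2) else config@maxRange
  gx <- seq(-arena@lengthMM / 2 + gridStep / 2, arena@lengthMM / 2, by = gridStep)
  gy <- seq(-arena@widthMM / 2 + gridStep / 2, arena@widthMM / 2, by = gridStep)
  g <- as.matrix(expand.grid(gx, gy))
  # inside test from the parametric stadium definition
  r <- arena@widthMM / 2
  a <- (arena@lengthMM - arena@widthMM) / 2
  if (arena@shape == "stadium") {
    qx <- pmin(pmax(g[, 1], -a), a)
    inside <- sqrt((g[, 1] - qx)^2 + g[, 2]^2) < r
  } else {
    inside <- (g[, 1] / (arena@lengthMM / 2))^2 + (g[, 2] / r)^2 < 1
  }
  g <- g[inside, , drop = FALSE]
  vx <- g[, 1] - e[1]; vy <- g[, 2] - e[2]
  L <- sqrt(vx^2 + vy^2)
  th0 <- atan2(st$hy, st$hx)
  ang <- atan2(vy, vx)
  da <- atan2(sin(ang - th0), cos(ang - th0))
  vis <- abs(da) <= half & L <= maxR
  others <- setdiff(which(!is.na(states$x)), focal)
  for (j in others) {
    idx <- which(vis)
    if (length(idx) == 0) break
    phi <- atan2(states$hy[j], states$hx[j])
    if (is.na(phi)) phi <- 0
    sa <- 0.5 * states$bl[j]
    sb <- 0.5 * config@aspectRatio * states$bl[j]
    # vectorised segment-ellipse test for all still-visible points
    cp <- cos(phi); sp <- sin(phi)
    rx <- e[1] - states$x[j]; ry <- e[2] - states$y[j]
    Px <- (cp * rx + sp * ry) / sa
    Py <- (-sp * rx + cp * ry) / sb
    gxr <- g[idx, 1] - states$x[j]; gyr <- g[idx, 2] - states$y[j]
    Qx <- (cp * gxr + sp * gyr) / sa
    Qy <- (-sp * gxr + cp * gyr) / sb
    Dx <- Qx - Px; Dy <- Qy - Py
    aa <- Dx^2 + Dy^2
    bb <- Px * Dx + Py * Dy
    cc <- Px^2 + Py^2 - 1
    disc <- bb^2 - aa * cc
    sq <- sqrt(pmax(disc, 0))
    t1 <- (-bb - sq) / aa
    t2 <- (-bb + sq) / aa
    blocked <- disc >= 0 &
      ((t1 > 1e-6 & t1 < 1 - 1e-6) | (t2 > 1e-6 & t2 < 1 - 1e-6))
    vis[idx[blocked]] <- FALSE
  }
  mean(vis)
}

# Monte-Carlo support-function test for convex-hull area: a point is in the
# hull iff its projection on every direction lies within the point set's
# projections
oracleHullArea <- function(p, nDir = 72, nSamples = 40000) {
  th <- seq(0, pi, length.out = nDir)
  D <- cbind(cos(th), sin(th))
  proj <- p %*% t(D)                      # points x directions
  lo <- apply(proj, 2, min); hi <- apply(proj, 2, max)
  bx <- range(p[, 1]); by <- range(p[, 2])
  sx <- runif(nSamples, bx[1], bx[2])
  sy <- runif(nSamples, by[1], by[2])
  sproj <- cbind(sx, sy) %*% t(D)
  ok <- rep(TRUE, nSamples)
  for (k in seq_len(nDir))
    ok <- ok & sproj[, k] >= lo[k] - 1e-9 & sproj[, k] <= hi[k] + 1e-9
  mean(ok) * diff(bx) * diff(by)
}

# random-heading polarization expectation for n fish by Monte Carlo
oracleRandomPolarization <- function(n, reps = 200000) {
  th <- matrix(runif(n * reps, 0, 2 * pi), reps, n)
  mean(sqrt(rowMeans(cos(th))^2 + rowMeans(sin(th))^2))
}
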