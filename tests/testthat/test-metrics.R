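# Individual and group position/movement parameters.

test_that("polarization matches its defining cases", {
  expect_identical(polarization(matrix(rep(c(1, 0), each = 8), ncol = 2)), 1)
  expect_equal(polarization(rbind(c(1, 0), c(-1, 0))), 0)
  th <- seq(0, 2 * pi, length.out = 9)[-9]        # 8 headings 45 deg apart
  expect_equal(polarization(cbind(cos(th), sin(th))), 0, tolerance = 1e-12)
  expect_warning(p <- polarization(rbind(c(1, 0))), "fewer than 2")
  expect_true(is.na(p))
})

test_that("polarization is rotation invariant and 1 only for coincident headings", {
  set.seed(5)
  for (k in 1:20) {
    th <- runif(8, 0, 2 * pi)
    h <- cbind(cos(th), sin(th))
    a <- runif(1, 0, 2 * pi)
    R <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
    expect_equal(polarization(h), polarization(h %*% t(R)), tolerance = 1e-12)
    if (length(unique(round(th, 6))) > 1)
      expect_lt(polarization(h), 1)
  }
})

test_that("bearing to a target covers the quadrant cases and errors", {
  expect_equal(bearingToTarget(c(0, 0), c(1, 0), c(10, 0)), 0)
  expect_equal(bearingToTarget(c(0, 0), c(1, 0), c(-10, 0)), 180)
  expect_equal(bearingToTarget(c(0, 0), c(1, 0), c(0, 5)), 90)
  expect_error(bearingToTarget(c(1, 1), c(1, 0), c(1, 1)), "coincides")
})

test_that("headings from displacement: direction, floor, circular tangent", {
  traj <- linearTraj(rbind(c(-300, 0), c(-300, 50)),
                     rbind(c(5, 0), c(0, 0)), 20)
  hf <- headingsFromDisplacement(traj)
  expect_equal(unname(hf@hx[10, 1]), 1)
  expect_equal(unname(hf@hy[10, 1]), 0)
  expect_false(hf@valid[10, 2])                  # stationary fish: no heading
  # circular motion: heading tangent to the circle within 1 degree
  r <- 50
  t <- seq_len(100)
  w <- 2.2 / r                                    # ~2.2 mm/frame speed
  x <- r * cos(w * t); y <- r * sin(w * t)
  ctraj <- toyTraj(cbind(x, x + 100), cbind(y, y))
  chf <- headingsFromDisplacement(ctraj)
  for (i in c(20, 50, 80)) {
    tangent <- c(-sin(w * t[i]), cos(w * t[i]))
    dp <- min(1, max(-1, sum(c(chf@hx[i, 1], chf@hy[i, 1]) * tangent)))
    ang <- acos(dp) * 180 / pi
    expect_lt(ang, 1)
  }
})

test_that("group metrics: hull area, edge flags, degenerate hulls", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  hull <- convexHullInfo(sq)
  expect_equal(hull$area, 1)
  expect_true(all(hull$onEdge))
  col <- cbind(seq(0, 70, 10), seq(0, 70, 10))    # 8 collinear fish
  hull2 <- convexHullInfo(col)
  expect_equal(hull2$area, 0)
  expect_true(all(hull2$onEdge))
  # N <= 3: everyone is on the hull
  expect_true(all(convexHullInfo(rbind(c(0, 0), c(10, 0), c(3, 8)))$onEdge))
})

test_that("hull area matches the support-function oracle on random sets", {
  set.seed(6)
  for (k in 1:5) {
    p <- cbind(runif(8, -100, 100), runif(8, -80, 80))
    mine <- convexHullInfo(p)$area
    ref <- oracleHullArea(p)
    expect_lt(abs(mine - ref) / ref, 0.04)
  }
})

test_that("hull area is invariant under rigid motion", {
  set.seed(7)
  p <- cbind(runif(8, -100, 100), runif(8, -80, 80))
  a <- 1.1
  R <- rbind(c(cos(a), -sin(a)), c(sin(a), cos(a)))
  pr <- sweep(p %*% t(R), 2, c(31, -17), "+")
  expect_equal(convexHullInfo(p)$area, convexHullInfo(pr)$area,
               tolerance = 1e-9)
})

test_that("window summary takes the pre-onset median and flags gaps", {
  frames <- 1:50
  expect_equal(windowSummary(rep(7, 50), frames, onset = 30), 7)
  expect_equal(windowSummary(1:50, frames, onset = 14), 7)   # window 1..13
  s <- 1:50; s[20] <- NA
  expect_true(is.na(windowSummary(s, frames, onset = 30)))
})

test_that("relative values divide by the group mean and average to 1", {
  expect_equal(relativizeGroup(rep(3, 8)), rep(1, 8))
  r <- relativizeGroup(c(rep(2, 7), 10))   # group mean 3: 2/3 and 10/3
  expect_equal(r, c(rep(2 / 3, 7), 10 / 3))
  expect_equal(mean(r), 1)
  set.seed(8)
  v <- runif(8, 1, 5)
  expect_equal(mean(relativizeGroup(v)), 1, tolerance = 1e-12)
  expect_warning(out <- relativizeGroup(c(-1, 1)), "zero")
  expect_true(all(is.na(out)))
})

test_that("bearing dispersion: closed-form SD and minimum", {
  bd <- bearingDispersion(rep(42, 8))
  expect_equal(bd$sd, 0)
  expect_equal(bd$min, 42)
  bd2 <- bearingDispersion(c(0, 180))
  expect_equal(bd2$sd, 127.28, tolerance = 1e-4)  # 180 / sqrt(2)
  expect_equal(bd2$min, 0)
  expect_error(bearingDispersion(5), "at least 2")
})

test_that("zero bearing SD does not imply polarization 1", {
  # two fish mirrored about the line to the stimulus: equal unsigned
  # bearings (SD = 0) but different headings (polarization < 1)
  target <- c(100, 0)
  h1 <- c(cos(pi / 4), sin(pi / 4))
  h2 <- c(cos(-pi / 4), sin(-pi / 4))
  b1 <- bearingToTarget(c(0, 10), h1, target)
  b2 <- bearingToTarget(c(0, -10), h2, target)
  expect_equal(stats::sd(c(b1, b2)), 0, tolerance = 1e-9)
  expect_lt(polarization(rbind(h1, h2)), 0.75)
})

test_that("nearest-neighbour heading difference handles ties and averages", {
  # 3 fish on a line, pair aligned, third antiparallel
  x <- matrix(c(0, 10, 40), 3, 3, byrow = TRUE) + 0:2
  y <- matrix(0, 3, 3)
  traj <- toyTraj(x, y)
  hx <- matrix(c(1, 1, -1), 3, 3, byrow = TRUE)
  hf <- new("HeadingField", hx = hx, hy = matrix(0, 3, 3),
            speed = matrix(1, 3, 3),
            valid = matrix(TRUE, 3, 3), speedFloor = 0.3)
  d <- nnHeadingDifference(traj, hf, 2)
  expect_equal(d, c(0, 0, 180))                    # fish 3's nn is fish 2
  m <- meanNNHeadingDifference(traj, hf, 1:3)
  expect_equal(m, c(0, 0, 180))
  # tie in nn distance resolves to the lower fish index
  xt <- matrix(c(-10, 0, 10), 1, 3)
  trajt <- toyTraj(rbind(xt, xt + 0.01), matrix(0, 2, 3))
  hft <- new("HeadingField", hx = matrix(c(1, 0, 1), 2, 3, byrow = TRUE),
             hy = matrix(c(0, 1, 0), 2, 3, byrow = TRUE),
             speed = matrix(1, 2, 3), valid = matrix(TRUE, 2, 3),
             speedFloor = 0.3)
  d2 <- nnHeadingDifference(trajt, hft, 1)
  expect_equal(d2[2], 90)                          # picked fish 1, not 3
})

test_that("presentation metrics summarise the pre-stimulus window", {
  # constant-velocity group: medians must equal the per-frame values
  start <- rbind(c(-400, -50), c(-400, 50), c(-350, 0), c(-450, 0))
  vel <- rbind(c(2, 0), c(2, 0), c(2, 0), c(2, 0))
  traj <- linearTraj(start, vel, 40)
  hf <- headingsFromDisplacement(traj)
  pres <- data.frame(presentationId = 1, onsetFrame = 30, portId = 1)
  pm <- presentationMetrics(traj, hf, pres)
  expect_equal(nrow(pm$individual), 4)
  expect_equal(pm$group$polarization, 1)
  expect_equal(pm$individual$speed, rep(2, 4), tolerance = 1e-9)
  expect_equal(pm$individual$rel_speed, rep(1, 4), tolerance = 1e-9)
  # hull of the diamond: area 100*50*... shoelace of the 4 start points
  expect_equal(pm$group$hullArea, 5000, tolerance = 1e-6)
  expect_equal(pm$group$minBearing, min(pm$individual$bearingStimulus))
  # gap in the window invalidates the presentation metrics
  traj2 <- traj
  traj2@x[25, 2] <- NA
  pm2 <- presentationMetrics(traj2, headingsFromDisplacement(traj2), pres)
  expect_true(is.na(pm2$group$polarization))
})
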