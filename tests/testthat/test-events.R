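# Presentation validation, response detection and arrival events.

# a valid presentation fixture: 4 fish on the -x half, far from port 1,
# fish 1 turns toward the port at onset and accelerates
eventFixture <- function(nFish = 4, onset = 20, accelFish = 1,
                         accelFrame = onset + 10, speed = 2, goal = 6) {
  a <- defaultArena()
  port <- portPosition(a, 1)
  nFrames <- onset + 520
  start <- cbind(seq(-480, -420, length.out = nFish),
                 seq(-60, 60, length.out = nFish))
  # baseline: everyone drifts slowly along -x (capped inside the arena)
  x <- sapply(seq_len(nFish), function(f)
    pmax(start[f, 1] - (seq_len(nFrames) - 1) * 0.5, -640))
  y <- sapply(seq_len(nFish), function(f) rep(start[f, 2], nFrames))
  # responder: from accelFrame, head straight to the port at goal speed
  f <- accelFish
  p0 <- c(x[accelFrame, f], y[accelFrame, f])
  L <- sqrt(sum((port - p0)^2))
  dir <- (port - p0) / L
  steps <- nFrames - accelFrame
  s <- pmin(goal * seq_len(steps), L - 30)   # stop just short of the wall
  x[(accelFrame + 1):nFrames, f] <- p0[1] + dir[1] * s
  y[(accelFrame + 1):nFrames, f] <- p0[2] + dir[2] * s
  toyTraj(x, y, arena = a)
}

test_that("presentation validation applies the distance, half and gap rules", {
  traj <- eventFixture()
  v <- validatePresentation(traj, onsetFrame = 20, portId = 1)
  expect_true(v$valid)
  # a fish too close to the port
  traj2 <- traj
  traj2@x[, 2] <- 100; traj2@y[, 2] <- 250   # ~300 mm from port 1
  v2 <- validatePresentation(traj2, 20, 1)
  expect_false(v2$valid)
  expect_match(v2$reason, "min-distance|same-half")
  # tracking gap in the pre-window
  traj3 <- traj
  traj3@x[12, 3] <- NA
  v3 <- validatePresentation(traj3, 20, 1)
  expect_false(v3$valid)
  expect_equal(v3$reason, "tracking-gap")
})

test_that("responses need both orientation and a sustained speed surge", {
  traj <- eventFixture(accelFrame = 30)
  hf <- headingsFromDisplacement(traj)
  re <- detectResponses(traj, hf, onsetFrame = 20, portId = 1)
  expect_equal(nrow(re), 1)
  expect_equal(re$fishId[1], "f1")
  expect_true(re$first[1])
  # latency close to the turn frame (sustain + heading lag allow a few frames)
  expect_gte(re$responseLatency[1], 10)
  expect_lte(re$responseLatency[1], 18)
  # orientation without a speed surge is not a response
  a <- defaultArena()
  port <- portPosition(a, 1)
  start <- cbind(rep(-450, 2), c(-30, 30))
  dirs <- t(apply(start, 1, function(p) (port - p) / sqrt(sum((port - p)^2))))
  slow <- linearTraj(start, dirs * 1.0, 540)      # constant speed, facing port
  hfs <- headingsFromDisplacement(slow)
  res <- detectResponses(slow, hfs, onsetFrame = 20, portId = 1)
  expect_equal(nrow(res), 0)
})

test_that("arrival latency follows the two-body-length kinematics", {
  # fish at 500 mm heading straight at 10 mm/frame with 27 mm body:
  # arrival when distance <= 54 mm, i.e. frame ceiling((500-54)/10) = 45
  a <- defaultArena()
  port <- portPosition(a, 1)
  dir <- port / sqrt(sum(port^2))
  start <- rbind(port - 500 * dir, port - 600 * dir)
  traj <- approachTraj(start, c(10, 0), port, 560, bodyLengthMM = 27,
                       stopDist = 30)
  ar <- arrivalEvents(traj, onsetFrame = 1, portId = 1)
  expect_equal(nrow(ar), 1)
  expect_equal(ar$fishId, "f1")
  expect_equal(ar$arrivalLatency, 45)
  # nobody approaches -> empty
  still <- approachTraj(start, c(0, 0), port, 520)
  expect_equal(nrow(arrivalEvents(still, 1, 1)), 0)
})

test_that("simultaneous arrivals break ties by distance then index", {
  a <- defaultArena()
  port <- portPosition(a, 1)
  dir <- port / sqrt(sum(port^2))
  # both arrive at the same frame; fish 2 ends nearer the port
  start <- rbind(port - 500 * dir, port - 497 * dir)
  traj <- approachTraj(start, c(10, 10), port, 540, bodyLengthMM = 27,
                       stopDist = 30)
  ar <- arrivalEvents(traj, 1, 1)
  expect_equal(ar$arrivalLatency[1], ar$arrivalLatency[2])
  expect_equal(ar$fishId, c("f2", "f1"))
  expect_equal(ar$arrivalOrder, 1:2)
})

test_that("arrival order is a bijection onto 1..k with latencies in (0, 500]", {
  set.seed(16)
  cfg <- simConfig()
  traj <- simulateShoal(cfg, nFrames = 4000, seed = 16)
  pres <- runPresentationProtocol(traj, nPresentations = 2, minGapS = 40)
  out <- applyDetectionModel(traj, pres)
  for (r in seq_len(nrow(pres))) {
    ar <- arrivalEvents(out$traj, pres$onsetFrame[r], pres$portId[r])
    if (nrow(ar) == 0) next
    expect_equal(sort(ar$arrivalOrder), seq_len(nrow(ar)))
    expect_true(all(ar$arrivalLatency > 0 & ar$arrivalLatency <= 500))
    expect_false(is.unsorted(ar$arrivalLatency))
    re <- detectResponses(out$traj, headingsFromDisplacement(out$traj),
                          pres$onsetFrame[r], pres$portId[r])
    if (nrow(re))
      expect_true(all(re$responseLatency > 0 & re$responseLatency <= 500))
  }
})

test_that("first-responder/first-arriver test gives the exact binomial tail", {
  r <- firstResponderFirstArriver(rep("a", 5), rep("a", 5), groupSize = 8)
  expect_equal(r$expected, 0.125)                  # null 1/8 for groups of 8
  expect_equal(r$observed, 1)
  # 3 matches in 10: p = sum_{k>=3} C(10,k) p0^k (1-p0)^(10-k)
  fr <- c(rep("a", 3), rep("b", 7))
  fa <- c(rep("a", 3), rep("c", 7))
  r2 <- firstResponderFirstArriver(fr, fa, groupSize = 8)
  expect_equal(r2$observed, 0.3)
  manual <- sum(vapply(3:10, function(k)
    choose(10, k) * 0.125^k * 0.875^(10 - k), numeric(1)))
  expect_equal(r2$p, manual, tolerance = 1e-12)
  expect_error(firstResponderFirstArriver(NA, NA), "no presentations")
})

test_that("label shuffling recovers the 1/N chance rate of double firsts", {
  set.seed(17)
  n <- 1000
  fish <- sprintf("f%d", 1:8)
  fr <- sample(fish, n, replace = TRUE)
  fa <- sample(fish, n, replace = TRUE)            # independent labels
  r <- firstResponderFirstArriver(fr, fa, groupSize = 8)
  ci <- stats::binom.test(round(r$observed * n), n)$conf.int
  expect_true(ci[1] <= 0.125 && 0.125 <= ci[2])
})

test_that("detected first responders match the simulator's ground truth", {
  set.seed(18)
  cfg <- simConfig()
  agree <- integer(0)
  for (g in 1:8) {
    ws <- wAlignForPolarization(runif(10, 0.15, 0.9), cfg)
    b <- simulatePresentationBatch(cfg, ws, burninFrames = 350,
                                   groupId = paste0("g", g))
    trs <- smoothSavGol(b$traj)
    hf <- headingsFromDisplacement(trs)
    for (r in seq_len(nrow(b$presentations))) {
      tru <- b$truth[b$truth$presentationId == r, ]
      det <- tru[!is.na(tru$tDetect), ]
      if (nrow(det) == 0) next
      truthFirst <- det$fishId[which.min(det$tDetect)]
      re <- detectResponses(trs, hf, b$presentations$onsetFrame[r],
                            b$presentations$portId[r])
      if (nrow(re) == 0) next
      agree <- c(agree, as.integer(re$fishId[1] == truthFirst))
    }
  }
  expect_gte(length(agree), 60)
  expect_gte(mean(agree), 0.9)
})
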