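# Agent-based synthetic shoal generator with ground-truth detection events.
#
# Zonal (repulsion / alignment / attraction) steering with wall avoidance
# and Gaussian heading noise; the alignment weight is the single knob that
# moves the group across the polarization range. The stimulus-response
# layer draws private detections (binocular sight of the port) and social
# responses (visible responding neighbours, gain increasing in pre-stimulus
# polarization), so the generated data carry the structure the analysis is
# meant to recover: first responses are faster in disordered groups, later
# arrivals faster in polarized ones.

arenaCppList <- function(arena) {
  sp <- stadiumParams(arena)
  list(shape = if (arena@shape == "stadium") 0L else 1L,
       a = sp$a, r = sp$r, A = sp$A, B = sp$B)
}

zoneCppList <- function(config) {
  list(rRep = config@rRep, rAli = config@rAli, rAtt = config@rAtt,
       wAlign = config@wAlign, wAttract = config@wAttract,
       wWall = config@wWall, wWander = config@wWander,
       wallDist = config@wallDist,
       noiseSD = config@headingNoiseSD * pi / 180,
       turnMax = config@turnMax * pi / 180)
}

# draw initial state: a loose cluster near the arena centre
initialState <- function(config) {
  n <- as.integer(config@nFish)
  ang <- runif(n, -pi, pi)
  rad <- sqrt(runif(n)) * 150
  x <- rad * cos(ang)
  y <- rad * sin(ang)
  base <- runif(1, -pi, pi)
  th <- base + rnorm(n, 0, 0.5)
  speeds <- pmax(0.5, rnorm(n, config@speedMeanMM, config@speedSDMM))
  bl <- pmax(18, rnorm(n, config@bodyLengthMeanMM, config@bodyLengthSDMM))
  list(x = x, y = y, th = th, speeds = speeds, bl = bl)
}

#' Simulate a freely swimming shoal
#'
#' Runs the zonal agent model for `nFrames` frames. Identical seeds give
#' identical output.
#'
#' @param config a [SimConfig-class].
#' @param nFrames number of frames to simulate.
#' @param seed optional integer seed (calls [set.seed()]).
#' @param groupId group identifier for the returned object.
#' @return A [TrajectorySet-class] with attributes `theta` (true heading
#'   angles, frames x fish), `baseSpeeds` and `config`.
#' @examples
#' traj <- simulateShoal(simConfig(wAlign = 6, headingNoiseSD = 6),
#'                       nFrames = 200, seed = 1)
#' @export
simulateShoal <- function(config, nFrames = 3000, seed = NULL,
                          groupId = "sim") {
  if (!is.null(seed)) set.seed(seed)
  st <- initialState(config)
  out <- simulate_shoal_cpp(st$x, st$y, st$th, st$speeds,
                            arenaCppList(config@arena), zoneCppList(config),
                            as.integer(nFrames))
  traj <- makeTrajectorySet(out$x, out$y, arena = config@arena,
                            units = unitSystem(fps = config@fps),
                            groupId = groupId, bodyLengthMM = st$bl)
  attr(traj, "theta") <- out$theta
  attr(traj, "baseSpeeds") <- st$speeds
  attr(traj, "config") <- config
  traj
}

#' True-heading polarization series of a simulated shoal
#'
#' @param traj a [simulateShoal()] result (must carry the `theta` attribute).
#' @return numeric vector, polarization per frame.
#' @export
truePolarizationSeries <- function(traj) {
  th <- attr(traj, "theta")
  if (is.null(th)) stop("trajectory carries no true headings")
  sqrt(rowMeans(cos(th))^2 + rowMeans(sin(th))^2)
}

#' Schedule stimulus presentations on a simulated trajectory
#'
#' Emulates the presentation protocol: for each presentation a port is drawn
#' uniformly at random, and the presentation fires at the first frame — at
#' least `minGapS` seconds after the previous onset — at which every fish is
#' on the half of the arena opposite the port and at least `minDistMM` from
#' it. If eligibility is never met within the trajectory, fewer
#' presentations are returned with a warning.
#'
#' @param traj a [TrajectorySet-class].
#' @param nPresentations presentations to attempt (default 6).
#' @param minGapS minimum onset gap in seconds (default 180).
#' @param minDistMM minimum fish-port distance at onset (default 430).
#' @param tailFrames frames that must remain after onset for scoring
#'   (default 500).
#' @param trialId trial identifier.
#' @param day cumulative days of testing recorded on the rows.
#' @param seed optional integer seed for the port draws.
#' @return data.frame `trialId, presentationId, onsetFrame, portId, valid,
#'   exclusionReason, cumulativeDaysOfTesting`.
#' @export
runPresentationProtocol <- function(traj, nPresentations = 6, minGapS = 180,
                                    minDistMM = 430, tailFrames = 500,
                                    trialId = "t1", day = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fps <- traj@units@fps
  minGap <- round(minGapS * fps)
  ports <- traj@arena@ports
  nf <- length(traj@frames)
  # per-port eligibility per frame
  elig <- matrix(FALSE, nf, nrow(ports))
  tracked <- !apply(is.na(traj@x), 1, any)
  for (k in seq_len(nrow(ports))) {
    px <- ports$x[k]; py <- ports$y[k]
    d2 <- (traj@x - px)^2 + (traj@y - py)^2
    farEnough <- apply(d2, 1, function(r) all(!is.na(r)) && min(r) >= minDistMM^2)
    opposite <- apply(traj@x * px < 0, 1, all)
    opposite[is.na(opposite)] <- FALSE
    elig[, k] <- tracked & farEnough & opposite
  }
  rows <- list()
  lastOnset <- -Inf
  for (p in seq_len(nPresentations)) {
    port <- sample(ports$id, 1)
    k <- match(port, ports$id)
    from <- max(15, lastOnset + minGap)
    cand <- which(elig[, k])
    cand <- cand[cand >= from & cand <= nf - tailFrames]
    if (length(cand) == 0) {
      warning(sprintf("eligibility never met for presentation %d; stopping at %d",
                      p, p - 1))
      break
    }
    onset <- traj@frames[cand[1]]
    lastOnset <- cand[1]
    rows[[p]] <- data.frame(trialId = trialId, presentationId = p,
                            onsetFrame = onset, portId = port,
                            valid = TRUE, exclusionReason = NA_character_,
                            cumulativeDaysOfTesting = day)
  }
  if (length(rows) == 0)
    return(data.frame(trialId = character(0), presentationId = integer(0),
                      onsetFrame = integer(0), portId = integer(0),
                      valid = logical(0), exclusionReason = character(0),
                      cumulativeDaysOfTesting = numeric(0)))
  do.call(rbind, rows)
}

#' Apply the detection model to scheduled presentations
#'
#' For each valid presentation, re-simulates the 500-frame post-onset window
#' from the state at onset under the two-channel detection model: private
#' detection (stimulus inside the binocular sector, unoccluded; hazard
#' `h0 * exp(-d / lambda)`) and social response (hazard `s0 * k *
#' (1 + gamma * P_pre)` for `k` visible responding neighbours). Responders
#' steer to the port at goal speed; arrival is within two body lengths.
#' The trajectory is patched over each window; ground truth (channel, true
#' detection frame, true arrival frame) is logged per fish per presentation.
#'
#' @param traj a [simulateShoal()] result.
#' @param presentations a [runPresentationProtocol()] data.frame.
#' @param vision a [VisionConfig-class] (binocular angle and occluder shape).
#' @param model a [DetectionModel-class].
#' @return list with `traj` (patched [TrajectorySet-class]), `presentations`,
#'   and `truth` (data.frame `presentationId, fishId, channel, tDetect,
#'   tArrive`, frames relative to onset; channel is `"private"`, `"social"`
#'   or `"none"`).
#' @export
applyDetectionModel <- function(traj, presentations, vision = visionConfig(),
                                model = detectionModel()) {
  config <- attr(traj, "config")
  theta <- attr(traj, "theta")
  speeds <- attr(traj, "baseSpeeds")
  if (is.null(config) || is.null(theta))
    stop("traj must come from simulateShoal()")
  truth <- list()
  for (r in seq_len(nrow(presentations))) {
    if (!isTRUE(presentations$valid[r])) next
    onset <- presentations$onsetFrame[r]
    i <- match(onset, traj@frames)
    port <- portPosition(traj@arena, presentations$portId[r])
    pre <- (i - 13):(i - 1)
    Ppre <- stats::median(sqrt(rowMeans(cos(theta[pre, , drop = FALSE]))^2 +
                               rowMeans(sin(theta[pre, , drop = FALSE]))^2))
    win <- simulate_window_cpp(traj@x[i, ], traj@y[i, ], theta[i, ], speeds,
                               traj@bodyLengthMM,
                               arenaCppList(traj@arena), zoneCppList(config),
                               port[1], port[2],
                               model@h0, model@lambdaMM, model@s0,
                               model@gamma, model@goalSpeedMult, Ppre,
                               vision@binocularHalfAngle * pi / 180,
                               vision@totalField / 2 * pi / 180,
                               vision@aspectRatio, 500L)
    idx <- (i + 1):(i + 500)
    traj@x[idx, ] <- win$x
    traj@y[idx, ] <- win$y
    theta[idx, ] <- win$theta
    truth[[r]] <- data.frame(
      presentationId = presentations$presentationId[r],
      fishId = traj@fishIds,
      channel = c("none", "private", "social")[win$channel + 1],
      tDetect = win$tDetect, tArrive = win$tArrive,
      prePolarization = Ppre)
  }
  attr(traj, "theta") <- theta
  list(traj = traj, presentations = presentations,
       truth = do.call(rbind, truth))
}

#' Calibrate the alignment weight to a target polarization
#'
#' Bisection on the alignment weight (noise fixed) until the mean true
#' polarization of a `nFrames`-frame run is within `tol` of the target.
#'
#' @param target desired mean polarization, in `(0.05, 0.98)`.
#' @param config template [SimConfig-class]; only `wAlign` is varied.
#' @param nFrames calibration run length (default 3000).
#' @param tol acceptance tolerance (default 0.05).
#' @param wRange bracketing interval for the alignment weight.
#' @param maxIter bisection iterations (default 14).
#' @param burnin frames discarded before averaging (default 250).
#' @return the calibrated [SimConfig-class], with attribute `achieved`.
#' @export
calibratePolarization <- function(target, config = simConfig(),
                                  nFrames = 3000, tol = 0.05,
                                  wRange = c(-1, 12), maxIter = 14,
                                  burnin = 250) {
  if (target <= 0.05 || target >= 0.98)
    stop("target must be in (0.05, 0.98)")
  evalW <- function(w) {
    cfg <- config
    cfg@wAlign <- w
    traj <- simulateShoal(cfg, nFrames = nFrames)
    mean(truePolarizationSeries(traj)[-seq_len(burnin)])
  }
  lo <- wRange[1]; hi <- wRange[2]
  plo <- evalW(lo); phi <- evalW(hi)
  if (!(plo < target && target < phi))
    stop(sprintf("target %.2f outside achieved bracket [%.3f, %.3f]",
                 target, plo, phi))
  achieved <- NA_real_; w <- NA_real_
  for (it in seq_len(maxIter)) {
    w <- (lo + hi) / 2
    p <- evalW(w)
    if (abs(p - target) <= tol) { achieved <- p; break }
    if (p < target) lo <- w else hi <- w
    achieved <- p
  }
  if (abs(achieved - target) > tol)
    stop(sprintf("calibration failed: achieved %.3f for target %.2f (w = %.3f)",
                 achieved, target, w))
  out <- config
  out@wAlign <- w
  attr(out, "achieved") <- achieved
  out
}

#' Alignment weights for target polarization levels
#'
#' Builds a calibration curve (mean polarization of short runs over a grid
#' of alignment weights, pooled and made monotone) and inverts it by linear
#' interpolation, so experiments can sample polarization levels uniformly.
#'
#' @param targets desired mean polarization levels.
#' @param config template [SimConfig-class].
#' @param wRange alignment-weight range of the curve.
#' @param nPoints grid points (default 12).
#' @param nFrames frames per calibration run (default 1500).
#' @param burnin frames discarded before averaging (default 250).
#' @return numeric vector of alignment weights, one per target.
#' @export
wAlignForPolarization <- function(targets, config = simConfig(),
                                  wRange = c(-1, 6), nPoints = 12,
                                  nFrames = 1500, burnin = 250) {
  ws <- seq(wRange[1], wRange[2], length.out = nPoints)
  ps <- vapply(ws, function(w) {
    cfg <- config
    cfg@wAlign <- w
    traj <- simulateShoal(cfg, nFrames = nFrames)
    mean(truePolarizationSeries(traj)[-seq_len(burnin)])
  }, numeric(1))
  ps <- cummax(ps)   # enforce monotonicity for inversion
  stats::approx(ps, ws, xout = pmin(pmax(targets, min(ps)), max(ps)),
                ties = "ordered")$y
}

#' Simulate a batch of standalone presentations for one group
#'
#' Convenience generator for pipeline experiments: each presentation is an
#' independent burn-in (at its own alignment weight, so polarization spans a
#' chosen range) followed by a 500-frame response window, concatenated into
#' one [TrajectorySet-class] with an aligned presentation table and ground
#' truth. The port is drawn among those on the half opposite the group
#' centroid with all fish at least 430 mm away; if none qualifies the
#' burn-in is extended.
#'
#' @param config a [SimConfig-class] (its `wAlign` is overridden per
#'   presentation).
#' @param wAligns numeric vector, one alignment weight per presentation.
#' @param vision a [VisionConfig-class].
#' @param model a [DetectionModel-class].
#' @param burninFrames burn-in length per presentation (default 400).
#' @param groupId group identifier.
#' @param day cumulative-days value recorded on the presentation rows.
#' @return list `traj`, `presentations`, `truth` as in
#'   [applyDetectionModel()].
#' @export
simulatePresentationBatch <- function(config, wAligns,
                                      vision = visionConfig(),
                                      model = detectionModel(),
                                      burninFrames = 400,
                                      groupId = "sim", day = 1) {
  n <- as.integer(config@nFish)
  nP <- length(wAligns)
  window <- 500L
  block <- burninFrames + window
  X <- matrix(NA_real_, nP * block, n)
  Y <- X
  TH <- X
  st0 <- initialState(config)
  pres <- list(); truth <- list()
  ports <- config@arena@ports
  for (p in seq_len(nP)) {
    cfg <- config
    cfg@wAlign <- wAligns[p]
    st <- initialState(cfg)
    burn <- simulate_shoal_cpp(st$x, st$y, st$th, st$speeds,
                               arenaCppList(cfg@arena), zoneCppList(cfg),
                               as.integer(burninFrames))
    # extend burn-in until a port qualifies (opposite half, >= 430 mm)
    pickPort <- function(bx, by) {
      cx <- mean(bx)
      ok <- which(ports$x * cx < 0)
      if (length(ok) == 0) return(NA_integer_)
      ok <- ok[vapply(ok, function(k) {
        min(sqrt((bx - ports$x[k])^2 + (by - ports$y[k])^2)) >= 430
      }, logical(1))]
      if (length(ok) == 0) NA_integer_ else ok[sample.int(length(ok), 1)]
    }
    lastRow <- burninFrames
    k <- pickPort(burn$x[lastRow, ], burn$y[lastRow, ])
    tries <- 0
    while (is.na(k) && tries < 30) {
      ext <- simulate_shoal_cpp(burn$x[lastRow, ], burn$y[lastRow, ],
                                burn$theta[lastRow, ], st$speeds,
                                arenaCppList(cfg@arena), zoneCppList(cfg), 101L)
      keep <- 2:101
      # keep the most recent burninFrames rows
      burn$x <- rbind(burn$x, ext$x[keep, ])
      burn$x <- burn$x[(nrow(burn$x) - burninFrames + 1):nrow(burn$x), , drop = FALSE]
      burn$y <- rbind(burn$y, ext$y[keep, ])
      burn$y <- burn$y[(nrow(burn$y) - burninFrames + 1):nrow(burn$y), , drop = FALSE]
      burn$theta <- rbind(burn$theta, ext$theta[keep, ])
      burn$theta <- burn$theta[(nrow(burn$theta) - burninFrames + 1):nrow(burn$theta), , drop = FALSE]
      lastRow <- burninFrames
      k <- pickPort(burn$x[lastRow, ], burn$y[lastRow, ])
      tries <- tries + 1
    }
    if (is.na(k)) k <- sample.int(nrow(ports), 1)   # degenerate fallback
    port <- c(ports$x[k], ports$y[k])
    pre <- (burninFrames - 13):(burninFrames - 1)
    Ppre <- stats::median(sqrt(rowMeans(cos(burn$theta[pre, , drop = FALSE]))^2 +
                               rowMeans(sin(burn$theta[pre, , drop = FALSE]))^2))
    win <- simulate_window_cpp(burn$x[lastRow, ], burn$y[lastRow, ],
                               burn$theta[lastRow, ], st$speeds, st0$bl,
                               arenaCppList(cfg@arena), zoneCppList(cfg),
                               port[1], port[2],
                               model@h0, model@lambdaMM, model@s0,
                               model@gamma, model@goalSpeedMult, Ppre,
                               vision@binocularHalfAngle * pi / 180,
                               vision@totalField / 2 * pi / 180,
                               vision@aspectRatio, window)
    rows <- ((p - 1) * block + 1):(p * block)
    X[rows, ] <- rbind(burn$x, win$x)
    Y[rows, ] <- rbind(burn$y, win$y)
    TH[rows, ] <- rbind(burn$theta, win$theta)
    pres[[p]] <- data.frame(trialId = groupId, presentationId = p,
                            onsetFrame = (p - 1) * block + burninFrames,
                            portId = ports$id[k], valid = TRUE,
                            exclusionReason = NA_character_,
                            cumulativeDaysOfTesting = day)
    truth[[p]] <- data.frame(presentationId = p,
                             fishId = sprintf("f%d", seq_len(n)),
                             channel = c("none", "private", "social")[win$channel + 1],
                             tDetect = win$tDetect, tArrive = win$tArrive,
                             prePolarization = Ppre)
  }
  traj <- makeTrajectorySet(X, Y, arena = config@arena,
                            units = unitSystem(fps = config@fps),
                            groupId = groupId, bodyLengthMM = st0$bl)
  attr(traj, "theta") <- TH
  attr(traj, "baseSpeeds") <- st0$speeds
  attr(traj, "config") <- config
  list(traj = traj, presentations = do.call(rbind, pres),
       truth = do.call(rbind, truth))
}
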