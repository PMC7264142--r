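# Presentation validation, first-response detection and arrival events.
#
# Responses and arrivals are scored inside a 20-s (500-frame) window after
# stimulus onset. The response criteria (orientation below a bearing
# threshold plus a sustained speed surge over the pre-stimulus median) are
# an explicit, configurable reconstruction; their adequacy is judged against
# the simulator's ground truth.

#' Response-detection criteria
#'
#' @slot maxWindowFrames scoring window after onset, frames (500 = 20 s).
#' @slot bearingThreshold orientation criterion, degrees.
#' @slot speedFactor surge criterion: multiple of the fish's pre-stimulus
#'   median speed.
#' @slot sustainFrames frames both criteria must hold consecutively.
#' @export
setClass("ResponseCriteria",
  representation(maxWindowFrames = "numeric", bearingThreshold = "numeric",
                 speedFactor = "numeric", sustainFrames = "numeric"),
  prototype(maxWindowFrames = 500, bearingThreshold = 30,
            speedFactor = 1.5, sustainFrames = 5))

setValidity("ResponseCriteria", function(object) {
  v <- c(object@maxWindowFrames, object@bearingThreshold,
         object@speedFactor, object@sustainFrames)
  if (any(v <= 0)) return("all criteria must be positive")
  TRUE
})

#' Construct response criteria
#'
#' @param maxWindowFrames scoring window length (default 500 frames = 20 s).
#' @param bearingThreshold degrees (default 30).
#' @param speedFactor speed-surge multiplier (default 1.5).
#' @param sustainFrames sustained frames required (default 5).
#' @return A [ResponseCriteria-class].
#' @export
responseCriteria <- function(maxWindowFrames = 500, bearingThreshold = 30,
                             speedFactor = 1.5, sustainFrames = 5) {
  new("ResponseCriteria", maxWindowFrames = maxWindowFrames,
      bearingThreshold = bearingThreshold, speedFactor = speedFactor,
      sustainFrames = sustainFrames)
}

#' Validate a stimulus presentation
#'
#' A presentation is valid when, at onset, every fish is at least
#' `minDistMM` from the port, every fish is on the half of the arena
#' opposite the port (split along the short axis), and the 13-frame
#' pre-stimulus window is fully tracked. Validation never raises; it flags.
#'
#' @param traj a [TrajectorySet-class].
#' @param onsetFrame stimulus onset frame.
#' @param portId port identifier in the trajectory's arena.
#' @param minDistMM minimum fish-stimulus distance (default 430 mm).
#' @param windowFrames pre-stimulus window checked for gaps (default 13).
#' @return list with `valid` (logical) and `reason` (`NA` or one of
#'   `"min-distance"`, `"same-half"`, `"tracking-gap"`).
#' @export
validatePresentation <- function(traj, onsetFrame, portId, minDistMM = 430,
                                 windowFrames = 13) {
  port <- portPosition(traj@arena, portId)
  want <- (onsetFrame - windowFrames):(onsetFrame - 1)
  ii <- match(want, traj@frames)
  if (anyNA(ii) || anyNA(traj@x[ii, , drop = FALSE]))
    return(list(valid = FALSE, reason = "tracking-gap"))
  i <- match(onsetFrame, traj@frames)
  if (is.na(i) || anyNA(traj@x[i, ]))
    return(list(valid = FALSE, reason = "tracking-gap"))
  p <- cbind(traj@x[i, ], traj@y[i, ])
  d <- sqrt((p[, 1] - port[1])^2 + (p[, 2] - port[2])^2)
  if (any(d < minDistMM))
    return(list(valid = FALSE, reason = "min-distance"))
  if (any(sign(p[, 1]) == sign(port[1])))
    return(list(valid = FALSE, reason = "same-half"))
  list(valid = TRUE, reason = NA_character_)
}

#' Detect responses to a stimulus presentation
#'
#' A fish responds at the first frame `t` in `(onset, onset + window]` at
#' which its bearing to the port is below `bearingThreshold` AND its speed
#' exceeds `speedFactor` times its own pre-stimulus median speed, with both
#' conditions holding for `sustainFrames` consecutive frames. The first
#' responder is the minimum-latency responder; latency ties break to the
#' lower fish index.
#'
#' @param traj a [TrajectorySet-class].
#' @param headings a [HeadingField-class].
#' @param onsetFrame stimulus onset frame.
#' @param portId port identifier.
#' @param criteria a [ResponseCriteria-class].
#' @return data.frame with one row per responding fish: `fishId`,
#'   `responseLatency` (frames), `first` (logical). Zero rows when nobody
#'   responds.
#' @export
detectResponses <- function(traj, headings, onsetFrame, portId,
                            criteria = responseCriteria()) {
  port <- portPosition(traj@arena, portId)
  n <- nFish(traj)
  win <- criteria@maxWindowFrames
  want <- (onsetFrame + 1):(onsetFrame + win)
  ii <- match(want, traj@frames)
  out <- data.frame(fishId = character(0), responseLatency = numeric(0),
                    first = logical(0))
  for (f in seq_len(n)) {
    pre <- windowSummary(headings@speed[, f], traj@frames, onsetFrame)
    if (is.na(pre)) next
    ok <- rep(FALSE, win)
    iv <- !is.na(ii)
    i2 <- ii[iv]
    p <- cbind(traj@x[i2, f], traj@y[i2, f])
    b <- bearingsToTarget(p, headings@hx[i2, f], headings@hy[i2, f], port)
    sp <- headings@speed[i2, f]
    ok[iv] <- !is.na(b) & b < criteria@bearingThreshold &
      !is.na(sp) & sp > criteria@speedFactor * pre
    # first start of a sustained run
    s <- criteria@sustainFrames
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    hit <- which(runs$values & runs$lengths >= s)
    if (length(hit) == 0) next
    lat <- starts[hit[1]]
    if (lat + s - 1 > win) next
    out <- rbind(out, data.frame(fishId = traj@fishIds[f],
                                 responseLatency = lat, first = FALSE))
  }
  if (nrow(out) > 0) {
    ord <- order(out$responseLatency, match(out$fishId, traj@fishIds))
    out <- out[ord, , drop = FALSE]
    out$first[1] <- TRUE
    rownames(out) <- NULL
  }
  out
}

#' Arrival events at the stimulus
#'
#' A fish arrives at the first frame within the 500-frame window at which
#' its distance to the port is at most two body lengths (per-fish measured
#' body length; the group mean is the fallback). Arrivals are ranked by
#' latency into `arrivalOrder`; simultaneous arrivals break ties by distance
#' at the shared frame, then by fish index.
#'
#' @param traj a [TrajectorySet-class].
#' @param onsetFrame stimulus onset frame.
#' @param portId port identifier.
#' @param maxWindowFrames scoring window (default 500).
#' @return data.frame `fishId, arrivalLatency, arrivalOrder` (zero rows when
#'   nobody arrives).
#' @export
arrivalEvents <- function(traj, onsetFrame, portId, maxWindowFrames = 500) {
  port <- portPosition(traj@arena, portId)
  n <- nFish(traj)
  bl <- traj@bodyLengthMM
  bl[is.na(bl)] <- mean(bl, na.rm = TRUE)
  want <- (onsetFrame + 1):(onsetFrame + maxWindowFrames)
  ii <- match(want, traj@frames)
  lat <- rep(NA_real_, n)
  tieDist <- rep(NA_real_, n)
  for (f in seq_len(n)) {
    iv <- which(!is.na(ii))
    d <- sqrt((traj@x[ii[iv], f] - port[1])^2 + (traj@y[ii[iv], f] - port[2])^2)
    hit <- which(!is.na(d) & d <= 2 * bl[f])
    if (length(hit) > 0) {
      lat[f] <- iv[hit[1]]
      tieDist[f] <- d[hit[1]]
    }
  }
  arr <- which(!is.na(lat))
  if (length(arr) == 0)
    return(data.frame(fishId = character(0), arrivalLatency = numeric(0),
                      arrivalOrder = integer(0)))
  ord <- arr[order(lat[arr], tieDist[arr], arr)]
  data.frame(fishId = traj@fishIds[ord], arrivalLatency = lat[ord],
             arrivalOrder = seq_along(ord))
}

#' Is the first responder also the first arriver?
#'
#' Across presentations, the observed proportion of cases in which the same
#' fish both responds first and arrives first, tested one-sided against the
#' chance expectation `1 / N` (exact binomial).
#'
#' @param firstResponder character vector, first responder per presentation.
#' @param firstArriver character vector, first arriver per presentation
#'   (same length).
#' @param groupSize group size `N` (default 8, null probability 0.125).
#' @return list with `observed` proportion, `expected` null probability,
#'   `n` presentations, and one-sided exact binomial `p`.
#' @export
firstResponderFirstArriver <- function(firstResponder, firstArriver,
                                       groupSize = 8) {
  keep <- !is.na(firstResponder) & !is.na(firstArriver)
  fr <- firstResponder[keep]
  fa <- firstArriver[keep]
  if (length(fr) == 0) stop("no presentations with both events")
  k <- sum(fr == fa)
  n <- length(fr)
  p0 <- 1 / groupSize
  bt <- stats::binom.test(k, n, p = p0, alternative = "greater")
  list(observed = k / n, expected = p0, n = n, p = bt$p.value)
}
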