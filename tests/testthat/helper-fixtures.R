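# Shared fixture builders. Everything is generated in code; no stored data.

# a TrajectorySet from position matrices (frames x fish), Cartesian mm
toyTraj <- function(x, y, arena = defaultArena(), bodyLengthMM = 27,
                    frames = NULL) {
  shoalsight:::makeTrajectorySet(as.matrix(x), as.matrix(y), arena = arena,
                                 bodyLengthMM = bodyLengthMM, frames = frames)
}

# straight-line swimmers: fish f moves from start[f, ] with velocity vel[f, ]
linearTraj <- function(start, vel, nFrames, arena = defaultArena(),
                       bodyLengthMM = 27) {
  n <- nrow(start)
  t <- seq_len(nFrames) - 1
  x <- sapply(seq_len(n), function(f) start[f, 1] + t * vel[f, 1])
  y <- sapply(seq_len(n), function(f) start[f, 2] + t * vel[f, 2])
  toyTraj(x, y, arena = arena, bodyLengthMM = bodyLengthMM)
}

# straight approach toward a target point, holding position on arrival
approachTraj <- function(start, speeds, target, nFrames,
                         arena = defaultArena(), bodyLengthMM = 27,
                         stopDist = 10) {
  n <- nrow(start)
  x <- matrix(NA_real_, nFrames, n)
  y <- matrix(NA_real_, nFrames, n)
  for (f in seq_len(n)) {
    v <- target - start[f, ]
    L <- sqrt(sum(v^2))
    u <- v / L
    s <- pmin((seq_len(nFrames) - 1) * speeds[f], max(L - stopDist, 0))
    x[, f] <- start[f, 1] + u[1] * s
    y[, f] <- start[f, 2] + u[2] * s
  }
  toyTraj(x, y, arena = arena, bodyLengthMM = bodyLengthMM)
}

# fish-state table for the vision module
mkStates <- function(x, y, angleDeg, bl = 27, valid = TRUE) {
  a <- angleDeg * pi / 180
  data.frame(fish = seq_along(x), x = x, y = y,
             hx = cos(a), hy = sin(a), bl = rep_len(bl, length(x)),
             valid = rep_len(valid, length(x)))
}

# write a long-format trajectory CSV; returns the path
writeTrajCSV <- function(d, path = tempfile(fileext = ".csv")) {
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}
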