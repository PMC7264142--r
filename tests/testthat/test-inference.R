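# Standardization, AICc multimodel inference, mixed-model contracts,
# Cook's filtering, repeatability, rank statistics.

test_that("standardization centres, scales, is idempotent and guards zero SD", {
  d <- data.frame(a = c(1, 2, 3), b = c(10, 20, 40))
  s <- standardize(d, c("a", "b"))
  expect_equal(s$a, c(-1, 0, 1))
  expect_equal(mean(s$b), 0, tolerance = 1e-12)
  expect_equal(stats::sd(s$b), 1, tolerance = 1e-12)
  s2 <- standardize(s, c("a", "b"))
  expect_equal(s2$a, s$a, tolerance = 1e-12)
  expect_error(standardize(data.frame(z = rep(4, 5)), "z"), "zero SD")
})

test_that("AICc follows the corrected formula and its limits", {
  expect_equal(aicc(-100, 3, 100), 206.25)
  aic <- -2 * (-50) + 2 * 4
  expect_gt(aicc(-50, 4, 30), aic)               # finite-n correction positive
  expect_equal(aicc(-50, 4, 1e9), aic, tolerance = 1e-6)
  expect_error(aicc(-10, 5, 6), "n > k")
})

test_that("Akaike weights and relative importance follow brute-force sums", {
  tab <- data.frame(model = c("(intercept)", "a", "b", "a + b"),
                    AICc = c(100, 100, 104, 106))
  wr <- weightsAndRI(tab, terms = c("a", "b"))
  expect_equal(wr$weights[1], wr$weights[2])
  d <- tab$AICc - 100
  wRef <- exp(-d / 2) / sum(exp(-d / 2))
  expect_equal(wr$weights, wRef)
  expect_equal(unname(wr$ri["a"]), wRef[2] + wRef[4])
  expect_equal(unname(wr$ri["b"]), wRef[3] + wRef[4])
  expect_equal(sum(wr$weights), 1)
})

test_that("full model averaging: zero substitution, shrinkage, CI behaviour", {
  set.seed(34)
  n <- 300
  d <- data.frame(x1 = rnorm(n), x2 = rnorm(n), group = rep(1:6, 50))
  d$y <- 1.5 * d$x1 + rnorm(n)                   # x2 is pure noise
  cs <- fitCandidateSet("y", c("x1", "x2"), d, random = NULL)
  av <- fullModelAverage(cs)
  e1 <- av[av$parameter == "x1", ]
  expect_equal(e1$estimate, 1.5, tolerance = 0.15)
  expect_true(e1$lower < e1$estimate & e1$estimate < e1$upper)
  expect_gt(e1$ri, 0.95)
  # parameter present in every model with identical coefficient -> that value
  csA <- fitCandidateSet("y", c("x2"), d, random = NULL, always = "x1")
  avA <- fullModelAverage(csA)
  b <- sapply(csA$fits, function(f) f$coef["x1"])
  expect_equal(avA$estimate[avA$parameter == "x1"], sum(
    weightsAndRI(csA, terms = "x2")$weights * b), tolerance = 1e-9)
  # shrinkage: the full average of a sometimes-absent parameter is smaller
  # in magnitude than its conditional (present-models-only) average
  tabw <- weightsAndRI(cs)$weights
  has2 <- grepl("x2", cs$table$model)
  cond <- sum(tabw[has2] * sapply(cs$fits[has2], function(f) f$coef["x2"])) /
    sum(tabw[has2])
  full <- av$estimate[av$parameter == "x2"]
  expect_lte(abs(full), abs(cond) + 1e-12)
})

test_that("averaging arithmetic on a constructed half-weight split", {
  # two models with equal weight: one has beta = 2, the other omits it:
  # full average must be 1.0
  fits <- list(
    structure(list(coef = c("(Intercept)" = 0, b = 2),
                   se = c("(Intercept)" = 0.1, b = 0.3),
                   logLik = -10, k = 3, n = 50), class = "shoalFit"),
    structure(list(coef = c("(Intercept)" = 0),
                   se = c("(Intercept)" = 0.1),
                   logLik = -10, k = 2, n = 50), class = "shoalFit"))
  tab <- data.frame(model = c("b", "(intercept)"),
                    logLik = c(-10, -10), k = c(3, 2), n = 50,
                    AICc = c(120, 120))
  tab$delta <- 0; tab$weight <- 0.5
  cand <- structure(list(table = tab, fits = fits, terms = "b",
                         always = character(0), dropped = 0),
                    class = "candidateSet")
  av <- fullModelAverage(cand, cumWeight = 1)
  expect_equal(av$estimate[av$parameter == "b"], 1.0)
  expect_equal(av$ri[av$parameter == "b"], 0.5)
})

test_that("the model contract returns means, links and recovers LMM effects", {
  d <- data.frame(y = c(2, 4, 6, 8), group = c("a", "a", "b", "b"),
                  fish = c("1", "2", "3", "4"))
  f <- fitModel("y", character(0), d, random = NULL)
  expect_equal(unname(f$coef["(Intercept)"]), 5)
  db <- data.frame(y = rep(c(0, 1), 50))
  fb <- fitModel("y", character(0), db, family = "binomial", random = NULL)
  expect_equal(unname(fb$coef["(Intercept)"]), 0, tolerance = 1e-6)
  # parameter recovery: beta = 0.5 with nested random intercepts
  set.seed(35)
  cover <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    ng <- 12; nf <- 8; no <- 20
    d2 <- expand.grid(obs = 1:no, fish = 1:nf, group = 1:ng)
    d2$fish <- paste(d2$group, d2$fish)
    idEff <- stats::setNames(rnorm(ng * nf, 0, 1), unique(d2$fish))
    d2$x <- rnorm(nrow(d2))
    d2$y <- 0.5 * d2$x + idEff[d2$fish] + rnorm(nrow(d2))
    fr <- suppressWarnings(suppressMessages(
      fitModel("y", "x", d2, random = "(1|group/fish)")))
    ci <- fr$coef["x"] + c(-1.96, 1.96) * fr$se["x"]
    if (ci[1] <= 0.5 && 0.5 <= ci[2]) cover <- cover + 1
  }
  expect_gte(cover, 17)
})

test_that("non-convergent models are flagged and dropped from candidate sets", {
  d <- data.frame(y = rnorm(10), x = rnorm(10), group = "g1",
                  fish = rep(c("a", "b"), 5))
  f <- fitModel("y", "x", d, family = "negbin")   # negbin on gaussian noise
  if (!f$converged) expect_true(is.na(f$logLik) || !f$converged)
  expect_s3_class(f, "shoalFit")
})

test_that("Cook's filter removes a gross outlier and spares clean data", {
  set.seed(36)
  n <- 60
  d <- data.frame(x = rnorm(n))
  d$y <- 2 * d$x + rnorm(n, sd = 0.5)
  fit <- stats::lm(y ~ x, data = d)
  cf <- cooksFilter(fit, d, factor = 6)
  expect_equal(nrow(cf$removed), 0)
  d2 <- rbind(d, data.frame(x = 4, y = -20))      # gross outlier
  fit2 <- stats::lm(y ~ x, data = d2)
  cf2 <- cooksFilter(fit2, d2, factor = 6)
  expect_true(nrow(cf2$removed) >= 1)
  expect_true(61 %in% as.integer(rownames(cf2$removed)))
  # the merMod branch also runs and reports distances
  d2$group <- rep(c("a", "b"), length.out = nrow(d2))
  d2$fish <- rep(letters[1:6], length.out = nrow(d2))
  fm <- fitModel("y", "x", d2, random = "(1|group)")
  cfm <- cooksFilter(fm, d2, factor = 6)
  expect_equal(length(cfm$cooks), nrow(d2))
  expect_true(nrow(cfm$removed) >= 1)
})

test_that("repeatability recovers variance ratios and is location invariant", {
  set.seed(37)
  mkData <- function(vid, vres, ng = 12, nf = 8, no = 20) {
    d <- expand.grid(obs = 1:no, fish = 1:nf, group = 1:ng)
    d$fish <- paste(d$group, d$fish)
    idEff <- stats::setNames(rnorm(ng * nf, 0, sqrt(vid)), unique(d$fish))
    d$y <- idEff[d$fish] + rnorm(nrow(d), 0, sqrt(vres))
    d
  }
  for (ratio in c(0.1, 0.25, 0.4)) {
    d <- mkData(ratio, 1 - ratio)
    r <- repeatability(d, "y", nBoot = 0)
    expect_lt(abs(r$R - ratio), 0.08)
  }
  # zero between-individual variance
  d0 <- mkData(0, 1)
  r0 <- repeatability(d0, "y", nBoot = 0)
  expect_lt(r0$R, 0.03)
  expect_gt(r0$p, 0.01)
  # location invariance + bootstrap CI brackets R
  d <- mkData(0.4, 0.6, ng = 6, nf = 4, no = 10)
  r1 <- repeatability(d, "y", nBoot = 30, seed = 1)
  d$y <- d$y + 100
  r2 <- repeatability(d, "y", nBoot = 0)
  expect_equal(r1$R, r2$R, tolerance = 1e-6)
  expect_true(r1$ci[1] <= r1$R + 0.02 && r1$R - 0.02 <= r1$ci[2])
})

test_that("Spearman wrapper matches the rank formula and flags bad input", {
  expect_equal(spearmanTest(1:10, (1:10)^2)$rs, 1)
  expect_equal(spearmanTest(1:10, -(1:10)^3)$rs, -1)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8)
  manual <- stats::cor(rank(x), rank(y))
  expect_equal(spearmanTest(x, y)$rs, manual, tolerance = 1e-12)
  expect_error(spearmanTest(rep(1, 5), 1:5), "constant")
})

test_that("model comparison flags polarization as an informative positive predictor of first-response latency", {
  set.seed(38)
  cfg <- simConfig()
  d <- do.call(rbind, lapply(1:6, function(g) {
    ws <- wAlignForPolarization(runif(24, 0.12, 0.95), cfg)
    b <- simulatePresentationBatch(cfg, ws, burninFrames = 400,
                                   groupId = paste0("g", g))
    trs <- smoothSavGol(b$traj)
    ps <- presentationSummary(trs, b$presentations)
    firstResponseTable(ps, groupId = paste0("g", g))
  }))
  d <- standardize(d, c("polarization", "groupBearingStimulus",
                        "centroidDistStimulus", "hullArea", "centroidSpeed"))
  cs <- suppressMessages(fitCandidateSet("firstResponseLatency",
                        c("polarization", "groupBearingStimulus",
                          "centroidDistStimulus", "hullArea", "centroidSpeed"),
                        d, family = "gaussian", random = "(1|group)",
                        transform = "log10"))
  av <- fullModelAverage(cs)
  ri <- weightsAndRI(cs)$ri
  expect_gt(av$estimate[av$parameter == "polarization"], 0)
  expect_gt(unname(ri["polarization"]), 0.3)
  expect_gt(unname(ri["groupBearingStimulus"]), 0.9)
})
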