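# Statistical layer: standardization, AICc multimodel inference with full
# model averaging and relative importance, mixed-model fitting contracts,
# Cook's-distance filtering, repeatability, and rank statistics.

#' Standardize columns to mean 0, SD 1
#'
#' @param data a data.frame.
#' @param cols character vector of numeric columns to standardize.
#' @return `data` with the named columns scaled; the original means and SDs
#'   are stored in `attr(, "scaling")` for back-mapping.
#' @export
standardize <- function(data, cols) {
  sc <- list()
  for (cc in cols) {
    x <- data[[cc]]
    m <- mean(x, na.rm = TRUE)
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("column '", cc, "' has zero SD; cannot standardize")
    data[[cc]] <- (x - m) / s
    sc[[cc]] <- c(mean = m, sd = s)
  }
  attr(data, "scaling") <- sc
  data
}

#' Small-sample corrected Akaike information criterion
#'
#' `AICc = -2 logLik + 2k + 2k(k+1) / (n - k - 1)`.
#'
#' @param loglik model log-likelihood.
#' @param k number of estimated parameters.
#' @param n sample size; must exceed `k + 1`.
#' @return the AICc value.
#' @examples
#' aicc(-100, 3, 100)  # 206.25
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit one mixed (or fixed-effect) model — the estimation contract
#'
#' Thin wrapper over `lme4` (and `lm`/`glm` when no random effects are
#' requested) returning the quantities the model-comparison layer needs:
#' log-likelihood, parameter count, fixed-effect estimates and SEs.
#' Gaussian models are fitted by ML (not REML) so that likelihoods are
#' comparable across fixed-effect structures.
#'
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms (may include `a:b`
#'   interactions); empty means intercept-only.
#' @param data a data.frame.
#' @param family `"gaussian"`, `"binomial"` or `"negbin"`.
#' @param random random-effects clause, e.g. `"(1|group/fish)"`; `NULL` for
#'   a fixed-effects model.
#' @param transform response transform: `"none"`, `"log10"` or `"sqrt"`.
#' @return list of class `"shoalFit"`: `fit`, `logLik`, `k`, `n`, `coef`,
#'   `se`, `family`, `formula`, `converged`.
#' @export
fitModel <- function(response, fixed = character(0), data,
                     family = c("gaussian", "binomial", "negbin"),
                     random = "(1|group/fish)",
                     transform = c("none", "log10", "sqrt")) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  data$.resp <- switch(transform,
                       none = data[[response]],
                       log10 = log10(data[[response]]),
                       sqrt = sqrt(data[[response]]))
  rhs <- if (length(fixed) == 0) "1" else paste(fixed, collapse = " + ")
  if (!is.null(random)) rhs <- paste(rhs, "+", random)
  fml <- stats::as.formula(paste(".resp ~", rhs))
  fit <- NULL
  converged <- TRUE
  res <- tryCatch({
    if (is.null(random)) {
      switch(family,
             gaussian = stats::lm(fml, data = data),
             binomial = stats::glm(fml, data = data, family = stats::binomial()),
             stop("negbin requires a random-effects clause here"))
    } else {
      switch(family,
             gaussian = lme4::lmer(fml, data = data, REML = FALSE),
             binomial = lme4::glmer(fml, data = data, family = stats::binomial()),
             negbin = lme4::glmer.nb(fml, data = data))
    }
  }, error = function(e) e)
  if (inherits(res, "error")) {
    return(structure(list(fit = NULL, logLik = NA_real_, k = NA_real_,
                          n = nrow(data), coef = NULL, se = NULL,
                          family = family, formula = fml,
                          converged = FALSE, message = conditionMessage(res)),
                     class = "shoalFit"))
  }
  fit <- res
  if (inherits(fit, "merMod")) {
    msgs <- fit@optinfo$conv$lme4$messages
    if (!is.null(msgs) && any(grepl("failed to converge", msgs)))
      converged <- FALSE
    cf <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  } else {
    cf <- stats::coef(fit)
    se <- sqrt(diag(stats::vcov(fit)))
  }
  ll <- stats::logLik(fit)
  structure(list(fit = fit, logLik = as.numeric(ll), k = attr(ll, "df"),
                 n = nrow(data), coef = cf, se = se, family = family,
                 formula = fml, converged = converged),
            class = "shoalFit")
}

#' @export
print.shoalFit <- function(x, ...) {
  cat(sprintf("shoalFit (%s): logLik %.2f, k %d, n %d, converged %s\n",
              x$family, x$logLik, as.integer(x$k), x$n, x$converged))
  invisible(x)
}

#' Fit all subsets of main effects as an AICc candidate set
#'
#' Fits every combination (2^k models) of the supplied main-effect terms,
#' optionally forcing some terms into every model, and ranks the set by
#' AICc with Akaike weights over the complete candidate set.
#'
#' @param response response column name.
#' @param terms main-effect terms to combine.
#' @param data a data.frame.
#' @param family,random,transform passed to [fitModel()].
#' @param always terms included in every model.
#' @return list of class `"candidateSet"`: `table` (one row per converged
#'   model: terms, logLik, k, n, AICc, delta, weight), `fits` (the
#'   `shoalFit` objects), `terms`, `dropped` (count of non-converged
#'   models).
#' @export
fitCandidateSet <- function(response, terms, data,
                            family = "gaussian", random = "(1|group/fish)",
                            transform = "none", always = character(0)) {
  k <- length(terms)
  subsets <- lapply(0:(2^k - 1), function(m) terms[bitwAnd(m, 2^(seq_len(k) - 1)) > 0])
  fits <- list(); rows <- list(); dropped <- 0
  for (s in seq_along(subsets)) {
    fx <- c(always, subsets[[s]])
    f <- fitModel(response, fx, data, family = family, random = random,
                  transform = transform)
    if (!f$converged || !is.finite(f$logLik)) { dropped <- dropped + 1; next }
    fits[[length(fits) + 1]] <- f
    rows[[length(rows) + 1]] <- data.frame(
      model = if (length(fx) == 0) "(intercept)" else paste(fx, collapse = " + "),
      logLik = f$logLik, k = f$k, n = f$n,
      AICc = aicc(f$logLik, f$k, f$n))
  }
  tab <- do.call(rbind, rows)
  tab$delta <- tab$AICc - min(tab$AICc)
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  structure(list(table = tab, fits = fits, terms = terms, always = always,
                 dropped = dropped),
            class = "candidateSet")
}

#' @export
print.candidateSet <- function(x, ...) {
  cat(sprintf("candidateSet: %d models over %d terms (%d dropped)\n",
              nrow(x$table), length(x$terms), x$dropped))
  ord <- order(x$table$AICc)
  print(utils::head(x$table[ord, c("model", "AICc", "delta", "weight")], 5),
        row.names = FALSE)
  invisible(x)
}

#' Akaike weights and relative importance
#'
#' Recomputes Akaike weights from the AICc column of a candidate table and
#' sums them over the models containing each parameter (relative
#' importance, computed on the complete candidate set).
#'
#' @param candidates a [fitCandidateSet()] result, or a data.frame with
#'   columns `model` and `AICc`.
#' @param terms parameter names (taken from the candidate set if omitted).
#' @return list with `weights` (per model) and `ri` (named, per parameter).
#' @export
weightsAndRI <- function(candidates, terms = NULL) {
  tab <- if (inherits(candidates, "candidateSet")) candidates$table else candidates
  if (is.null(terms))
    terms <- if (inherits(candidates, "candidateSet")) candidates$terms
             else stop("terms required for a bare table")
  delta <- tab$AICc - min(tab$AICc)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  inModel <- function(term, model) {
    parts <- trimws(strsplit(model, "+", fixed = TRUE)[[1]])
    term %in% parts
  }
  ri <- vapply(terms, function(tt)
    sum(w[vapply(tab$model, inModel, logical(1), term = tt)]), numeric(1))
  list(weights = w, ri = ri)
}

#' Full model averaging over the 95% cumulative-weight set
#'
#' Orders models by Akaike weight, keeps the smallest prefix whose
#' cumulative weight reaches `cumWeight`, renormalizes, and averages every
#' parameter over that subset with zero substituted where a parameter is
#' absent (full averaging, which shrinks weakly supported effects).
#' Unconditional SEs include the between-model variance component:
#' `se = sqrt(sum_m w_m (se_m^2 + (b_m - bbar)^2))`. Relative importance is
#' computed on the complete candidate set.
#'
#' @param candidates a [fitCandidateSet()] result.
#' @param ciLevel confidence level (default 0.95).
#' @param cumWeight cumulative-weight cutoff for the averaging subset
#'   (default 0.95).
#' @param unconditional include between-model variance in the SE (default
#'   `TRUE`; `FALSE` gives the conditional within-model SE only).
#' @return data.frame of class `"averagingResult"`, one row per parameter:
#'   `parameter, estimate, se, lower, upper, ri`; `attr(, "subsetSize")`
#'   gives the number of models averaged.
#' @export
fullModelAverage <- function(candidates, ciLevel = 0.95, cumWeight = 0.95,
                             unconditional = TRUE) {
  tab <- candidates$table
  fits <- candidates$fits
  ord <- order(tab$weight, decreasing = TRUE)
  cum <- cumsum(tab$weight[ord])
  nKeep <- which(cum >= cumWeight - 1e-12)[1]
  keep <- ord[seq_len(nKeep)]
  w <- tab$weight[keep] / sum(tab$weight[keep])
  params <- unique(unlist(lapply(fits[keep], function(f) names(f$coef))))
  params <- setdiff(params, "(Intercept)")
  ri <- weightsAndRI(candidates)$ri
  rows <- lapply(params, function(pp) {
    b <- vapply(fits[keep], function(f) {
      v <- f$coef[pp]; if (is.na(names(v)) || is.na(v)) 0 else unname(v)
    }, numeric(1))
    s <- vapply(fits[keep], function(f) {
      v <- f$se[pp]; if (is.null(v) || is.na(v)) 0 else unname(v)
    }, numeric(1))
    bbar <- sum(w * b)
    se <- if (unconditional) sqrt(sum(w * (s^2 + (b - bbar)^2)))
          else sqrt(sum(w * s^2))
    z <- stats::qnorm(1 - (1 - ciLevel) / 2)
    data.frame(parameter = pp, estimate = bbar, se = se,
               lower = bbar - z * se, upper = bbar + z * se,
               ri = if (pp %in% names(ri)) ri[[pp]] else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "subsetSize") <- nKeep
  class(out) <- c("averagingResult", class(out))
  out
}

#' Cook's-distance outlier filter
#'
#' Removes observations whose Cook's distance exceeds `factor` times the
#' mean Cook's distance of the fit. For `lm`/`glm` fits the standard
#' influence measures are used; for mixed models the fixed-effects
#' leverage-based analogue (hat values and conditional residuals) is
#' computed.
#'
#' @param fit a `shoalFit`, `lm`/`glm`, or `merMod` object.
#' @param data the data the model was fitted to.
#' @param factor exclusion multiplier (default 6).
#' @return list with `kept` and `removed` data.frames, and `cooks` (the
#'   distances). Errors if every row would be removed.
#' @export
cooksFilter <- function(fit, data, factor = 6) {
  f <- if (inherits(fit, "shoalFit")) fit$fit else fit
  if (inherits(f, "merMod")) {
    h <- stats::hatvalues(f)
    e <- stats::residuals(f)
    p <- length(lme4::fixef(f))
    s2 <- stats::sigma(f)^2
    cd <- (e^2 / (p * s2)) * h / (1 - h)^2
  } else {
    cd <- stats::cooks.distance(f)
  }
  thr <- factor * mean(cd, na.rm = TRUE)
  bad <- which(cd > thr)
  if (length(bad) == nrow(data)) stop("Cook's filter would remove every row")
  list(kept = data[setdiff(seq_len(nrow(data)), bad), , drop = FALSE],
       removed = data[bad, , drop = FALSE],
       cooks = cd, threshold = thr)
}

#' Behavioural repeatability from mixed-model variance components
#'
#' Fits `response ~ fixed + (1|group) + (1|group:fish)` and returns
#' `R = var_fish / (var_fish + var_group + var_residual)` (the group
#' component can be excluded from the denominator via `includeGroup`).
#' The p-value is a likelihood-ratio test of the individual-identity
#' intercept (boundary-corrected, chi-square df 1 halved); the CI is a
#' seeded parametric bootstrap.
#'
#' @param data a data.frame with columns `group` and `fish` (factors) plus
#'   the model variables.
#' @param response response column name.
#' @param fixed character vector of fixed-effect terms.
#' @param transform response transform (see [fitModel()]).
#' @param family `"gaussian"` or `"binomial"` (binomial uses the
#'   latent-scale residual variance pi^2 / 3).
#' @param includeGroup include the group variance in the denominator
#'   (default `TRUE`).
#' @param nBoot parametric bootstrap replicates for the CI (default 1000;
#'   0 skips the CI).
#' @param seed optional seed for the bootstrap.
#' @return list of class `"repeatabilityResult"`: `R`, `ci`, `p`,
#'   `varComponents`, `nBoot`.
#' @export
repeatability <- function(data, response, fixed = character(0),
                          transform = "none", family = "gaussian",
                          includeGroup = TRUE, nBoot = 1000, seed = NULL) {
  stopifnot(all(c("group", "fish") %in% names(data)))
  data$group <- factor(data$group)
  data$fish <- factor(data$fish)
  full <- fitModel(response, fixed, data, family = family,
                   random = "(1|group) + (1|group:fish)", transform = transform)
  red <- fitModel(response, fixed, data, family = family,
                  random = "(1|group)", transform = transform)
  if (!full$converged) stop("repeatability model did not converge")
  getR <- function(fit) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    vFish <- vc$vcov[vc$grp == "group:fish"][1]
    vGroup <- vc$vcov[vc$grp == "group"][1]
    vRes <- if (family == "binomial") pi^2 / 3 else vc$vcov[vc$grp == "Residual"][1]
    if (is.na(vGroup)) vGroup <- 0
    den <- vFish + vRes + if (includeGroup) vGroup else 0
    if (den <= 0) return(0)
    max(0, vFish) / den
  }
  R <- getR(full$fit)
  lrt <- max(0, 2 * (full$logLik - red$logLik))
  p <- 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  ci <- c(NA_real_, NA_real_)
  if (nBoot > 0) {
    if (!is.null(seed)) set.seed(seed)
    sims <- stats::simulate(full$fit, nsim = nBoot)
    Rb <- vapply(seq_len(nBoot), function(b) {
      d2 <- data
      d2$.resp <- sims[[b]]
      rf <- tryCatch(lme4::lmer(stats::as.formula(
        paste(".resp ~", if (length(fixed) == 0) "1" else
          paste(fixed, collapse = " + "),
          "+ (1|group) + (1|group:fish)")), data = d2, REML = FALSE),
        error = function(e) NULL)
      if (is.null(rf)) return(NA_real_)
      getR(rf)
    }, numeric(1))
    ci <- stats::quantile(Rb, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  }
  vc <- as.data.frame(lme4::VarCorr(full$fit))
  structure(list(R = R, ci = ci, p = p, lrt = lrt,
                 varComponents = vc, nBoot = nBoot),
            class = "repeatabilityResult")
}

#' @export
print.repeatabilityResult <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f (95%% CI %.3f-%.3f), LRT p = %.3g\n",
              x$R, x$ci[1], x$ci[2], x$p))
  invisible(x)
}

#' Spearman rank correlation
#'
#' Tie-corrected rank correlation with a two-sided p-value (asymptotic,
#' as appropriate at the sample sizes used here).
#'
#' @param x,y paired numeric vectors (pairs with `NA` are dropped).
#' @return list with `rs`, `p`, `n`.
#' @export
spearmanTest <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector; rank correlation undefined")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rs = unname(ct$estimate), p = ct$p.value, n = length(x))
}
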