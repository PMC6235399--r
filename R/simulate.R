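## Synthetic-data generator for the mutation- and gene-level designs, plus
## the type-I-error / power experiment harness.

#' Build a simulation configuration
#'
#' @param n sample count
#' @param level "mutation" or "gene"
#' @param rho1 mutation frequency (gene level: gene mutation frequency)
#' @param p loci per gene
#' @param beta effect size
#' @param family outcome family
#' @param gamma1,gamma0 call sensitivity/specificity (mutation level)
#' @param depthBetween \code{\link{NegBinParams}} for per-mutation mean
#'   depths
#' @param depthWithinPhi within-mutation depth overdispersion
#' @param wgsMode single-stage low-coverage depths (mean
#'   \code{wgsDepthMean}, overdispersion \code{depthWithinPhi})
#' @param wgsDepthMean mean depth under \code{wgsMode}
#' @param readCountModel \code{\link{ReadCountModel}} for alternative counts
#' @param seed RNG seed (mandatory)
#' @return a \code{\link{SimulationConfig}}
#' @export
simConfig <- function(n = 400, level = c("mutation", "gene"), rho1 = 0.05,
                      p = 10, beta = 0, family = c("gaussian", "binomial"),
                      gamma1 = 0.9, gamma0 = 0.98,
                      depthBetween = NegBinParams(113, 3.28),
                      depthWithinPhi = 1.9, wgsMode = FALSE,
                      wgsDepthMean = 40,
                      readCountModel = defaultReadCountModel(), seed) {
  new("SimulationConfig", n = as.integer(n), level = match.arg(level),
      rho1 = rho1, p = as.integer(p), beta = beta,
      family = match.arg(family), gamma1 = gamma1, gamma0 = gamma0,
      depthBetween = depthBetween, depthWithinPhi = depthWithinPhi,
      wgsMode = wgsMode, wgsDepthMean = wgsDepthMean,
      readCountModel = readCountModel, seed = as.integer(seed))
}

.simOutcome <- function(cfg, S) {
  x <- stats::rnorm(cfg@n)
  if (cfg@family == "gaussian") {
    Y <- 1 + x + cfg@beta * S + stats::rnorm(cfg@n)
  } else {
    Y <- stats::rbinom(cfg@n, 1, stats::plogis(-0.5 + x + cfg@beta * S))
  }
  list(Y = Y, X = matrix(x, ncol = 1L, dimnames = list(NULL, "x")))
}

## depths for one mutation across samples: two-stage in the exome design
## (per-mutation mean from depthBetween, per-sample NB around it), or
## single-stage NB(wgsDepthMean, depthWithinPhi) in wgsMode
.simDepths <- function(cfg) {
  if (cfg@wgsMode)
    return(stats::rnbinom(cfg@n, mu = cfg@wgsDepthMean,
                          size = cfg@depthWithinPhi))
  mu <- max(rnegbin(1L, cfg@depthBetween), 1)
  stats::rnbinom(cfg@n, mu = mu, size = cfg@depthWithinPhi)
}

## calls and alternative counts for one locus given true statuses/depths
.simCountsCalls <- function(S, D, rc, gamma1, gamma0) {
  n <- length(S)
  O <- rep(NA_integer_, n)
  A <- integer(n)
  hi <- D >= rc@d0
  pCall <- ifelse(S == 1L, gamma1, 1 - gamma0)
  O[hi] <- stats::rbinom(sum(hi), 1L, pCall[hi])
  for (s in 0:1) for (o in 0:1) {
    sel <- hi & S == s & O == o
    if (any(sel))
      A[sel] <- rbetabinom(sum(sel), D[sel], rc@highDepth[[paste0(s, o)]])
  }
  for (s in 0:1) {
    sel <- !hi & S == s
    if (any(sel))
      A[sel] <- rbetabinom(sum(sel), D[sel], rc@lowDepth[[as.character(s)]])
  }
  list(A = A, O = O)
}

#' Simulate one mutation with outcome and covariate
#'
#' Generates true statuses S ~ Bernoulli(rho1), a standard-normal covariate,
#' the outcome from the configured GLM, two-stage negative-binomial depths,
#' calls O from the (gamma1, gamma0) error model where depth >= d0, and
#' alternative counts A from the (S, O)- or S-indexed beta-binomial
#' components.
#'
#' @param cfg a \code{\link{SimulationConfig}} (level "mutation")
#' @param seed overrides \code{cfg@seed} when non-NULL
#' @return list with \code{site} (\code{\link{SiteData}}), \code{S} (true
#'   statuses), \code{Y}, \code{X}
#' @export
simulateMutationSite <- function(cfg, seed = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(if (is.null(seed)) cfg@seed else seed)
  S <- stats::rbinom(cfg@n, 1L, cfg@rho1)
  out <- .simOutcome(cfg, S)
  D <- .simDepths(cfg)
  ac <- .simCountsCalls(S, D, cfg@readCountModel, cfg@gamma1, cfg@gamma0)
  list(site = SiteData(ac$A, D, ac$O, siteId = "sim:1"),
       S = S, Y = out$Y, X = out$X)
}

#' Simulate one gene with outcome and covariate
#'
#' Per-locus true statuses are independent Bernoulli with success
#' probability \code{1 - (1 - rho1g)^(1/p)}, so the collapsed gene status
#' has frequency rho1g. Each locus draws its own mean depth, and its own
#' sensitivity from {0.9, 1} and specificity from {0.98, 1} with equal
#' probabilities; counts and calls then follow the mutation-level recipe.
#'
#' @param cfg a \code{\link{SimulationConfig}} (level "gene"; \code{rho1} is
#'   the gene mutation frequency)
#' @param seed overrides \code{cfg@seed} when non-NULL
#' @return list with \code{gene} (\code{\link{GeneData}}), \code{Sg} (true
#'   gene statuses), \code{Smat} (true per-locus statuses), \code{Y},
#'   \code{X}, \code{gamma1}, \code{gamma0} (per-locus draws)
#' @export
simulateGene <- function(cfg, seed = NULL) {
  stopifnot(is(cfg, "SimulationConfig"))
  set.seed(if (is.null(seed)) cfg@seed else seed)
  p <- cfg@p
  qLocus <- 1 - (1 - cfg@rho1)^(1 / p)
  Smat <- matrix(stats::rbinom(p * cfg@n, 1L, qLocus), p, cfg@n)
  Sg <- collapseTrueStatus(Smat)
  out <- .simOutcome(cfg, Sg)
  g1 <- sample(c(0.9, 1), p, replace = TRUE)
  g0 <- sample(c(0.98, 1), p, replace = TRUE)
  A <- matrix(0L, p, cfg@n); D <- matrix(0L, p, cfg@n)
  O <- matrix(NA_integer_, p, cfg@n)
  for (j in seq_len(p)) {
    D[j, ] <- .simDepths(cfg)
    ac <- .simCountsCalls(Smat[j, ], D[j, ], cfg@readCountModel,
                          g1[j], g0[j])
    A[j, ] <- ac$A; O[j, ] <- ac$O
  }
  list(gene = GeneData(A, D, O, geneId = "simgene"),
       Sg = Sg, Smat = Smat, Y = out$Y, X = out$X,
       gamma1 = g1, gamma0 = g0)
}

#' Run a type-I-error / power experiment
#'
#' Generates \code{reps} independent replicates from \code{cfg}, runs each
#' requested method on every replicate, and aggregates rejection rates at
#' level \code{xi} with Monte-Carlo standard errors, plus the mean and MSE
#' of the effect estimates. Within a replicate all methods see the same
#' dataset. Replicate-level failures (errors or NA p-values) are counted
#' and excluded from the rates, not fatal.
#'
#' @param cfg a \code{\link{SimulationConfig}}; its \code{seed} spawns one
#'   sub-seed per replicate
#' @param reps number of replicates (>= 50)
#' @param methods subset of "mSAME", "gSAME", "GLM" (defaults by level)
#' @param xi significance level
#' @param ce plug-in \code{\link{CallErrorModel}} for mSAME; when NULL the
#'   generating (gamma1, gamma0) are used (gene level always estimates per
#'   locus)
#' @return a data.frame with one row per method: rejections, valid
#'   replicates, rejection rate, MC standard error, mean and MSE of the
#'   effect estimate, failures
#' @export
runExperiment <- function(cfg, reps, methods = NULL, xi = 0.05, ce = NULL) {
  stopifnot(is(cfg, "SimulationConfig"), reps >= 50)
  if (is.null(methods))
    methods <- if (cfg@level == "gene") c("gSAME", "GLM")
               else c("mSAME", "GLM")
  set.seed(cfg@seed)
  repSeeds <- sample.int(.Machine$integer.max - 1L, reps)
  if (is.null(ce) && cfg@level == "mutation")
    ce <- CallErrorModel(cfg@gamma1, cfg@gamma0)
  pv <- matrix(NA_real_, reps, length(methods),
               dimnames = list(NULL, methods))
  bh <- pv
  for (r in seq_len(reps)) {
    if (cfg@level == "mutation") {
      sim <- simulateMutationSite(cfg, seed = repSeeds[r])
      for (m in methods) {
        res <- tryCatch(switch(m,
          mSAME = msameTest(sim$site, sim$Y, sim$X, cfg@readCountModel,
                            ce, cfg@family),
          GLM = glmWaldTest(sim$site@O, sim$Y, sim$X, cfg@family),
          stop("unknown method ", m)), error = function(e) NULL)
        if (is.null(res)) next
        pv[r, m] <- res@pvalue
        bh[r, m] <- if (is(res, "SameTest")) res@fitAlt@outcome@beta
                    else res@betaHat
      }
    } else {
      sim <- simulateGene(cfg, seed = repSeeds[r])
      for (m in methods) {
        res <- tryCatch(switch(m,
          gSAME = gsameTest(sim$gene, sim$Y, sim$X, cfg@readCountModel,
                            family = cfg@family),
          GLM = glmWaldTest(collapseObservedCalls(sim$gene@O), sim$Y,
                            sim$X, cfg@family),
          stop("unknown method ", m)), error = function(e) NULL)
        if (is.null(res)) next
        pv[r, m] <- res@pvalue
        bh[r, m] <- if (is(res, "SameTest")) res@fitAlt@outcome@beta
                    else res@betaHat
      }
    }
  }
  rows <- lapply(methods, function(m) {
    ok <- !is.na(pv[, m])
    nOk <- sum(ok)
    rate <- if (nOk) mean(pv[ok, m] < xi) else NA_real_
    data.frame(method = m, reps = reps, valid = nOk,
               rejections = sum(pv[ok, m] < xi), rate = rate,
               mcse = if (nOk) sqrt(rate * (1 - rate) / nOk) else NA_real_,
               betaMean = mean(bh[ok, m]),
               betaMSE = mean((bh[ok, m] - cfg@beta)^2),
               failures = reps - nOk)
  })
  out <- do.call(rbind, rows)
  attr(out, "pvalues") <- pv
  attr(out, "betaHat") <- bh
  attr(out, "xi") <- xi
  out
}
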