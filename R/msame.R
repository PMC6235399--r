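## Mutation-level latent-status association test (mSAME).
##
## The observed-data likelihood for one mutation is
##   L = prod_i sum_{s=0,1} rho_s f_Y(Y_i | S_i=s) f(A_i, D_i, O_i | S_i=s),
## with f(A,D,O|S) factored into a beta-binomial for A given (D, S, O) at
## depth >= d0 (plus a Bernoulli call-error term for O given S) and a
## beta-binomial for A given (D, S) below d0, where O is missing. Depth D is
## ancillary (its law does not involve S) and cancels from all likelihood
## ratios. The model is fitted by EM over the latent S and tested by a
## likelihood-ratio statistic against beta = 0 with a chi-square(1)
## reference.

.logsumexp2 <- function(l0, l1) {
  m <- pmax(l0, l1)
  out <- m + log(exp(l0 - m) + exp(l1 - m))
  out[l0 == -Inf & l1 == -Inf] <- -Inf
  out
}

#' Per-sample evidence log-likelihood for one mutation
#'
#' For each sample, the log of f(A_i, D_i, O_i | S_i = s) for s = 0 and 1.
#' At depth >= d0 this is the (S, O)-stratum beta-binomial for A plus the
#' Bernoulli call term P(O | S); below d0 the call is missing and only the
#' status-indexed low-depth beta-binomial enters.
#'
#' @param site a \code{\link{SiteData}}
#' @param rc a \code{\link{ReadCountModel}}
#' @param ce a \code{\link{CallErrorModel}}
#' @return a 2-column matrix (columns s = 0, s = 1) of log evidence
#' @export
evidenceLoglik <- function(site, rc, ce) {
  stopifnot(is(site, "SiteData"), is(rc, "ReadCountModel"),
            is(ce, "CallErrorModel"))
  n <- length(site@D)
  hi <- site@D >= rc@d0
  if (any(hi & is.na(site@O)))
    stop("site ", site@siteId, ": call missing at depth >= d0 (sample ",
         paste(which(hi & is.na(site@O)), collapse = ", "), ")")
  if (any(!hi & !is.na(site@O)))
    stop("site ", site@siteId, ": call present at depth < d0; ",
         "coerce to missing on load")
  out <- matrix(0, n, 2L, dimnames = list(NULL, c("s0", "s1")))
  ## Bernoulli call factors: P(O|S=0) = gamma0^(1-O) (1-gamma0)^O,
  ##                         P(O|S=1) = gamma1^O (1-gamma1)^(1-O)
  for (o in 0:1) {
    sel <- hi & site@O == o
    if (!any(sel)) next
    out[sel, 1L] <- dbetabinomLog(site@A[sel], site@D[sel],
                                  rc@highDepth[[paste0("0", o)]]) +
      log(if (o == 1L) 1 - ce@gamma0 else ce@gamma0)
    out[sel, 2L] <- dbetabinomLog(site@A[sel], site@D[sel],
                                  rc@highDepth[[paste0("1", o)]]) +
      log(if (o == 1L) ce@gamma1 else 1 - ce@gamma1)
  }
  if (any(!hi)) {
    out[!hi, 1L] <- dbetabinomLog(site@A[!hi], site@D[!hi], rc@lowDepth[["0"]])
    out[!hi, 2L] <- dbetabinomLog(site@A[!hi], site@D[!hi], rc@lowDepth[["1"]])
  }
  out
}

#' Estimate per-mutation call sensitivity and specificity
#'
#' Posterior-weighted concordance between calls and the read-count evidence:
#' with w_i = P(S_i = 1 | A_i, D_i) from a two-component beta-binomial
#' mixture (components taken from the read-count model's (0,0) and (1,1)
#' strata, mixing proportion re-estimated by EM), the estimates are
#' gamma1 = sum(w O) / sum(w) and gamma0 = sum((1-w)(1-O)) / sum(1-w) over
#' high-depth samples, clipped into (0.5, 1].
#'
#' @param site a \code{\link{SiteData}}
#' @param rc a \code{\link{ReadCountModel}}
#' @return a \code{\link{CallErrorModel}}
#' @export
estimateCallError <- function(site, rc) {
  stopifnot(is(site, "SiteData"), is(rc, "ReadCountModel"))
  hi <- site@D >= rc@d0 & !is.na(site@O)
  if (!any(hi)) stop("no samples with depth >= d0")
  a <- site@A[hi]; d <- site@D[hi]; o <- site@O[hi]
  mix <- .betabinomMixture(a, d, rc@highDepth[["00"]], rc@highDepth[["11"]],
                           rho1 = max(mean(o), 1 / length(o)),
                           updateComponents = FALSE, maxIter = 50)
  w <- mix$posterior
  clip <- function(g) min(max(g, 0.5 + 1e-6), 1)
  if (sum(w) < 1e-8) {
    warning("site ", site@siteId,
            ": no mutated samples to assess; sensitivity set to 1")
    g1 <- 1
  } else g1 <- sum(w * o) / sum(w)
  if (sum(1 - w) < 1e-8) {
    warning("site ", site@siteId,
            ": no unmutated samples to assess; specificity set to 1")
    g0 <- 1
  } else g0 <- sum((1 - w) * (1 - o)) / sum(1 - w)
  CallErrorModel(gamma1 = clip(g1), gamma0 = clip(g0))
}

## ---- EM machinery shared by the mutation- and gene-level models ----

## outcome log-density columns for s = 0 and s = 1 under current parameters
.outcomeLL <- function(Y, Xmat, fam, alpha, beta, disp) {
  eta0 <- drop(Xmat %*% alpha)
  if (fam == "gaussian") {
    cbind(stats::dnorm(Y, eta0, sqrt(disp), log = TRUE),
          stats::dnorm(Y, eta0 + beta, sqrt(disp), log = TRUE))
  } else {
    cbind(stats::dbinom(Y, 1, stats::plogis(eta0), log = TRUE),
          stats::dbinom(Y, 1, stats::plogis(eta0 + beta), log = TRUE))
  }
}

## Weighted GLM M-step on the augmented design (each sample contributes an
## s=0 row with weight 1-w and an s=1 row with weight w). With betaFixed
## the status effect enters as a fixed offset and only alpha (and the
## dispersion) are re-estimated.
.glmMstep <- function(Y, Xmat, w, fam, betaFixed = NULL) {
  n <- length(Y)
  ## a posterior with all mass on one status leaves beta unidentified;
  ## freeze it at 0 and let the caller flag the site as monomorphic
  if (is.null(betaFixed) && (sum(w) < 1e-8 || sum(1 - w) < 1e-8))
    betaFixed <- 0
  s <- rep(c(0, 1), each = n)
  yaug <- c(Y, Y)
  waug <- c(1 - w, w)
  keep <- waug > 1e-12
  if (is.null(betaFixed)) {
    Xaug <- cbind(rbind(Xmat, Xmat), status = s)
    off <- rep(0, 2L * n)
  } else {
    Xaug <- rbind(Xmat, Xmat)
    off <- s * betaFixed
  }
  if (fam == "gaussian") {
    fit <- stats::lm.wfit(Xaug[keep, , drop = FALSE],
                          (yaug - off)[keep], waug[keep])
    cf <- fit$coefficients
    disp <- max(sum(waug[keep] * fit$residuals^2) / n, 1e-12)
  } else {
    fit <- suppressWarnings(
      stats::glm.fit(Xaug[keep, , drop = FALSE], yaug[keep],
                     weights = waug[keep], offset = off[keep],
                     family = stats::binomial()))
    cf <- fit$coefficients
    disp <- 1
  }
  if (anyNA(cf)) stop("singular design in M-step")
  p <- ncol(Xmat)
  list(alpha = unname(cf[seq_len(p)]),
       beta = if (is.null(betaFixed)) unname(cf[p + 1L]) else betaFixed,
       dispersion = disp)
}

.designMatrix <- function(X, n) {
  if (is.null(X)) return(matrix(1, n, 1L, dimnames = list(NULL, "intercept")))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("covariate rows do not match outcome length")
  cbind(intercept = 1, X)
}

## EM initialization: rho1 by method-of-moments from calls through the error
## model, coefficients from the naive GLM on observed calls (missing -> 0).
.emInit <- function(Y, Xmat, O, fam, ce) {
  n <- length(Y)
  oc <- ifelse(is.na(O), 0L, O)
  r <- (mean(oc) - (1 - ce@gamma0)) / (ce@gamma1 + ce@gamma0 - 1)
  r <- min(max(r, 1 / n), 1 - 1 / n)
  Xa <- cbind(Xmat, status = oc)
  cf <- tryCatch({
    if (fam == "gaussian") stats::lm.fit(Xa, Y)$coefficients
    else suppressWarnings(
      stats::glm.fit(Xa, Y, family = stats::binomial())$coefficients)
  }, error = function(e) NULL)
  if (is.null(cf) || anyNA(cf))
    cf <- c(rep(0, ncol(Xmat)), 0)
  p <- ncol(Xmat)
  list(rho1 = r, alpha = unname(cf[seq_len(p)]), beta = unname(cf[p + 1L]),
       dispersion = if (fam == "gaussian") max(stats::var(Y), 1e-6) else 1)
}

## Core EM over a per-sample 2-column evidence matrix; used directly by
## msameFit and (with gene-level evidence recomputed per iteration) mirrored
## in gsameFit.
.emLatentStatus <- function(Y, Xmat, evid, fam, init, betaFixed = NULL,
                            tol = 1e-8, maxIter = 1000L) {
  rho1 <- init$rho1; alpha <- init$alpha
  beta <- if (is.null(betaFixed)) init$beta else betaFixed
  disp <- init$dispersion
  n <- length(Y)
  trace <- numeric(0)
  ll <- -Inf; conv <- FALSE; w <- rep(NA_real_, n)
  for (it in seq_len(maxIter)) {
    ly <- .outcomeLL(Y, Xmat, fam, alpha, beta, disp)
    l0 <- log(1 - rho1) + ly[, 1L] + evid[, 1L]
    l1 <- log(rho1) + ly[, 2L] + evid[, 2L]
    den <- .logsumexp2(l0, l1)
    newll <- sum(den)
    if (!is.finite(newll))
      stop("non-finite log-likelihood at EM iteration ", it)
    w <- exp(l1 - den)
    trace <- c(trace, newll)
    if (is.finite(ll) && abs(newll - ll) < tol) { ll <- newll; conv <- TRUE; break }
    ll <- newll
    ms <- .glmMstep(Y, Xmat, w, fam, betaFixed)
    alpha <- ms$alpha; beta <- ms$beta; disp <- ms$dispersion
    rho1 <- min(max(mean(w), 1e-8), 1 - 1e-8)
  }
  list(rho1 = rho1, alpha = alpha, beta = beta, dispersion = disp,
       loglik = ll, trace = trace, nIter = length(trace),
       converged = conv, posterior = w)
}

.asSameFit <- function(em, fam, level) {
  new("SameFit",
      outcome = OutcomeModel(fam, alpha = em$alpha, beta = em$beta,
                             dispersion = em$dispersion),
      rho1 = em$rho1, loglik = em$loglik, loglikTrace = em$trace,
      nIter = as.integer(em$nIter), converged = em$converged,
      posterior = em$posterior, level = level)
}

#' Fit the mutation-level latent-status model by EM
#'
#' Maximizes the observed-data likelihood over the outcome GLM coefficients,
#' the outcome dispersion (gaussian) and the latent-status prior rho1, with
#' the read-count and call-error models plugged in (estimated a priori and
#' held fixed). The E-step computes per-sample posterior mutation
#' probabilities; the M-step is a weighted GLM on the augmented design.
#'
#' @param site a \code{\link{SiteData}}
#' @param Y outcome vector (numeric; 0/1 for binomial)
#' @param X covariate matrix without intercept (or NULL)
#' @param rc a \code{\link{ReadCountModel}}
#' @param ce a \code{\link{CallErrorModel}}; estimated from the site via
#'   \code{\link{estimateCallError}} when NULL
#' @param family "gaussian" or "binomial"
#' @param betaFixed fix the mutation effect (0 for the null fit); NULL to
#'   estimate it
#' @param tol EM convergence tolerance on the log-likelihood
#' @param maxIter maximum EM iterations (non-convergence is reported, not an
#'   error)
#' @return a \code{\link{SameFit}}
#' @export
msameFit <- function(site, Y, X = NULL, rc = defaultReadCountModel(),
                     ce = NULL, family = c("gaussian", "binomial"),
                     betaFixed = NULL, tol = 1e-8, maxIter = 1000L) {
  family <- match.arg(family)
  if (is.null(ce)) ce <- estimateCallError(site, rc)
  n <- length(Y)
  if (length(site@D) != n) stop("outcome length does not match site samples")
  Xmat <- .designMatrix(X, n)
  evid <- evidenceLoglik(site, rc, ce)
  init <- .emInit(Y, Xmat, site@O, family, ce)
  em <- .emLatentStatus(Y, Xmat, evid, family, init, betaFixed,
                        tol = tol, maxIter = maxIter)
  .asSameFit(em, family, "mutation")
}

.lrtFromFits <- function(fitAlt, fitNull, id) {
  Tstat <- -2 * (fitNull@loglik - fitAlt@loglik)
  note <- ""
  if (Tstat < 0) {
    note <- sprintf("negative statistic %.3g clipped to 0", Tstat)
    Tstat <- 0
  }
  w <- fitAlt@posterior
  if (all(w < 1e-10) || all(w > 1 - 1e-10)) {
    return(new("SameTest", statistic = NA_real_, df = 1,
               pvalue = NA_real_, fitAlt = fitAlt, fitNull = fitNull,
               id = id,
               note = "monomorphic: posterior mass all on one status"))
  }
  new("SameTest", statistic = Tstat, df = 1,
      pvalue = stats::pchisq(Tstat, df = 1, lower.tail = FALSE),
      fitAlt = fitAlt, fitNull = fitNull, id = id, note = note)
}

#' Mutation-level likelihood-ratio test (mSAME)
#'
#' Fits the latent-status model with and without the mutation effect and
#' returns T = -2 (loglik_null - loglik_alt) with its chi-square(1)
#' upper-tail p-value. Monomorphic sites (posterior mass entirely on one
#' status) return an NA p-value with a diagnostic note.
#'
#' @inheritParams msameFit
#' @return a \code{\link{SameTest}}
#' @examples
#' set.seed(1)
#' cfg <- simConfig(n = 120, rho1 = 0.2, beta = 1, seed = 1)
#' sim <- simulateMutationSite(cfg)
#' msameTest(sim$site, sim$Y, sim$X, cfg@readCountModel,
#'           CallErrorModel(0.9, 0.98))
#' @export
msameTest <- function(site, Y, X = NULL, rc = defaultReadCountModel(),
                      ce = NULL, family = c("gaussian", "binomial"),
                      tol = 1e-8, maxIter = 1000L) {
  family <- match.arg(family)
  if (is.null(ce)) ce <- estimateCallError(site, rc)
  fitAlt <- tryCatch(
    msameFit(site, Y, X, rc, ce, family, betaFixed = NULL,
             tol = tol, maxIter = maxIter),
    error = function(e) stop("site ", site@siteId, ": ", conditionMessage(e),
                             call. = FALSE))
  fitNull <- tryCatch(
    msameFit(site, Y, X, rc, ce, family, betaFixed = 0,
             tol = tol, maxIter = maxIter),
    error = function(e) stop("site ", site@siteId, ": ", conditionMessage(e),
                             call. = FALSE))
  .lrtFromFits(fitAlt, fitNull, site@siteId)
}
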