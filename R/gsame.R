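## Gene-level latent-status association test (gSAME).
##
## The gene-level status S^g collapses the per-locus latent statuses S^m by
## "any mutation": S^g = 1 iff some S^m_j = 1. The observed-data likelihood
## sums, per sample, over S^g = 0 (all loci unmutated) and S^g = 1, where
## the per-locus configuration is marginalized over the admissible non-zero
## status vectors. A locus can be mutated in a sample only if its
## alternative-allele count is positive, so the configuration sum runs over
## the 2^m_i - 1 non-zero vectors on the m_i "active" loci (A > 0); this is
## the computational device that keeps the enumeration tractable.

#' Collapse per-locus true statuses to a gene status
#'
#' Gene status is 1 if one or more loci are mutated.
#'
#' @param s per-locus statuses in {0, 1} (vector, or p x n matrix collapsed
#'   column-wise)
#' @return 0/1 gene status (per sample for a matrix)
#' @export
collapseTrueStatus <- function(s) {
  if (is.matrix(s)) return(as.integer(apply(s, 2L, max)))
  as.integer(max(s))
}

#' Collapse observed per-locus calls to a gene call
#'
#' Observed gene-level call: 1 if any observed locus call is 1; missing
#' calls are treated as 0. When every call is missing the result is 0 and
#' the \code{"lowCoverage"} attribute flags it.
#'
#' @param o per-locus calls in {0, 1, NA} (vector, or p x n matrix collapsed
#'   column-wise)
#' @return 0/1 gene call(s) with a logical \code{lowCoverage} attribute
#' @export
collapseObservedCalls <- function(o) {
  if (is.matrix(o)) {
    val <- as.integer(apply(o, 2L, function(col) any(col == 1L, na.rm = TRUE)))
    attr(val, "lowCoverage") <- apply(o, 2L, function(col) all(is.na(col)))
    return(val)
  }
  val <- as.integer(any(o == 1L, na.rm = TRUE))
  attr(val, "lowCoverage") <- all(is.na(o))
  val
}

.DEAD_SAMPLE <- -1e8    # per-sample log-likelihood below this means
                        # zero support under both gene-status branches

## all non-zero 0/1 vectors of length m, as a (2^m - 1) x m matrix;
## memoized since only small m occur
.configCache <- new.env(parent = emptyenv())
.nonzeroConfigs <- function(m) {
  key <- as.character(m)
  if (!is.null(.configCache[[key]])) return(.configCache[[key]])
  grid <- as.matrix(expand.grid(rep(list(0:1), m)))[-1L, , drop = FALSE]
  dimnames(grid) <- NULL
  storage.mode(grid) <- "integer"
  .configCache[[key]] <- grid
  grid
}

#' Enumerate admissible latent configurations for one sample
#'
#' Loci with zero alternative reads are pinned to S = 0; the remaining
#' "active" loci are enumerated over their 2^m - 1 non-zero status vectors
#' (the S^g = 1 branch). With no active locus the branch is impossible and
#' an empty enumeration is returned.
#'
#' @param aRow per-locus alternative counts for one sample
#' @param cap maximum number of active loci (enumeration guard)
#' @return list with \code{active} (indices of active loci) and
#'   \code{configs} (matrix of non-zero status vectors over the active loci)
#' @export
enumerateConfigs <- function(aRow, cap = 12L) {
  if (any(aRow < 0)) stop("counts must be non-negative")
  active <- which(aRow > 0)
  m <- length(active)
  if (m > cap)
    stop(m, " active loci exceed the enumeration cap (", cap,
         "); pre-filter loci before gene-level testing")
  configs <- if (m == 0L) matrix(integer(0), 0L, 0L) else .nonzeroConfigs(m)
  list(active = active, configs = configs)
}

#' Configuration prior given a mutated gene
#'
#' Conditional on S^g = 1, per-locus statuses on the active loci are
#' independent Bernoulli(q) renormalized to exclude the all-zero vector, so
#' the enumerated configurations have probabilities proportional to
#' prod q^{c_j} (1-q)^{1-c_j} and sum to one.
#'
#' @param configs matrix of non-zero status vectors (rows)
#' @param q per-locus inclusion probability/ies, in (0, 1)
#' @return per-row probabilities summing to 1
#' @export
configPrior <- function(configs, q) {
  m <- ncol(configs)
  q <- rep_len(q, m)
  if (any(q <= 0 | q >= 1)) stop("inclusion probabilities must be in (0, 1)")
  lp <- configs %*% log(q) + (1L - configs) %*% log(1 - q)
  p <- exp(drop(lp))
  p / sum(p)
}

## ---- gene-level evidence, precomputed once per gene ----

## Per-locus two-column evidence logliks, the all-zero baseline, and the
## flattened configuration table. Everything except the configuration prior
## is free of the model parameters, so the EM only reweights these rows.
.geneEvidence <- function(gene, rc, ceList, restrict = TRUE, cap = 12L) {
  p <- nrow(gene@D); n <- ncol(gene@D)
  stopifnot(length(ceList) == p)
  l0 <- matrix(0, p, n); l1 <- matrix(0, p, n)
  for (j in seq_len(p)) {
    sd <- SiteData(gene@A[j, ], gene@D[j, ], gene@O[j, ],
                   siteId = gene@siteIds[j])
    ev <- evidenceLoglik(sd, rc, ceList[[j]])
    l0[j, ] <- ev[, 1L]; l1[j, ] <- ev[, 2L]
  }
  ## zero-probability components (calls conflicting with an error rate of
  ## exactly 1) are clamped to a large negative log so that configuration
  ## products stay finite; a sample dead under both branches then surfaces
  ## as a per-sample log-likelihood below .DEAD_SAMPLE and is diagnosed
  l0[l0 == -Inf] <- -1e9
  l1[l1 == -Inf] <- -1e9
  base0 <- colSums(l0)              # log evidence of the all-zero vector
  sampleIdx <- integer(0); kOnes <- integer(0); mAct <- integer(0)
  logEvid <- numeric(0)
  rowsOf <- vector("list", n)
  pos <- 0L
  for (i in seq_len(n)) {
    act <- if (restrict) which(gene@A[, i] > 0L) else seq_len(p)
    m <- length(act)
    if (m > cap)
      stop("sample ", i, ": ", m, " active loci exceed the enumeration cap (",
           cap, "); pre-filter loci before gene-level testing")
    if (m == 0L) { rowsOf[[i]] <- integer(0); next }
    cfg <- .nonzeroConfigs(m)
    k <- nrow(cfg)
    ## direct sum per configuration (not base0 + deltas): components with
    ## zero probability (e.g. a positive call under specificity 1 and S=0)
    ## make l0 = -Inf, which must propagate, not cancel
    inact <- if (m == p) 0 else sum(l0[-act, i])
    le <- inact + drop(cfg %*% l1[act, i] + (1L - cfg) %*% l0[act, i])
    idx <- pos + seq_len(k)
    rowsOf[[i]] <- idx
    sampleIdx <- c(sampleIdx, rep.int(i, k))
    kOnes <- c(kOnes, as.integer(rowSums(cfg)))
    mAct <- c(mAct, rep.int(m, k))
    logEvid <- c(logEvid, le)
    pos <- pos + k
  }
  list(p = p, n = n, base0 = base0, rowsOf = rowsOf,
       sampleIdx = sampleIdx, kOnes = kOnes, mAct = mAct, logEvid = logEvid)
}

## log marginal evidence of the S^g = 1 branch per sample, under common
## per-locus inclusion probability q (renormalized over non-zero configs of
## each sample's active loci); samples with no active locus get -Inf.
.geneBranch1 <- function(ge, q) {
  out <- rep(-Inf, ge$n)
  if (!length(ge$logEvid)) return(out)
  lq <- log(q); l1q <- log1p(-q)
  v <- ge$logEvid + ge$kOnes * lq + (ge$mAct - ge$kOnes) * l1q -
    log1p(-(1 - q)^ge$mAct)
  for (i in seq_len(ge$n)) {
    ix <- ge$rowsOf[[i]]
    if (!length(ix)) next
    m <- max(v[ix])
    out[i] <- m + log(sum(exp(v[ix] - m)))
  }
  out
}

#' Gene-level observed-data log-likelihood
#'
#' Evaluates the gene-level likelihood at given outcome-model parameters and
#' gene mutation frequency: per sample, the S^g = 0 branch (all loci
#' unmutated) plus the S^g = 1 branch marginalized over admissible
#' configurations with the common-q Bernoulli prior, where
#' q = 1 - (1 - rho1g)^(1/p). Stabilized by log-sum-exp.
#'
#' @param gene a \code{\link{GeneData}}
#' @param Y outcome vector
#' @param X covariate matrix without intercept (or NULL)
#' @param rc a \code{\link{ReadCountModel}}
#' @param outcome an \code{\link{OutcomeModel}} (its alpha must include the
#'   intercept first)
#' @param rho1g gene mutation frequency P(S^g = 1)
#' @param ceList list of per-locus \code{\link{CallErrorModel}}s
#' @param restrict pin loci with zero alternative reads to S = 0 (the
#'   default); FALSE enumerates all loci
#' @param cap active-locus enumeration cap
#' @return the observed-data log-likelihood (scalar)
#' @export
gsameLoglik <- function(gene, Y, X = NULL, rc, outcome, rho1g, ceList,
                        restrict = TRUE, cap = 12L) {
  n <- ncol(gene@D)
  Xmat <- .designMatrix(X, n)
  ge <- .geneEvidence(gene, rc, ceList, restrict, cap)
  q <- 1 - (1 - rho1g)^(1 / ge$p)
  b1 <- .geneBranch1(ge, q)
  ly <- .outcomeLL(Y, Xmat, outcome@family, outcome@alpha, outcome@beta,
                   outcome@dispersion)
  l0 <- log(1 - rho1g) + ly[, 1L] + ge$base0
  l1 <- log(rho1g) + ly[, 2L] + b1
  den <- .logsumexp2(l0, l1)
  if (any(bad <- den < .DEAD_SAMPLE))
    stop("gene ", gene@geneId, ": zero likelihood under both gene-status ",
         "branches for sample(s) ", paste(which(bad), collapse = ", "))
  ll <- sum(den)
  if (!is.finite(ll))
    stop("gene ", gene@geneId, ": non-finite likelihood")
  ll
}

## per-locus call-error estimation with pooled fallback for sparse loci
.geneCallErrors <- function(gene, rc, minCarriers = 3L) {
  p <- nrow(gene@D)
  sites <- lapply(seq_len(p), function(j)
    SiteData(gene@A[j, ], gene@D[j, ], gene@O[j, ],
             siteId = gene@siteIds[j]))
  pooled <- suppressWarnings(estimateCallError(
    SiteData(as.vector(gene@A), as.vector(gene@D), as.vector(gene@O),
             siteId = paste0(gene@geneId, ":pooled")), rc))
  lapply(sites, function(sd) {
    carriers <- sum(sd@O == 1L, na.rm = TRUE)
    if (carriers < minCarriers) return(pooled)
    suppressWarnings(estimateCallError(sd, rc))
  })
}

#' Fit the gene-level latent-status model by EM
#'
#' As \code{\link{msameFit}}, with the E-step taken jointly over the gene
#' status S^g and the per-locus configuration. The per-locus inclusion
#' probability q is re-derived from the current rho1g each iteration.
#'
#' @param gene a \code{\link{GeneData}}
#' @param Y outcome vector
#' @param X covariate matrix without intercept (or NULL)
#' @param rc a \code{\link{ReadCountModel}}
#' @param ceList per-locus \code{\link{CallErrorModel}} list; estimated per
#'   locus (with pooled fallback for sparse loci) when NULL
#' @param family "gaussian" or "binomial"
#' @param betaFixed fix the mutation effect (0 for the null fit)
#' @param restrict pin zero-count loci to S = 0
#' @param cap active-locus enumeration cap
#' @param tol,maxIter EM control
#' @return a \code{\link{SameFit}} (rho1 slot holds rho1g)
#' @export
gsameFit <- function(gene, Y, X = NULL, rc = defaultReadCountModel(),
                     ceList = NULL, family = c("gaussian", "binomial"),
                     betaFixed = NULL, restrict = TRUE, cap = 12L,
                     tol = 1e-8, maxIter = 1000L) {
  family <- match.arg(family)
  if (is.null(ceList)) ceList <- .geneCallErrors(gene, rc)
  n <- ncol(gene@D)
  Xmat <- .designMatrix(X, n)
  ge <- .geneEvidence(gene, rc, ceList, restrict, cap)
  og <- collapseObservedCalls(gene@O)
  init <- .emInit(Y, Xmat, as.integer(og), family,
                  CallErrorModel(0.9, 0.98))
  em <- .gsameEM(ge, Y, Xmat, family, init, betaFixed, tol, maxIter)
  .asSameFit(em, family, "gene")
}

.gsameEM <- function(ge, Y, Xmat, fam, init, betaFixed = NULL,
                     tol = 1e-8, maxIter = 1000L) {
  rho1 <- init$rho1; alpha <- init$alpha
  beta <- if (is.null(betaFixed)) init$beta else betaFixed
  disp <- init$dispersion
  trace <- numeric(0); ll <- -Inf; conv <- FALSE
  w <- rep(NA_real_, ge$n)
  for (it in seq_len(maxIter)) {
    q <- 1 - (1 - rho1)^(1 / ge$p)
    b1 <- .geneBranch1(ge, q)
    ly <- .outcomeLL(Y, Xmat, fam, alpha, beta, disp)
    l0 <- log(1 - rho1) + ly[, 1L] + ge$base0
    l1 <- log(rho1) + ly[, 2L] + b1
    den <- .logsumexp2(l0, l1)
    if (it == 1L && any(bad <- den < .DEAD_SAMPLE))
      stop("zero likelihood under both gene-status branches for sample(s) ",
           paste(which(bad), collapse = ", "))
    newll <- sum(den)
    if (!is.finite(newll))
      stop("non-finite log-likelihood at EM iteration ", it)
    w <- exp(l1 - den)
    w[b1 == -Inf] <- 0
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

#' Gene-level likelihood-ratio test (gSAME)
#'
#' Fits the gene-level model with and without the mutation effect and
#' returns T = -2 (loglik_null - loglik_alt) with its chi-square(1)
#' upper-tail p-value.
#'
#' @inheritParams gsameFit
#' @return a \code{\link{SameTest}}
#' @export
gsameTest <- function(gene, Y, X = NULL, rc = defaultReadCountModel(),
                      ceList = NULL, family = c("gaussian", "binomial"),
                      restrict = TRUE, cap = 12L, tol = 1e-8,
                      maxIter = 1000L) {
  family <- match.arg(family)
  if (is.null(ceList)) ceList <- .geneCallErrors(gene, rc)
  n <- ncol(gene@D)
  Xmat <- .designMatrix(X, n)
  ge <- tryCatch(.geneEvidence(gene, rc, ceList, restrict, cap),
                 error = function(e)
                   stop("gene ", gene@geneId, ": ", conditionMessage(e),
                        call. = FALSE))
  og <- collapseObservedCalls(gene@O)
  init <- .emInit(Y, Xmat, as.integer(og), family, CallErrorModel(0.9, 0.98))
  wrap <- function(bf) tryCatch(
    .gsameEM(ge, Y, Xmat, family, init, bf, tol, maxIter),
    error = function(e)
      stop("gene ", gene@geneId, ": ", conditionMessage(e), call. = FALSE))
  fitAlt <- .asSameFit(wrap(NULL), family, "gene")
  fitNull <- .asSameFit(wrap(0), family, "gene")
  .lrtFromFits(fitAlt, fitNull, gene@geneId)
}
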