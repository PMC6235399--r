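#' @import methods
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Beta-binomial parameters
#'
#' Mean/overdispersion parameterization of the beta-binomial used for
#' allele-specific read counts. \code{pi} is the mean alternative-allele
#' fraction and \code{phi} the intra-class correlation; the underlying beta
#' shapes are \code{a = pi (1 - phi) / phi} and \code{b = (1 - pi) (1 - phi) /
#' phi}. \code{phi = 0} degenerates to the binomial.
#'
#' @slot pi mean alternative-allele fraction, in (0, 1)
#' @slot phi overdispersion (intra-class correlation), in [0, 1)
#' @export
setClass("BetaBinomParams",
  representation(pi = "numeric", phi = "numeric"),
  validity = function(object) {
    if (length(object@pi) != 1L || length(object@phi) != 1L)
      return("pi and phi must be scalars")
    if (!is.finite(object@pi) || object@pi <= 0 || object@pi >= 1)
      return("pi must lie strictly in (0, 1)")
    if (!is.finite(object@phi) || object@phi < 0 || object@phi >= 1)
      return("phi must lie in [0, 1)")
    TRUE
  })

#' @param pi mean alternative-allele fraction
#' @param phi overdispersion (intra-class correlation)
#' @rdname BetaBinomParams-class
#' @export
BetaBinomParams <- function(pi, phi) new("BetaBinomParams", pi = pi, phi = phi)

#' Negative-binomial depth parameters
#'
#' Mean/overdispersion parameterization with variance \code{mu + mu^2 /
#' phiNB}; \code{phiNB} is the size parameter of \code{\link[stats]{rnbinom}}.
#'
#' @slot mu mean read depth (reads)
#' @slot phiNB overdispersion; variance is \code{mu + mu^2 / phiNB}
#' @export
setClass("NegBinParams",
  representation(mu = "numeric", phiNB = "numeric"),
  validity = function(object) {
    if (!is.finite(object@mu) || object@mu <= 0) return("mu must be > 0")
    if (!is.finite(object@phiNB) || object@phiNB <= 0)
      return("phiNB must be > 0")
    TRUE
  })

#' @param mu mean read depth
#' @param phiNB overdispersion (variance = mu + mu^2 / phiNB)
#' @rdname NegBinParams-class
#' @export
NegBinParams <- function(mu, phiNB) new("NegBinParams", mu = mu, phiNB = phiNB)

#' Read-count model for alternative-allele counts
#'
#' Beta-binomial components for the alternative read count A given depth D.
#' At depth \code{D >= d0} a mutation call O is available and A is modeled
#' given (S, O) by four components; below the calling threshold \code{d0} the
#' call is missing and A is modeled given the true status S alone by two
#' components.
#'
#' @slot highDepth named list of four \code{BetaBinomParams}, names
#'   \code{"00","01","10","11"} indexing (S, O)
#' @slot lowDepth named list of two \code{BetaBinomParams}, names
#'   \code{"0","1"} indexing S
#' @slot d0 read-depth threshold below which calls are missing
#' @export
setClass("ReadCountModel",
  representation(highDepth = "list", lowDepth = "list", d0 = "numeric"),
  validity = function(object) {
    hn <- c("00", "01", "10", "11")
    if (!identical(sort(names(object@highDepth)), sort(hn)))
      return("highDepth must have components named 00, 01, 10, 11")
    if (!identical(sort(names(object@lowDepth)), c("0", "1")))
      return("lowDepth must have components named 0 and 1")
    ok <- vapply(c(object@highDepth, object@lowDepth),
                 function(p) is(p, "BetaBinomParams"), TRUE)
    if (!all(ok)) return("all components must be BetaBinomParams")
    if (!is.finite(object@d0) || object@d0 < 1) return("d0 must be >= 1")
    TRUE
  })

#' Mutation-call error model
#'
#' Bernoulli model for the observed call O given the true status S:
#' sensitivity \code{gamma1 = P(O = 1 | S = 1)} and specificity
#' \code{gamma0 = P(O = 0 | S = 0)}.
#'
#' @slot gamma1 sensitivity, in (0.5, 1]
#' @slot gamma0 specificity, in (0.5, 1]
#' @export
setClass("CallErrorModel",
  representation(gamma1 = "numeric", gamma0 = "numeric"),
  validity = function(object) {
    if (object@gamma1 <= 0.5 || object@gamma1 > 1)
      return("gamma1 must lie in (0.5, 1]")
    if (object@gamma0 <= 0.5 || object@gamma0 > 1)
      return("gamma0 must lie in (0.5, 1]")
    TRUE
  })

#' @param gamma1 sensitivity P(O=1 | S=1)
#' @param gamma0 specificity P(O=0 | S=0)
#' @rdname CallErrorModel-class
#' @export
CallErrorModel <- function(gamma1 = 0.9, gamma0 = 0.98)
  new("CallErrorModel", gamma1 = gamma1, gamma0 = gamma0)

#' Outcome generalized linear model
#'
#' The conditional outcome model \code{E(Y) = g^{-1}(x' alpha + S beta)} with
#' identity link for gaussian outcomes and logit link for binomial outcomes.
#'
#' @slot family "gaussian" or "binomial"
#' @slot link "identity" or "logit" (must match the family)
#' @slot alpha covariate coefficients including the intercept
#' @slot beta mutation effect
#' @slot dispersion outcome variance for gaussian; unused for binomial
#' @export
setClass("OutcomeModel",
  representation(family = "character", link = "character",
                 alpha = "numeric", beta = "numeric",
                 dispersion = "numeric"),
  validity = function(object) {
    if (!object@family %in% c("gaussian", "binomial"))
      return("family must be gaussian or binomial")
    want <- if (object@family == "gaussian") "identity" else "logit"
    if (object@link != want)
      return(sprintf("link must be '%s' for family '%s'", want, object@family))
    if (object@family == "gaussian" &&
        (!is.finite(object@dispersion) || object@dispersion <= 0))
      return("dispersion must be > 0 for gaussian outcomes")
    if (length(object@beta) != 1L) return("beta must be a scalar")
    TRUE
  })

#' @param family "gaussian" or "binomial"
#' @param alpha covariate coefficients (including intercept)
#' @param beta mutation effect
#' @param dispersion outcome variance (gaussian only)
#' @rdname OutcomeModel-class
#' @export
OutcomeModel <- function(family = c("gaussian", "binomial"), alpha, beta,
                         dispersion = 1) {
  family <- match.arg(family)
  new("OutcomeModel", family = family,
      link = if (family == "gaussian") "identity" else "logit",
      alpha = alpha, beta = beta, dispersion = dispersion)
}

#' Per-mutation read counts and calls
#'
#' One somatic mutation's data across samples: alternative-allele counts A,
#' total depths D, and possibly-missing binary calls O. Calls must be missing
#' exactly where the depth is below the calling threshold; this is checked
#' against \code{d0} when the object is used with a \code{ReadCountModel}.
#'
#' @slot A integer alternative-allele counts per sample
#' @slot D integer read depths per sample
#' @slot O integer calls in {0, 1, NA} per sample
#' @slot siteId mutation identifier, conventionally "chr:pos" (1-based)
#' @slot gene gene symbol label
#' @export
setClass("SiteData",
  representation(A = "integer", D = "integer", O = "integer",
                 siteId = "character", gene = "character"),
  validity = function(object) {
    n <- length(object@D)
    if (n < 1L) return("at least one sample required")
    if (length(object@A) != n || length(object@O) != n)
      return("A, D, O must have equal length")
    if (anyNA(object@A) || anyNA(object@D))
      return("A and D must not contain NA")
    if (any(object@A < 0L) || any(object@D < 0L))
      return("A and D must be non-negative")
    if (any(object@A > object@D))
      return(sprintf("A > D at sample(s) %s",
                     paste(which(object@A > object@D), collapse = ", ")))
    o <- object@O[!is.na(object@O)]
    if (length(o) && !all(o %in% c(0L, 1L)))
      return("observed calls must be 0 or 1")
    TRUE
  })

#' @param A alternative-allele counts
#' @param D read depths
#' @param O calls (0/1/NA)
#' @param siteId mutation id, e.g. "chr7:140753336"
#' @param gene gene symbol
#' @rdname SiteData-class
#' @export
SiteData <- function(A, D, O, siteId = "site", gene = NA_character_) {
  new("SiteData", A = as.integer(A), D = as.integer(D), O = as.integer(O),
      siteId = siteId, gene = gene)
}

#' Per-gene stacked mutation data
#'
#' All mutation loci within one gene, stacked on a shared sample axis:
#' p x n matrices of alternative counts, depths and calls.
#'
#' @slot A p x n integer matrix of alternative-allele counts
#' @slot D p x n integer matrix of depths
#' @slot O p x n integer matrix of calls with NA for missing
#' @slot geneId gene identifier
#' @slot siteIds per-locus mutation ids
#' @export
setClass("GeneData",
  representation(A = "matrix", D = "matrix", O = "matrix",
                 geneId = "character", siteIds = "character"),
  validity = function(object) {
    dm <- dim(object@D)
    if (dm[1L] < 1L) return("at least one locus required")
    if (!identical(dim(object@A), dm) || !identical(dim(object@O), dm))
      return("A, D, O must share dimensions (loci x samples)")
    if (anyNA(object@A) || anyNA(object@D)) return("A and D must not be NA")
    if (any(object@A > object@D)) return("A must be <= D elementwise")
    if (any(object@A < 0L)) return("A must be non-negative")
    if (length(object@siteIds) != dm[1L])
      return("siteIds must have one entry per locus")
    TRUE
  })

#' @param A,D,O p x n matrices (loci x samples)
#' @param geneId gene identifier
#' @param siteIds per-locus ids
#' @rdname GeneData-class
#' @export
GeneData <- function(A, D, O, geneId = "gene", siteIds = NULL) {
  A <- as.matrix(A); D <- as.matrix(D); O <- as.matrix(O)
  storage.mode(A) <- "integer"; storage.mode(D) <- "integer"
  storage.mode(O) <- "integer"
  if (is.null(siteIds)) siteIds <- paste0(geneId, ":", seq_len(nrow(D)))
  new("GeneData", A = A, D = D, O = O, geneId = geneId, siteIds = siteIds)
}

#' EM fit of the latent-status association model
#'
#' Result of fitting the mutation-level or gene-level latent-status model by
#' EM: the outcome GLM, the latent-status prior, the observed-data
#' log-likelihood trace and the per-sample posterior mutation probabilities.
#'
#' @slot outcome fitted \code{OutcomeModel}
#' @slot rho1 fitted prior P(S = 1) (gene-level: P(S^g = 1))
#' @slot loglik observed-data log-likelihood at convergence
#' @slot loglikTrace per-iteration log-likelihoods (non-decreasing)
#' @slot nIter EM iterations used
#' @slot converged logical convergence flag
#' @slot posterior per-sample posterior P(S = 1 | data)
#' @slot level "mutation" or "gene"
#' @export
setClass("SameFit",
  representation(outcome = "OutcomeModel", rho1 = "numeric",
                 loglik = "numeric", loglikTrace = "numeric",
                 nIter = "integer", converged = "logical",
                 posterior = "numeric", level = "character"),
  validity = function(object) {
    if (!is.finite(object@loglik)) return("loglik must be finite")
    if (any(object@posterior < -1e-12 | object@posterior > 1 + 1e-12))
      return("posterior probabilities must lie in [0, 1]")
    TRUE
  })

#' Likelihood-ratio test result
#'
#' The LRT statistic \code{T = -2 (loglik_null - loglik_alt)} (clipped at 0),
#' its chi-square(1) upper-tail p-value, and the two nested EM fits. The
#' p-value is NA for monomorphic sites where the posterior puts all mass on
#' one status.
#'
#' @slot statistic LRT statistic T
#' @slot df degrees of freedom (1)
#' @slot pvalue upper-tail chi-square p-value (NA if degenerate)
#' @slot fitAlt unconstrained fit
#' @slot fitNull fit under beta = 0
#' @slot id site or gene identifier
#' @slot note diagnostic note ("" when clean)
#' @export
setClass("SameTest",
  representation(statistic = "numeric", df = "numeric", pvalue = "numeric",
                 fitAlt = "SameFit", fitNull = "SameFit",
                 id = "character", note = "character"),
  validity = function(object) {
    if (is.finite(object@statistic) && object@statistic < 0)
      return("statistic must be >= 0 (clipped)")
    TRUE
  })

#' Simulation configuration
#'
#' Generative settings for the synthetic mutation/gene datasets: sample size,
#' mutation frequency, effect size, outcome family, call-error rates, the
#' two-stage negative-binomial depth model, and the read-count model. The
#' defaults reproduce an exome-sequencing design: depth means drawn per
#' mutation from NB(113, 3.28), per-sample depths from NB(site mean, 1.9),
#' calling threshold d0 = 20, sensitivity 0.9 and specificity 0.98. With
#' \code{wgsMode = TRUE} depths are drawn in one stage from NB(40, 1.9),
#' resembling whole-genome sequencing coverage.
#'
#' @slot n sample count
#' @slot level "mutation" or "gene"
#' @slot rho1 mutation frequency P(S = 1) (gene level: P(S^g = 1))
#' @slot p loci per gene (gene level)
#' @slot beta effect size
#' @slot family "gaussian" or "binomial"
#' @slot gamma1,gamma0 call sensitivity/specificity (mutation level; gene
#'   level draws per-locus values from {0.9, 1} x {0.98, 1})
#' @slot depthBetween \code{NegBinParams} for per-mutation mean depths
#' @slot depthWithinPhi within-mutation depth overdispersion
#' @slot wgsMode single-stage low-coverage depth model
#' @slot wgsDepthMean mean depth in wgsMode
#' @slot readCountModel \code{ReadCountModel} used for A
#' @slot seed RNG seed (mandatory for reproducibility)
#' @export
setClass("SimulationConfig",
  representation(n = "integer", level = "character", rho1 = "numeric",
                 p = "integer", beta = "numeric", family = "character",
                 gamma1 = "numeric", gamma0 = "numeric",
                 depthBetween = "NegBinParams", depthWithinPhi = "numeric",
                 wgsMode = "logical", wgsDepthMean = "numeric",
                 readCountModel = "ReadCountModel", seed = "integer"),
  validity = function(object) {
    if (object@n < 2L) return("n must be >= 2")
    if (!object@level %in% c("mutation", "gene"))
      return("level must be mutation or gene")
    if (object@rho1 <= 0 || object@rho1 >= 1)
      return("rho1 must lie in (0, 1)")
    if (!object@family %in% c("gaussian", "binomial"))
      return("family must be gaussian or binomial")
    if (object@p < 1L) return("p must be >= 1")
    if (is.na(object@seed)) return("seed is mandatory")
    TRUE
  })
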