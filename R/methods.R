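## Accessors and show methods.

#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' Extract the p-value
#' @param x a \code{\link{SameTest}} or \code{\link{WaldResult}}
#' @return numeric p-value (NA when the test was degenerate)
#' @rdname pValue
#' @export
setMethod("pValue", "SameTest", function(x) x@pvalue)
#' @rdname pValue
#' @export
setMethod("pValue", "WaldResult", function(x) x@pvalue)

#' @export
setGeneric("lrtStat", function(x) standardGeneric("lrtStat"))
#' Extract the likelihood-ratio statistic
#' @param x a \code{\link{SameTest}}
#' @rdname lrtStat
#' @export
setMethod("lrtStat", "SameTest", function(x) x@statistic)

#' @export
setGeneric("betaHat", function(x) standardGeneric("betaHat"))
#' Extract the estimated mutation effect
#' @param x a \code{\link{SameTest}}, \code{\link{SameFit}} or
#'   \code{\link{WaldResult}}
#' @rdname betaHat
#' @export
setMethod("betaHat", "SameTest", function(x) x@fitAlt@outcome@beta)
#' @rdname betaHat
#' @export
setMethod("betaHat", "SameFit", function(x) x@outcome@beta)
#' @rdname betaHat
#' @export
setMethod("betaHat", "WaldResult", function(x) x@betaHat)

#' @export
setGeneric("posteriorStatus", function(x) standardGeneric("posteriorStatus"))
#' Per-sample posterior mutation probabilities
#' @param x a \code{\link{SameFit}} or \code{\link{SameTest}} (alternative
#'   fit)
#' @rdname posteriorStatus
#' @export
setMethod("posteriorStatus", "SameFit", function(x) x@posterior)
#' @rdname posteriorStatus
#' @export
setMethod("posteriorStatus", "SameTest", function(x) x@fitAlt@posterior)

setMethod("show", "BetaBinomParams", function(object) {
  cat(sprintf("BetaBinomParams: pi = %.4g, phi = %.4g\n",
              object@pi, object@phi))
})

setMethod("show", "ReadCountModel", function(object) {
  cat("ReadCountModel (d0 =", object@d0, ")\n")
  cat("  high depth (S,O):\n")
  for (k in c("00", "01", "10", "11"))
    cat(sprintf("    %s: pi = %.4g, phi = %.4g\n", k,
                object@highDepth[[k]]@pi, object@highDepth[[k]]@phi))
  cat("  low depth (S):\n")
  for (k in c("0", "1"))
    cat(sprintf("    %s:  pi = %.4g, phi = %.4g\n", k,
                object@lowDepth[[k]]@pi, object@lowDepth[[k]]@phi))
})

setMethod("show", "CallErrorModel", function(object) {
  cat(sprintf("CallErrorModel: sensitivity = %.4g, specificity = %.4g\n",
              object@gamma1, object@gamma0))
})

setMethod("show", "SiteData", function(object) {
  n <- length(object@D)
  cat(sprintf("SiteData %s (%s): %d samples, %d called, %d alt-positive\n",
              object@siteId, object@gene, n,
              sum(!is.na(object@O)), sum(object@A > 0L)))
})

setMethod("show", "GeneData", function(object) {
  cat(sprintf("GeneData %s: %d loci x %d samples\n", object@geneId,
              nrow(object@D), ncol(object@D)))
})

setMethod("show", "SameFit", function(object) {
  cat(sprintf(
    "SameFit (%s level): beta = %.4g, rho1 = %.4g, loglik = %.4f\n",
    object@level, object@outcome@beta, object@rho1, object@loglik))
  cat(sprintf("  %d EM iterations, converged: %s\n", object@nIter,
              object@converged))
})

setMethod("show", "SameTest", function(object) {
  meth <- if (object@fitAlt@level == "gene") "gSAME" else "mSAME"
  cat(sprintf("%s test for %s\n", meth, object@id))
  cat(sprintf("  T = %.4g (df = 1), p = %.4g, beta_hat = %.4g\n",
              object@statistic, object@pvalue, object@fitAlt@outcome@beta))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "WaldResult", function(object) {
  cat(sprintf("GLM Wald test: beta_hat = %.4g, se = %.4g, z = %.4g, p = %.4g\n",
              object@betaHat, object@se, object@z, object@pvalue))
  if (nzchar(object@note)) cat("  note:", object@note, "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: %s level, n = %d, rho1 = %.3g, beta = %.3g, %s\n",
    object@level, object@n, object@rho1, object@beta, object@family))
})
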