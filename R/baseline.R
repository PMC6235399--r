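## Naive GLM comparator: treats observed calls as the true mutation status
## and Wald-tests the call coefficient.

#' Wald result container
#'
#' @slot betaHat estimated call coefficient
#' @slot se standard error
#' @slot z Wald statistic
#' @slot pvalue two-sided normal p-value
#' @slot note diagnostic ("" when clean)
#' @export
setClass("WaldResult",
  representation(betaHat = "numeric", se = "numeric", z = "numeric",
                 pvalue = "numeric", note = "character"))

#' Naive GLM Wald test on observed mutation calls
#'
#' Fits the outcome GLM with the observed call (missing coerced to 0) as if
#' it were the true mutation status and performs a two-sided Wald test on
#' its coefficient. Constant calls, or separation in the logistic fit,
#' yield an NA result with a diagnostic note.
#'
#' @param calls per-sample 0/1 calls (NA treated as 0)
#' @param Y outcome vector
#' @param X covariate matrix without intercept (or NULL)
#' @param family "gaussian" or "binomial"
#' @return a \code{\link{WaldResult}}
#' @export
glmWaldTest <- function(calls, Y, X = NULL,
                        family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  calls <- ifelse(is.na(calls), 0L, as.integer(calls))
  n <- length(Y)
  if (length(calls) != n) stop("calls length does not match outcomes")
  naRes <- function(msg) new("WaldResult", betaHat = NA_real_, se = NA_real_,
                             z = NA_real_, pvalue = NA_real_, note = msg)
  if (length(unique(calls)) < 2L)
    return(naRes("constant calls: coefficient not estimable"))
  Xmat <- cbind(.designMatrix(X, n), status = calls)
  fam <- if (family == "gaussian") stats::gaussian() else stats::binomial()
  fit <- tryCatch(stats::glm.fit(Xmat, Y, family = fam),
                  error = function(e) NULL)
  if (is.null(fit) || !fit$converged || anyNA(fit$coefficients))
    return(naRes("GLM fit failed or did not converge"))
  k <- ncol(Xmat)
  ## dispersion: 1 for binomial, residual MSE for gaussian (matching
  ## summary.glm); covariance from the weighted cross-product inverse
  XtWX <- crossprod(sqrt(fit$weights) * Xmat)
  vc <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(vc)) return(naRes("singular information matrix"))
  disp <- if (family == "gaussian")
    sum(fit$residuals^2 * fit$weights) / fit$df.residual else 1
  se <- sqrt(disp * vc[k, k])
  if (!is.finite(se) || se > 1e3)
    return(naRes("separation: unstable standard error"))
  b <- unname(fit$coefficients[k])
  z <- b / se
  new("WaldResult", betaHat = b, se = se, z = z,
      pvalue = 2 * stats::pnorm(-abs(z)), note = "")
}
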