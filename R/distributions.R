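## Probability kernels: beta-binomial allele counts, negative-binomial depths,
## outcome GLM densities.

.bbShapes <- function(pi, phi) {
  list(a = pi * (1 - phi) / phi, b = (1 - pi) * (1 - phi) / phi)
}

#' Beta-binomial log probability mass
#'
#' Log-pmf of the beta-binomial in the (pi, phi) mean/intra-class-correlation
#' parameterization. At \code{phi = 0} this is the binomial log-pmf with
#' success probability \code{pi}.
#'
#' @param a alternative-allele count(s), 0 <= a <= d
#' @param d depth(s)
#' @param params a \code{\link{BetaBinomParams}} object
#' @return log-probabilities, recycled over \code{a} and \code{d}
#' @examples
#' dbetabinomLog(3, 10, BetaBinomParams(0.146, 0.10))
#' @export
dbetabinomLog <- function(a, d, params) {
  stopifnot(is(params, "BetaBinomParams"))
  if (any(a < 0 | d < 0)) stop("counts must be non-negative")
  if (any(a > d)) stop("alternative count a exceeds depth d")
  if (any(a != round(a)) || any(d != round(d)))
    stop("counts must be integers")
  if (params@phi == 0)
    return(stats::dbinom(a, d, params@pi, log = TRUE))
  sh <- .bbShapes(params@pi, params@phi)
  if (params@phi >= 1e-4)
    return(lchoose(d, a) + lbeta(a + sh$a, d - a + sh$b) - lbeta(sh$a, sh$b))
  ## small phi: beta shapes are huge and the lbeta differences cancel
  ## catastrophically; accumulate the rising-factorial ratios instead
  n <- max(length(a), length(d))
  a <- rep_len(a, n); d <- rep_len(d, n)
  lchoose(d, a) + vapply(seq_len(n), function(i) {
    ai <- a[i]; di <- d[i]
    t1 <- if (ai > 0)
      sum(log((sh$a + 0:(ai - 1)) / (sh$a + sh$b + 0:(ai - 1)))) else 0
    t2 <- if (di - ai > 0)
      sum(log((sh$b + 0:(di - ai - 1)) /
              (sh$a + sh$b + ai + 0:(di - ai - 1)))) else 0
    t1 + t2
  }, 0)
}

#' Sample beta-binomial alternative-allele counts
#'
#' @param n number of draws
#' @param d depth(s), recycled to length n
#' @param params a \code{\link{BetaBinomParams}} object
#' @return integer counts in [0, d]
#' @export
rbetabinom <- function(n, d, params) {
  stopifnot(is(params, "BetaBinomParams"))
  if (any(d < 0)) stop("depth must be non-negative")
  d <- rep_len(d, n)
  if (params@phi < 1e-12) return(stats::rbinom(n, d, params@pi))
  sh <- .bbShapes(params@pi, params@phi)
  q <- stats::rbeta(n, sh$a, sh$b)
  stats::rbinom(n, d, q)
}

#' Sample negative-binomial read depths
#'
#' Negative binomial with mean \code{mu} and variance \code{mu + mu^2 /
#' phiNB}; a thin wrapper over \code{\link[stats]{rnbinom}} fixing the
#' parameterization used throughout the depth model.
#'
#' @param n number of draws
#' @param params a \code{\link{NegBinParams}} object
#' @return non-negative integer depths
#' @export
rnegbin <- function(n, params) {
  stopifnot(is(params, "NegBinParams"))
  stats::rnbinom(n, mu = params@mu, size = params@phiNB)
}

#' Outcome log-density under the GLM
#'
#' Log-density of the outcome given covariates and a (possibly latent)
#' mutation status: gaussian with mean \code{x' alpha + s beta} and variance
#' \code{dispersion}, or Bernoulli with logit mean.
#'
#' @param y outcome value(s)
#' @param x covariate matrix (rows = samples, including the intercept column)
#'   or a single covariate vector for one sample
#' @param s mutation status in {0, 1} (scalar or per-sample)
#' @param model an \code{\link{OutcomeModel}}
#' @return log-density per sample
#' @export
outcomeLogDensity <- function(y, x, s, model) {
  stopifnot(is(model, "OutcomeModel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = length(y), byrow = length(y) > 1)
  if (ncol(x) != length(model@alpha))
    stop("covariate dimension does not match alpha")
  eta <- drop(x %*% model@alpha) + s * model@beta
  if (model@family == "gaussian") {
    stats::dnorm(y, mean = eta, sd = sqrt(model@dispersion), log = TRUE)
  } else {
    stats::dbinom(y, 1, stats::plogis(eta), log = TRUE)
  }
}

#' Read-count model with the exome-seq default components
#'
#' The high-depth components (pi_{so}, phi_{so}) over the four (S, O) strata
#' and the low-depth components (pi_s, phi_s), as estimated from a colon
#' adenocarcinoma exome-sequencing cohort, with calling threshold d0 = 20:
#' high depth pi = (0.001, 0.002, 0.1179, 0.3207) and phi = (0.0006, 0.3457,
#' 0.0001, 0.1018) for (S,O) = 00, 01, 10, 11; low depth pi_0 = 0.001, phi_0
#' = 0.001, pi_1 = 0.146, phi_1 = 0.10.
#'
#' @param d0 calling depth threshold
#' @return a \code{\link{ReadCountModel}}
#' @export
defaultReadCountModel <- function(d0 = 20) {
  new("ReadCountModel",
      highDepth = list(
        "00" = BetaBinomParams(0.0010, 0.0006),
        "01" = BetaBinomParams(0.0020, 0.3457),
        "10" = BetaBinomParams(0.1179, 0.0001),
        "11" = BetaBinomParams(0.3207, 0.1018)),
      lowDepth = list(
        "0" = BetaBinomParams(0.001, 0.001),
        "1" = BetaBinomParams(0.146, 0.10)),
      d0 = d0)
}

.checkSeparability <- function(rc) {
  hi <- rc@highDepth
  if (hi[["10"]]@pi <= max(hi[["00"]]@pi, hi[["01"]]@pi) ||
      hi[["11"]]@pi <= max(hi[["00"]]@pi, hi[["01"]]@pi) ||
      rc@lowDepth[["1"]]@pi <= rc@lowDepth[["0"]]@pi)
    warning("read-count components for S=1 do not dominate S=0: ",
            "mutated and unmutated allele fractions are poorly separated")
  invisible(rc)
}

## ---- weighted beta-binomial maximum likelihood ----

.PI_FLOOR <- 1e-4
.PHI_FLOOR <- 1e-6
.PHI_CEIL <- 0.999

## bounded quasi-Newton on (logit pi, logit phi)
.fitBetaBinomWeighted <- function(a, d, w = NULL, init = c(0.05, 0.05)) {
  if (is.null(w)) w <- rep(1, length(a))
  keep <- w > 1e-12 & d > 0
  a <- a[keep]; d <- d[keep]; w <- w[keep]
  if (!length(a)) return(NULL)
  nll <- function(par) {
    pi <- stats::plogis(par[1L]); phi <- stats::plogis(par[2L])
    pi <- min(max(pi, .PI_FLOOR), 1 - .PI_FLOOR)
    phi <- min(max(phi, .PHI_FLOOR), .PHI_CEIL)
    -sum(w * dbetabinomLog(a, d, BetaBinomParams(pi, phi)))
  }
  lo <- stats::qlogis(c(.PI_FLOOR, .PHI_FLOOR))
  hi <- stats::qlogis(c(1 - .PI_FLOOR, .PHI_CEIL))
  fit <- stats::optim(stats::qlogis(pmin(pmax(init, 1e-3), 1 - 1e-3)), nll,
                      method = "L-BFGS-B", lower = lo, upper = hi,
                      control = list(maxit = 500, factr = 1e4))
  pi <- stats::plogis(fit$par[1L]); phi <- stats::plogis(fit$par[2L])
  atBound <- pi <= .PI_FLOOR * 1.0001 || pi >= 1 - .PI_FLOOR * 1.0001
  list(params = BetaBinomParams(min(max(pi, .PI_FLOOR), 1 - .PI_FLOOR),
                                min(max(phi, .PHI_FLOOR), .PHI_CEIL)),
       nll = fit$value, atBound = atBound)
}

## Two-component beta-binomial mixture on (A, D) by EM; component parameters
## optionally held fixed (updateComponents = FALSE re-estimates only the
## mixing proportion). Used for the preliminary status classification that
## drives stratum labeling and call-error estimation.
.betabinomMixture <- function(a, d, comp0, comp1, rho1 = 0.1,
                              updateComponents = TRUE,
                              maxIter = 100, tol = 1e-6) {
  ll <- -Inf
  for (it in seq_len(maxIter)) {
    l0 <- log(1 - rho1) + dbetabinomLog(a, d, comp0)
    l1 <- log(rho1) + dbetabinomLog(a, d, comp1)
    m <- pmax(l0, l1)
    den <- m + log(exp(l0 - m) + exp(l1 - m))
    w <- exp(l1 - den)
    newll <- sum(den)
    rho1 <- min(max(mean(w), 1e-6), 1 - 1e-6)
    if (updateComponents) {
      f0 <- .fitBetaBinomWeighted(a, d, 1 - w, c(comp0@pi, comp0@phi))
      f1 <- .fitBetaBinomWeighted(a, d, w, c(comp1@pi, comp1@phi))
      if (!is.null(f0)) comp0 <- f0$params
      if (!is.null(f1)) comp1 <- f1$params
    }
    if (is.finite(ll) && abs(newll - ll) < tol) { ll <- newll; break }
    ll <- newll
  }
  ## keep the convention that component 1 is the high-VAF (mutated) one
  if (comp1@pi < comp0@pi) {
    tmp <- comp0; comp0 <- comp1; comp1 <- tmp; rho1 <- 1 - rho1; w <- 1 - w
  }
  list(comp0 = comp0, comp1 = comp1, rho1 = rho1, posterior = w, loglik = ll)
}

.stackSites <- function(sites) {
  stopifnot(length(sites) >= 1L,
            all(vapply(sites, is, TRUE, class2 = "SiteData")))
  list(A = unlist(lapply(sites, slot, "A")),
       D = unlist(lapply(sites, slot, "D")),
       O = unlist(lapply(sites, slot, "O")))
}

#' Estimate the high-depth beta-binomial components
#'
#' Fits the four (S, O)-stratum beta-binomial components for alternative
#' read counts at depth >= d0, pooling samples across mutations. The latent
#' status label S for stratification is a preliminary posterior
#' classification (threshold 0.5) from a two-component beta-binomial mixture
#' on (A, D); crossing it with the observed call O defines the four strata,
#' each fitted by bounded maximum likelihood. Empty strata fall back to the
#' supplied defaults with a warning.
#'
#' @param sites list of \code{\link{SiteData}} objects (>= 2 mutations)
#' @param d0 depth threshold
#' @param defaults a \code{\link{ReadCountModel}} providing fallback
#'   components (and the low-depth half of the returned model)
#' @return a \code{\link{ReadCountModel}} with fitted high-depth components
#' @export
fitBetaBinomHighDepth <- function(sites, d0 = 20,
                                  defaults = defaultReadCountModel(d0)) {
  if (length(sites) < 2L) stop("need at least 2 mutations")
  st <- .stackSites(sites)
  hi <- st$D >= d0
  if (!any(hi)) stop("no samples with depth >= d0")
  a <- st$A[hi]; d <- st$D[hi]; o <- st$O[hi]
  if (anyNA(o)) stop("calls missing at depth >= d0")
  mix <- .betabinomMixture(a, d, defaults@highDepth[["00"]],
                           defaults@highDepth[["11"]], rho1 = 0.1)
  sHat <- as.integer(mix$posterior > 0.5)
  out <- defaults@highDepth
  for (s in 0:1) for (oo in 0:1) {
    key <- paste0(s, oo)
    sel <- sHat == s & o == oo
    if (!any(sel)) {
      warning("no observations in stratum (S=", s, ", O=", oo,
              "); using default component")
      next
    }
    init <- c(out[[key]]@pi, out[[key]]@phi)
    f <- .fitBetaBinomWeighted(a[sel], d[sel], init = init)
    if (is.null(f)) {
      warning("stratum (S=", s, ", O=", oo, ") has no usable depth; ",
              "using default component")
      next
    }
    if (f$atBound)
      warning("pi estimate pinned at its bound in stratum (S=", s,
              ", O=", oo, ")")
    out[[key]] <- f$params
  }
  rc <- new("ReadCountModel", highDepth = out, lowDepth = defaults@lowDepth,
            d0 = d0)
  .checkSeparability(rc)
  rc
}

#' Estimate the low-depth beta-binomial components
#'
#' Fits the two status-indexed components for alternative counts at depth
#' < d0, where no call is available. Status labels are imputed from a
#' mixture classification of the low-depth (A, D) themselves, initialized at
#' the default low-depth components and iterated once (one classification
#' pass followed by one weighted maximum-likelihood fit per component).
#'
#' @inheritParams fitBetaBinomHighDepth
#' @return a \code{\link{ReadCountModel}} with fitted low-depth components
#' @export
fitBetaBinomLowDepth <- function(sites, d0 = 20,
                                 defaults = defaultReadCountModel(d0)) {
  st <- .stackSites(sites)
  lo <- st$D < d0 & st$D > 0
  if (!any(lo)) {
    warning("no low-depth samples; returning default low-depth components")
    return(defaults)
  }
  a <- st$A[lo]; d <- st$D[lo]
  mix <- .betabinomMixture(a, d, defaults@lowDepth[["0"]],
                           defaults@lowDepth[["1"]], rho1 = 0.1,
                           updateComponents = FALSE, maxIter = 50)
  w <- mix$posterior
  out <- defaults@lowDepth
  f0 <- .fitBetaBinomWeighted(a, d, 1 - w,
                              c(out[["0"]]@pi, out[["0"]]@phi))
  f1 <- .fitBetaBinomWeighted(a, d, w, c(out[["1"]]@pi, out[["1"]]@phi))
  if (!is.null(f0)) out[["0"]] <- f0$params
  if (sum(w) < 1) {
    warning("essentially no low-depth samples classified as mutated; ",
            "keeping the default S=1 component")
  } else if (!is.null(f1)) out[["1"]] <- f1$params
  rc <- new("ReadCountModel", highDepth = defaults@highDepth, lowDepth = out,
            d0 = d0)
  .checkSeparability(rc)
  rc
}

## ---- flat key-value serialization of the read-count model ----

#' Write / read a read-count model as a flat key-value text file
#'
#' Serializes the six beta-binomial components and d0 as \code{key = value}
#' lines, e.g. \code{high.11.pi = 0.3207}.
#'
#' @param rc a \code{\link{ReadCountModel}}
#' @param file path to write to / read from
#' @return \code{readReadCountModel} returns a \code{ReadCountModel};
#'   \code{writeReadCountModel} returns \code{file} invisibly
#' @export
writeReadCountModel <- function(rc, file) {
  stopifnot(is(rc, "ReadCountModel"))
  kv <- c(d0 = rc@d0)
  for (k in names(rc@highDepth)) {
    kv[paste0("high.", k, ".pi")] <- rc@highDepth[[k]]@pi
    kv[paste0("high.", k, ".phi")] <- rc@highDepth[[k]]@phi
  }
  for (k in names(rc@lowDepth)) {
    kv[paste0("low.", k, ".pi")] <- rc@lowDepth[[k]]@pi
    kv[paste0("low.", k, ".phi")] <- rc@lowDepth[[k]]@phi
  }
  writeLines(sprintf("%s = %.17g", names(kv), kv), file)
  invisible(file)
}

#' @rdname writeReadCountModel
#' @export
readReadCountModel <- function(file) {
  ln <- readLines(file)
  ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
  parts <- strsplit(ln, "=", fixed = TRUE)
  kv <- stats::setNames(
    as.numeric(trimws(vapply(parts, `[`, "", 2L))),
    trimws(vapply(parts, `[`, "", 1L)))
  gp <- function(pre, k) BetaBinomParams(kv[[paste0(pre, k, ".pi")]],
                                         kv[[paste0(pre, k, ".phi")]])
  new("ReadCountModel",
      highDepth = stats::setNames(
        lapply(c("00", "01", "10", "11"), gp, pre = "high."),
        c("00", "01", "10", "11")),
      lowDepth = stats::setNames(lapply(c("0", "1"), gp, pre = "low."),
                                 c("0", "1")),
      d0 = kv[["d0"]])
}
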