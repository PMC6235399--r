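# Beta-binomial / negative-binomial kernels and component estimation.

test_that("beta-binomial log-pmf matches quadrature, sums to one, and has the binomial limit", {
  # binomial limit at phi = 0 and the empty-trial convention
  expect_equal(dbetabinomLog(1, 2, BetaBinomParams(0.5, 0)), log(0.5))
  expect_equal(dbetabinomLog(0, 0, BetaBinomParams(0.3, 0.2)), 0)

  # quadrature oracle
  expect_equal(dbetabinomLog(3, 10, BetaBinomParams(0.146, 0.10)),
               log(oracleBBQuad(3, 10, 0.146, 0.10)), tolerance = 1e-9)

  # normalization across a grid of components, d <= 30
  for (pp in list(c(0.001, 0.0006), c(0.3207, 0.1018), c(0.146, 0.10),
                  c(0.002, 0.3457), c(0.5, 0.8))) {
    for (d in c(1, 7, 30)) {
      s <- sum(exp(dbetabinomLog(0:d, d, BetaBinomParams(pp[1], pp[2]))))
      expect_equal(s, 1, tolerance = 1e-10)
    }
  }

  # tiny-phi agreement with the binomial out to d = 100
  lp <- dbetabinomLog(0:100, 100, BetaBinomParams(0.2, 1e-12))
  expect_equal(lp, dbinom(0:100, 100, 0.2, log = TRUE), tolerance = 1e-6)

  expect_error(dbetabinomLog(5, 3, BetaBinomParams(0.5, 0.1)), "exceeds")
  expect_error(dbetabinomLog(-1, 3, BetaBinomParams(0.5, 0.1)),
               "non-negative")
})

test_that("beta-binomial sampler matches its pmf in moments and distribution", {
  set.seed(401)
  expect_identical(rbetabinom(5, 0, BetaBinomParams(0.3, 0.1)),
                   rep(0L, 5))
  draws <- rbetabinom(1e5, 100, BetaBinomParams(0.3207, 0.1018))
  # mean fraction within 3 SE of pi
  v <- 100 * 0.3207 * (1 - 0.3207) * (1 + 99 * 0.1018)
  se <- sqrt(v / 1e5) / 100
  expect_lt(abs(mean(draws) / 100 - 0.3207), 3 * se)

  # phi = 0 degenerates to the binomial: chi-square goodness of fit at 1%
  set.seed(402)
  d2 <- rbetabinom(2e4, 50, BetaBinomParams(0.2, 0))
  br <- 0:50
  expected <- dbinom(br, 50, 0.2) * 2e4
  keep <- expected > 5
  obs <- tabulate(d2 + 1L, nbins = 51)
  chi <- sum((obs[keep] - expected[keep])^2 / expected[keep]) +
    (sum(obs[!keep]) - sum(expected[!keep]))^2 / sum(expected[!keep])
  dfc <- sum(keep)  # lumped tail adds one cell, minus one constraint
  expect_gt(pchisq(chi, dfc), 0.01)
})

test_that("negative-binomial depths have the stated mean/variance law", {
  set.seed(403)
  d <- rnegbin(1e5, NegBinParams(113, 3.28))
  sdTarget <- sqrt(113 + 113^2 / 3.28)   # 63.3
  expect_equal(sdTarget, 63.3, tolerance = 0.005)
  expect_lt(abs(mean(d) - 113), 3 * sdTarget / sqrt(1e5))
  # SE of the sample SD, normal approximation with kurtosis correction skipped
  expect_lt(abs(sd(d) - sdTarget), 5 * sdTarget / sqrt(2 * 1e5) * 3)

  d2 <- rnegbin(1e5, NegBinParams(40, 1.9))
  expect_lt(abs(mean(d2) - 40), 3 * sqrt((40 + 40^2 / 1.9) / 1e5))

  # phi -> Inf limit is Poisson: variance close to the mean
  d3 <- rnegbin(1e5, NegBinParams(50, 1e9))
  expect_lt(abs(var(d3) / 50 - 1), 0.05)
})

test_that("outcome log-density matches the GLM closed forms", {
  gm <- OutcomeModel("gaussian", alpha = c(1, 1), beta = 0.4,
                     dispersion = 1)
  x <- matrix(c(1, 0.3), nrow = 1)
  # at the mean, the normal log-density is -log(2 pi)/2
  expect_equal(outcomeLogDensity(1.7, x, 1, gm), -0.5 * log(2 * pi))
  # hand-computed: y = 2, mean = 1 + 0.3 + 0.4 = 1.7
  expect_equal(outcomeLogDensity(2.0, x, 1, gm),
               -0.5 * log(2 * pi) - 0.5 * 0.3^2)
  bm <- OutcomeModel("binomial", alpha = c(0.5, -0.5), beta = 0)
  xb <- matrix(c(1, 1), nrow = 1)    # eta = 0
  expect_equal(outcomeLogDensity(1, xb, 0, bm), log(0.5))
  expect_equal(outcomeLogDensity(0, xb, 0, bm), log(0.5))
  expect_error(outcomeLogDensity(1, matrix(1, 1, 3), 0, gm), "dimension")
})

test_that("high-depth component estimation recovers the mutated-called stratum", {
  cfg <- simConfig(n = 400, rho1 = 0.10, beta = 0, seed = 501)
  sites <- lapply(1:50, function(i)
    simulateMutationSite(cfg, seed = 500 + i)$site)
  rc <- suppressWarnings(fitBetaBinomHighDepth(sites, d0 = 20))
  # (1,1) stratum generated from pi = 0.3207: recovery within +-20%
  expect_gt(rc@highDepth[["11"]]@pi, 0.26)
  expect_lt(rc@highDepth[["11"]]@pi, 0.38)
  # the unmutated-uncalled stratum stays near zero VAF
  expect_lt(rc@highDepth[["00"]]@pi, 0.01)

  # scale consistency: doubling the number of mutations moves the estimate
  # by no more than rough MC error
  rc2 <- suppressWarnings(fitBetaBinomHighDepth(sites[1:25], d0 = 20))
  expect_lt(abs(rc2@highDepth[["11"]]@pi - rc@highDepth[["11"]]@pi), 0.06)
})

test_that("degenerate high-depth strata fall back with warnings", {
  # all-zero counts: every sample classifies to S=0/O=0; other strata empty,
  # and the fitted stratum pins pi at its floor
  s1 <- SiteData(rep(0L, 60), rep(50L, 60), rep(0L, 60))
  s2 <- SiteData(rep(0L, 60), rep(60L, 60), rep(0L, 60))
  w <- capture_warnings(rc <- fitBetaBinomHighDepth(list(s1, s2), d0 = 20))
  expect_true(any(grepl("stratum|pinned", w)))
  expect_lte(rc@highDepth[["00"]]@pi, 1.1e-4)
})

test_that("low-depth component estimation recovers the mutated component", {
  set.seed(502)
  mk <- function() {
    n <- 400
    D <- sample(5:19, n, replace = TRUE)
    S <- rbinom(n, 1, 0.3)
    A <- integer(n)
    A[S == 1] <- rbetabinom(sum(S), D[S == 1], BetaBinomParams(0.146, 0.10))
    A[S == 0] <- rbetabinom(sum(!S), D[S == 0],
                            BetaBinomParams(0.001, 0.001))
    SiteData(A, D, rep(NA_integer_, n))
  }
  sites <- replicate(10, mk())
  rc <- fitBetaBinomLowDepth(sites, d0 = 20)
  expect_gt(rc@lowDepth[["1"]]@pi, 0.146 * 0.75)
  expect_lt(rc@lowDepth[["1"]]@pi, 0.146 * 1.25)

  # no low-depth data: defaults returned unchanged, with a warning
  hi <- SiteData(c(0L, 30L), c(100L, 100L), c(0L, 1L))
  expect_warning(rc2 <- fitBetaBinomLowDepth(list(hi), d0 = 20),
                 "no low-depth")
  expect_equal(rc2@lowDepth[["1"]]@pi, 0.146)
  expect_equal(rc2@lowDepth[["0"]]@pi, 0.001)
})

test_that("read-count model round-trips through the key-value config file", {
  rc <- defaultReadCountModel()
  f <- withr::local_tempfile(fileext = ".cfg")
  writeReadCountModel(rc, f)
  rc2 <- readReadCountModel(f)
  expect_equal(rc2@d0, rc@d0)
  for (k in names(rc@highDepth)) {
    expect_equal(rc2@highDepth[[k]]@pi, rc@highDepth[[k]]@pi)
    expect_equal(rc2@highDepth[[k]]@phi, rc@highDepth[[k]]@phi)
  }
  for (k in names(rc@lowDepth))
    expect_equal(rc2@lowDepth[[k]]@pi, rc@lowDepth[[k]]@pi)
})
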