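# Gene-level collapsed test: status collapsing, configuration enumeration,
# likelihood against brute-force enumeration, EM and LRT.

rcDef <- defaultReadCountModel()
ceDef <- CallErrorModel(0.9, 0.98)

test_that("true statuses and observed calls collapse by any-mutation", {
  expect_identical(collapseTrueStatus(c(0L, 0L, 0L)), 0L)
  expect_identical(collapseTrueStatus(c(0L, 1L, 0L)), 1L)
  expect_identical(collapseTrueStatus(c(1L, 1L, 1L)), 1L)
  m <- matrix(c(0L, 0L, 1L, 0L), 2, 2)
  expect_identical(collapseTrueStatus(m), c(0L, 1L))

  expect_identical(as.integer(collapseObservedCalls(c(0L, NA, 0L))), 0L)
  expect_identical(as.integer(collapseObservedCalls(c(NA, 1L))), 1L)
  allMiss <- collapseObservedCalls(c(NA_integer_, NA_integer_))
  expect_identical(as.integer(allMiss), 0L)
  expect_true(attr(allMiss, "lowCoverage"))
})

test_that("configuration enumeration pins zero-count loci and caps m", {
  e0 <- enumerateConfigs(c(0, 0, 0))
  expect_length(e0$active, 0)
  expect_identical(nrow(e0$configs), 0L)

  e2 <- enumerateConfigs(c(3, 0, 1))
  expect_identical(e2$active, c(1L, 3L))
  expect_identical(nrow(e2$configs), 3L)   # {10, 01, 11}

  e3 <- enumerateConfigs(c(1, 2, 3))
  expect_identical(nrow(e3$configs), 7L)   # 2^3 - 1

  expect_error(enumerateConfigs(rep(1, 13)), "cap")
})

test_that("the configuration prior renormalizes the Bernoulli product", {
  expect_equal(configPrior(matrix(1L, 1, 1), 0.3), 1)
  pr <- configPrior(enumerateConfigs(c(1, 1))$configs, c(0.5, 0.5))
  expect_equal(pr, rep(1 / 3, 3))
  # q = (1 - eps, eps): the first-locus-only configuration dominates
  cf <- enumerateConfigs(c(1, 1))$configs
  pr2 <- configPrior(cf, c(1 - 1e-9, 1e-9))
  expect_equal(pr2[which(cf[, 1] == 1L & cf[, 2] == 0L)], 1,
               tolerance = 1e-6)
  # normalization across random enumerations
  set.seed(700)
  for (m in c(2, 4, 6)) {
    q <- runif(m, 0.05, 0.95)
    expect_equal(sum(configPrior(enumerateConfigs(rep(1, m))$configs, q)), 1,
                 tolerance = 1e-12)
  }
})

test_that("gene likelihood matches the full 2^p brute-force enumeration", {
  toy <- toyGene(p = 3, n = 8, seed = 11)
  set.seed(701)
  x <- rnorm(8)
  Y <- 1 + x + 0.5 * collapseTrueStatus(toy$S) + rnorm(8)
  gamma1 <- c(0.9, 0.95, 1)
  gamma0 <- c(0.98, 1, 0.99)
  ceList <- lapply(1:3, function(j)
    CallErrorModel(gamma1[j], gamma0[j]))
  om <- OutcomeModel("gaussian", alpha = c(0.8, 1.1), beta = 0.4,
                     dispersion = 1.3)
  for (rho in c(0.05, 0.2)) {
    expect_equal(
      gsameLoglik(toy$gene, Y, matrix(x), rcDef, om, rho, ceList,
                  restrict = FALSE),
      oracleGeneLoglik(toy$gene@A, toy$gene@D, toy$gene@O, Y, x,
                       alpha = c(0.8, 1.1), beta = 0.4, disp = 1.3,
                       rho1g = rho, rc = rcDef, gamma1 = gamma1,
                       gamma0 = gamma0),
      tolerance = 1e-10)
  }
})

test_that("restricting to alt-positive loci changes only zero-support terms", {
  # when every locus of every sample has positive alt counts the
  # restriction is vacuous and both enumerations agree exactly
  toy <- toyGene(p = 2, n = 6, seed = 13)
  g <- toy$gene
  A <- pmax(g@A, 1L)
  g2 <- GeneData(A, pmax(g@D, A), g@O, geneId = "toy2")
  set.seed(702)
  x <- rnorm(6); Y <- rnorm(6)
  ce2 <- list(ceDef, ceDef)
  om <- OutcomeModel("gaussian", alpha = c(1, 1), beta = 0.2, dispersion = 1)
  expect_equal(
    gsameLoglik(g2, Y, matrix(x), rcDef, om, 0.1, ce2, restrict = TRUE),
    gsameLoglik(g2, Y, matrix(x), rcDef, om, 0.1, ce2, restrict = FALSE),
    tolerance = 1e-12)
})

test_that("a single-locus gene reduces exactly to the mutation-level model", {
  cfg <- simConfig(n = 150, rho1 = 0.15, beta = 0.7, seed = 703)
  sim <- simulateMutationSite(cfg)
  gene <- GeneData(matrix(sim$site@A, 1), matrix(sim$site@D, 1),
                   matrix(sim$site@O, 1), geneId = "p1")

  # likelihood evaluation: mutation-level form computed from the evidence
  om <- OutcomeModel("gaussian", alpha = c(1, 1), beta = 0.7, dispersion = 1)
  ev <- evidenceLoglik(sim$site, rcDef, ceDef)
  Xm <- cbind(1, sim$X)
  ly0 <- dnorm(sim$Y, drop(Xm %*% c(1, 1)), 1, log = TRUE)
  ly1 <- dnorm(sim$Y, drop(Xm %*% c(1, 1)) + 0.7, 1, log = TRUE)
  l0 <- log(0.9) + ly0 + ev[, 1]
  l1 <- log(0.1) + ly1 + ev[, 2]
  mref <- sum(pmax(l0, l1) + log(exp(l0 - pmax(l0, l1)) +
                                 exp(l1 - pmax(l0, l1))))
  expect_equal(
    gsameLoglik(gene, sim$Y, sim$X, rcDef, om, 0.1, list(ceDef),
                restrict = FALSE),
    mref, tolerance = 1e-10)

  # full test path: identical statistic and p-value
  gres <- gsameTest(gene, sim$Y, sim$X, rcDef, list(ceDef),
                    restrict = FALSE, tol = 1e-10)
  mres <- msameTest(sim$site, sim$Y, sim$X, rcDef, ceDef, tol = 1e-10)
  expect_equal(gres@statistic, mres@statistic, tolerance = 1e-6)
  expect_equal(gres@pvalue, mres@pvalue, tolerance = 1e-8)
  expect_equal(gres@fitAlt@loglik, mres@fitAlt@loglik, tolerance = 1e-8)
})

test_that("a gene with no alternative reads is dominated by the unmutated branch", {
  n <- 60
  gene <- GeneData(matrix(0L, 3, n),
                   matrix(100L, 3, n),
                   matrix(0L, 3, n), geneId = "empty")
  set.seed(704)
  fit <- gsameFit(gene, rnorm(n), NULL, rcDef,
                  ceList = replicate(3, ceDef))
  expect_true(all(fit@posterior < 0.10))
  res <- gsameTest(gene, rnorm(n), NULL, rcDef, replicate(3, ceDef))
  expect_true(is.na(res@pvalue))   # monomorphic: nothing to test
})

test_that("gene-level EM matches the oracle GLM under informative evidence and nests", {
  set.seed(705)
  n <- 150; p <- 3
  Smat <- matrix(rbinom(p * n, 1, 0.08), p, n)
  Sg <- collapseTrueStatus(Smat)
  x <- rnorm(n)
  Y <- 1 + x + 0.9 * Sg + rnorm(n)
  d <- 300L
  A <- matrix(0L, p, n)
  A[Smat == 1] <- as.integer(round(0.32 * d))
  gene <- GeneData(A, matrix(d, p, n), Smat, geneId = "inf")
  rcSharp <- new("ReadCountModel",
                 highDepth = list("00" = BetaBinomParams(0.002, 1e-4),
                                  "01" = BetaBinomParams(0.002, 1e-4),
                                  "10" = BetaBinomParams(0.32, 1e-4),
                                  "11" = BetaBinomParams(0.32, 1e-4)),
                 lowDepth = list("0" = BetaBinomParams(0.002, 1e-4),
                                 "1" = BetaBinomParams(0.32, 1e-4)),
                 d0 = 20)
  ceL <- replicate(p, CallErrorModel(0.999, 0.999))
  fit <- gsameFit(gene, Y, matrix(x), rcSharp, ceL)
  oracle <- lm(Y ~ x + Sg)
  expect_equal(fit@outcome@beta, unname(coef(oracle)[3]), tolerance = 1e-5)
  expect_equal(fit@posterior, Sg, tolerance = 1e-6)

  nullFit <- gsameFit(gene, Y, matrix(x), rcSharp, ceL, betaFixed = 0)
  expect_identical(nullFit@outcome@beta, 0)
  expect_lte(nullFit@loglik, fit@loglik + 1e-8)
  expect_true(all(diff(fit@loglikTrace) > -1e-6))
})

test_that("gene-level EM recovers the effect size across replicates", {
  cfg <- simConfig(n = 400, level = "gene", rho1 = 0.10, p = 10,
                   beta = 1.0, seed = 706)
  bh <- numeric(200)
  for (r in 1:200) {
    sim <- simulateGene(cfg, seed = 710 + r)
    bh[r] <- gsameFit(sim$gene, sim$Y, sim$X, rcDef)@outcome@beta
  }
  expect_lt(abs(mean(bh) - 1.0), 0.12)
})
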