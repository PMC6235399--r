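# Independent reference computations used to check the package's
# likelihoods, plus small fixture builders.

# beta-binomial pmf written directly from the beta-mixture definition
oracleBB <- function(a, d, pi, phi) {
  if (phi < 1e-12) return(dbinom(a, d, pi))
  sa <- pi * (1 - phi) / phi
  sb <- (1 - pi) * (1 - phi) / phi
  exp(lchoose(d, a) + lbeta(a + sa, d - a + sb) - lbeta(sa, sb))
}

# quadrature version: integrates Binom(a | d, q) against the Beta mixing law
oracleBBQuad <- function(a, d, pi, phi) {
  sa <- pi * (1 - phi) / phi
  sb <- (1 - pi) * (1 - phi) / phi
  integrate(function(q) dbinom(a, d, q) * dbeta(q, sa, sb),
            0, 1, rel.tol = 1e-12)$value
}

# per-locus evidence f(A, D, O | S = s) for the brute-force oracle,
# written without the package's stratum bookkeeping
oracleLocusEvidence <- function(a, d, o, s, rc, gamma1, gamma0) {
  hp <- function(key) c(rc@highDepth[[key]]@pi, rc@highDepth[[key]]@phi)
  lp <- function(key) c(rc@lowDepth[[key]]@pi, rc@lowDepth[[key]]@phi)
  if (d >= rc@d0) {
    pp <- hp(paste0(s, o))
    pcall <- if (s == 1) (if (o == 1) gamma1 else 1 - gamma1)
             else (if (o == 1) 1 - gamma0 else gamma0)
    oracleBB(a, d, pp[1], pp[2]) * pcall
  } else {
    pp <- lp(as.character(s))
    oracleBB(a, d, pp[1], pp[2])
  }
}

# full 2^p enumeration of the gene-level likelihood, no A>0 restriction:
# per sample, the S^g=0 branch uses the all-zero status vector and the
# S^g=1 branch sums over every non-zero vector with the common-q Bernoulli
# prior renormalized to exclude zero
oracleGeneLoglik <- function(A, D, O, Y, x, alpha, beta, disp, rho1g,
                             rc, gamma1, gamma0) {
  p <- nrow(A); n <- ncol(A)
  q <- 1 - (1 - rho1g)^(1 / p)
  svecs <- as.matrix(expand.grid(rep(list(0:1), p)))
  nz <- rowSums(svecs) > 0
  ll <- 0
  for (i in seq_len(n)) {
    fS <- function(sv) {
      out <- 1
      for (j in seq_len(p))
        out <- out * oracleLocusEvidence(A[j, i], D[j, i], O[j, i], sv[j],
                                         rc, gamma1[j], gamma0[j])
      out
    }
    mu0 <- alpha[1] + alpha[2] * x[i]
    fy0 <- dnorm(Y[i], mu0, sqrt(disp))
    fy1 <- dnorm(Y[i], mu0 + beta, sqrt(disp))
    L0 <- (1 - rho1g) * fy0 * fS(rep(0L, p))
    L1terms <- apply(svecs[nz, , drop = FALSE], 1, function(sv) {
      k <- sum(sv)
      pri <- q^k * (1 - q)^(p - k) / (1 - (1 - q)^p)
      pri * fS(sv)
    })
    ll <- ll + log(L0 + rho1g * fy1 * sum(L1terms))
  }
  ll
}

# small deterministic gene fixture with informative counts
toyGene <- function(p = 3, n = 8, seed = 11, d0 = 20) {
  set.seed(seed)
  D <- matrix(sample(25:120, p * n, replace = TRUE), p, n)
  S <- matrix(rbinom(p * n, 1, 0.25), p, n)
  A <- matrix(0L, p, n)
  for (j in seq_len(p)) for (i in seq_len(n))
    A[j, i] <- rbinom(1, D[j, i], ifelse(S[j, i] == 1, 0.3, 0.004))
  O <- (A / D > 0.1) * 1L
  list(gene = GeneData(A, D, O, geneId = "toy"), S = S)
}
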