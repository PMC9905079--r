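# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths wherever they check one.

# toy genotype matrix with binomial dosages at given MAFs
toy_genotypes <- function(n, mafs, prefix = "1") {
  G <- sapply(seq_along(mafs), function(j) rbinom(n, 2, mafs[j]))
  colnames(G) <- paste(prefix, seq_along(mafs) * 1000, "A", "T", sep = ":")
  G
}

# Permutation oracle for the omnibus min-p statistic under an
# intercept-only null model (where phenotype permutation is exact).
# The same permutations are used for every rho; per-rho permutation
# p-values are rank-based, and the omnibus permutation p is the fraction
# of permutations whose min-p is at least as extreme as the observed one.
perm_omnibus_p <- function(G, y, trait = "quantitative",
                           B = 1e5,
                           rho_grid = c(0, 0.01, 0.04, 0.09, 0.16,
                                        0.25, 0.5, 1)) {
  n <- length(y)
  af <- colMeans(G) / 2
  w <- dbeta(pmin(af, 1 - af), 1, 25)
  Gw <- sweep(G, 2, w, `*`)
  center <- function(v) v - mean(v)
  R <- matrix(0, B + 1L, n)
  R[1L, ] <- center(y)
  for (b in seq_len(B)) R[b + 1L, ] <- center(y)[sample.int(n)]
  S <- R %*% Gw
  Qs <- rowSums(S^2)
  Qb <- rowSums(S)^2
  pm <- rep(1, B + 1L)
  for (r in rho_grid) {
    Q <- (1 - r) * Qs + r * Qb
    pr <- (B + 2L - rank(Q, ties.method = "max")) / (B + 1L)
    pm <- pmin(pm, pr)
  }
  mean(pm <= pm[1L])
}

# Straightforward variance-component (SKAT) test written from the kernel
# definition: Q = r' G W^2 G' r / sigma^2, null = eigenvalues of the
# covariate-projected weighted genotype crossproduct.
independent_skat_p <- function(G, y, X = NULL) {
  Xf <- cbind(1, X)
  fit <- lm.fit(Xf, y)
  r <- fit$residuals
  s2 <- sum(r^2) / (length(y) - ncol(Xf))
  af <- colMeans(G) / 2
  w <- dbeta(pmin(af, 1 - af), 1, 25)
  K <- (G %*% diag(w^2, ncol(G))) %*% t(G)
  Q <- as.numeric(t(r) %*% K %*% r) / s2
  H <- Xf %*% solve(crossprod(Xf)) %*% t(Xf)
  M <- diag(length(y)) - H
  Gw <- sweep(G, 2, w, `*`)
  lam <- eigen(crossprod(Gw, M %*% Gw), symmetric = TRUE,
               only.values = TRUE)$values
  lam <- lam[lam > max(lam) * 1e-10]
  as.numeric(quad_form_pvalue(lam, Q))
}

# null-cohort phenotype/genotype pair shaped like the analysis inputs
null_cohort_small <- function(seed, n = 400, mafs = c(0.002, 0.005, 0.01)) {
  set.seed(seed)
  G <- toy_genotypes(n, mafs)
  y <- rnorm(n)
  list(G = G, y = y)
}
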