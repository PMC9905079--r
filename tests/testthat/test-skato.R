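test_that("null model matches closed forms and flags degenerate designs", {
  set.seed(3)
  n <- 20
  y <- rnorm(n)
  # intercept-only: residuals are the centered phenotype
  nl <- fit_null_model(y, NULL, "quantitative")
  expect_equal(nl$residuals, y - mean(y))
  expect_equal(nl$sigma2, var(y))
  # residuals match an independent normal-equations solve
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n))
  nl2 <- fit_null_model(y, X, "quantitative")
  Xf <- cbind(1, X)
  beta <- solve(t(Xf) %*% Xf, t(Xf) %*% y)
  expect_equal(nl2$residuals, as.vector(y - Xf %*% beta), tolerance = 1e-10)
  # residuals orthogonal to covariates
  expect_lt(max(abs(crossprod(Xf, nl2$residuals))), 1e-8)
  # phenotype equal to a covariate column: degenerate
  expect_warning(nl3 <- fit_null_model(X[, 1], X, "quantitative"),
                 "residual variance")
  expect_true(nl3$degenerate)
  # collinear design is rejected with the offending column named
  expect_error(fit_null_model(y, cbind(a = X[, 1], b = 2 * X[, 1])), "b")
  # binary guards
  expect_error(fit_null_model(rep(1, n), NULL, "binary"), "single class")
  expect_error(fit_null_model(y, NULL, "binary"), "0/1")
})

test_that("beta weights evaluate the beta(1,25) density", {
  expect_equal(beta_weight(1e-9), 25, tolerance = 1e-6)
  expect_equal(beta_weight(0.5), 25 * 0.5^24)
  expect_equal(beta_weight(c(0.1, 0.7), a = 1, b = 1), c(1, 1))
  expect_error(beta_weight(0), "strictly")
  expect_error(beta_weight(1), "strictly")
})

test_that("rho = 1 on one variant reduces to the single-variant score test", {
  set.seed(4)
  n <- 150
  g <- matrix(rbinom(n, 2, 0.1), ncol = 1, dimnames = list(NULL, "1:5:A:T"))
  y <- rnorm(n) + 0.3 * g[, 1]
  X <- cbind(age = rnorm(n))
  nl <- fit_null_model(y, X, "quantitative")
  fit <- skat_o_test(g, nl, rho_grid = 1)
  # independent score test: z^2 of the residual-on-residual regression
  Xf <- cbind(1, X)
  M <- diag(n) - Xf %*% solve(crossprod(Xf)) %*% t(Xf)
  r <- M %*% y
  gr <- M %*% g[, 1]
  s2 <- sum(r^2) / (n - ncol(Xf))
  z2 <- sum(g[, 1] * r)^2 / (s2 * sum(g[, 1] * gr))
  expect_equal(fit$p_value, pchisq(z2, 1, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("rho = 0 equals an independently coded variance-component test", {
  set.seed(5)
  n <- 200
  G <- toy_genotypes(n, c(0.02, 0.05, 0.1, 0.15))
  y <- rnorm(n)
  X <- cbind(sex = rbinom(n, 1, 0.5))
  nl <- fit_null_model(y, X, "quantitative")
  fit <- skat_o_test(G, nl, rho_grid = 0)
  expect_equal(fit$p_value, independent_skat_p(G, y, X), tolerance = 1e-6)
})

test_that("omnibus p respects the per-rho envelope and ordering invariants", {
  set.seed(6)
  n <- 300
  G <- toy_genotypes(n, c(0.01, 0.03, 0.08, 0.12, 0.2))
  y <- rnorm(n) + 0.1 * G[, 1]
  nl <- fit_null_model(y, NULL, "quantitative")
  fit <- skat_o_test(G, nl)
  expect_gte(fit$p_value, min(fit$p_rho))
  expect_lte(fit$p_value, min(1, min(fit$p_rho) * length(fit$p_rho)))
  # permuting subjects (consistently) or variant order leaves p unchanged
  perm_s <- sample.int(n)
  nl_p <- fit_null_model(y[perm_s], NULL, "quantitative")
  fit_s <- skat_o_test(G[perm_s, ], nl_p)
  expect_equal(fit_s$p_value, fit$p_value, tolerance = 1e-10)
  perm_v <- sample.int(ncol(G))
  fit_v <- skat_o_test(G[, perm_v], nl)
  expect_equal(fit_v$p_value, fit$p_value, tolerance = 1e-8)
  # scaling all weights by a positive constant leaves p unchanged
  af <- colMeans(G) / 2
  w <- beta_weight(pmin(af, 1 - af))
  fit_w <- skat_o_test(G, nl, weights = w)
  fit_w10 <- skat_o_test(G, nl, weights = 10 * w)
  expect_equal(fit_w$p_value, fit_w10$p_value, tolerance = 1e-10)
})

test_that("missing dosages are mean-imputed and zero-variance genes excluded", {
  set.seed(7)
  n <- 100
  G <- toy_genotypes(n, c(0.1, 0.2))
  y <- rnorm(n)
  nl <- fit_null_model(y, NULL, "quantitative")
  Gm <- G
  Gm[sample(n, 5), 1] <- NA
  fit <- skat_o_test(Gm, nl)
  expect_equal(fit$status, "tested")
  # manual mean imputation reproduces the same p
  Gi <- Gm
  Gi[is.na(Gi[, 1]), 1] <- 2 * (sum(Gm[, 1], na.rm = TRUE) /
                                  (2 * sum(!is.na(Gm[, 1]))))
  expect_equal(skat_o_test(Gi, nl)$p_value, fit$p_value, tolerance = 1e-12)
  # all-identical dosages: excluded, not an error
  G0 <- matrix(0, n, 2, dimnames = list(NULL, c("1:1:A:T", "1:2:A:T")))
  expect_equal(skat_o_test(G0, nl)$status, "excluded_empty")
})

test_that("binary-trait test is calibrated against its permutation oracle", {
  set.seed(8)
  n <- 100
  G <- toy_genotypes(n, c(0.08, 0.12, 0.2))
  y <- rbinom(n, 1, 0.5)
  nl <- fit_null_model(y, NULL, "binary")
  fit <- skat_o_test(G, nl)
  pp <- perm_omnibus_p(G, y, B = 2e4)
  expect_lt(abs(fit$p_value - pp), 3 * sqrt(pp * (1 - pp) / 2e4) + 0.01)
})

test_that("category scan preserves gene accounting and position order", {
  set.seed(9)
  co <- simulate_cohort(sim_config(n_subjects = 400, n_genes = 12, seed = 21))
  st <- variant_stats(co$genotypes)
  ann <- co$annotations[st, on = "variant_id"]
  mk <- build_mask(ann, "pLOF_missense",
                   mask_config(caf_min = 1e-4))
  nl <- fit_null_model(co$pheno$proxy_score, as.matrix(co$covariates))
  res <- run_category_scan(mk, co$genotypes, nl)
  expect_equal(nrow(res), nrow(mk))
  expect_true(all(res$status %in% c("tested", "excluded_caf",
                                    "excluded_empty")))
  expect_false(is.unsorted(res$chrom + res$pos / 1e9))
  expect_true(all(res[status == "tested", p] > 0 &
                    res[status == "tested", p] <= 1))
})
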