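test_that("single-variant scan matches an independent least-squares solve", {
  set.seed(11)
  n <- 120
  G <- toy_genotypes(n, c(0.1, 0.2, 0.3))
  X <- cbind(age = rnorm(n), sex = rbinom(n, 1, 0.5))
  y <- rnorm(n) + 0.2 * G[, 2]
  res <- single_variant_scan(G, y, X)
  for (j in 1:3) {
    fit <- lm(y ~ G[, j] + X)
    cf <- summary(fit)$coefficients[2, ]
    row <- res[variant_id == colnames(G)[j]]
    expect_equal(row$beta, unname(cf[1]), tolerance = 1e-8)
    expect_equal(row$se, unname(cf[2]), tolerance = 1e-8)
    expect_equal(row$p, unname(cf[4]), tolerance = 1e-8)
  }
  expect_false(is.unsorted(res$p))
  # monomorphic variant is skipped with a flag
  G0 <- cbind(G, `1:9999:A:T` = 0L)
  res0 <- single_variant_scan(G0, y, X)
  expect_equal(res0[variant_id == "1:9999:A:T", flag], "monomorphic")
})

test_that("genomic inflation is 1 at p = 0.5 and tracks inflated chi-squares", {
  expect_equal(genomic_inflation(rep(0.5, 10))$lambda, 1.0)
  set.seed(12)
  u <- runif(2e4)
  expect_equal(genomic_inflation(u)$lambda, 1, tolerance = 0.02)
  infl <- pchisq(1.2 * rchisq(2e4, 1), 1, lower.tail = FALSE)
  expect_equal(genomic_inflation(infl)$lambda, 1.2, tolerance = 0.03)
  expect_error(genomic_inflation(numeric(0)), "no p-values")
})

test_that("Bonferroni thresholds reproduce the published across-category arithmetic", {
  th <- bonferroni_thresholds(c(6749, 11037, 16010, 18425), alpha = 0.05)
  expect_equal(signif(th$across, 3), 6.78e-7)
  expect_equal(th$within, 0.05 / c(6749, 11037, 16010, 18425))
  th1 <- bonferroni_thresholds(rep(1, 4))
  expect_equal(th1$across, 0.05 / 4)
  expect_equal(unname(th1$within), rep(0.05, 4))
  expect_equal(bonferroni_thresholds(rep(10, 4))$across, 1.25e-3)
  expect_error(bonferroni_thresholds(c(0, 5)), "at least one")
})

test_that("BH step-up agrees with a brute-force threshold search", {
  expect_equal(bh_fdr(c(0.001, 0.2, 0.9), q = 0.1), c(TRUE, FALSE, FALSE))
  expect_equal(bh_fdr(rep(1, 5), q = 0.1), rep(FALSE, 5))
  expect_equal(bh_fdr(rep(0.001, 5), q = 0.1), rep(TRUE, 5))
  brute <- function(p, q) {
    m <- length(p)
    o <- order(p)
    k <- max(c(0, which(p[o] <= q * seq_len(m) / m)))
    disc <- rep(FALSE, m)
    if (k > 0) disc[o[seq_len(k)]] <- TRUE
    disc
  }
  set.seed(13)
  for (i in 1:25) {
    p <- runif(sample(3:40, 1))^sample(1:3, 1)
    expect_equal(bh_fdr(p, 0.1), brute(p, 0.1))
  }
})

test_that("no-op sensitivity rerun is identical; exclusions remove what they claim", {
  set.seed(14)
  n <- 500
  G <- toy_genotypes(n, c(0.05, 0.1, 0.002))
  y <- rnorm(n)
  nl <- fit_null_model(y, NULL)
  base <- skat_o_test(G, nl)
  noop <- sensitivity_rerun(G, nl, sensitivity_config())
  expect_identical(noop$p_value, base$p_value)
  expect_equal(sum(noop$removed), 0L)
  # low-MAC exclusion drops the rare column
  st <- variant_stats(G)
  low <- sensitivity_rerun(G, nl, sensitivity_config(min_mac = 5))
  expect_equal(unname(low$removed["low_mac"]), sum(st$mac < 5))
  # moderate-p exclusion needs the single-variant p-values
  expect_error(sensitivity_rerun(G, nl,
                                 sensitivity_config(moderate_p_threshold = 1e-4)),
               "per-variant")
  sv <- single_variant_scan(G, y, NULL)
  pv <- setNames(sv$p, sv$variant_id)
  mod <- sensitivity_rerun(G, nl,
                           sensitivity_config(moderate_p_threshold = 0.99),
                           single_variant_p = pv)
  expect_true(sum(mod$removed) > 0)
  # removing everything gives an explicit empty status
  all_gone <- sensitivity_rerun(G, nl,
                                sensitivity_config(moderate_p_threshold = 1),
                                single_variant_p = pv)
  expect_equal(all_gone$status, "excluded_empty")
})

test_that("conditional rerun validates the conditioning vector and perturbs p only slightly under noise", {
  set.seed(15)
  n <- 400
  G <- toy_genotypes(n, c(0.05, 0.1))
  y <- rnorm(n)
  X <- cbind(age = rnorm(n))
  expect_error(conditional_rerun(G, y, X, rep(0, n)), "no variance")
  expect_error(conditional_rerun(G, y, X, X[, 1] * 3), "collinear")
  base <- skat_o_test(G, fit_null_model(y, X))
  cond <- conditional_rerun(G, y, X, rnorm(n))
  # random-noise conditioning barely moves the p-value
  expect_equal(cond$p_value, base$p_value, tolerance = 0.15)
})
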