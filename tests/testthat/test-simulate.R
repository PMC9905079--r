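test_that("same seed gives bit-identical cohorts; components are seed-stable", {
  cfg <- sim_config(n_subjects = 200, n_genes = 6, seed = 41)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$pheno, b$pheno)
  expect_identical(a$covariates, b$covariates)
  c2 <- simulate_cohort(sim_config(n_subjects = 200, n_genes = 6, seed = 42))
  expect_false(identical(a$genotypes, c2$genotypes))
})

test_that("offspring dosages are Mendelian-consistent with parental dosages", {
  co <- simulate_cohort(sim_config(n_subjects = 2000, n_genes = 10,
                                   seed = 43))
  off <- co$genotypes; fa <- co$father; mo <- co$mother
  # a parent with dosage 0 cannot transmit; dosage 2 always transmits
  expect_true(all(off <= (fa > 0) + (mo > 0) + (fa == 2) + (mo == 2)))
  expect_true(all(off >= (fa == 2) + (mo == 2)))
  expect_true(all(off >= 0 & off <= 2))
})

test_that("transmission correlation approaches its random-mating expectation", {
  co <- simulate_cohort(sim_config(n_subjects = 20000, n_genes = 12,
                                   variants_per_gene = 12,
                                   maf_shape1 = 2, maf_shape2 = 50,
                                   seed = 44))
  keep <- colMeans(co$genotypes) / 2 > 0.002
  off <- rowSums(co$genotypes[, keep])
  mid <- rowSums(co$father[, keep] + co$mother[, keep]) / 2
  one <- rowSums(co$father[, keep])
  # corr(offspring, mid-parent) ~ 1/sqrt(2); corr(offspring, one parent) ~ 1/2
  expect_equal(cor(off, mid), 1 / sqrt(2), tolerance = 0.05)
  expect_equal(cor(off, one), 0.5, tolerance = 0.05)
})

test_that("realized MAFs track generating MAFs and annotations are coherent", {
  co <- simulate_cohort(sim_config(n_subjects = 20000, n_genes = 10,
                                   maf_shape1 = 1, maf_shape2 = 100,
                                   seed = 45))
  vm <- co$variant_map
  realized <- colMeans(co$genotypes) / 2
  fit <- lm(realized ~ vm$maf)
  expect_equal(unname(coef(fit)[2]), 1, tolerance = 0.05)
  # REVEL present iff missense
  expect_true(all(!is.na(vm$revel[vm$class == "missense"])))
  expect_true(all(is.na(vm$revel[vm$class != "missense"])))
  # LOFTEE flags match classes
  expect_true(all(vm$loftee[vm$class == "HiC_pLOF"] == "HC"))
  expect_true(all(vm$loftee[vm$class == "missense"] == ""))
})

test_that("null cohorts carry no burden-phenotype association", {
  cors <- vapply(1:5, function(s) {
    co <- simulate_cohort(sim_config(n_subjects = 2000, n_genes = 5,
                                     seed = 450 + s))
    burden <- rowSums(co$genotypes)
    cor(burden, co$pheno$proxy_score)
  }, 0)
  expect_lt(max(abs(cors)), 3 / sqrt(2000))
})

test_that("proxy-score association is attenuated relative to the parents' own phenotype", {
  cfg <- sim_config(n_subjects = 8000, n_genes = 4, seed = 46,
                    causal_genes = data.frame(gene = "GENE001",
                                              causal_fraction = 1,
                                              effect = 2))
  co <- simulate_cohort(cfg)
  vids <- co$truth$variant_id
  off_burden <- rowSums(co$genotypes[, vids, drop = FALSE])
  fa_burden <- rowSums(co$father[, vids, drop = FALSE])
  # slope of proxy score on offspring burden, standardized, vs slope of
  # parental affection on the parent's own burden, standardized
  z_off <- abs(cor(off_burden, co$pheno$proxy_score))
  z_par <- abs(cor(fa_burden, co$pheno$father_affected))
  expect_lt(z_off, z_par)
})

test_that("the LD conditioning locus creates and conditioning removes the signal", {
  cfg <- sim_config(n_subjects = 6000, n_genes = 5, seed = 47,
                    variants_per_gene = 12, maf_shape1 = 2, maf_shape2 = 120)
  co <- simulate_cohort(cfg)
  inj <- inject_ld_conditioning_locus(co, "GENE002")
  # conditioning dosage has the configured MAF within sampling error
  expect_equal(mean(inj$conditioning) / 2, inj$common_maf, tolerance = 0.02)
  # rare dosages correlate with the common dosage (the planted haplotype
  # structure), and effect = 0 injection keeps the gene null
  vids <- co$variant_map[gene == "GENE002", variant_id]
  burden <- rowSums(inj$cohort$genotypes[, vids, drop = FALSE])
  expect_gt(cor(burden, inj$conditioning), 0.2)
  # infeasible request errors with the bound
  cfg_bad <- sim_config(n_subjects = 100, n_genes = 2, seed = 48,
                        maf_max = 0.009)
  co_bad <- simulate_cohort(cfg_bad)
  expect_error(inject_ld_conditioning_locus(co_bad, "GENE001",
                                            common_maf = 1e-4),
               "feasible")
})

test_that("fixtures round-trip through the package readers", {
  co <- simulate_cohort(sim_config(n_subjects = 40, n_genes = 4, seed = 49,
                                   missing_rate = 0.01))
  dir <- file.path(tempdir(), "fixtures-test")
  paths <- write_fixtures(co, dir)
  expect_true(all(file.exists(paths)))
  G2 <- read_vcf_dosage(paths[["genotypes"]])
  expect_equal(unname(G2[rownames(co$genotypes), colnames(co$genotypes)]),
               unname(co$genotypes))
  ann <- read_table_tsv(paths[["annotation"]])
  expect_equal(ann$variant_id, co$annotations$variant_id)
  ph <- read_table_tsv(paths[["phenotype"]])
  resc <- score_phenotypes(ph)
  expect_equal(resc$proxy_score, co$pheno$proxy_score)
  tr <- read_table_tsv(paths[["truth"]])
  expect_equal(nrow(tr), nrow(co$truth))
  unlink(dir, recursive = TRUE)
})
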