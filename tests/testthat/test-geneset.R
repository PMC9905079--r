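geneset_fixture <- function(seed = 16, n = 500, n_genes = 8) {
  set.seed(seed)
  co <- simulate_cohort(sim_config(n_subjects = n, n_genes = n_genes,
                                   seed = seed))
  st <- variant_stats(co$genotypes)
  ann <- co$annotations[st, on = "variant_id"]
  masks <- build_mask(ann, "pLOF_missense", mask_config(caf_min = 0))
  nl <- fit_null_model(co$pheno$proxy_score, as.matrix(co$covariates))
  list(co = co, masks = masks, null = nl)
}

test_that("a singleton set reproduces the gene's own test and pooling deduplicates", {
  fx <- geneset_fixture()
  g <- fx$masks$gene[1]
  single <- run_geneset_test(gene_set("one", g), fx$masks, fx$co$genotypes,
                             fx$null)
  own <- skat_o_test(
    fx$co$genotypes[, fx$masks$variant_ids[[1]], drop = FALSE], fx$null)
  expect_equal(single$p_value, own$p_value, tolerance = 1e-10)
  # duplicating the member gene in the list changes nothing
  dup <- run_geneset_test(gene_set("dup", c(g, g)), fx$masks,
                          fx$co$genotypes, fx$null)
  expect_equal(dup$p_value, single$p_value, tolerance = 1e-12)
  # a variant shared by two member genes enters once: fake an overlap
  masks2 <- data.table::copy(fx$masks)
  masks2$variant_ids[[2]] <- c(masks2$variant_ids[[2]],
                               masks2$variant_ids[[1]][1])
  both <- run_geneset_test(gene_set("two", fx$masks$gene[1:2]), masks2,
                           fx$co$genotypes, fx$null)
  pooled <- unique(unlist(masks2$variant_ids[1:2]))
  direct <- skat_o_test(fx$co$genotypes[, pooled, drop = FALSE], fx$null)
  expect_equal(both$p_value, direct$p_value, tolerance = 1e-12)
})

test_that("region and gene exclusions empty the set when they cover it", {
  fx <- geneset_fixture()
  genes <- fx$masks$gene
  # excluded_genes covering all members
  empty <- run_geneset_test(gene_set("none", genes, excluded_genes = genes),
                            fx$masks, fx$co$genotypes, fx$null)
  expect_equal(empty$status, "excluded_empty")
  # region spanning every simulated position (all chromosomes share pos range)
  pos <- proxyrvat:::variant_positions(unlist(fx$masks$variant_ids))
  chroms <- unique(data.table::tstrsplit(
    unlist(fx$masks$variant_ids), ":")[[1]])
  one_chr <- chroms[1]
  inside <- gene_set("region", genes,
                     excluded_region = c(one_chr, 0, 4e9))
  res <- run_geneset_test(inside, fx$masks, fx$co$genotypes, fx$null)
  # only genes on that chromosome are excluded
  remaining <- genes[!vapply(seq_along(genes), function(i) {
    any(data.table::tstrsplit(fx$masks$variant_ids[[i]], ":")[[1]] == one_chr)
  }, NA)]
  expect_equal(res$n_genes_effective, length(remaining))
  # closed-open convention: a region ending exactly at a variant position
  # does not exclude it
  vid <- fx$masks$variant_ids[[1]][1]
  parts <- strsplit(vid, ":")[[1]]
  boundary <- gene_set("edge", fx$masks$gene[1],
                       excluded_region = c(parts[1], 0,
                                           as.numeric(parts[2])))
  gs <- proxyrvat:::genes_in_region(fx$masks[1], boundary$excluded_region)
  other_pos <- proxyrvat:::variant_positions(
    fx$masks$variant_ids[[1]])$pos
  if (all(other_pos >= as.numeric(parts[2]))) {
    expect_length(gs, 0)
  }
})

test_that("leave-one-out identifies an injected driver gene", {
  set.seed(17)
  cfg <- sim_config(n_subjects = 2500, n_genes = 8, seed = 171,
                    causal_genes = data.frame(gene = "GENE003",
                                              causal_fraction = 1,
                                              effect = 2.5))
  co <- simulate_cohort(cfg)
  st <- variant_stats(co$genotypes)
  ann <- co$annotations[st, on = "variant_id"]
  masks <- build_mask(ann, "pLOF_missense", mask_config(caf_min = 0))
  nl <- fit_null_model(co$pheno$proxy_score, as.matrix(co$covariates))
  loo <- leave_one_out(gene_set("all", masks$gene), masks, co$genotypes, nl)
  expect_equal(nrow(loo), nrow(masks))
  expect_equal(attr(loo, "driver"), "GENE003")
  # omitting the driver hurts the set p far more than any null omission
  p_driver <- loo[omitted_gene == "GENE003", p]
  expect_gt(p_driver, max(loo[omitted_gene != "GENE003", p]) )
  # two-member set yields two rows
  loo2 <- leave_one_out(gene_set("two", masks$gene[1:2]), masks,
                        co$genotypes, nl)
  expect_equal(nrow(loo2), 2L)
})

test_that("GMT round-trip parses set names and members", {
  tf <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tG1\tG2\tG3", "setB\tdesc\tG9"), tf)
  sets <- read_gmt(tf)
  expect_named(sets, c("setA", "setB"))
  expect_equal(sets$setA$member_genes, c("G1", "G2", "G3"))
  writeLines("bad\tonlydesc", tf)
  expect_error(read_gmt(tf), "malformed")
})
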