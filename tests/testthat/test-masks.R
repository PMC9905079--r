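toy_annotation <- function() {
  data.table::data.table(
    variant_id = sprintf("1:%d:A:T", 1:8),
    gene = c("G1", "G1", "G1", "G1", "G2", "G2", "G2", "G3"),
    consequence = c("stop_gained", "frameshift_variant", "missense_variant",
                    "missense_variant", "synonymous_variant",
                    "missense_variant", "splice_donor_variant",
                    "intron_variant"),
    loftee = c("HC", "LC", "", "", "", "", "HC", ""),
    revel = c(NA, NA, 0.607, 0.335, NA, 0.8, NA, NA),
    maf = c(0.001, 0.002, 0.003, 0.004, 0.005, 4e-5, 3e-5, 0.002))
}

test_that("QC filter tallies missingness, MAC 0 and duplicates", {
  set.seed(10)
  n <- 50
  G <- toy_genotypes(n, c(0.1, 0.2, 0.15, 0.1, 0.05))
  G[1:6, 1] <- NA                                  # 12% missing
  G[, 2] <- 0L                                     # MAC 0
  colnames(G)[4] <- colnames(G)[3]                 # positional duplicate
  qc <- qc_filter_variants(G, max_missing = 0.05)
  expect_equal(unname(qc$tally), c(1L, 1L, 1L))
  expect_equal(ncol(qc$genotypes), 2L)
  # the first record of the duplicate pair is the one kept
  expect_equal(colnames(qc$genotypes)[1], colnames(G)[3])
  # clean matrix passes through identically
  G2 <- toy_genotypes(n, c(0.1, 0.2))
  qc2 <- qc_filter_variants(G2)
  expect_identical(qc2$genotypes, G2)
  expect_equal(sum(qc2$tally), 0L)
  # removing everything warns rather than failing silently
  G3 <- matrix(0L, n, 2, dimnames = list(NULL, c("1:1:A:T", "1:2:A:T")))
  expect_warning(qc3 <- qc_filter_variants(G3), "every variant")
  expect_equal(ncol(qc3$genotypes), 0L)
})

test_that("consequence classification maps the canonical LOF terms", {
  expect_equal(as.character(classify_consequence("stop_gained", "HC")),
               "HiC_pLOF")
  expect_equal(as.character(classify_consequence("stop_gained", "LC")),
               "pLOF_other")
  expect_equal(as.character(classify_consequence("missense_variant", "")),
               "missense")
  expect_equal(as.character(classify_consequence("synonymous_variant", "")),
               "synonymous")
  expect_message(cls <- classify_consequence("intron_variant", ""),
                 "unrecognized")
  expect_equal(as.character(cls), "other")
  lof <- c("start_lost", "stop_lost", "frameshift_variant", "stop_gained",
           "splice_donor_variant", "splice_acceptor_variant",
           "transcript_ablation")
  expect_true(all(classify_consequence(lof, rep("HC", 7)) == "HiC_pLOF"))
})

test_that("masks nest, REVEL threshold splits missense, CAF filter excludes", {
  ann <- toy_annotation()
  cfg <- mask_config()
  masks <- suppressMessages(build_masks(ann, cfg))
  vids <- function(cat, g) {
    mk <- masks[[cat]]
    if (!g %in% mk$gene) return(character())
    mk$variant_ids[[match(g, mk$gene)]]
  }
  for (g in c("G1", "G2")) {
    expect_true(all(vids("HiC_pLOF", g) %in% vids("pLOF", g)))
    expect_true(all(vids("pLOF", g) %in% vids("pLOF_REVEL", g)))
    expect_true(all(vids("pLOF_REVEL", g) %in% vids("pLOF_missense", g)))
    expect_length(intersect(vids("synonymous", g), vids("pLOF_missense", g)),
                  0)
  }
  # REVEL 0.607 passes the 0.5 threshold, 0.335 does not
  expect_true("1:3:A:T" %in% vids("pLOF_REVEL", "G1"))
  expect_false("1:4:A:T" %in% vids("pLOF_REVEL", "G1"))
  expect_true("1:4:A:T" %in% vids("pLOF_missense", "G1"))
  # G2's REVEL+pLOF variants sum to 7e-5 < 1e-4: excluded
  mk <- masks[["pLOF_REVEL"]]
  expect_false(mk[gene == "G2", included])
  expect_equal(mk[gene == "G2", caf], 7e-5)
  # CAF filtering is idempotent
  again <- suppressMessages(
    build_mask(ann[variant_id %in% unlist(mk[included == TRUE, variant_ids])],
               "pLOF_REVEL", cfg))
  expect_equal(again[order(gene), .(gene, n_variants, caf)],
               mk[included == TRUE][order(gene), .(gene, n_variants, caf)])
})

test_that("mask nesting and gene-count monotonicity hold on simulated tables", {
  co <- simulate_cohort(sim_config(n_subjects = 300, n_genes = 25, seed = 33))
  st <- variant_stats(co$genotypes)
  ann <- co$annotations[st, on = "variant_id"]
  masks <- build_masks(ann, mask_config(caf_min = 0))
  summ <- mask_summary(masks)
  counts <- summ$n_genes_total[match(c("HiC_pLOF", "pLOF", "pLOF_REVEL",
                                       "pLOF_missense"), summ$category)]
  expect_true(all(diff(counts) >= 0))
  for (g in unique(ann$gene)) {
    sets <- lapply(c("HiC_pLOF", "pLOF", "pLOF_REVEL", "pLOF_missense"),
                   function(cat) {
                     mk <- masks[[cat]]
                     if (!g %in% mk$gene) character()
                     else mk$variant_ids[[match(g, mk$gene)]]
                   })
    expect_true(all(sets[[1]] %in% sets[[2]]))
    expect_true(all(sets[[2]] %in% sets[[3]]))
    expect_true(all(sets[[3]] %in% sets[[4]]))
  }
})
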