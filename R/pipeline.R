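# End-to-end orchestration: discovery scan over all categories with the
# synonymous control, replication of candidate genes in a second cohort,
# and export of plot-ready tables.

#' Run configuration for the discovery / replication pipeline
#'
#' @param categories functional categories scanned as the main analyses
#'   (default the four nested masks; the synonymous control always runs
#'   alongside in discovery).
#' @param maf_max,caf_min,revel_threshold,caf_method see [mask_config()].
#' @param qc_max_missing variant missingness ceiling at QC.
#' @param alpha family-wise error target for Bonferroni decisions.
#' @param fdr_q BH false-discovery-rate level.
#' @param moderate_p single-variant p threshold defining "moderately
#'   associated" variants in sensitivity reruns.
#' @param min_mac MAC floor of the low-MAC sensitivity scenario.
#' @param use_batch include the batch covariate (discovery cohorts; a
#'   single-batch replication cohort sets this `FALSE`).
#' @param rho_grid,weight_a,weight_b see [skat_o_test()].
#' @param seed recorded in the run manifest.
#' @return a `run_config` list.
#' @export
run_config <- function(categories = setdiff(mask_categories(), "synonymous"),
                       maf_max = 0.01, caf_min = 1e-4, revel_threshold = 0.5,
                       caf_method = "sum_maf", qc_max_missing = 0.05,
                       alpha = 0.05, fdr_q = 0.1, moderate_p = 1e-4,
                       min_mac = 5L, use_batch = TRUE,
                       rho_grid = default_rho_grid(),
                       weight_a = 1, weight_b = 25, seed = NA_integer_) {
  structure(as.list(environment()), class = "run_config")
}

covariate_matrix <- function(covariates, use_batch) {
  X <- data.table::as.data.table(covariates)
  if ("subject_id" %in% names(X)) X[, subject_id := NULL]
  if (!use_batch && "batch" %in% names(X)) X[, batch := NULL]
  as.matrix(X)
}

prepare_inputs <- function(genotypes, annotations, config) {
  qc <- qc_filter_variants(genotypes, max_missing = config$qc_max_missing)
  st <- variant_stats(qc$genotypes)
  ann <- data.table::as.data.table(annotations)
  ann <- ann[st, on = "variant_id", nomatch = NULL]
  if (!"class" %in% names(ann)) {
    ann[, class := classify_consequence(consequence, loftee)]
  }
  mcfg <- mask_config(config$maf_max, config$revel_threshold,
                      config$caf_min, config$caf_method)
  masks <- build_masks(ann, mcfg,
                       categories = unique(c(config$categories,
                                             "synonymous")),
                       genotypes = qc$genotypes)
  maf <- stats::setNames(st$maf, st$variant_id)
  list(genotypes = qc$genotypes, qc_tally = qc$tally, annotations = ann,
       masks = masks, maf = maf)
}

#' Discovery analysis: all-category gene scan with synonymous control
#'
#' Applies variant QC, builds the functional masks, fits the quantitative
#' null model of the proxy score on the covariates, scans every category
#' (plus the synonymous control), computes per-category genomic inflation,
#' Bonferroni thresholds within and across the main categories, BH-FDR
#' flags, and single-variant results for the significant genes.
#'
#' @param genotypes dosage matrix (subjects x variants).
#' @param annotations VEP-like annotation table (`variant_id`, `gene`,
#'   `consequence`, `loftee`, `revel`).
#' @param pheno scored phenotype table (see [score_phenotypes()]).
#' @param covariates covariate table (`sex`, `age`, `batch`, `PC1`...).
#' @param config a [run_config()].
#' @return a `discovery_bundle` list: `results`, `mask_summary`,
#'   `inflation`, `thresholds`, `significant`, `fdr`, `single_variants`,
#'   `null`, `prepared`, `manifest`.
#' @export
run_discovery <- function(genotypes, annotations, pheno, covariates,
                          config = run_config()) {
  prep <- prepare_inputs(genotypes, annotations, config)
  X <- covariate_matrix(covariates, config$use_batch)
  null <- fit_null_model(pheno$proxy_score, X, "quantitative")
  cats <- unique(c(config$categories, "synonymous"))
  results <- data.table::rbindlist(lapply(cats, function(cat) {
    run_category_scan(prep$masks[[cat]], prep$genotypes, null,
                      maf = prep$maf, rho_grid = config$rho_grid,
                      weight_a = config$weight_a, weight_b = config$weight_b)
  }))
  inflation <- data.table::rbindlist(lapply(cats, function(cat) {
    p <- results[category == cat & status == "tested", p]
    lam <- if (length(p)) genomic_inflation(p)$lambda else NA_real_
    data.table::data.table(category = cat, lambda = lam,
                           n_tests = length(p))
  }))
  counts <- vapply(config$categories, function(cat) {
    sum(results$category == cat & results$status == "tested")
  }, 0L)
  thresholds <- bonferroni_thresholds(counts, config$alpha)
  main <- results[category %in% config$categories & status == "tested"]
  significant <- main[p < thresholds$across][order(p)]
  fdr <- data.table::rbindlist(lapply(config$categories, function(cat) {
    sub <- results[category == cat & status == "tested"]
    sub[, fdr_discovery := bh_fdr(p, config$fdr_q)]
    sub[fdr_discovery == TRUE, .(gene, category, p)]
  }))
  sv <- data.table::rbindlist(lapply(unique(significant$gene), function(g) {
    row <- significant[gene == g][which.min(p)]
    vids <- intersect(
      prep$masks[[row$category]][gene == g, variant_ids][[1]],
      colnames(prep$genotypes))
    out <- single_variant_scan(prep$genotypes[, vids, drop = FALSE],
                               pheno$proxy_score, X)
    out[, gene := g]
    out
  }))
  manifest <- list(seed = config$seed,
                   n_subjects = nrow(prep$genotypes),
                   n_variants_post_qc = ncol(prep$genotypes),
                   qc_tally = prep$qc_tally,
                   categories = cats,
                   package = as.character(utils::packageVersion("proxyrvat")))
  structure(list(results = results, mask_summary = mask_summary(prep$masks),
                 inflation = inflation, thresholds = thresholds,
                 significant = significant, fdr = fdr,
                 single_variants = sv, null = null, prepared = prep,
                 config = config, manifest = manifest),
            class = "discovery_bundle")
}

#' Replication analysis of candidate genes in an independent cohort
#'
#' Tests only the candidate genes, with the replication cohort's own masks
#' and in-sample MAFs; `use_batch = FALSE` drops the batch covariate for a
#' single-batch cohort.
#'
#' @inheritParams run_discovery
#' @param candidate_genes gene ids carried over from discovery.
#' @param threshold significance threshold applied to replication p-values
#'   (typically the discovery across-analyses threshold).
#' @return list with `results` (gene x category), `verdicts` (per gene:
#'   `replicated`, `failed`, `not_testable`) and a manifest.
#' @export
run_replication <- function(genotypes, annotations, pheno, covariates,
                            candidate_genes, threshold,
                            config = run_config(use_batch = FALSE)) {
  if (length(candidate_genes) == 0L) stop("no candidate genes supplied")
  prep <- prepare_inputs(genotypes, annotations, config)
  X <- covariate_matrix(covariates, config$use_batch)
  null <- fit_null_model(pheno$proxy_score, X, "quantitative")
  results <- data.table::rbindlist(lapply(config$categories, function(cat) {
    mk <- prep$masks[[cat]][gene %in% candidate_genes]
    if (nrow(mk) == 0L) return(NULL)
    run_category_scan(mk, prep$genotypes, null, maf = prep$maf,
                      rho_grid = config$rho_grid,
                      weight_a = config$weight_a, weight_b = config$weight_b)
  }))
  verdicts <- data.table::rbindlist(lapply(candidate_genes, function(g) {
    sub <- results[gene == g & status == "tested"]
    verdict <- if (nrow(sub) == 0L) "not_testable"
      else if (any(sub$p < threshold, na.rm = TRUE)) "replicated"
      else "failed"
    data.table::data.table(gene = g, verdict = verdict,
                           best_p = if (nrow(sub)) min(sub$p) else NA_real_)
  }))
  list(results = results, verdicts = verdicts,
       manifest = list(seed = config$seed,
                       n_subjects = nrow(prep$genotypes),
                       threshold = threshold))
}

#' Export plot-ready gene and variant tables
#'
#' Gene table: one row per tested gene and category with genomic position
#' and `-log10(p)` (the Manhattan-plot data); variant table: the
#' single-variant associations of the significant genes with functional
#' labels (the locus-plot data). The across-analyses threshold is attached
#' for the significance line.
#'
#' @param bundle a [run_discovery()] result.
#' @return list of two `data.table`s, `genes` and `variants`.
#' @export
export_plot_data <- function(bundle) {
  genes <- bundle$results[status == "tested",
                          .(gene, category, chrom, pos, p,
                            neglog10_p = -log10(p))]
  genes[, threshold_line := bundle$thresholds$across]
  variants <- data.table::data.table()
  if (nrow(bundle$single_variants)) {
    ann <- bundle$prepared$annotations[, .(variant_id, class)]
    variants <- bundle$single_variants[!is.na(p)][ann, on = "variant_id",
                                                  nomatch = NULL]
    pos <- variant_positions(variants$variant_id)
    variants[, `:=`(chrom = pos$chrom, pos = pos$pos,
                    neglog10_p = -log10(p))]
  }
  list(genes = genes[], variants = variants)
}

#' Write a result bundle's tables to a directory
#'
#' Deterministic tab-delimited outputs (no timestamps), so identical
#' config + seed reproduce byte-identical files.
#'
#' @param bundle a [run_discovery()] result.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, name) {
    p <- file.path(dir, name)
    data.table::fwrite(x, p, sep = "\t", na = "NA", quote = FALSE)
    p
  }
  paths <- c(
    tsv(bundle$results, "gene_results.tsv"),
    tsv(bundle$mask_summary, "mask_summary.tsv"),
    tsv(bundle$inflation, "inflation.tsv"),
    tsv(data.table::data.table(category = names(bundle$thresholds$within),
                               within = bundle$thresholds$within,
                               across = bundle$thresholds$across),
        "thresholds.tsv"),
    tsv(bundle$significant, "significant_genes.tsv"),
    if (nrow(bundle$single_variants)) {
      tsv(bundle$single_variants, "single_variants.tsv")
    })
  manifest <- bundle$manifest
  writeLines(paste(names(manifest),
                   vapply(manifest, function(x) paste(format(x),
                                                      collapse = ","), ""),
                   sep = "\t"),
             file.path(dir, "manifest.tsv"))
  invisible(c(paths, file.path(dir, "manifest.tsv")))
}
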