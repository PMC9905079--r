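# Variant-level QC, VEP-style consequence classification, functional
# category (mask) construction, and cumulative-allele-frequency gene
# filtering.

plof_terms <- c("start_lost", "stop_lost", "frameshift_variant",
                "stop_gained", "splice_donor_variant",
                "splice_acceptor_variant", "transcript_ablation")

mask_categories <- function() {
  c("HiC_pLOF", "pLOF", "pLOF_REVEL", "pLOF_missense", "synonymous")
}

#' Per-variant allele statistics of a dosage matrix
#'
#' @param G subjects x variants dosage matrix (0/1/2 with `NA` allowed).
#' @return `data.table` with `variant_id`, `n_called`, `missingness`, `mac`
#'   (minor allele count) and in-sample `maf`.
#' @export
variant_stats <- function(G) {
  n <- nrow(G)
  ncall <- colSums(!is.na(G))
  ac <- colSums(G, na.rm = TRUE)
  af <- ac / (2 * pmax(ncall, 1L))
  mac <- as.integer(round(ifelse(af <= 0.5, ac, 2 * ncall - ac)))
  data.table::data.table(
    variant_id = colnames(G),
    n_called = as.integer(ncall),
    missingness = 1 - ncall / n,
    mac = mac,
    maf = pmin(af, 1 - af))
}

#' Variant quality-control filter
#'
#' Drops variants with call-rate missingness above `max_missing`, variants
#' with a minor allele count of zero, and positional duplicates (same
#' `chrom:pos:ref:alt` key; the first record in column order is kept).
#'
#' @param G dosage matrix with `chrom:pos:ref:alt` column names.
#' @param max_missing maximum tolerated missingness fraction (default 0.05).
#' @param drop_mac_zero,drop_duplicates toggles for the remaining filters.
#' @return list with `genotypes` (filtered matrix, column order preserved)
#'   and `tally`, a named integer vector of per-reason exclusion counts.
#' @export
qc_filter_variants <- function(G, max_missing = 0.05, drop_mac_zero = TRUE,
                               drop_duplicates = TRUE) {
  st <- variant_stats(G)
  drop_missing <- st$missingness > max_missing
  drop_mac <- drop_mac_zero & !drop_missing & st$mac == 0L
  dup <- duplicated(st$variant_id)
  drop_dup <- drop_duplicates & !drop_missing & !drop_mac & dup
  keep <- !(drop_missing | drop_mac | drop_dup)
  tally <- c(missingness = sum(drop_missing), mac0 = sum(drop_mac),
             duplicate = sum(drop_dup))
  if (!any(keep)) warning("QC removed every variant; empty genotype matrix")
  list(genotypes = G[, keep, drop = FALSE], tally = tally)
}

#' Classify VEP-style consequence terms into functional classes
#'
#' The seven canonical loss-of-function terms map to `pLOF_other`, or to
#' `HiC_pLOF` when the LOFTEE flag is high-confidence (`"HC"`);
#' `missense_variant` maps to `missense`, `synonymous_variant` to
#' `synonymous`, and everything else to `other` (each unrecognized term is
#' reported once).
#'
#' @param raw_consequence character vector of VEP consequence terms.
#' @param loftee_flag character vector of LOFTEE confidence flags (`"HC"`,
#'   `"LC"`, or empty).
#' @return factor with levels `HiC_pLOF`, `pLOF_other`, `missense`,
#'   `synonymous`, `other`.
#' @export
classify_consequence <- function(raw_consequence, loftee_flag = "") {
  loftee_flag <- rep_len(ifelse(is.na(loftee_flag), "", loftee_flag),
                         length(raw_consequence))
  out <- rep("other", length(raw_consequence))
  is_plof <- raw_consequence %in% plof_terms
  out[is_plof] <- ifelse(loftee_flag[is_plof] == "HC", "HiC_pLOF",
                         "pLOF_other")
  out[raw_consequence == "missense_variant"] <- "missense"
  out[raw_consequence == "synonymous_variant"] <- "synonymous"
  known <- is_plof | raw_consequence %in%
    c("missense_variant", "synonymous_variant")
  unseen <- unique(raw_consequence[!known])
  if (length(unseen)) {
    message("unrecognized consequence term(s) mapped to 'other': ",
            paste(utils::head(unseen, 10), collapse = ", "))
  }
  factor(out, levels = c("HiC_pLOF", "pLOF_other", "missense", "synonymous",
                         "other"))
}

#' Mask configuration
#'
#' @param maf_max variant inclusion ceiling on minor allele frequency
#'   (default 0.01).
#' @param revel_threshold REVEL cut for the high-confidence missense class
#'   on REVEL's native 0-1 scale (default 0.5, i.e. "REVEL > 50" in
#'   percent units).
#' @param caf_min cumulative-allele-frequency floor below which a gene is
#'   excluded from testing (default 1e-4).
#' @param caf_method `"sum_maf"` (cumulative allele frequency as the sum of
#'   member MAFs, default) or `"carrier"` (fraction of subjects carrying at
#'   least one minor allele; requires genotypes).
#' @return a `mask_config` list.
#' @export
mask_config <- function(maf_max = 0.01, revel_threshold = 0.5,
                        caf_min = 1e-4, caf_method = c("sum_maf", "carrier")) {
  stopifnot(maf_max > 0, maf_max <= 0.5,
            revel_threshold >= 0, revel_threshold <= 1, caf_min >= 0)
  structure(list(maf_max = maf_max, revel_threshold = revel_threshold,
                 caf_min = caf_min, caf_method = match.arg(caf_method)),
            class = "mask_config")
}

category_members <- function(class, revel, category, revel_threshold) {
  plof <- class %in% c("HiC_pLOF", "pLOF_other")
  switch(category,
         HiC_pLOF = class == "HiC_pLOF",
         pLOF = plof,
         pLOF_REVEL = plof | (class == "missense" & !is.na(revel) &
                                revel > revel_threshold),
         pLOF_missense = plof | class == "missense",
         synonymous = class == "synonymous",
         stop("unknown category: ", category))
}

#' Build per-gene variant masks for one functional category
#'
#' Category membership is nested: `HiC_pLOF` contains only high-confidence
#' LOF variants; `pLOF` adds the remaining LOF; `pLOF_REVEL` adds missense
#' with REVEL above the threshold; `pLOF_missense` adds all missense. The
#' `synonymous` control category is disjoint from the four. Genes whose
#' cumulative allele frequency falls below `config$caf_min` are retained in
#' the table but marked excluded.
#'
#' @param annotations `data.table`/`data.frame` with columns `variant_id`,
#'   `gene`, `class` (from [classify_consequence()]) or `consequence` +
#'   `loftee`, `revel`, and `maf`.
#' @param category one of `r paste(mask_categories(), collapse = ", ")`.
#' @param config a [mask_config()].
#' @param genotypes optional dosage matrix, needed for
#'   `caf_method = "carrier"`.
#' @return a `gene_masks` `data.table`: `gene`, `category`, `variant_ids`
#'   (list column), `n_variants`, `caf`, `included`, `exclusion_reason`.
#' @export
build_mask <- function(annotations, category, config = mask_config(),
                       genotypes = NULL) {
  ann <- data.table::as.data.table(annotations)
  if (!"class" %in% names(ann)) {
    ann[, class := classify_consequence(consequence, loftee)]
  }
  no_gene <- is.na(ann$gene) | ann$gene == ""
  if (any(no_gene)) {
    message(sum(no_gene), " variant(s) without a gene assignment skipped")
    ann <- ann[!no_gene]
  }
  ann <- ann[maf < config$maf_max & maf > 0]
  revel <- if ("revel" %in% names(ann)) ann$revel else rep(NA_real_, nrow(ann))
  ann <- ann[category_members(ann$class, revel, category,
                              config$revel_threshold)]
  if (nrow(ann) == 0L) {
    return(data.table::data.table(gene = character(), category = character(),
                                  variant_ids = list(),
                                  n_variants = integer(), caf = numeric(),
                                  included = logical(),
                                  exclusion_reason = character()))
  }
  caf_of <- function(vids, mafs) {
    if (config$caf_method == "sum_maf") return(sum(mafs))
    if (is.null(genotypes)) {
      stop("caf_method = 'carrier' requires the genotype matrix")
    }
    vids <- intersect(vids, colnames(genotypes))
    mean(rowSums(genotypes[, vids, drop = FALSE], na.rm = TRUE) > 0)
  }
  out <- ann[, .(variant_ids = list(variant_id),
                 n_variants = .N,
                 caf = caf_of(variant_id, maf)), by = gene]
  out[, category := category]
  out[, included := caf >= config$caf_min & n_variants >= 1L]
  out[, exclusion_reason := ifelse(included, NA_character_, "low_caf")]
  data.table::setcolorder(out, c("gene", "category", "variant_ids",
                                 "n_variants", "caf", "included",
                                 "exclusion_reason"))
  out[]
}

#' Build all five masks (four nested categories plus synonymous control)
#'
#' @inheritParams build_mask
#' @param categories categories to build (default all five).
#' @return named list of `gene_masks` tables.
#' @export
build_masks <- function(annotations, config = mask_config(),
                        categories = mask_categories(), genotypes = NULL) {
  stats::setNames(lapply(categories, function(cat) {
    build_mask(annotations, cat, config, genotypes)
  }), categories)
}

#' Per-category gene and variant totals
#'
#' The machine-readable twin of a category-summary table: per category the
#' number of genes and variants passing the CAF filter, with the
#' pre-filtering totals in parentheses columns.
#'
#' @param masks named list from [build_masks()].
#' @return `data.table` with `category`, `n_genes`, `n_genes_total`,
#'   `n_variants`, `n_variants_total`.
#' @export
mask_summary <- function(masks) {
  data.table::rbindlist(lapply(names(masks), function(cat) {
    mk <- masks[[cat]]
    data.table::data.table(
      category = cat,
      n_genes = sum(mk$included),
      n_genes_total = nrow(mk),
      n_variants = sum(mk$n_variants[mk$included]),
      n_variants_total = sum(mk$n_variants))
  }))
}
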