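# Single-variant association, genomic inflation, multiple-testing
# decisions, and the sensitivity / conditional reruns of gene-level tests.

#' Per-variant linear regression within a gene
#'
#' Ordinary least squares of the phenotype on each variant's minor-allele
#' dosage, adjusted for the covariates, reported as slope, standard error
#' and two-sided p. Variants monomorphic in the analyzed subset are skipped
#' with a flag.
#'
#' @param G dosage matrix restricted to the variants entering the gene's
#'   aggregation test.
#' @param phenotype numeric response.
#' @param covariates covariate matrix/data.frame or `NULL`.
#' @return `data.table` `variant_id`, `beta`, `se`, `p`, `maf`, `mac`,
#'   `flag`, sorted by `p`; skipped variants carry `NA` results.
#' @export
single_variant_scan <- function(G, phenotype, covariates = NULL) {
  if (is.vector(G)) G <- matrix(G, ncol = 1,
                                dimnames = list(NULL, "variant"))
  null <- fit_null_model(phenotype, covariates, "quantitative")
  st <- variant_stats(G)
  n <- nrow(G)
  p_cov <- ncol(null$X)
  rows <- lapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    gr <- qr.resid(null$qr, g)
    sg <- sum(gr^2)
    if (st$mac[j] == 0L || sg < 1e-12) {
      return(data.table::data.table(variant_id = colnames(G)[j],
                                    beta = NA_real_, se = NA_real_,
                                    p = NA_real_, maf = st$maf[j],
                                    mac = st$mac[j],
                                    flag = if (st$mac[j] == 0L) "monomorphic"
                                           else "degenerate"))
    }
    beta <- sum(gr * null$residuals) / sg
    rss <- sum((null$residuals - beta * gr)^2)
    df <- n - p_cov - 1L
    se <- sqrt(rss / df / sg)
    tval <- beta / se
    data.table::data.table(variant_id = colnames(G)[j], beta = beta, se = se,
                           p = 2 * stats::pt(abs(tval), df,
                                             lower.tail = FALSE),
                           maf = st$maf[j], mac = st$mac[j],
                           flag = NA_character_)
  })
  out <- data.table::rbindlist(rows)
  out[order(is.na(p), p)]
}

#' Genomic inflation factor
#'
#' `lambda` is the median of the 1-df chi-square quantiles of the observed
#' p-values divided by the null median `qchisq(0.5, 1)` (about 0.4549);
#' values below 1 indicate sparse or deflated association signal.
#'
#' @param pvalues p-values in (0, 1]; `NA` entries are dropped.
#' @return list with `lambda` and `n_tests`.
#' @export
genomic_inflation <- function(pvalues) {
  p <- pvalues[!is.na(pvalues)]
  if (length(p) == 0L) stop("no p-values supplied")
  if (any(p <= 0 | p > 1)) stop("p-values must lie in (0, 1]")
  chisq <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  list(lambda = stats::median(chisq) / stats::qchisq(0.5, df = 1),
       n_tests = length(p))
}

#' Bonferroni thresholds within and across variant categories
#'
#' Within each category the threshold is `alpha / n_genes`; across the
#' analyses it is `alpha / (max(n_genes) * n_categories)` — the largest
#' category's gene count times the number of categories.
#'
#' @param gene_counts integer vector of per-category tested-gene counts.
#' @param alpha family-wise error target (default 0.05).
#' @return list with `within` (named per-category thresholds) and `across`.
#' @export
bonferroni_thresholds <- function(gene_counts, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  if (any(gene_counts < 1)) stop("every category must test at least one gene")
  list(within = alpha / gene_counts,
       across = alpha / (max(gene_counts) * length(gene_counts)))
}

#' Benjamini-Hochberg discovery flags
#'
#' Standard step-up procedure at FDR level `q`; flags are returned in input
#' order.
#'
#' @param pvalues p-values (NA allowed, never discovered).
#' @param q FDR level in (0, 1).
#' @return logical vector of discoveries.
#' @export
bh_fdr <- function(pvalues, q = 0.1) {
  stopifnot(q > 0, q < 1)
  adj <- stats::p.adjust(pvalues, method = "BH")
  !is.na(adj) & adj <= q
}

#' Sensitivity configuration for gene-test reruns
#'
#' @param drop_singletons remove variants with MAC exactly 1.
#' @param min_mac remove variants with MAC below this (0 disables; the
#'   MAC < 5 scenario uses 5).
#' @param moderate_p_threshold remove variants whose single-variant p falls
#'   below this (NA disables; the moderate-association scenario uses 1e-4).
#' @return a `sensitivity_config` list.
#' @export
sensitivity_config <- function(drop_singletons = FALSE, min_mac = 0L,
                               moderate_p_threshold = NA_real_) {
  stopifnot(min_mac >= 0)
  structure(list(drop_singletons = drop_singletons,
                 min_mac = as.integer(min_mac),
                 moderate_p_threshold = moderate_p_threshold),
            class = "sensitivity_config")
}

#' Re-run a gene's aggregation test on a reduced variant set
#'
#' Applies the configured exclusions (singletons, MAC floor, moderately
#' associated variants) and re-executes [skat_o_test()]. A rerun that
#' removes no variants reproduces the base p-value exactly.
#'
#' @param G dosage matrix for the gene's mask variants.
#' @param null the same [fit_null_model()] fit as the base analysis.
#' @param config a [sensitivity_config()].
#' @param single_variant_p named per-variant p-values (required when the
#'   moderate-p exclusion is active); typically from
#'   [single_variant_scan()] on the same cohort and covariates.
#' @param ... passed to [skat_o_test()].
#' @return a `gene_test` with an extra `removed` element: named counts of
#'   variants removed per reason.
#' @export
sensitivity_rerun <- function(G, null, config, single_variant_p = NULL, ...) {
  st <- variant_stats(G)
  drop_singleton <- config$drop_singletons & st$mac == 1L
  drop_mac <- st$mac < config$min_mac
  drop_moderate <- rep(FALSE, ncol(G))
  if (!is.na(config$moderate_p_threshold)) {
    if (is.null(single_variant_p)) {
      stop("moderate-p exclusion requires per-variant p-values")
    }
    pv <- single_variant_p[st$variant_id]
    drop_moderate <- !is.na(pv) & pv < config$moderate_p_threshold
  }
  drop <- drop_singleton | drop_mac | drop_moderate
  removed <- c(singleton = sum(drop_singleton), low_mac = sum(drop_mac),
               moderate_p = sum(drop_moderate))
  if (all(drop)) {
    fit <- structure(list(gene_id = NA_character_, p_value = NA_real_,
                          rho_selected = NA_real_, p_rho = NULL,
                          n_variants = 0L, status = "excluded_empty",
                          flags = "all_variants_removed"),
                     class = "gene_test")
  } else {
    fit <- skat_o_test(G[, !drop, drop = FALSE], null, ...)
  }
  fit$removed <- removed
  fit
}

#' Conditional rerun with an extra covariate
#'
#' Repeats the aggregation test with the conditioning dosage (for instance
#' a nearby common risk allele's dosage) appended to the covariates, to
#' assess whether a gene's rare-variant signal is independent of it.
#'
#' @param G dosage matrix for the gene.
#' @param phenotype numeric response.
#' @param covariates base covariates.
#' @param conditioning numeric vector aligned to subjects.
#' @param trait_kind passed to [fit_null_model()].
#' @param ... passed to [skat_o_test()].
#' @return a `gene_test`.
#' @export
conditional_rerun <- function(G, phenotype, covariates, conditioning,
                              trait_kind = "quantitative", ...) {
  cond <- as.numeric(conditioning)
  if (length(cond) != nrow(G)) {
    stop("conditioning vector is not aligned to subjects")
  }
  if (stats::var(cond) == 0) stop("conditioning vector has no variance")
  Xc <- cbind(if (is.null(covariates)) NULL else as.matrix(covariates),
              conditioning = cond)
  null <- fit_null_model(phenotype, Xc, trait_kind)
  skat_o_test(G, null, ...)
}
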