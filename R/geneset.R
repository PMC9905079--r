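# Set-level aggregation: pool the variants of a gene set into a single
# aggregation unit (deduplicated across overlapping genes), optionally
# excluding named genes or a genomic region, and run the same omnibus test.

#' Define a gene set
#'
#' @param name set label.
#' @param member_genes character vector of gene ids.
#' @param excluded_genes genes removed from the effective membership.
#' @param excluded_region optional `c(chrom, start, end)`; the closed-open
#'   interval `[start, end)` on that chromosome. A gene is excluded when any
#'   of its mask variants falls inside.
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, member_genes, excluded_genes = character(),
                     excluded_region = NULL) {
  if (!is.null(excluded_region)) {
    stopifnot(length(excluded_region) == 3L)
    if (as.numeric(excluded_region[2]) >= as.numeric(excluded_region[3])) {
      stop("excluded_region start must be below end")
    }
  }
  structure(list(name = name, member_genes = unique(member_genes),
                 excluded_genes = unique(excluded_genes),
                 excluded_region = excluded_region), class = "gene_set")
}

#' Read gene sets from a GMT file
#'
#' GMT layout: one set per line, tab-delimited: name, description, then
#' gene symbols.
#'
#' @param path GMT file.
#' @return named list of [gene_set()] objects.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) stop("malformed GMT line: ", substr(l, 1, 60))
    gene_set(f[1], f[-(1:2)])
  })
  stats::setNames(sets, vapply(sets, `[[`, "", "name"))
}

# genes of a mask whose variants touch the excluded region
genes_in_region <- function(masks, region) {
  if (is.null(region)) return(character())
  chrom <- sub("^chr", "", as.character(region[1]))
  start <- as.numeric(region[2]); end <- as.numeric(region[3])
  hit <- vapply(seq_len(nrow(masks)), function(i) {
    pos <- variant_positions(masks$variant_ids[[i]])
    chr_i <- sub("^chr", "", data.table::tstrsplit(
      masks$variant_ids[[i]], ":", fixed = TRUE)[[1]])
    any(chr_i == chrom & pos$pos >= start & pos$pos < end)
  }, NA)
  masks$gene[hit]
}

# pooled, deduplicated variant ids of the effective membership
effective_set_variants <- function(set, masks) {
  members <- setdiff(intersect(set$member_genes, masks$gene),
                     set$excluded_genes)
  members <- setdiff(members, genes_in_region(
    masks[masks$gene %in% members], set$excluded_region))
  vids <- unique(unlist(
    masks$variant_ids[match(members, masks$gene)], use.names = FALSE))
  list(members = members, variant_ids = vids)
}

#' Set-level aggregation test
#'
#' Pools all member variants of one category's mask into a single unit
#' (each variant enters once even when mapped to several member genes) and
#' applies [skat_o_test()].
#'
#' @param set a [gene_set()].
#' @param masks one category's `gene_masks` table (see [build_mask()]).
#' @param genotypes dosage matrix.
#' @param null a [fit_null_model()] fit.
#' @param ... passed to [skat_o_test()].
#' @return a `gene_test` with `n_genes_effective` and the pooled variant
#'   count; status `excluded_empty` when no member survives the exclusions.
#' @export
run_geneset_test <- function(set, masks, genotypes, null, ...) {
  eff <- effective_set_variants(set, masks)
  vids <- intersect(eff$variant_ids, colnames(genotypes))
  if (length(eff$members) == 0L || length(vids) == 0L) {
    out <- structure(list(gene_id = set$name, p_value = NA_real_,
                          rho_selected = NA_real_, p_rho = NULL,
                          n_variants = 0L, status = "excluded_empty",
                          flags = "empty_effective_set"),
                     class = "gene_test")
    out$n_genes_effective <- length(eff$members)
    return(out)
  }
  fit <- skat_o_test(genotypes[, vids, drop = FALSE], null,
                     gene_id = set$name, ...)
  fit$n_genes_effective <- length(eff$members)
  fit
}

#' Leave-one-out scan over a gene set
#'
#' Re-runs the set-level test omitting each member gene in turn; the driver
#' gene is the omission producing the largest p-value increase.
#'
#' @inheritParams run_geneset_test
#' @return `data.table` `omitted_gene`, `p`, `n_variants`, plus attributes
#'   `base_p` and `driver` (the identified driver gene).
#' @export
leave_one_out <- function(set, masks, genotypes, null, ...) {
  eff <- effective_set_variants(set, masks)
  if (length(eff$members) < 2L) stop("leave-one-out needs at least 2 members")
  base <- run_geneset_test(set, masks, genotypes, null, ...)
  rows <- lapply(eff$members, function(g) {
    sub <- gene_set(set$name, eff$members, excluded_genes = g)
    fit <- run_geneset_test(sub, masks, genotypes, null, ...)
    data.table::data.table(omitted_gene = g, p = fit$p_value,
                           n_variants = fit$n_variants)
  })
  out <- data.table::rbindlist(rows)
  driver <- out$omitted_gene[which.max(out$p)]
  data.table::setattr(out, "base_p", base$p_value)
  data.table::setattr(out, "driver", driver)
  out[]
}
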