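# Plain-text interchange: VCF 4.2 for genotypes, tab-delimited tables for
# phenotype, covariates, annotation and truth records.

dosage_to_gt <- function(d) {
  gt <- c("0/0", "0/1", "1/1")[d + 1L]
  gt[is.na(d)] <- "./."
  gt
}

#' Write offspring genotypes as a VCF 4.2 file
#'
#' @param G dosage matrix (subjects x variants) with `chrom:pos:ref:alt`
#'   column names and subject ids as row names.
#' @param path output file.
#' @export
write_vcf <- function(G, path) {
  parts <- data.table::tstrsplit(colnames(G), ":", fixed = TRUE)
  chrom <- parts[[1]]; pos <- parts[[2]]; ref <- parts[[3]]; alt <- parts[[4]]
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=proxyrvat",
    paste0("##contig=<ID=", unique(chrom), ">"),
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(G)), collapse = "\t"))
  gt <- matrix(dosage_to_gt(t(G)), nrow = ncol(G))
  body <- paste(chrom, pos, colnames(G), ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
}

#' Read a VCF into a minor-allele dosage matrix
#'
#' Dosages are derived from the GT field (count of ALT alleles; `./.` to
#' `NA`). Variant ids are rebuilt as `chrom:pos:ref:alt`.
#'
#' @param path VCF file.
#' @return subjects x variants integer dosage matrix.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  dos[gt %in% c("0/0", "0|0")] <- 0L
  dos[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
  dos[gt %in% c("1/1", "1|1")] <- 2L
  fix <- vcfR::getFIX(v)
  ids <- paste(fix[, "CHROM"], fix[, "POS"], fix[, "REF"], fix[, "ALT"],
               sep = ":")
  out <- t(dos)
  colnames(out) <- ids
  out
}

#' Write a simulated cohort's fixture files
#'
#' Emits `genotypes.vcf` (offspring), `annotation.tsv`, `phenotype.tsv`,
#' `covariates.tsv` and `truth.tsv` into `dir`; all files round-trip
#' through the package's readers losslessly.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if absent).
#' @return invisibly, the named vector of written paths.
#' @export
write_fixtures <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create fixture directory: ", dir)
  paths <- c(
    genotypes = file.path(dir, "genotypes.vcf"),
    annotation = file.path(dir, "annotation.tsv"),
    phenotype = file.path(dir, "phenotype.tsv"),
    covariates = file.path(dir, "covariates.tsv"),
    truth = file.path(dir, "truth.tsv"))
  write_vcf(cohort$genotypes, paths[["genotypes"]])
  tsv <- function(x, p) data.table::fwrite(x, p, sep = "\t", na = "NA",
                                           quote = FALSE)
  tsv(cohort$annotations, paths[["annotation"]])
  keep <- c("subject_id", "own_diagnosis", "father_affected", "father_age",
            "mother_affected", "mother_age")
  tsv(cohort$pheno[, keep, with = FALSE], paths[["phenotype"]])
  tsv(cbind(data.table::data.table(subject_id = cohort$pheno$subject_id),
            cohort$covariates), paths[["covariates"]])
  tsv(cohort$truth, paths[["truth"]])
  invisible(paths)
}

#' Read the tab-delimited fixture tables
#'
#' @param path file path.
#' @return a `data.table`.
#' @export
read_table_tsv <- function(path) {
  data.table::fread(path, sep = "\t", na.strings = "NA")
}
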