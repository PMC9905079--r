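# Synthetic exome + family-history cohort generator: rare-variant genotypes
# under Hardy-Weinberg for two parents, Mendelian transmission to offspring,
# age-dependent parental affection on a logistic liability with a per-allele
# causal burden, offspring own diagnosis, covariates with batch structure,
# and a VEP-like annotation fixture. All randomness flows from one seed
# through per-component substreams.

#' Simulation configuration
#'
#' Defaults describe a mid-sized biobank-style cohort: rare-skewed MAF
#' spectrum below 1%, an exome-like consequence mix, per-parent dementia
#' affection near 7.5% (so roughly 15% of subjects have an affected
#' parent), and a rare own-diagnosis rate of 0.2%.
#'
#' @param n_subjects cohort size.
#' @param n_genes number of genes.
#' @param variants_per_gene mean of the (min-2) Poisson variant count per
#'   gene.
#' @param maf_shape1,maf_shape2 Beta shapes of the MAF spectrum, truncated
#'   to `(maf_min, maf_max)`.
#' @param maf_min,maf_max truncation bounds of the spectrum.
#' @param causal_genes `data.frame` with columns `gene` (id), `causal_fraction`
#'   in `[0,1]` and `effect` (log-odds per minor allele on the parental
#'   liability and own-diagnosis scales); `NULL` for a fully null cohort.
#' @param consequence_mix named proportions over `HiC_pLOF`, `pLOF_other`,
#'   `missense`, `synonymous` (must sum to 1).
#' @param revel_shape1,revel_shape2 Beta shapes of the REVEL scores
#'   assigned to missense variants.
#' @param parent_prevalence per-parent affection probability at the
#'   reference age of 80.
#' @param parent_age_slope log-odds change in affection per year of
#'   parental age.
#' @param parent_age_range,subject_age_range uniform age ranges (years).
#' @param own_diagnosis_rate baseline own-diagnosis probability.
#' @param batch_fraction fraction of subjects in the early sequencing batch.
#' @param n_pcs number of standard-normal principal-component stand-ins.
#' @param missing_rate per-entry genotype missingness.
#' @param seed integer seed; fully determines the cohort.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects = 5000, n_genes = 60,
                       variants_per_gene = 10,
                       maf_shape1 = 0.2, maf_shape2 = 50,
                       maf_min = 1e-6, maf_max = 0.01,
                       causal_genes = NULL,
                       consequence_mix = c(HiC_pLOF = 0.04, pLOF_other = 0.03,
                                           missense = 0.63,
                                           synonymous = 0.30),
                       revel_shape1 = 0.5, revel_shape2 = 1.2,
                       parent_prevalence = 0.07, parent_age_slope = 0.07,
                       parent_age_range = c(60, 100),
                       subject_age_range = c(40, 70),
                       own_diagnosis_rate = 0.002,
                       batch_fraction = 0.25, n_pcs = 10,
                       missing_rate = 0, seed = 1L) {
  if (abs(sum(consequence_mix) - 1) > 1e-8) {
    stop("consequence_mix proportions must sum to 1")
  }
  if (!is.null(causal_genes)) {
    causal_genes <- as.data.frame(causal_genes)
    stopifnot(all(c("gene", "causal_fraction", "effect") %in%
                    names(causal_genes)),
              all(causal_genes$causal_fraction >= 0),
              all(causal_genes$causal_fraction <= 1))
  }
  structure(as.list(environment()), class = "sim_config")
}

# per-component substream seeds derived once from the master seed
component_seeds <- function(seed, components) {
  set.seed(seed)
  stats::setNames(sample.int(.Machine$integer.max - 1L, length(components)),
                  components)
}

rtrunc_beta <- function(n, shape1, shape2, lo, hi) {
  u <- stats::runif(n, stats::pbeta(lo, shape1, shape2),
                    stats::pbeta(hi, shape1, shape2))
  pmin(pmax(stats::qbeta(u, shape1, shape2), lo), hi)
}

# gene/variant architecture: ids, positions, MAFs, functional classes
simulate_variant_map <- function(config) {
  n_genes <- config$n_genes
  genes <- sprintf("GENE%03d", seq_len(n_genes))
  chrom <- rep(1:22, length.out = n_genes)
  gene_start <- 1e6 + (seq_len(n_genes) %/% 22L) * 2e6
  counts <- pmax(stats::rpois(n_genes, config$variants_per_gene), 2L)
  M <- sum(counts)
  gene_of <- rep(genes, counts)
  chrom_of <- rep(chrom, counts)
  pos <- rep(gene_start, counts) +
    unlist(lapply(counts, function(k) sort(sample.int(5e4, k))))
  maf <- rtrunc_beta(M, config$maf_shape1, config$maf_shape2,
                     config$maf_min, config$maf_max)
  class <- sample(names(config$consequence_mix), M, replace = TRUE,
                  prob = config$consequence_mix)
  consequence <- character(M)
  is_plof <- class %in% c("HiC_pLOF", "pLOF_other")
  consequence[is_plof] <- sample(plof_terms, sum(is_plof), replace = TRUE)
  consequence[class == "missense"] <- "missense_variant"
  consequence[class == "synonymous"] <- "synonymous_variant"
  loftee <- ifelse(class == "HiC_pLOF", "HC",
                   ifelse(class == "pLOF_other", "LC", ""))
  revel <- rep(NA_real_, M)
  revel[class == "missense"] <- stats::rbeta(sum(class == "missense"),
                                             config$revel_shape1,
                                             config$revel_shape2)
  alleles <- c("A", "C", "G", "T")
  ref <- sample(alleles, M, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(alleles, r), 1L), "")
  data.table::data.table(
    variant_id = paste(chrom_of, pos, ref, unname(alt), sep = ":"),
    gene = gene_of, chrom = chrom_of, pos = pos, ref = ref,
    alt = unname(alt), maf = maf, class = class, consequence = consequence,
    loftee = loftee, revel = revel)
}

# mark causal variants and attach per-allele effects
assign_causal <- function(vmap, config) {
  vmap[, `:=`(causal = FALSE, effect = 0)]
  if (is.null(config$causal_genes)) return(vmap)
  for (i in seq_len(nrow(config$causal_genes))) {
    g <- config$causal_genes$gene[i]
    frac <- config$causal_genes$causal_fraction[i]
    eff <- config$causal_genes$effect[i]
    idx <- which(vmap$gene == g & vmap$class != "synonymous")
    if (length(idx) == 0L) {
      stop("causal gene ", g, " has no functional variants")
    }
    k <- max(1L, round(frac * length(idx)))
    pick <- sample(idx, k)
    vmap[pick, `:=`(causal = TRUE, effect = eff)]
  }
  vmap
}

draw_dosages <- function(n, maf) {
  matrix(stats::rbinom(n * length(maf), 2L, rep(maf, each = n)), nrow = n)
}

transmit <- function(parent_dosage) {
  matrix(stats::rbinom(length(parent_dosage), 1L, parent_dosage / 2),
         nrow = nrow(parent_dosage))
}

#' Simulate a cohort with the structure the proxy analysis assumes
#'
#' Per variant, parental dosages are drawn under Hardy-Weinberg at the
#' sampled MAF and each parent transmits one allele (carried with
#' probability dosage/2). Parental affection follows a logistic model in
#' the parent's own causal burden plus an age term; the offspring's own
#' diagnosis follows their burden at the configured baseline rate. Proxy
#' scores are then computed by the phenotype module.
#'
#' @param config a [sim_config()].
#' @param variant_map optionally, the `variant_map` of a previously
#'   simulated cohort (including its causal assignment). Supplying it
#'   fixes the genome — same variants, same MAFs, same causal alleles —
#'   while genotypes, ages, affection and covariates are drawn fresh:
#'   the paired-cohort design used for replication analyses.
#' @return a `sim_cohort` list: `genotypes` (offspring dosage matrix),
#'   `father`, `mother` (parental dosage matrices), `pheno` (scored
#'   phenotype table), `covariates`, `annotations` (VEP-like fixture),
#'   `variant_map` (with generating MAFs), `truth` (causal record),
#'   parental/offspring liability components, and the config.
#' @export
simulate_cohort <- function(config = sim_config(), variant_map = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seeds <- component_seeds(config$seed,
                           c("map", "causal", "parents", "transmission",
                             "ages", "affection", "covariates", "missing"))
  if (is.null(variant_map)) {
    set.seed(seeds[["map"]])
    vmap <- simulate_variant_map(config)
    set.seed(seeds[["causal"]])
    vmap <- assign_causal(vmap, config)
  } else {
    vmap <- data.table::copy(data.table::as.data.table(variant_map))
    stopifnot(all(c("variant_id", "gene", "maf", "class", "effect") %in%
                    names(vmap)))
  }
  n <- config$n_subjects
  M <- nrow(vmap)
  set.seed(seeds[["parents"]])
  father <- draw_dosages(n, vmap$maf)
  mother <- draw_dosages(n, vmap$maf)
  colnames(father) <- colnames(mother) <- vmap$variant_id
  set.seed(seeds[["transmission"]])
  offspring <- transmit(father) + transmit(mother)
  colnames(offspring) <- vmap$variant_id
  set.seed(seeds[["ages"]])
  father_age <- round(stats::runif(n, config$parent_age_range[1],
                                   config$parent_age_range[2]))
  mother_age <- round(stats::runif(n, config$parent_age_range[1],
                                   config$parent_age_range[2]))
  subject_age <- round(stats::runif(n, config$subject_age_range[1],
                                    config$subject_age_range[2]))
  eff <- vmap$effect
  burden <- function(Gm) as.vector(Gm %*% eff)
  lp_father <- stats::qlogis(config$parent_prevalence) +
    config$parent_age_slope * (father_age - 80) + burden(father)
  lp_mother <- stats::qlogis(config$parent_prevalence) +
    config$parent_age_slope * (mother_age - 80) + burden(mother)
  lp_self <- stats::qlogis(config$own_diagnosis_rate) + burden(offspring)
  set.seed(seeds[["affection"]])
  father_aff <- stats::rbinom(n, 1L, stats::plogis(lp_father))
  mother_aff <- stats::rbinom(n, 1L, stats::plogis(lp_mother))
  own_dx <- stats::rbinom(n, 1L, stats::plogis(lp_self))
  pheno <- data.table::data.table(
    subject_id = sprintf("S%05d", seq_len(n)),
    own_diagnosis = own_dx,
    father_affected = father_aff, father_age = father_age,
    mother_affected = mother_aff, mother_age = mother_age)
  pheno <- score_phenotypes(pheno)
  set.seed(seeds[["covariates"]])
  covariates <- data.table::data.table(
    sex = stats::rbinom(n, 1L, 0.5),
    age = subject_age,
    batch = stats::rbinom(n, 1L, config$batch_fraction))
  if (config$n_pcs > 0) {
    pcs <- matrix(stats::rnorm(n * config$n_pcs), n,
                  dimnames = list(NULL, paste0("PC", seq_len(config$n_pcs))))
    covariates <- cbind(covariates, data.table::as.data.table(pcs))
  }
  if (config$missing_rate > 0) {
    set.seed(seeds[["missing"]])
    nas <- stats::runif(n * M) < config$missing_rate
    offspring[matrix(nas, n)] <- NA_integer_
  }
  rownames(offspring) <- pheno$subject_id
  out <- list(
    genotypes = offspring, father = father, mother = mother,
    pheno = pheno, covariates = covariates,
    annotations = vmap[, .(variant_id, gene, consequence, loftee, revel)],
    variant_map = vmap,
    truth = vmap[causal == TRUE,
                 .(variant_id, gene, class, maf_generating = maf, effect)],
    lp_father = lp_father, lp_mother = lp_mother, lp_self = lp_self,
    config = config)
  class(out) <- "sim_cohort"
  out
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("simulated cohort:", x$config$n_subjects, "subjects,",
      x$config$n_genes, "genes,", nrow(x$variant_map), "variants,",
      nrow(x$truth), "causal variants\n")
  invisible(x)
}

#' Inject a common conditioning locus in linkage with one gene's rare variants
#'
#' Builds the scenario of a gene whose rare variants ride the haplotypes of
#' a nearby common causal variant (the TOMM40-next-to-APOE configuration):
#' a common variant is simulated at `common_maf`, the target gene's rare
#' variants are re-drawn so that they occur only on haplotypes carrying the
#' common allele (complete D'), the causal effect is attached to the common
#' variant only, parental affection / own diagnosis / proxy scores are
#' re-drawn, and the offspring's common-variant dosage is returned as the
#' conditioning vector.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param target_gene gene id whose rare variants are re-drawn.
#' @param common_maf MAF of the conditioning variant (default 0.15,
#'   an APOE-e4-like allele frequency).
#' @param effect log-odds per common allele on the parental liability and
#'   own-diagnosis scales (default 1.1, a strong late-onset risk allele).
#' @return list with `cohort` (modified) and `conditioning` (offspring
#'   dosage of the common variant).
#' @export
inject_ld_conditioning_locus <- function(cohort, target_gene,
                                         common_maf = 0.15, effect = 1.1) {
  stopifnot(inherits(cohort, "sim_cohort"))
  vmap <- cohort$variant_map
  idx <- which(vmap$gene == target_gene)
  if (length(idx) == 0L) stop("target gene not found: ", target_gene)
  bad <- vmap$maf[idx] > common_maf
  if (any(bad)) {
    stop("rare MAF exceeds the common MAF; feasible bound is ",
         common_maf)
  }
  n <- cohort$config$n_subjects
  set.seed(component_seeds(cohort$config$seed, "ld_locus")[[1]])
  draw_parent <- function() {
    # two haplotypes per parent for the common allele; rare alleles ride
    # only on common-carrier haplotypes with conditional frequency
    # maf_rare / maf_common (complete D')
    h <- matrix(stats::rbinom(2 * n, 1L, common_maf), n)
    rare <- lapply(1:2, function(k) {
      m <- matrix(0L, n, length(idx))
      carrier <- h[, k] == 1L
      if (any(carrier)) {
        m[carrier, ] <- stats::rbinom(sum(carrier) * length(idx), 1L,
                                      rep(vmap$maf[idx] / common_maf,
                                          each = sum(carrier)))
      }
      m
    })
    list(h = h, rare = rare)
  }
  fa <- draw_parent(); mo <- draw_parent()
  tf <- sample(1:2, n, replace = TRUE)   # transmitted haplotype, father
  tm <- sample(1:2, n, replace = TRUE)
  pick <- function(par, t) {
    cbind(common = par$h[cbind(seq_len(n), t)],
          par$rare[[1]] * (t == 1L) + par$rare[[2]] * (t == 2L))
  }
  off_f <- pick(fa, tf); off_m <- pick(mo, tm)
  conditioning <- off_f[, 1] + off_m[, 1]
  cohort$genotypes[, idx] <- off_f[, -1, drop = FALSE] +
    off_m[, -1, drop = FALSE]
  cohort$father[, idx] <- fa$rare[[1]] + fa$rare[[2]]
  cohort$mother[, idx] <- mo$rare[[1]] + mo$rare[[2]]
  common_f <- rowSums(fa$h); common_m <- rowSums(mo$h)
  lp_father <- cohort$lp_father + effect * common_f
  lp_mother <- cohort$lp_mother + effect * common_m
  lp_self <- cohort$lp_self + effect * conditioning
  father_aff <- stats::rbinom(n, 1L, stats::plogis(lp_father))
  mother_aff <- stats::rbinom(n, 1L, stats::plogis(lp_mother))
  own_dx <- stats::rbinom(n, 1L, stats::plogis(lp_self))
  pheno <- data.table::data.table(
    subject_id = cohort$pheno$subject_id,
    own_diagnosis = own_dx,
    father_affected = father_aff, father_age = cohort$pheno$father_age,
    mother_affected = mother_aff, mother_age = cohort$pheno$mother_age)
  cohort$pheno <- score_phenotypes(pheno)
  cohort$lp_father <- lp_father
  cohort$lp_mother <- lp_mother
  cohort$lp_self <- lp_self
  list(cohort = cohort, conditioning = conditioning,
       common_maf = common_maf, effect = effect)
}

#' Power scan over effect size, causal fraction and sample size
#'
#' Per grid cell, simulates single-causal-gene cohorts and reports the
#' rejection rate of that gene's aggregation test at `alpha`, with
#' Monte-Carlo standard errors. `design = "parental"` tests the parents'
#' own affection status against parental genotypes (the undiluted design),
#' for quantifying the transmission dilution of the proxy score.
#'
#' @param effect_sizes,causal_fractions,n_subjects grid vectors.
#' @param replicates simulations per cell.
#' @param alpha rejection threshold.
#' @param design `"proxy"` or `"parental"`.
#' @param base_config template [sim_config()] (its causal settings and
#'   cohort size are overridden per cell).
#' @param seed master seed for the scan.
#' @return `data.table` with one row per cell: `effect`, `causal_fraction`,
#'   `n`, `power`, `mc_se`.
#' @export
power_scan <- function(effect_sizes, causal_fractions, n_subjects,
                       replicates = 100, alpha = 6.25e-4,
                       design = c("proxy", "parental"),
                       base_config = sim_config(n_genes = 4,
                                                variants_per_gene = 10),
                       seed = 1L) {
  design <- match.arg(design)
  grid <- expand.grid(effect = effect_sizes,
                      causal_fraction = causal_fractions, n = n_subjects)
  set.seed(seed)
  cell_seeds <- sample.int(.Machine$integer.max - 1L, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    rej <- vapply(seq_len(replicates), function(r) {
      cfg <- base_config
      cfg$n_subjects <- grid$n[i]
      cfg$causal_genes <- data.frame(
        gene = "GENE001", causal_fraction = grid$causal_fraction[i],
        effect = grid$effect[i])
      cfg$seed <- (cell_seeds[i] + r) %% (.Machine$integer.max - 1L) + 1L
      co <- simulate_cohort(cfg)
      vids <- co$variant_map[gene == "GENE001" &
                               class != "synonymous", variant_id]
      if (design == "proxy") {
        null <- fit_null_model(co$pheno$proxy_score, co$covariates,
                               "quantitative")
        G <- co$genotypes[, vids, drop = FALSE]
      } else {
        if (sum(co$pheno$father_affected) < 2) return(FALSE)
        null <- fit_null_model(co$pheno$father_affected,
                               co$pheno$father_age, "binary")
        G <- co$father[, vids, drop = FALSE]
      }
      fit <- skat_o_test(G, null)
      !is.na(fit$p_value) && fit$p_value < alpha
    }, NA)
    p <- mean(rej)
    data.table::data.table(effect = grid$effect[i],
                           causal_fraction = grid$causal_fraction[i],
                           n = grid$n[i], power = p,
                           mc_se = sqrt(p * (1 - p) / replicates))
  })
  data.table::rbindlist(rows)
}
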