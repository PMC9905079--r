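#!/usr/bin/env Rscript
# Set-level analysis: pool the rare variants of a candidate gene set,
# test the pooled unit, find the driver gene by leave-one-out, and show
# the region-exclusion mechanics. Closes with a small power scan,
# including the proxy-vs-parental-phenotype dilution comparison.

suppressMessages(library(proxyrvat))
dir.create("results", showWarnings = FALSE)

causal <- data.frame(gene = "GENE003", causal_fraction = 1, effect = 2.5)
co <- simulate_cohort(sim_config(n_subjects = 3000, n_genes = 10,
                                 seed = 20260105, causal_genes = causal))
st <- variant_stats(co$genotypes)
ann <- co$annotations[st, on = "variant_id"]
masks <- build_mask(ann, "pLOF_missense", mask_config())
null <- fit_null_model(co$pheno$proxy_score, as.matrix(co$covariates))

set_all <- gene_set("candidate_set", masks$gene)
fit <- run_geneset_test(set_all, masks, co$genotypes, null)
cat(sprintf("pooled set (%d genes, %d variants): p = %.3g\n",
            fit$n_genes_effective, fit$n_variants, fit$p_value))

loo <- leave_one_out(set_all, masks, co$genotypes, null)
cat("leave-one-out (driver = omission with the largest p increase):\n")
print(loo)
cat("identified driver:", attr(loo, "driver"),
    "(truth: GENE003)\n")
data.table::fwrite(loo, "results/geneset_leave_one_out.tsv", sep = "\t")

# removing the driver gene (as a region exclusion) empties the signal
drv <- attr(loo, "driver")
vid1 <- masks[gene == drv, variant_ids][[1]][1]
parts <- strsplit(vid1, ":")[[1]]
no_region <- gene_set("minus_region", masks$gene,
                      excluded_region = c(parts[1], 0, 3e9))
fit2 <- run_geneset_test(no_region, masks, co$genotypes, null)
cat(sprintf("after excluding the driver's chromosome: p = %s (%d genes)\n",
            format(fit2$p_value, digits = 3), fit2$n_genes_effective))

# power scan: effect size grid at two sample sizes, proxy vs parental
scan <- power_scan(effect_sizes = c(0, 1.5, 2.5),
                   causal_fractions = 0.8,
                   n_subjects = c(1000, 3000),
                   replicates = 60, alpha = 6.25e-4,
                   design = "proxy", seed = 20260106)
scan[, design := "proxy"]
scan_par <- power_scan(effect_sizes = c(0, 1.5, 2.5),
                       causal_fractions = 0.8,
                       n_subjects = c(1000, 3000),
                       replicates = 60, alpha = 6.25e-4,
                       design = "parental", seed = 20260106)
scan_par[, design := "parental"]
power <- data.table::rbindlist(list(scan, scan_par))
cat("power scan (rejection rate at the across-analyses-scale threshold):\n")
print(power)
data.table::fwrite(power, "results/power_scan.tsv", sep = "\t")
cat("note the null row (effect 0) sits near the nominal level and the\n")
cat("parental design dominates the diluted proxy design at equal settings\n")
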