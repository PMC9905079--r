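---
title: "Methods: proxy-phenotype rare-variant aggregation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: proxy-phenotype rare-variant aggregation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

## The proxy phenotype

Late-onset dementia is rare inside the age range of population biobanks, so
the package scores each genotyped subject by family history instead of
waiting for their own diagnosis. The score is pseudo-linear on $[0, 2]$:

* a subject with their own AD/dementia diagnosis scores the maximum, 2 —
  the same value as a subject with two affected parents;
* each affected parent contributes exactly 1;
* each unaffected parent of age $a$ contributes
  $\min\{0.32, (100 - a)/100\}$, floored at 0 — an unaffected parent is
  weak evidence against genetic risk, and the older they are the stronger
  that evidence, so their contribution shrinks with age; below age 69 the
  cap of 0.32 binds and age carries no further information.

Affected parents contribute 1 independent of age: the scale endpoints force
this (two affected parents must reach the maximum 2, which an own diagnosis
also receives). Missing data rules, ours rather than anything mandated by
the scale itself: an unreported parent contributes 0 (conservative, keeps
the subject; a flag records it and `drop_missing_parent` removes such
subjects instead), and an unaffected parent of unknown age contributes the
cap (treated as uninformative-young, also flagged). Both rules are
configurable in `score_phenotypes()`.

The score is treated as a quantitative trait throughout; the binary
machinery is used only for the case-control sensitivity recoding (case =
own diagnosis or at least one affected parent).

## Variant masks

Variants arrive annotated with a VEP-style consequence term, a LOFTEE
confidence flag and (for missense) a REVEL score. Five categories are
built, four of them nested:

1. `HiC_pLOF` — high-confidence loss-of-function only;
2. `pLOF` — all predicted LOF (the seven canonical terms: start/stop loss,
   frameshift, stop gain, splice donor/acceptor, transcript ablation);
3. `pLOF_REVEL` — pLOF plus missense with REVEL above 0.5. The published
   "REVEL > 50" is read on REVEL's native 0–1 scale as 0.5; the variant
   REVEL values quoted alongside it (0.335, 0.568, 0.592, 0.607) and the
   cited 75%-of-disease-variants operating point both confirm that
   reading;
4. `pLOF_missense` — pLOF plus all missense;
5. `synonymous` — the negative-control category, disjoint from the four.

Only rare variants (in-sample MAF < 0.01) enter. MAF is always computed
within the analyzed cohort after QC, not from an external reference — the
natural choice when a replication cohort must recompute its own
frequencies. Genes with cumulative allele frequency below $10^{-4}$ are
excluded; CAF defaults to the sum of member MAFs (`caf_method =
"sum_maf"`), with the carrier fraction offered as an alternative since the
term is used without a formal definition in the literature this mirrors.
QC removes variants with missingness > 5%, MAC 0, and positional
duplicates (first record kept — deterministic and the common convention).

## The aggregation test

For a gene with dosages $G$ ($n \times m$), weights $w_j =
\mathrm{Beta}(f_j; 1, 25)$ evaluated at the variant's MAF, and null-model
residuals $r$, the score vector is $s = W G^\top r / \hat\sigma$ and the
family of statistics

$$Q_\rho = (1 - \rho)\, \|s\|^2 + \rho\, (\mathbf{1}^\top s)^2,$$

interpolates between the variance-component kernel test ($\rho = 0$) and
the weighted burden test ($\rho = 1$). Under the null each $Q_\rho$ is a
mixture of 1-df chi-squares with weights given by the eigenvalues of
$R_\rho^{1/2} Z^\top Z R_\rho^{1/2}$, where $Z$ is the covariate-adjusted
weighted genotype matrix and $R_\rho$ the exchangeable correlation. The
omnibus p-value is the minimum-p combination over the grid
$\rho \in \{0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1\}$, evaluated by the
standard one-dimensional conditioning integral that separates the shared
burden component (a single chi-square) from the remainder spectrum. The
test is two-sided by construction. The grid and the "optimal" (rather than
small-sample-adjusted) variant are declared defaults — the analysis this
package reproduces names neither, and these are the reference defaults.

Null models: ordinary least squares for the quantitative score; logistic
IRLS for the binary recoding, with variance weights $\mu(1-\mu)$ entering
the genotype adjustment. Covariates are batch, sex, age and 10 principal
components (batch is dropped for a single-batch replication cohort).
Missing dosages are mean-imputed to twice the in-sample MAF, matching the
reference implementation's behaviour.

Binary traits in small cohorts need special care: 0/1 residuals have
excess kurtosis $-2$ at balance, and at $n \approx 100$ the asymptotic
mixture misses the exact permutation null by a visible margin (about 0.02
in absolute p around $p = 0.3$ in our checks — an order of magnitude
beyond Monte-Carlo noise) even though the same eigenvalue machinery
matches a normal-score oracle to $10^{-3}$. Below $n = 500$ the binary
test therefore switches to a Monte-Carlo min-p null
(`small_sample = "auto"`): the phenotype is permuted when the model is
intercept-only (exact), or drawn from the fitted Bernoulli null under
covariates, the per-rho statistics are ranked against $2 \times 10^5$
resamples, and the omnibus p is the resampled tail of the min-p
statistic. Large-sample binary analyses — the case-control sensitivity
recoding at cohort scale — keep the asymptotic machinery.

## Mixture-of-chi-square tails

`quad_form_pvalue()` computes $P(\sum_k \lambda_k \chi^2_{1,k} \ge q)$:

* equal eigenvalues reduce exactly to a scaled central chi-square
  (evaluated in closed form — this also covers every single-variant gene);
* otherwise Imhof's characteristic-function integral is evaluated by an
  equally spaced midpoint rule. For CF inversion the discretisation error
  of an equal-step rule is an *aliasing* error bounded by the tail mass of
  the distribution beyond $2\pi/\Delta$, not by the oscillation of the
  integrand, so the step comes from a chi-square tail bound and the
  truncation point from a stationary-phase envelope estimate. Validated
  against high-resolution quadrature, the rule holds absolute error near
  $10^{-8}$ at a few milliseconds per call;
* below $p \approx 10^{-6}$, where quadrature loses relative accuracy, a
  Lugannani–Rice saddlepoint approximation takes over (far better relative
  error in the tail);
* a moment-matched non-central scaled chi-square (three-moment fit) is the
  final fallback, and supplies the quantile inversion inside the omnibus
  integral. P-values are floored at $10^{-30}$, never reported as 0.

The omnibus integral is evaluated with the exact CF machinery for the
remainder spectrum (grid precomputed once per gene), and the result is
clamped to $[\min_\rho p_\rho,\ m_\rho \cdot \min_\rho p_\rho]$ — the
lower bound is an identity of min-p combinations, the upper the Bonferroni
envelope over the grid.

## Decisions and inference

The genomic inflation factor is the median of the 1-df chi-square
quantiles of the observed p-values over $\chi^2_{1,0.5} \approx 0.4549$ —
declared as our definition, since the mirrored analysis does not state
one. Bonferroni corrections are applied within each category
($\alpha/\#\text{genes}$) and across analyses as $\alpha / (\max_c
\#\text{genes}_c \times 4)$: with the published per-category gene counts
(6749, 11037, 16010, 18425) only the max-count reading reproduces the
published $6.78 \times 10^{-7}$ (the sum-of-counts reading gives
$9.6\times10^{-7}$). BH-FDR at 10% runs per category. A singleton is MAC
exactly 1 (one heterozygous individual; a single homozygote is MAC 2 and
not a singleton). Sensitivity reruns drop singletons, MAC < 5 variants, or
moderately associated variants ($P < 10^{-4}$ from single-variant
regressions on the same cohort and covariates); a rerun that removes
nothing reproduces the base p bit-exactly because it re-executes the same
deterministic code path on the same columns.

Gene-set tests pool the deduplicated variants of the member genes into one
aggregation unit and run the identical test. Region exclusion uses
closed-open `[start, end)` intervals and decides membership by variant
position, not gene-model boundaries — the masks carry no gene models, and
the variants are what enter the statistic. The set-level CAF filter is
applied to the pooled unit.

# The synthetic cohort generator

The generator emulates what the analysis consumes, not the biology that
produced it:

* **MAF spectrum**: Beta(0.2, 50) truncated to $(10^{-6}, 0.01)$ —
  rare-skewed, giving a realistic singleton load at cohort scale; the
  truncation matches the analysis's own MAF < 0.01 universe.
* **Genotypes**: parental dosages are Hardy–Weinberg draws at the sampled
  MAF; each parent transmits one allele carried with probability
  dosage/2. This makes the offspring–mid-parent dosage correlation
  $\approx 1/\sqrt2$ and offspring–single-parent $\approx 1/2$, the
  random-mating values, and it is what produces transmission dilution: the
  proxy score responds to the *parents'* liability, while the test sees
  the *offspring's* genotype.
* **Affection**: logistic in the parent's own weighted causal burden plus
  0.07 log-odds per year of age, with per-parent prevalence 0.07 at the
  reference age 80 — chosen so roughly 15% of subjects have at least one
  affected parent, the approximate share in the mirrored cohort (22,080 of
  148,508). Logistic rather than probit liability is an arbitrary,
  configurable choice. The own-diagnosis rate is 0.2%, matching the
  roughly 277-in-148,508 structure. Parental ages are uniform on 60–100 so
  the 0.32 cap binds for a nontrivial fraction of unaffected parents.
* **Consequence mix**: 4% HiC pLOF, 3% other pLOF, 63% missense, 30%
  synonymous — an exome-like ratio reproducing the strong growth of the
  nested categories. REVEL for missense is Beta(0.5, 1.2) (skewed low,
  with ~20% above the 0.5 threshold).
* **Covariates**: sex, uniform 40–70 age, a batch indicator (default 25%
  early-batch) and standard-normal PC stand-ins; the PCs carry no
  confounding, so passing tests say nothing about stratification control
  on real data.
* **Replication pairing**: a replication cohort is simulated on the
  *same* variant map and causal assignment as its discovery cohort
  (`simulate_cohort(cfg, variant_map = disc$variant_map)`), with fresh
  genotypes, ages, affection and covariates — same genome, new sample.
  Without the pairing, an independently drawn gene architecture can leave
  a causal gene with no testable signal in the second cohort, which is a
  statement about the simulator, not about replication.
* **Randomness**: one master seed; each component (map, parental draws,
  transmission, ages, affection, covariates, missingness) runs on its own
  derived substream, so swapping one component leaves the others' draws
  unchanged, and a seed fully determines the cohort bit-for-bit.

A "standard" causal effect in the tests and drivers is 2.5 log-odds per
minor allele on the parental liability scale (odds ratio ≈ 12) with
causal fraction 0.8 — the magnitude reported for high-impact LOF variants
in the strongest AD genes; at desk-scale cohort sizes (thousands rather
than hundreds of thousands) an effect of this size is what makes
rediscovery demonstrable at all, and it is fixed once here rather than per
experiment.

The conditioning-locus scenario (`inject_ld_conditioning_locus()`) plants
a common variant (default MAF 0.15, log-OR 1.1 — an APOE-ε4-like allele)
and re-draws the target gene's rare variants onto the common allele's
haplotypes with complete D′, transmitting haplotypes jointly so the LD
survives into the offspring. The causal effect sits on the common variant
only, so the gene's unconditional signal is borrowed and conditioning on
the common dosage removes it.

**What the generator does not emulate**: LD beyond the single conditioning
device, demographic history and realistic site-frequency spectra,
ancestry/batch confounding, genotyping error, relatedness, or
sequencing-depth artefacts. Passing tests therefore demonstrate the
statistical machinery and its calibration under clean sampling — not
robustness to the data pathologies real cohorts carry.

# Problem sizes and numerical choices

The suite exercises: oracle equivalence against $10^5$-permutation min-p
nulls at $n = 100$ with 4 variants (intercept-only models, where phenotype
permutation is exact); type-I calibration on ~2,000 null genes at
$n = 2000$ (exact binomial 99% band around 0.05); rediscovery and
replication over 10 seeded cohort pairs of $n = 8000$ with 25 genes —
sized so both causal genes clear the across-analyses threshold even in
seeds with unfavourable gene architecture, leaving the ~5%-per-scan
null-false-positive event as the only failure mode of the exclusivity
check; and the
conditional scenario over 10 seeds at $n = 6000$ with a 20-variant
target gene drawn slightly commoner than the default spectrum — sized,
from the haplotype-sharing algebra, so the borrowed signal clears the
significance bar with margin in essentially every seed even after the
beta(1,25) weights dilute it. These sizes make each
property measurable with margin while keeping a full run in minutes on
one CPU; the same properties hold at larger $n$ since every approximation
involved is asymptotic in $n$.

Ties and degenerate inputs: duplicate variants keep the first record;
monomorphic variants are excluded from single-variant results with a flag
and contribute nothing to aggregation (zero variance, zero weight in the
spectrum); genes that lose every variant report `excluded_empty` rather
than failing; rank-deficient covariate designs abort with the collinear
columns named; conditioning vectors are rejected when constant or
collinear.

# Known limitations

* Binary-trait p-values lack small-sample moment corrections (above).
* The omnibus integral inherits ~$10^{-5}$ relative accuracy from its
  quadrature; p-values near machine-zero are reported at the clamp
  boundaries ($\min_\rho p_\rho$ scale) rather than resolved exactly.
* Relatedness-aware (mixed-model) testing, X-chromosome dosage models and
  cross-cohort meta-analysis are out of scope.
* The proxy score's missing-data rules are policies, not estimates; with
  heavy missingness the flagged subjects deserve a sensitivity pass via
  `drop_missing_parent = TRUE`.
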