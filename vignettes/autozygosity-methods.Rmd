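---
title: "Autozygosity, runs of homozygosity, and inbreeding-depression regression: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autozygosity, runs of homozygosity, and inbreeding-depression regression: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Offspring of related parents carry long chromosomal segments that are
identical by descent from the shared ancestor. Homozygosity across such
*autozygous* segments exposes the full effect of recessive and partially
recessive deleterious alleles, so traits under directional selection are
expected to decline with the autozygous genome fraction — *inbreeding
depression* via *directional dominance*. Because everyone is somewhat
inbred, the quantity of interest is continuous: the fraction of the
autosomal genome lying in runs of homozygosity (ROH), written F_ROH.

`autozyg` implements the complete analysis chain used in biobank-scale
studies of this question: genotype QC, PLINK-style sliding-window ROH
detection, the F statistics, and nested regression model sets that test
trait associations while controlling sociodemographic confounding and
partitioning the recessive signal into common- versus rare-variant
homozygosity. Because individual-level biobank data are access-restricted,
the package also ships a synthetic-cohort generator that reproduces the
statistical structure the analysis assumes, making every stage testable.

# Quality control

Variant filters follow standard ROH practice, in the order Hardy-Weinberg,
missingness, minor allele frequency:

* **HWE exact test**, removal at p < 1e-6. The exact conditional test
  (summing probabilities of all heterozygote counts no more probable than
  the observed one, given the allele totals) is used rather than the
  chi-square approximation, because the screening threshold sits in the
  far tail where the approximation fails. Implementation is direct
  log-factorial enumeration; the test suite cross-checks it against an
  independent probability-recurrence oracle to 1e-12.
* **Missingness**: variants and samples with a missing call rate above
  0.02 are removed. Samples are filtered before variants: the two orders
  give slightly different results and the convention must be fixed; the
  sample-first order means variant statistics are computed on the cohort
  actually analysed.
* **MAF** below 0.05 removed: rare variants are poorly called on arrays
  and a homozygous rare genotype carries little evidence of autozygosity.
* **Relatedness**: a genomic relationship matrix (standardized
  minor-allele counts, pairwise-complete over missing calls) feeds a
  greedy unrelated-subset selection at pi-hat > 0.2 (0.05 as a strict
  sensitivity cutoff). Exact minimum removal is a vertex-cover problem
  (NP-hard); the greedy maximum-degree heuristic is documented as such and
  is checked against an exhaustive solver at n <= 8 in the tests.

**LD pruning.** ROH windows assume exchangeable, roughly independent
markers, so dense LD is thinned with PLINK's `--indep 50 5 10` semantics:
50-SNP windows advanced by 5, removing the variant with the largest
variance inflation factor while any VIF exceeds 10. The VIF is the true
multiple-regression quantity — the diagonal of the inverse correlation
matrix — not a pairwise approximation (VIF 10 corresponds to a multiple
R^2 of 0.90). Exactly collinear windows are handled with a tiny ridge so
duplicated variants are removed deterministically.

# ROH detection and F statistics

Detection follows the PLINK sliding-window algorithm with the parameter
set standard for ~1 SNP / 10 kb pruned array data:

| parameter | default | meaning |
|---|---|---|
| `window_snps` | 65 | scanning window size (SNPs) |
| `window_het_max` | 0 | heterozygous calls allowed per window |
| `window_missing_max` | 3 | missing calls allowed per window |
| `min_snps` | 65 | minimum SNPs per reported segment |
| `min_kb` | 10 | minimum segment span (kb; effectively inactive at 65 SNPs) |
| `gap_kb` | 500 | split a run at larger inter-SNP gaps |
| `density_kb_per_snp` | 200 | maximum mean SNP spacing in a segment |
| `hit_rate_min` | 0.05 | per-SNP qualifying-window fraction |

`hit_rate_min` is the one parameter the usual command line leaves at the
tool default rather than setting explicitly; 0.05 is adopted here as that
default and exposed in configuration like everything else.

Each SNP's hit rate is the fraction of qualifying windows containing it.
SNPs at or above `hit_rate_min` form candidate runs; heterozygous SNPs
terminate a run (with `window_het_max = 0` they can never qualify anyway,
so no segment-level heterozygote allowance exists); runs split at gaps
over `gap_kb`; leading and trailing missing calls are trimmed, so segment
boundaries are the first and last homozygous SNP — no extension into
flanking gaps. Whether a published analysis trims run edges is usually
unstated; trimming is chosen here and fixed. The density rule is evaluated
on the final trimmed segment, not per window. Segment length is
`end_bp - start_bp + 1` (1-based inclusive, matching `.bim` coordinates);
the `+1` convention is applied consistently so the F statistics are
internally coherent.

**F statistics.** For each individual,

* `f_roh` = summed autosomal segment length / 2.77e9 bp (the SNP-mappable
  autosome length for human array data; synthetic genomes use their own
  length — both are configuration constants),
* `f_roh_long` / `f_roh_short` split that sum at 8.5 Mb. Under a 1 cM/Mb
  map, tracts from an ancestor g generations back average 100/(2g) cM, so
  segments under 8.5 Mb trace to ancestors roughly 6+ generations back:
  the split separates recent from distant inbreeding, and the partition
  sums to `f_roh` exactly.
* `f_snp` = (O − E) / (T − E): observed homozygous count against the
  Hardy-Weinberg expectation from cohort allele frequencies, over the
  individual's non-missing variants. The small-sample correction
  2N/(2N−1) on expected heterozygosity is applied by default and can be
  toggled — published descriptions rarely say which variant was used, and
  at biobank N the difference is negligible. Computed from genotyped
  (common) SNPs, `f_snp` indexes excess homozygosity at common variants
  only, which is what makes the joint model below informative.

# The regression model sets

Each trait Y is modelled as `Y = b0 + b1 * F + gamma' C + e`, by OLS for
quantitative traits (standardized to within-sex z-scores first, so b1
reads as trait SD per unit F_ROH) and by logistic regression for binary
traits (b1 a log odds ratio, Wald p). Rows with any missing model variable
are dropped per model (complete-case per trait and set). Physiological
range exclusions are applied trait-wise beforehand with strict bounds (a
value exactly on a bound is kept).

Three nested covariate sets per trait:

1. **Minimal**: genotyping batch, per-sample missingness, ancestry PCs,
   age, age^2, sex — technical and demographic confounders of F_ROH.
2. **+ sociodemographic**: income, education years, area deprivation,
   college, urbanicity, religious participation, breastfed — proxies for
   parental background that can drive outbreeding and trait values
   simultaneously. Traits that are themselves sociodemographic are
   skipped here (they would sit on both sides of the adjustment); the
   same applies in set 3.
3. **+ f_snp** as a second focal predictor: since `f_snp` sees only
   common-variant homozygosity while `f_roh` sees both, a trait driven by
   rare recessives keeps its `f_roh` coefficient, while a common-variant
   signal migrates to `f_snp`.

Each set carries its own Bonferroni threshold `0.05 / (traits in set)` —
0.05/26 ≈ 0.002 for the full family, 0.05/19 ≈ 0.003 once the seven
sociodemographic traits drop out. **Attenuation** between sets is
`100 * (|b1_set1| − |b1_set2|) / |b1_set1|` (negative when adjustment
grows the estimate). Sex-specific effects are tested by adding a
sex-by-predictor product to the set-2 design. Long and short F_ROH can be
run as two separate models or jointly, by passing one or both as focal
predictors.

**Indirect (mediated) effects** of the sociodemographic block are
estimated by the coefficient-difference method — total (set 1) minus
direct (set 2) effect on the same complete-case rows — with a
nonparametric bootstrap over individuals and a 95% percentile interval.
Difference-of-coefficients and product-of-coefficients estimators agree
for linear models; the difference form needs no structural model for the
mediators, which is why it is used here, and the choice is isolated
behind one function so it can be swapped. The point estimate comes from
the original sample and is unaffected by the bootstrap; degenerate
resamples (a constant model column) are redrawn and counted.

# What the synthetic cohorts emulate

`simulate_cohort()` draws independent sites (positions uniform, MAFs
uniform or beta, folded to <= 0.5) and plants per-individual autozygous
tracts: exponential lengths with mean 100/(2g) Mb, placed uniformly
without overlap until the summed length reaches the individual's target
fraction, with the second haplotype copying the first inside tracts.
Placement "until >= target" can overshoot by a partial tract; the realized
fraction is recorded in the truth record, and on small genomes the
granularity of whole tracts makes realized F lumpy around its target —
analyses therefore always regress against the *realized* truth.

Recessive phenotypes add `effect_size` per causal minor-allele homozygote
(causal variants confined to a MAF class: common > 0.05 or rare < 0.05)
plus Gaussian noise; negative effects encode inbreeding depression. The
confounded scenario draws a latent sociodemographic score S ~ N(0,1),
makes the target autozygous fraction a decreasing logistic function of S
(`f_max * plogis(qlogis(base_p) - strength_on_f * S)`), and the trait a
linear function of S only — any F-trait association is then spurious by
construction, and S is exported as an observable covariate so adjustment
can be demonstrated.

Deliberate simplifications, and what they mean for the tests: there is
**no background LD** (the pruning stage is exercised by a separate
correlated-blocks fixture generator built on a Gaussian-copula threshold
model), no realistic allele-frequency spectrum, a fixed 1 cM = 1 Mb map,
uniform tract placement rather than pedigree inheritance, and a single
synthetic chromosome. Passing tests therefore demonstrate the detector,
the estimators and the regression machinery under the assumed statistical
structure — not robustness to real-data pathologies such as LD shadows,
array batch artefacts, or assortative mating.

# Numerical and design choices

* Missing genotypes are a sentinel (`NA`) end to end; never imputed.
* The minor allele is defined per dataset after QC; ties broken by allele
  label order. The HWE test and `f_snp` are invariant to the labelling.
* Greedy unrelated-selection breaks degree ties by input order, making
  the removal set deterministic.
* Logistic fits detect separation (saturated fitted probabilities, or
  non-convergence) and raise an error rather than returning a huge beta.
* `attenuation()` is undefined at `beta_main = 0` and errors.
* Every stochastic routine takes an explicit seed; the pipeline derives
  per-stage seeds from the run seed, so a config reproduces its outputs
  byte for byte.

# Problem sizes used in the shipped tests

The replicate suites run at deliberately scaled cohort dimensions chosen
to keep the full test run on one CPU pleasant while leaving each check
statistically decisive (the checked properties — CI coverage,
significance-rate patterns, median shrinkage — are size-invariant):
planted-tract recovery at n = 500 with 20,000 variants over 200 Mb
(1 SNP / 10 kb, the density the default ROH parameters assume);
slope-recovery coverage at n = 600 over 100 replicates; the common/rare
partition at n = 1,000 with 300 causal variants per class over 100
replicates per class; the confounding demonstration at n = 1,200 over 100
seeds; null calibration over 1,000 trait replicates. Effect sizes and
causal counts for the partition suite were fixed by a priori power
analysis so that each class's loaded statistic is detected with high
probability at those sizes. The tract scale is g = 6 where recent
inbreeding is the point, g = 20–50 where fine-grained control of the
autozygous fraction matters more than tract length realism (the
confounded scenario models outbreeding-degree differences, i.e. distant
inbreeding).

# Known limitations

* ROH calling is physical-distance based; no genetic-map (cM) mode, no
  phased-haplotype IBD detection, no ROH-island mapping.
* Ancestry PCs are accepted as covariate columns, not computed from
  genotypes; X/Y/mitochondrial data are excluded throughout.
* `read_plink()` handles the SNP-major PLINK 1 layout only; no VCF/BGEN
  or dosage support.
* The greedy unrelated subset is not guaranteed minimal (the exact
  problem is NP-hard); on random small graphs it is within one removal of
  the optimum.
* Mediation uses one estimator (coefficient difference); causal
  interpretation still rests on the usual no-unmeasured-confounding
  assumptions, which the confounded simulation deliberately violates for
  the *unadjusted* model.
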