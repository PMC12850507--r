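# tribechip

HyperTRIBE edit-site calling and clonal hematopoiesis dynamics, as a
tested, reusable R pipeline.

## What this package is for

Two linked questions in stem-cell genomics:

1. **Which mRNAs does an RNA-binding protein touch in primary human
   cells?** HyperTRIBE fuses the protein to a hyperactive ADAR deaminase so
   that bound transcripts acquire A>G edits. `tribechip` calls those edit
   sites from per-sample allele-count tables (3 ADAR-fusion vs 3
   empty-vector samples), scores target genes, intersects the targets with
   perturbation differential expression to define a regulatory network, and
   tests 3'UTR k-mer motif enrichment (e.g. the UAG motif of MSI2) around
   the edit sites.
2. **Does an inherited variant slow the expansion of mutant blood
   clones?** From two serial blood draws per person, `tribechip` classifies
   CHIP (clonal hematopoiesis) mutations as persistent or transient, fits
   annualized clonal growth rates, and runs covariate-adjusted growth and
   transience regressions, plus allele-specific read-skew tests and
   fixed-effect meta-analysis of per-cohort effects.

It is written for analysts who have count-level data (allele counts,
expression matrices, serial VAFs) and want the bespoke statistics of this
analysis without the upstream alignment machinery. A seeded synthetic-data
generator with ground-truth tables makes every stage testable end to end.

## The statistics at the core

**Edit-site test.** At each candidate site, edited counts across the six
samples are modeled as

    k_i ~ NegBinom(mu_i, theta),   log(mu_i) = b0 + b1 * group_i + log(n_i)

with coverage `n_i` as offset and `group_i` indicating the ADAR-fusion
group. Two-sided p-values on `b1` (Wald; likelihood-ratio at the fitted
dispersion when one group's counts are all zero and the Wald statistic
degenerates) are BH-adjusted across all sites. Per-group editing frequency
is the no-intercept regression slope of `k` on `n`,
`sum(k*n) / sum(n^2)`. A site is retained when the treatment-minus-control
frequency difference is >= 0.1, the control frequency is < 0.02, and
FDR < 0.05.

**HyperTRIBE score.** Per gene, the sum of differential editing frequencies
of its retained sites. The **network** is genes with score >= 0.2,
relative expression <= 0.95 after perturbation, and adjusted P < 0.05.

**Clonal growth.** CHIP mutations are called at >= 100x depth, >= 3 variant
reads, VAF >= 2%. For persistent clones the annualized compound-interest
growth rate is `r = (VAF2/VAF1)^(1/t) - 1`, modeled as
`r ~ age + age^2 + VAF + sex + dosage + driver gene`; transience
(second-draw VAF < 2%) is modeled by logistic regression on the same
covariates, with the genotype odds ratio as the quantity of interest.

**Association utilities.** Allele-specific skew at a heterozygous site
(fractions, fold ratio, exact binomial test vs 0.5) and inverse-variance
fixed-effect meta-analysis (`w_i = 1/se_i^2`).

## A worked example

```r
library(tribechip)

# a target mRNA edited at two nucleotides in 50% and 70% of reads,
# another at one nucleotide in 25%
hypertribe_scores(data.frame(gene_id = c("TSPAN3", "TSPAN3", "CDK6"),
                             diff_freq = c(0.5, 0.7, 0.25)))
#>   gene_id n_sites score
#> 1  TSPAN3       2  1.20
#> 2    CDK6       1  0.25

# allele-specific binding skew: 61 vs 39 reads at a heterozygous site
sk <- allelic_skew(61, 39, ref_label = "C", alt_label = "T")
sk$fold_rounded   # 1.6   (1.6-fold enrichment of the C allele)
sk$p_value        # 0.035 (exact binomial vs 50:50)

# pooling three cohort effect estimates (log-OR scale)
m <- ivw_meta(beta = c(-0.174, -0.120, -0.260),
              se   = c(0.031, 0.054, 0.090))
sprintf("OR %.3f (95%% CI %.3f-%.3f)", m$or, m$or_ci[1], m$or_ci[2])
#> "OR 0.845 (95% CI 0.803-0.888)"

# a clone going from 2% to 8% VAF in 2 years doubles yearly
growth_rate(0.02, 0.08, 2)
#> [1] 1
```

The scores mean: TSPAN3 carries 1.2 summed differential editing — a strong
direct target — while CDK6 at 0.25 clears the 0.2 network gate only if it
is also downregulated upon perturbation. The 1.6-fold skew says binding is
depleted on the variant allele. The pooled OR of 0.845 is a protective
per-allele effect.

An end-to-end synthetic run (simulation -> filtering -> GLM -> scores ->
network -> motifs -> cohort models) is one call:

```r
man <- run_full_pipeline(pipeline_config(seed = 11, out_dir = "out"))
man$edit_site_recovery   # recall of planted edit sites vs the truth table
```

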