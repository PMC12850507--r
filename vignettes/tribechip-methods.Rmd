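---
title: "tribechip: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{tribechip: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tribechip)
```

This vignette is the package's own account of its methods: the statistical
models, why each tunable parameter has the default it has, what the
synthetic-data generators do and do not emulate, and the places where the
design was genuinely open and a choice had to be made.

## 1. Edit-site calling

### The filtering funnel

HyperTRIBE experiments tag RNA-binding-protein targets with A>G edits
deposited by an ADAR fusion. Starting from per-sample allele counts
(`chrom, pos, strand, ref, alt, sample, group, k, n`), candidate sites
pass four gates before any model is fitted:

1. **Per-sample discovery** (`discover_sites`): coverage >= 10 reads and
   minor allele frequency >= 0.01. Ten reads is the floor below which a 1%
   allele fraction is unobservable; both thresholds are the package-wide
   discovery defaults.
2. **Known-variant exclusion** (`filter_known_variants`): exact
   `(chrom, pos, alt)` matches against a dbSNP-style blacklist are
   germline polymorphisms masquerading as edits.
3. **Candidacy** (`select_candidates`): discovered in at least 2 of the 3
   ADAR-fusion samples; mismatch chemistry must be A>G on the forward
   strand or T>C on the reverse strand; and the reference allele must be
   the majority allele in *pooled* control reads. Pooling
   (`sum(k)/sum(n) < 0.5`) is used because a per-sample majority rule is
   unstable at low coverage; a site with zero pooled control coverage
   fails candidacy because the majority condition cannot be verified.
   Discovery thresholds are applied to treatment samples only for the
   >= 2 rule: control editing frequencies are *expected* to sit below the
   1% discovery MAF, and gating controls would bias candidacy.
4. **Matrix assembly** (`assemble_count_matrix`): every candidate gets one
   row per sample, with `k = 0` where the control simply shows no
   mismatch. Rows with zero coverage are flagged unusable; a site with no
   coverage across an entire group is dropped with a warning.

Strand is taken from the annotation of the overlapping gene
(`assign_strand_from_annotation`); intergenic mismatches are dropped
before candidacy because the analysis is defined on gene-annotated
transcripts.

### The per-site model

Edited counts are modeled per site as negative binomial with a log link
and coverage offset:

$$k_i \sim \mathrm{NB}(\mu_i, \theta), \qquad
\log \mu_i = \beta_0 + \beta_1\,\mathrm{group}_i + \log n_i .$$

`fit_nb_glm` fits this by maximum likelihood (`MASS::glm.nb`, which
alternates IRLS for the coefficients with ML updates of $\theta$). With
six observations $\theta$ is frequently unidentifiable; when the NB fit
fails or does not converge the site is refit as a Poisson GLM
($\theta \to \infty$) and flagged `converged = FALSE` — a conservative,
visible fallback rather than a silent failure.

**Wald versus likelihood ratio.** The reported p-value for $\beta_1$ is
the Wald test, with one deliberate exception. When every control count is
zero — which happens often by design, since control editing is rare
(at a background rate of 0.005 and ~200x coverage, all three controls are
zero at a non-trivial rate) — the design quasi-separates: $\hat\beta_1$
diverges, its standard error diverges faster, and the Wald p collapses
toward 1 precisely at the strongest sites (the Hauck–Donner effect). For
exactly those sites the p-value comes instead from the deviance drop at
the fitted dispersion ($\chi^2_1$), and the result row carries
`test = "lrt"`. Without this guard the caller discards its best sites.

**Frequencies.** Per-group editing frequency is the no-intercept
least-squares slope of `k` on `n`, $\sum k_i n_i / \sum n_i^2$, clipped to
$[0,1]$ (the slope can exceed 1 on pathological inputs, but a frequency
cannot). Under unequal coverages this differs from the pooled ratio
$\sum k / \sum n$; the pooled ratio is therefore exposed as a diagnostic
column (`pooled_treatment`, `pooled_control`) so the two can be compared.

**Retention.** BH adjustment is applied once, across *all* tested sites,
before any filtering; a site is retained iff

* differential frequency >= 0.1 (inclusive),
* control frequency < 0.02 (strict),
* FDR < 0.05 (strict).

The inclusivities matter at the boundaries and are tested there.

## 2. Gene scores, differential expression, and the network

The **HyperTRIBE score** of a gene is the sum of differential editing
frequencies over its retained sites (two sites at 0.5 and 0.7 give 1.2).
A site inside two overlapping genes is credited to both: the alternative
— dropping ambiguously mapped sites — silently deflates scores, whereas
assignment-to-all is visible in the output and can be audited.

`rank_sum_de` is a deliberately plain single-cell-style DE routine:
counts-per-10k, log1p, two-sided Wilcoxon rank-sum per gene, BH over the
genes actually tested (those expressed in >= 10% of cells in at least one
group). Relative expression is the ratio of de-logged group means with a
pseudocount of 1e-9 — just enough to keep an all-zero control group from
dividing by zero without distorting any expressed gene. Genes with
|rel_expr − 1| < 0.05 are reported but flagged non-significant.

The **network** is the threshold intersection: score >= 0.2 (inclusive),
relative expression <= 0.95 (inclusive), adjusted P < 0.05 (strict).

## 3. Motif windows and k-mer enrichment

Around each retained 3'UTR site, `build_windows` takes ±100 bp, clips to
the containing UTR (the analysis is defined on 3'UTR sequence, so windows
never extend into coding sequence), merges overlaps, and emits
strand-oriented RNA (T→U). A single interior site gives a 201-bp window;
two sites 50 bp apart merge to 251 bp.

`sample_background` draws 201-bp segments uniformly from the non-target
3'UTR space (UTRs shorter than 201 bp are never sampled), rejecting draws
that touch any target window, with an explicit failure once the rejection
budget (10x the requested segments) is exhausted — silent undersampling
would bias the background.

`kmer_enrichment` counts **all overlapping occurrences** of each observed
k-mer (k = 6, 7, 8), converts to per-base rates, and tests the target
count against the background rate with a one-sided binomial upper tail; a
pseudocount of 1 on the background count keeps p-values finite for
k-mers the background never shows. BH runs separately within each k-mer
length, since 6-mers and 8-mers have incomparable occurrence scales.
Occurrence counting (rather than per-segment presence/absence) is the
simpler convention and is stated so the conservation invariant
(`sum(counts) = L − k + 1` per window) is exact. This is a transparent
replacement for dedicated motif-discovery software: it ranks short
enriched k-mers and their direction, not position-weight matrices.

## 4. Clonal dynamics

Calling thresholds: >= 100x total depth, >= 3 variant reads, VAF >= 2% in
at least one draw. Among mutations *called at baseline* (first draw passes
all three), persistence is second-draw VAF >= 2%, transience is below;
everything else, including missing second draws, is `uncalled`.

The annualized growth rate of a persistent clone is the compound-interest
form $r = (\mathrm{VAF}_2/\mathrm{VAF}_1)^{1/t} - 1$, which inverts
exactly: $\mathrm{VAF}_1 (1+r)^t = \mathrm{VAF}_2$.

Two regressions share one design
(`~ age + age^2 + VAF + sex + dosage + driver gene`):

* `fit_growth_model`: OLS on `r` over persistent clones;
* `fit_transience_model`: logistic regression of the transience indicator
  over all baseline-called clones, reporting the exponentiated genotype
  coefficient as an odds ratio with a Wald CI.

Open choices resolved here: the protective genotype enters as **allele
dosage** (0/1/2), the additive coding standard in association work; the
driver-gene factor is releveled to its **most frequent** gene, a stable
reference on any dataset; the "VAF" covariate is **baseline VAF1**, since
growth is measured from baseline. Per-gene refits subset to one driver
gene and drop the gene covariate. Firth correction is not implemented:
separation is rare at cohort scale, and when it occurs the fit *errors*
with the fitted log-odds magnitude rather than returning an untrustworthy
estimate. Detection uses the linear predictor directly
(max |log-odds| > 15) because `glm` can report convergence without any
warning under perfect separation.

## 5. Allelic skew and meta-analysis

`allelic_skew` reports allele read fractions, their fold ratio (raw and
rounded — default one decimal, the conventional "1.6-fold" reporting
style), and an exact two-sided binomial test against 0.5. With zero
alternate reads the fold is undefined and flagged rather than reported as
a number. `ivw_meta` is the textbook fixed-effect pool:
$w_i = 1/se_i^2$, $\hat\beta = \sum w_i \beta_i / \sum w_i$,
$se = (\sum w_i)^{-1/2}$, normal 95% CI (multiplier 1.96). It is invariant
to study order and to splitting a study into equivalent half-precision
pieces, and its SE can never exceed the best single study's.

## 6. What the synthetic generators emulate — and what they do not

`generate_editing_dataset` simulates the 3-vs-3 design: coverage is
negative binomial (default mean 200, dispersion 0.5) truncated at 1 read,
matching the overdispersion the GLM assumes; edited counts are binomial
at each group's true frequency; true edits are A>G/T>C in annotated
3'UTRs with treatment frequencies drawn from a range (default 0.2–0.7);
control and unedited-site noise is 0.005; SNP contaminants sit at alt
fraction 0.5 or 1.0 in *all* samples (het/hom germline mimics);
wrong-strand contaminants carry treatment-high C>T mismatches so that
only the strand rule can remove them. The coverage defaults are
placeholders for a library-level quantity the analysis never pins down,
not estimates of any particular experiment. Not simulated: read-level
artifacts, alignment error, doublets, ambient RNA.

`generate_cohort` simulates serial draws: baseline VAFs from a scaled
Beta on [0.02, 0.40] (skewed low, as clone sizes are), a latent per-year
growth rate `mean_growth + dosage * effect + N(0, sd)` truncated at −0.99
(a clone cannot lose more than itself in a year), compound-interest
propagation to the second draw, and **binomial resampling of both VAFs at
the sequencing depth** — the observation noise of error-corrected
counting. Defaults describe a biobank-scale serial cohort: 3,000 people,
~1,725x mean depth, draws 0.7–13 years apart, median non-carrier growth
near +0.1%/yr, a protective-allele effect near −0.4%/yr, and a residual
SD (0.20/yr) chosen so that roughly a fifth of baseline-called mutations
are transient, the regime the classifier is meant to operate in. Age and
sex are simulated independently of genotype, so covariate-recovery tests
run against a known-null confounding structure.

`generate_expression` emulates the *well-captured stratum* of a
perturbation scRNA-seq comparison at desk scale: per-gene means are
log-normal (median ~30 counts), NB dispersion 0.05, and target genes are
scaled by a multiplicative effect (default 0.8, a 20% knockdown). The
test suite uses 100 cells per group — two orders of magnitude fewer than
a real experiment — so the generator preserves per-gene information
content instead of droplet-level sparsity. Passing the network-recovery
tests therefore demonstrates the *logic* of the DE gates and the
threshold intersection; it does **not** demonstrate power to detect 20%
shifts in sparse droplet data at these cell counts, and no such claim
should be read into it. No batch structure is simulated, so the relative
expression ratio is computed on a batch-free quantity by construction.

## 7. Numerical conventions

* Coordinates: site tables are 1-based inclusive (VCF convention); BED
  emission is 0-based half-open. Each format keeps its own convention;
  they are never mixed.
* Degenerate sites (all counts zero) return p = 1 with NA coefficients,
  flagged `test = "degenerate"`.
* Frequencies and VAFs are proportions in [0, 1]; clipping points are
  noted where they apply.
* All generators take a mandatory seed; identical seeds give
  byte-identical outputs, and the pipeline writes a resolved
  configuration copy and a manifest (row counts, truth recall, collected
  warnings) next to its artifacts.
* Test problem sizes are chosen for a laptop-scale run: 2,000 null
  simulations for type-I calibration, 100 seeded cohorts of n = 5,000
  for regression recovery, 150-site editing simulations for caller
  recovery, 500-gene expression matrices for the network property. These
  are the package's own test scales; larger runs only sharpen the same
  comparisons.

## 8. Known limitations

* Six observations per site is little data for a dispersion parameter;
  the Poisson fallback is flagged but still a model change, and sites
  fitted that way have slightly anti-conservative tails.
* The no-intercept frequency slope weights samples by coverage squared;
  under strongly unequal coverages it can differ noticeably from the
  pooled ratio (both are reported).
* The k-mer test treats overlapping occurrences as independent, which
  inflates counts of self-overlapping motifs equally in target and
  background; enrichment ratios are unaffected, absolute p-values are
  approximate.
* The transience model deliberately has no small-sample (Firth)
  correction; per-gene refits on few transient events may separate and
  error.
* The pipeline's `assoc` stage and expression stage simulate their
  inputs; with real data, call the underlying functions
  (`allelic_skew`, `ivw_meta`, `rank_sum_de`) directly on your tables.
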