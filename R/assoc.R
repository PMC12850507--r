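# Allele-specific read skew at a heterozygous site and inverse-variance
# fixed-effect meta-analysis of per-cohort effect estimates.

#' Allele-specific read skew
#'
#' Quantifies departure from the 50:50 read balance expected at a
#' heterozygous site: read fractions for the two alleles, their fold ratio
#' (reference over alternate, reported both raw and rounded), and an exact
#' two-sided binomial test against 0.5. With zero alternate reads the fold
#' is undefined: the reference fraction is 1 and `fold` is `NA` with
#' `fold_undefined = TRUE`.
#'
#' @param ref_reads,alt_reads Read counts for the two alleles.
#' @param ref_label,alt_label Allele names (default "ref"/"alt").
#' @param digits Decimal places for the rounded fold (default 1, i.e.
#'   "1.6-fold" style).
#' @return List: `ref_label`, `alt_label`, `ref_fraction`, `alt_fraction`,
#'   `fold`, `fold_rounded`, `fold_undefined`, `p_value`.
#' @examples
#' allelic_skew(61, 39) # 61% vs 39% of reads: 1.6-fold
#' @export
allelic_skew <- function(ref_reads, alt_reads, ref_label = "ref",
                         alt_label = "alt", digits = 1) {
  stopifnot(ref_reads >= 0, alt_reads >= 0)
  total <- ref_reads + alt_reads
  if (total < 1) stop("need at least one read", call. = FALSE)
  rf <- ref_reads / total
  af <- alt_reads / total
  p <- binom.test(ref_reads, total, p = 0.5,
                  alternative = "two.sided")$p.value
  undef <- alt_reads == 0
  fold <- if (undef) NA_real_ else rf / af
  list(ref_label = ref_label, alt_label = alt_label,
       ref_fraction = rf, alt_fraction = af,
       fold = fold,
       fold_rounded = if (undef) NA_real_ else round(fold, digits),
       fold_undefined = undef, p_value = p)
}

#' Inverse-variance-weighted fixed-effect meta-analysis
#'
#' Pools per-study effect estimates (e.g. log odds ratios) with weights
#' `w_i = 1/se_i^2`: `beta_meta = sum(w_i beta_i) / sum(w_i)`,
#' `se_meta = 1/sqrt(sum(w_i))`, odds ratio `exp(beta_meta)` with a normal
#' 95% CI (`+/- 1.96 se`).
#'
#' @param beta Per-study effect estimates (log-OR scale).
#' @param se Per-study standard errors (all > 0).
#' @param labels Optional study labels.
#' @param level CI level (default 0.95).
#' @return List: `beta`, `se`, `or`, `or_ci`, `z`, `p_value`, `n_studies`.
#' @export
ivw_meta <- function(beta, se, labels = NULL, level = 0.95) {
  stopifnot(length(beta) == length(se), length(beta) >= 1)
  if (any(se <= 0)) stop("all standard errors must be positive", call. = FALSE)
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  zq <- qnorm(1 - (1 - level) / 2)
  z <- b / s
  list(beta = b, se = s, or = exp(b),
       or_ci = c(exp(b - zq * s), exp(b + zq * s)),
       z = z, p_value = 2 * pnorm(-abs(z)),
       n_studies = length(beta), labels = labels)
}
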