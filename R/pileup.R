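# Candidate-site discovery and filtering applied before statistical testing.
# Input is a long per-sample allele-count table (chrom, pos [1-based],
# strand, ref, alt, sample, group, k, n); filters only remove rows or sites,
# never alter k or n.

site_key <- function(df) paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")

#' Per-sample mismatch discovery
#'
#' Flags, for every row of a per-sample count table, whether the mismatch is
#' discovered in that sample: coverage at least `min_coverage` and minor
#' allele frequency `k/n` at least `min_maf`. Rows with zero coverage are
#' silently undiscovered.
#'
#' @param counts Long count table with columns `k` and `n`.
#' @param min_coverage Minimum per-sample coverage (default 10 reads).
#' @param min_maf Minimum per-sample minor allele frequency (default 0.01).
#' @return `counts` with a logical `discovered` column added.
#' @export
discover_sites <- function(counts, min_coverage = 10, min_maf = 0.01) {
  stopifnot(all(c("k", "n") %in% names(counts)))
  if (any(counts$k < 0 | counts$n < 0)) stop("negative counts", call. = FALSE)
  maf <- ifelse(counts$n > 0, counts$k / counts$n, 0)
  counts$discovered <- counts$n >= min_coverage & maf >= min_maf
  counts
}

#' Remove known germline variants
#'
#' Drops rows whose `(chrom, pos, alt)` key exactly matches a blacklist
#' entry (a dbSNP-style exclusion list); all other rows are untouched.
#'
#' @param sites Table with `chrom`, `pos`, `alt` columns (site-level or
#'   long per-sample).
#' @param blacklist Data.frame with `chrom`, `pos`, `alt` columns; may be
#'   empty.
#' @return `sites` without blacklisted rows.
#' @export
filter_known_variants <- function(sites, blacklist) {
  stopifnot(all(c("chrom", "pos", "alt") %in% names(sites)))
  if (is.null(blacklist) || nrow(blacklist) == 0) return(sites)
  stopifnot(all(c("chrom", "pos", "alt") %in% names(blacklist)))
  key <- paste(sites$chrom, sites$pos, sites$alt, sep = ":")
  bad <- paste(blacklist$chrom, blacklist$pos, blacklist$alt, sep = ":")
  out <- sites[!key %in% bad, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select candidate edit sites
#'
#' Applies the three candidacy rules to a discovered count table: a site is
#' retained iff (1) it passes per-sample discovery thresholds in at least
#' `min_treatment_samples` treatment samples; (2) its mismatch type is A>G
#' on the forward strand or T>C on the reverse strand; and (3) the reference
#' allele is the majority allele in pooled control reads (pooled control
#' `sum(k)/sum(n) < 0.5`; zero pooled control coverage fails candidacy
#' because the majority condition is unverifiable). Discovery thresholds are
#' applied to treatment samples only; control editing frequencies may be
#' below the discovery MAF by design.
#'
#' @param counts Long count table (all samples, both groups).
#' @param min_coverage,min_maf Per-sample discovery thresholds.
#' @param min_treatment_samples Minimum treatment samples in which the site
#'   must be discovered (default 2).
#' @return Site-level data.frame of candidates (chrom, pos, strand, ref,
#'   alt), ordered by position.
#' @export
select_candidates <- function(counts, min_coverage = 10, min_maf = 0.01,
                              min_treatment_samples = 2) {
  stopifnot(all(c("chrom", "pos", "strand", "ref", "alt",
                  "group", "k", "n") %in% names(counts)))
  stopifnot(all(counts$group %in% c("treatment", "control")))
  counts <- discover_sites(counts, min_coverage, min_maf)
  key <- site_key(counts)

  tr <- counts$group == "treatment"
  n_disc <- tapply(counts$discovered[tr], key[tr], sum)
  ctl <- counts[!tr, , drop = FALSE]
  ctl_key <- site_key(ctl)
  ctl_k <- tapply(ctl$k, ctl_key, sum)
  ctl_n <- tapply(ctl$n, ctl_key, sum)

  sites <- unique(counts[, c("chrom", "pos", "strand", "ref", "alt")])
  skey <- site_key(sites)
  disc_ok <- !is.na(n_disc[skey]) & n_disc[skey] >= min_treatment_samples
  allele_ok <- (sites$ref == "A" & sites$alt == "G" & sites$strand == "+") |
    (sites$ref == "T" & sites$alt == "C" & sites$strand == "-")
  ck <- ctl_k[skey]; cn <- ctl_n[skey]
  major_ok <- !is.na(cn) & cn > 0 & (ck / cn) < 0.5
  keep <- disc_ok & allele_ok & major_ok
  keep[is.na(keep)] <- FALSE
  out <- sites[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the per-candidate count matrix across all samples
#'
#' For every candidate site, emits one row per sample: `k = 0` where no
#' mismatch was observed in that sample, `n` equal to that sample's coverage
#' at the position (0 when the sample has no row at all). Rows with `n = 0`
#' are flagged `usable = FALSE` and excluded from model fitting; a candidate
#' with zero coverage in every sample of either group is dropped with a
#' warning.
#'
#' @param candidates Site-level table from [select_candidates()].
#' @param counts Long count table across all samples.
#' @return Long data.frame: one row per retained candidate x sample, with
#'   columns `k`, `n`, `group`, `usable`.
#' @export
assemble_count_matrix <- function(candidates, counts) {
  if (nrow(candidates) == 0) stop("candidate set is empty", call. = FALSE)
  samples <- unique(counts[, c("sample", "group")])
  ckey <- site_key(candidates)
  grid <- merge(cbind(candidates, .site = ckey), samples, by = NULL)
  obs_key <- paste(site_key(counts), counts$sample, sep = "@")
  m <- match(paste(grid$.site, grid$sample, sep = "@"), obs_key)
  grid$k <- ifelse(is.na(m), 0L, counts$k[m])
  grid$n <- ifelse(is.na(m), 0L, counts$n[m])
  grid$usable <- grid$n > 0

  cov_by_group <- tapply(grid$n, list(grid$.site, grid$group), sum)
  dead <- rownames(cov_by_group)[apply(cov_by_group == 0, 1, any)]
  if (length(dead)) {
    warning(sprintf("dropping %d candidate site(s) with zero coverage in an entire group: %s",
                    length(dead), paste(dead, collapse = ", ")))
    grid <- grid[!grid$.site %in% dead, , drop = FALSE]
  }
  grid <- grid[order(grid$chrom, grid$pos, grid$group, grid$sample), , drop = FALSE]
  grid$.site <- NULL
  rownames(grid) <- NULL
  grid
}
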