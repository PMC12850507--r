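# Gene-level integration: site-to-gene assignment, per-gene HyperTRIBE
# scores, rank-sum differential expression on a cells-by-genes matrix, and
# the threshold-defined regulatory network.

#' Assign retained edit sites to overlapping genes
#'
#' A site is assigned to every annotated gene whose interval contains its
#' position on the matching strand (a site inside two overlapping genes
#' contributes to both). Sites overlapping no gene are dropped with a
#' warning.
#'
#' @param sites Site table with `chrom`, `pos`, `strand` (plus any result
#'   columns, e.g. `diff_freq`).
#' @param annotation Annotation data.frame (gene_id, chrom, start, end,
#'   strand; 1-based inclusive).
#' @return `sites` rows replicated per overlapping gene, with a `gene_id`
#'   column.
#' @export
map_sites_to_genes <- function(sites, annotation) {
  if (nrow(sites) == 0)
    return(cbind(sites, gene_id = character(0)))
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos, sites$pos),
                                     strand = sites$strand)
  gr_genes <- GenomicRanges::GRanges(annotation$chrom,
                                     IRanges::IRanges(annotation$start,
                                                      annotation$end),
                                     strand = annotation$strand)
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes, ignore.strand = FALSE)
  unassigned <- setdiff(seq_len(nrow(sites)), S4Vectors::queryHits(hits))
  if (length(unassigned))
    warning(sprintf("%d site(s) overlap no annotated gene and were dropped",
                    length(unassigned)))
  out <- sites[S4Vectors::queryHits(hits), , drop = FALSE]
  out$gene_id <- annotation$gene_id[S4Vectors::subjectHits(hits)]
  rownames(out) <- NULL
  out
}

#' Per-gene HyperTRIBE scores
#'
#' The HyperTRIBE score of a gene is the sum of the differential editing
#' frequencies of its retained edit sites: a target edited at two
#' nucleotides in 50% and 70% of reads scores 1.2. Genes with no retained
#' sites are absent from the table (score 0 by convention).
#'
#' @param mapped_sites Output of [map_sites_to_genes()] on retained sites;
#'   must contain `gene_id` and `diff_freq`.
#' @return Data.frame: `gene_id`, `n_sites`, `score`, sorted by decreasing
#'   score.
#' @export
hypertribe_scores <- function(mapped_sites) {
  stopifnot(all(c("gene_id", "diff_freq") %in% names(mapped_sites)))
  if (nrow(mapped_sites) == 0)
    return(data.frame(gene_id = character(0), n_sites = integer(0),
                      score = numeric(0), stringsAsFactors = FALSE))
  score <- tapply(mapped_sites$diff_freq, mapped_sites$gene_id, sum)
  nsite <- tapply(mapped_sites$diff_freq, mapped_sites$gene_id, length)
  out <- data.frame(gene_id = names(score),
                    n_sites = as.integer(nsite),
                    score = as.numeric(score), stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank-sum differential expression between two cell groups
#'
#' Single-cell-style DE: counts are normalized to counts-per-10k and
#' log1p-transformed; genes expressed (count > 0) in at least `min_pct` of
#' cells in either group are tested with a two-sided Wilcoxon rank-sum test
#' on the normalized values; BH adjustment is computed over tested genes
#' only. Relative expression is the ratio of de-logged group means
#' (perturbed / control) with a pseudocount; genes whose
#' `|rel_expr - 1| < min_abs_change` are reported but flagged
#' non-significant.
#'
#' @param expr Genes-by-cells count matrix (dense or `dgCMatrix`), rownames
#'   = gene ids.
#' @param groups Character vector of group labels, one per column.
#' @param perturbed,control The two labels to compare.
#' @param min_pct Minimum fraction of expressing cells in at least one
#'   group (default 0.10).
#' @param min_abs_change Minimum absolute change in relative expression
#'   (default 0.05).
#' @param max_adj_p BH-adjusted significance threshold (default 0.05).
#' @param pseudocount Added to group means before the ratio (default 1e-9).
#' @return Data.frame: `gene_id`, `rel_expr`, `p_value`, `adj_p`,
#'   `pct_perturbed`, `pct_control`, `significant`.
#' @export
rank_sum_de <- function(expr, groups, perturbed = "perturbed",
                        control = "control", min_pct = 0.10,
                        min_abs_change = 0.05, max_adj_p = 0.05,
                        pseudocount = 1e-9) {
  stopifnot(ncol(expr) == length(groups))
  ip <- which(groups == perturbed); ic <- which(groups == control)
  if (length(ip) < 3 || length(ic) < 3)
    stop("need at least 3 cells per group", call. = FALSE)
  expr <- as.matrix(expr)
  if (is.null(rownames(expr)))
    rownames(expr) <- sprintf("gene%05d", seq_len(nrow(expr)))
  # counts-per-10k, log1p
  size <- pmax(colSums(expr), 1)
  norm <- log1p(sweep(expr, 2, 10000 / size, `*`))

  pct_p <- rowMeans(expr[, ip, drop = FALSE] > 0)
  pct_c <- rowMeans(expr[, ic, drop = FALSE] > 0)
  tested <- pmax(pct_p, pct_c) >= min_pct
  if (!any(tested)) {
    if (pseudocount == 0) stop("no testable genes", call. = FALSE)
    return(data.frame(gene_id = character(0), rel_expr = numeric(0),
                      p_value = numeric(0), adj_p = numeric(0),
                      pct_perturbed = numeric(0), pct_control = numeric(0),
                      significant = logical(0)))
  }
  mean_p <- rowMeans(expm1(norm[, ip, drop = FALSE]))
  mean_c <- rowMeans(expm1(norm[, ic, drop = FALSE]))
  if (pseudocount == 0 && any(mean_c[tested] == 0))
    stop("all-zero control group with zero pseudocount", call. = FALSE)
  rel <- (mean_p + pseudocount) / (mean_c + pseudocount)

  p <- rep(NA_real_, nrow(expr))
  for (g in which(tested)) {
    p[g] <- suppressWarnings(
      wilcox.test(norm[g, ip], norm[g, ic], alternative = "two.sided")$p.value)
  }
  adj <- rep(NA_real_, nrow(expr))
  adj[tested] <- p.adjust(p[tested], method = "BH")
  out <- data.frame(gene_id = rownames(expr)[tested],
                    rel_expr = rel[tested],
                    p_value = p[tested], adj_p = adj[tested],
                    pct_perturbed = pct_p[tested],
                    pct_control = pct_c[tested],
                    stringsAsFactors = FALSE)
  out$significant <- out$adj_p < max_adj_p &
    abs(out$rel_expr - 1) >= min_abs_change
  rownames(out) <- NULL
  out
}

#' Define the bound-and-downregulated network
#'
#' Intersects HyperTRIBE target scores with differential expression: a gene
#' enters the network iff its score is at least `min_score` (inclusive), its
#' relative expression is at most `max_rel` (inclusive) and its adjusted
#' p-value is strictly below `max_adj_p`.
#'
#' @param scores Output of [hypertribe_scores()].
#' @param de Output of [rank_sum_de()].
#' @param min_score Minimum HyperTRIBE score (default 0.2).
#' @param max_rel Maximum relative expression (default 0.95).
#' @param max_adj_p Adjusted p-value threshold (default 0.05, exclusive).
#' @return Data.frame: `gene_id`, `score`, `rel_expr`, `adj_p`.
#' @export
define_network <- function(scores, de, min_score = 0.2, max_rel = 0.95,
                           max_adj_p = 0.05) {
  m <- merge(scores[, c("gene_id", "score")],
             de[, c("gene_id", "rel_expr", "adj_p")], by = "gene_id")
  keep <- m$score >= min_score & m$rel_expr <= max_rel & m$adj_p < max_adj_p
  keep[is.na(keep)] <- FALSE
  out <- m[keep, , drop = FALSE]
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}
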