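# 3'UTR motif-window construction and k-mer enrichment: merged +/-100 bp
# windows around edit sites, length-matched background segments sampled from
# non-target 3'UTR space, and a one-sided binomial enrichment test per
# k-mer (lengths 6-8). All sequences are strand-oriented RNA (T -> U).

extract_rna <- function(genome, chrom, start, end, strand) {
  s <- Biostrings::subseq(genome[[chrom]], start = start, end = end)
  if (strand == "-") s <- Biostrings::reverseComplement(s)
  chartr("T", "U", as.character(s))
}

#' Build merged target windows around 3'UTR edit sites
#'
#' For each edit site inside an annotated 3'UTR, takes the interval
#' `[pos - flank, pos + flank]`, clips it to the containing UTR, merges
#' overlapping intervals, and extracts the strand-oriented RNA sequence
#' (reverse-complemented for minus-strand genes, T written as U). Sites
#' outside every UTR are skipped with a warning.
#'
#' @param sites Retained-site table with `chrom`, `pos`, `strand`.
#' @param annotation Annotation data.frame with `utr_start`, `utr_end`,
#'   `strand`, `gene_id`, `chrom`.
#' @param genome A [Biostrings::DNAStringSet].
#' @param flank Bases on each side of the site (default 100, so an interior
#'   single-site window spans 201 bp).
#' @return Data.frame (`role = "target"`): chrom, start, end, strand,
#'   gene_id, seq.
#' @export
build_windows <- function(sites, annotation, genome, flank = 100) {
  stopifnot(nrow(sites) > 0)
  gr_sites <- GenomicRanges::GRanges(sites$chrom,
                                     IRanges::IRanges(sites$pos, sites$pos),
                                     strand = sites$strand)
  gr_utr <- GenomicRanges::GRanges(annotation$chrom,
                                   IRanges::IRanges(annotation$utr_start,
                                                    annotation$utr_end),
                                   strand = annotation$strand)
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_utr, ignore.strand = FALSE)
  skipped <- setdiff(seq_len(nrow(sites)), S4Vectors::queryHits(hits))
  if (length(skipped))
    warning(sprintf("%d site(s) outside annotated 3'UTRs skipped",
                    length(skipped)))
  if (length(hits) == 0) stop("no sites fall inside annotated 3'UTRs",
                              call. = FALSE)
  qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
  win <- data.frame(chrom = sites$chrom[qi],
                    start = pmax(sites$pos[qi] - flank,
                                 annotation$utr_start[si]),
                    end = pmin(sites$pos[qi] + flank,
                               annotation$utr_end[si]),
                    strand = annotation$strand[si],
                    gene_id = annotation$gene_id[si],
                    stringsAsFactors = FALSE)
  merged <- do.call(rbind, lapply(split(win, win$gene_id), function(w) {
    red <- IRanges::reduce(IRanges::IRanges(w$start, w$end))
    data.frame(chrom = w$chrom[1], start = IRanges::start(red),
               end = IRanges::end(red), strand = w$strand[1],
               gene_id = w$gene_id[1], stringsAsFactors = FALSE)
  }))
  merged <- merged[order(merged$chrom, merged$start), , drop = FALSE]
  merged$seq <- vapply(seq_len(nrow(merged)), function(i)
    extract_rna(genome, merged$chrom[i], merged$start[i], merged$end[i],
                merged$strand[i]), character(1))
  merged$role <- "target"
  rownames(merged) <- NULL
  merged
}

#' Sample length-matched background segments from 3'UTRs
#'
#' Draws `n_segments` fixed-width (default 201 bp) segments uniformly from
#' the annotated 3'UTR space, rejecting any draw that overlaps a target
#' window; UTRs shorter than the segment width are never sampled. Seeded
#' and reproducible; errors if the rejection budget (10 x `n_segments`
#' rejections) is exhausted.
#'
#' @param annotation Annotation data.frame (as in [build_windows()]).
#' @param genome A [Biostrings::DNAStringSet].
#' @param targets Target window set from [build_windows()].
#' @param n_segments Number of background segments.
#' @param seed Integer seed.
#' @param width Segment width (default 201 bp, matching a single-site
#'   window).
#' @return Data.frame (`role = "background"`) with the same columns as the
#'   target set.
#' @export
sample_background <- function(annotation, genome, targets, n_segments,
                              seed, width = 201) {
  set.seed(seed)
  avail <- annotation$utr_end - annotation$utr_start + 1L - width + 1L
  ok <- which(avail > 0)
  if (!length(ok)) stop("no 3'UTR is long enough for background segments",
                        call. = FALSE)
  t_rng <- IRanges::IRanges(targets$start, targets$end)
  out <- vector("list", n_segments)
  got <- 0L; rejected <- 0L
  while (got < n_segments) {
    if (rejected > 10 * n_segments)
      stop(sprintf(paste0("could not place %d background segments: %d draws ",
                          "rejected for target overlap; only %d placed"),
                   n_segments, rejected, got), call. = FALSE)
    gi <- ok[sample.int(length(ok), 1L, prob = avail[ok])]
    s <- annotation$utr_start[gi] + sample.int(avail[gi], 1L) - 1L
    seg <- IRanges::IRanges(s, s + width - 1L)
    if (length(IRanges::findOverlaps(seg, t_rng)) > 0) {
      rejected <- rejected + 1L
      next
    }
    got <- got + 1L
    out[[got]] <- data.frame(chrom = annotation$chrom[gi], start = s,
                             end = s + width - 1L,
                             strand = annotation$strand[gi],
                             gene_id = annotation$gene_id[gi],
                             stringsAsFactors = FALSE)
  }
  bg <- do.call(rbind, out)
  bg$seq <- vapply(seq_len(nrow(bg)), function(i)
    extract_rna(genome, bg$chrom[i], bg$start[i], bg$end[i], bg$strand[i]),
    character(1))
  bg$role <- "background"
  rownames(bg) <- NULL
  bg
}

count_kmers <- function(seqs, k) {
  rs <- Biostrings::RNAStringSet(seqs)
  freq <- Biostrings::oligonucleotideFrequency(rs, width = k)
  colSums(freq)
}

#' K-mer enrichment of target windows against background
#'
#' Counts all (overlapping) k-mer occurrences in the target and background
#' window sets, converts them to per-base occurrence rates, and tests each
#' observed k-mer's target count against the background rate with a
#' one-sided binomial upper tail. A pseudocount of 1 on the background
#' count keeps p-values finite for k-mers absent from the background.
#' BH adjustment is applied separately within each k-mer length.
#'
#' @param targets,background Window sets from [build_windows()] /
#'   [sample_background()], or character vectors of RNA sequences.
#' @param k Integer vector of k-mer lengths (default `c(6, 7, 8)`).
#' @param pseudocount Added to background counts (default 1).
#' @return Data.frame: `kmer`, `k`, `target_count`, `background_count`,
#'   `enrichment`, `p_value`, `adj_p`, sorted by `k` then `p_value`.
#' @export
kmer_enrichment <- function(targets, background, k = c(6L, 7L, 8L),
                            pseudocount = 1) {
  tseq <- if (is.data.frame(targets)) targets$seq else targets
  bseq <- if (is.data.frame(background)) background$seq else background
  stopifnot(length(tseq) > 0, length(bseq) > 0)
  res <- lapply(k, function(kk) {
    tc <- count_kmers(tseq, kk)
    bc <- count_kmers(bseq, kk)
    tp <- sum(pmax(nchar(tseq) - kk + 1L, 0L))
    bp <- sum(pmax(nchar(bseq) - kk + 1L, 0L))
    obs <- tc > 0 | bc > 0
    rate_bg <- pmin((bc[obs] + pseudocount) / bp, 1)
    p <- pbinom(tc[obs] - 1, tp, rate_bg, lower.tail = FALSE)
    data.frame(kmer = names(tc)[obs], k = kk,
               target_count = as.integer(tc[obs]),
               background_count = as.integer(bc[obs]),
               enrichment = (tc[obs] / tp) / rate_bg,
               p_value = p, adj_p = p.adjust(p, method = "BH"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$k, out$p_value, -out$enrichment), , drop = FALSE]
  rownames(out) <- NULL
  out
}
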