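# Format readers and writers: TSV with '#' provenance comments, BED
# (0-based half-open) for the gene/3'UTR annotation, FASTA via Biostrings,
# a minimal VCF-like dialect with per-sample k:n counts, and expression
# matrices (matrix-market triplet or dense TSV). Site tables are 1-based
# inclusive (VCF convention); BED is 0-based half-open.

#' Write a table as TSV with provenance comment lines
#'
#' @param df Data.frame.
#' @param path Output path.
#' @param provenance Character vector written as leading `#` comment lines.
#' @export
write_tsv <- function(df, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(paste0("# ", provenance), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()] (skipping `#` comment lines)
#' @param path Input path.
#' @return Data.frame.
#' @export
read_tsv <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write the gene/3'UTR annotation as BED (0-based half-open)
#'
#' Emits one BED6 line per feature: `<gene_id>|gene` for the gene interval
#' and `<gene_id>|utr3` for its 3'UTR.
#'
#' @param annotation Annotation data.frame (1-based inclusive columns).
#' @param path Output path.
#' @export
write_annotation_bed <- function(annotation, path) {
  bed <- rbind(
    data.frame(chrom = annotation$chrom, start = annotation$start - 1L,
               end = annotation$end,
               name = paste0(annotation$gene_id, "|gene"),
               score = 0L, strand = annotation$strand),
    data.frame(chrom = annotation$chrom, start = annotation$utr_start - 1L,
               end = annotation$utr_end,
               name = paste0(annotation$gene_id, "|utr3"),
               score = 0L, strand = annotation$strand))
  bed <- bed[order(bed$chrom, bed$start), ]
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an annotation BED written by [write_annotation_bed()]
#' @param path BED path.
#' @return Annotation data.frame (1-based inclusive).
#' @export
read_annotation_bed <- function(path) {
  bed <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                    col.names = c("chrom", "start", "end", "name",
                                  "score", "strand"))
  parts <- strsplit(bed$name, "|", fixed = TRUE)
  bed$gene_id <- vapply(parts, `[`, character(1), 1L)
  bed$feature <- vapply(parts, `[`, character(1), 2L)
  genes <- bed[bed$feature == "gene", ]
  utrs <- bed[bed$feature == "utr3", ]
  m <- match(genes$gene_id, utrs$gene_id)
  data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
             start = genes$start + 1L, end = genes$end,
             strand = genes$strand,
             utr_start = utrs$start[m] + 1L, utr_end = utrs$end[m],
             stringsAsFactors = FALSE)
}

#' Write sequences as FASTA
#' @param seqs A [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet")) {
    stopifnot(!is.null(names(seqs)))
    seqs <- Biostrings::DNAStringSet(seqs)
  }
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a FASTA file
#' @param path FASTA path.
#' @return A [Biostrings::DNAStringSet].
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Read a minimal VCF-like site-count file
#'
#' Dialect: `##SAMPLE=<ID=name,GROUP=treatment|control>` header lines, a
#' `#CHROM POS ID REF ALT` header row, then one column per sample holding
#' `k:n` (edited count : coverage). Returns the long count table used
#' throughout the pipeline; strand is `NA` until assigned from annotation
#' with [assign_strand_from_annotation()].
#'
#' @param path Input path.
#' @return Long count data.frame (chrom, pos, strand, ref, alt, sample,
#'   group, k, n).
#' @export
read_site_counts_vcf <- function(path) {
  lines <- readLines(path)
  meta <- grep("^##", lines, value = TRUE)
  sm <- regmatches(meta,
                   regexec("^##SAMPLE=<ID=([^,>]+),GROUP=([^,>]+)>", meta))
  sm <- Filter(function(x) length(x) == 3, sm)
  groups <- setNames(vapply(sm, `[`, character(1), 3L),
                     vapply(sm, `[`, character(1), 2L))
  body <- lines[!grepl("^##", lines)]
  hdr <- strsplit(sub("^#", "", body[1]), "\t")[[1]]
  tab <- read.delim(text = paste(body[-1], collapse = "\n"), header = FALSE,
                    col.names = hdr, stringsAsFactors = FALSE)
  samples <- setdiff(hdr, c("CHROM", "POS", "ID", "REF", "ALT"))
  if (!all(samples %in% names(groups)))
    stop("VCF sample columns missing ##SAMPLE group declarations: ",
         paste(setdiff(samples, names(groups)), collapse = ", "),
         call. = FALSE)
  long <- do.call(rbind, lapply(samples, function(s) {
    kn <- strsplit(tab[[s]], ":", fixed = TRUE)
    data.frame(chrom = tab$CHROM, pos = tab$POS, strand = NA_character_,
               ref = tab$REF, alt = tab$ALT, sample = s,
               group = unname(groups[s]),
               k = as.integer(vapply(kn, `[`, character(1), 1L)),
               n = as.integer(vapply(kn, `[`, character(1), 2L)),
               stringsAsFactors = FALSE)
  }))
  rownames(long) <- NULL
  long
}

#' Assign strand to sites from the overlapping gene annotation
#'
#' Sets each site's strand to that of its overlapping annotated gene;
#' intergenic sites (no overlapping gene) are dropped with a warning, since
#' candidacy requires gene annotation.
#'
#' @param counts Long count table (strand may be `NA`).
#' @param annotation Annotation data.frame.
#' @return `counts` with `strand` filled in; intergenic rows removed.
#' @export
assign_strand_from_annotation <- function(counts, annotation) {
  gr_sites <- GenomicRanges::GRanges(counts$chrom,
                                     IRanges::IRanges(counts$pos, counts$pos))
  gr_genes <- GenomicRanges::GRanges(annotation$chrom,
                                     IRanges::IRanges(annotation$start,
                                                      annotation$end))
  hits <- GenomicRanges::findOverlaps(gr_sites, gr_genes, select = "first")
  drop <- is.na(hits)
  if (any(drop))
    warning(sprintf("%d intergenic row(s) dropped before candidacy",
                    sum(drop)))
  counts$strand <- annotation$strand[hits]
  out <- counts[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read an expression matrix (matrix-market triplet or dense TSV)
#'
#' @param path `.mtx` file (with optional sidecar `<path>.genes` /
#'   `<path>.cells` name files, one id per line) or a dense TSV with gene
#'   ids in the first column.
#' @return A genes-by-cells numeric matrix.
#' @export
read_expression_matrix <- function(path) {
  if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    gf <- paste0(path, ".genes"); cf <- paste0(path, ".cells")
    if (file.exists(gf)) rownames(m) <- readLines(gf)
    if (file.exists(cf)) colnames(m) <- readLines(cf)
    m
  } else {
    tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    m
  }
}
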