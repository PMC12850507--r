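# Seeded synthetic-data generators: gene/3'UTR annotation with sequence,
# ADAR-fusion editing experiments (treatment vs empty-vector control), and
# serial-VAF clonal-hematopoiesis cohorts. Every generator returns a
# ground-truth table alongside the data so downstream recovery is testable.

#' Configuration for the synthetic editing experiment
#'
#' Holds the simulation parameters for [generate_editing_dataset()]: a
#' 3-vs-3 ADAR-fusion design in which true edit sites are A>G mismatches on
#' the forward strand (or T>C on the reverse strand) inside annotated 3'UTRs,
#' plus SNP-like contaminants and background mismatch noise.
#'
#' @param seed Integer seed; identical seeds give byte-identical output.
#' @param n_treatment,n_control Samples per group (default 3 + 3).
#' @param n_sites Total simulated mismatch sites.
#' @param frac_true_edits Fraction of sites that are genuinely edited in the
#'   treatment group.
#' @param coverage_mean,coverage_dispersion Mean and negative-binomial
#'   dispersion of per-site per-sample coverage (`size = 1/dispersion`),
#'   truncated below at 1 read.
#' @param edit_freq_range Length-2 range from which each true site's
#'   treatment editing frequency is drawn uniformly.
#' @param control_noise_freq Background mismatch rate at unedited sites and
#'   in control samples (default 0.005).
#' @param frac_snp_contaminants Fraction of sites mimicking germline SNPs:
#'   group-independent alt fraction ~0.5 (het) or ~1.0 (hom) in all samples.
#' @param frac_wrong_strand Fraction of sites carrying a treatment-high
#'   mismatch of a type (C>T on forward strand) that the strand/major-allele
#'   rule must reject.
#' @return A validated list of class `edit_sim_config`.
#' @export
edit_sim_config <- function(seed,
                            n_treatment = 3L, n_control = 3L,
                            n_sites = 200L,
                            frac_true_edits = 0.25,
                            coverage_mean = 200,
                            coverage_dispersion = 0.5,
                            edit_freq_range = c(0.2, 0.7),
                            control_noise_freq = 0.005,
                            frac_snp_contaminants = 0.05,
                            frac_wrong_strand = 0.05) {
  check_range(seed, "seed")
  check_range(n_treatment, "n_treatment", lo = 1)
  check_range(n_control, "n_control", lo = 1)
  check_range(n_sites, "n_sites", lo = 1)
  check_range(frac_true_edits, "frac_true_edits", 0, 1)
  check_range(coverage_mean, "coverage_mean", lo = 10)
  check_range(coverage_dispersion, "coverage_dispersion", lo = 0, lo_open = TRUE)
  stopifnot(length(edit_freq_range) == 2L)
  check_range(edit_freq_range, "edit_freq_range", 0, 1)
  check_range(control_noise_freq, "control_noise_freq", 0, 1)
  check_range(frac_snp_contaminants, "frac_snp_contaminants", 0, 1)
  check_range(frac_wrong_strand, "frac_wrong_strand", 0, 1)
  if (frac_true_edits + frac_snp_contaminants + frac_wrong_strand > 1)
    stop("site-class fractions sum to more than 1", call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_treatment = as.integer(n_treatment),
                 n_control = as.integer(n_control),
                 n_sites = as.integer(n_sites),
                 frac_true_edits = frac_true_edits,
                 coverage_mean = coverage_mean,
                 coverage_dispersion = coverage_dispersion,
                 edit_freq_range = edit_freq_range,
                 control_noise_freq = control_noise_freq,
                 frac_snp_contaminants = frac_snp_contaminants,
                 frac_wrong_strand = frac_wrong_strand),
            class = "edit_sim_config")
}

#' Configuration for the synthetic serial-VAF cohort
#'
#' Parameters for [generate_cohort()]: each person carries one CHIP driver
#' mutation observed in two blood draws. The latent clone grows at a
#' per-year rate `r = mean_growth_noncarrier + dosage * genotype_effect +
#' noise`; observed VAFs are binomial resamples at the sequencing depth.
#'
#' Defaults describe a biobank-style serial-sequencing cohort: 3,000 people,
#' ~1,700x error-corrected depth, draws 0.7-13 years apart, a slightly
#' positive median clonal growth for non-carriers and a protective allele
#' that lowers growth by ~0.4 percentage points per year.
#'
#' @param seed Integer seed.
#' @param n_people Cohort size.
#' @param carrier_freq Heterozygote frequency of the protective allele
#'   (dosage 1 vs 0).
#' @param baseline_vaf_dist List `(shape1, shape2, lo, hi)`: baseline VAFs
#'   are `lo + (hi-lo) * Beta(shape1, shape2)`.
#' @param mean_growth_noncarrier Mean per-year growth rate, non-carriers.
#' @param genotype_effect Additive per-allele shift in growth rate per year
#'   (negative = protective).
#' @param residual_sd Person-level SD of the growth rate (per year).
#' @param dt_range Length-2 range (years) for the inter-draw interval.
#' @param depth_mean Mean sequencing depth per draw (must allow depth >= 100).
#' @param driver_genes Named numeric vector of driver-gene sampling weights.
#' @return A validated list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(seed,
                              n_people = 3000L,
                              carrier_freq = 0.13,
                              baseline_vaf_dist = list(shape1 = 1, shape2 = 6,
                                                       lo = 0.02, hi = 0.40),
                              mean_growth_noncarrier = 0.0012,
                              genotype_effect = -0.0043,
                              residual_sd = 0.20,
                              dt_range = c(0.7, 13),
                              depth_mean = 1725,
                              driver_genes = c(DNMT3A = 0.55, TET2 = 0.25,
                                               ASXL1 = 0.10, other = 0.10)) {
  check_range(seed, "seed")
  check_range(n_people, "n_people", lo = 1)
  check_range(carrier_freq, "carrier_freq", 0, 1)
  stopifnot(is.list(baseline_vaf_dist),
            all(c("shape1", "shape2", "lo", "hi") %in% names(baseline_vaf_dist)))
  check_range(baseline_vaf_dist$lo, "baseline_vaf_dist$lo", 0, 1, TRUE, TRUE)
  check_range(baseline_vaf_dist$hi, "baseline_vaf_dist$hi",
              baseline_vaf_dist$lo, 1, TRUE, TRUE)
  check_range(residual_sd, "residual_sd", lo = 0)
  stopifnot(length(dt_range) == 2L)
  check_range(dt_range, "dt_range", lo = 0, lo_open = TRUE)
  check_range(depth_mean, "depth_mean", lo = 100)
  if (is.null(names(driver_genes)) || any(driver_genes < 0))
    stop("driver_genes must be a named non-negative weight vector", call. = FALSE)
  structure(list(seed = as.integer(seed), n_people = as.integer(n_people),
                 carrier_freq = carrier_freq,
                 baseline_vaf_dist = baseline_vaf_dist,
                 mean_growth_noncarrier = mean_growth_noncarrier,
                 genotype_effect = genotype_effect,
                 residual_sd = residual_sd,
                 dt_range = dt_range, depth_mean = depth_mean,
                 driver_genes = driver_genes),
            class = "cohort_sim_config")
}

#' Generate a synthetic gene/3'UTR annotation with sequence
#'
#' Lays out non-overlapping genes on a single synthetic chromosome, each with
#' one 3'UTR interval at its downstream end (strand-aware), over a
#' random-nucleotide sequence. Coordinates are 1-based inclusive in the
#' returned table; [write_annotation_bed()] emits 0-based half-open BED.
#'
#' @param seed Integer seed.
#' @param n_genes Number of genes.
#' @param utr_len_range Length-2 range of 3'UTR lengths (bp).
#' @param gene_len_range Length-2 range of gene lengths (bp); must admit the
#'   UTR.
#' @param intergenic_gap Gap between consecutive genes (bp).
#' @param motif,motif_positions Optionally overwrite the sequence with
#'   `motif` at each 1-based chromosome position in `motif_positions`
#'   (forward strand, as written).
#' @return List with `annotation` (data.frame: gene_id, chrom, start, end,
#'   strand, utr_start, utr_end) and `genome` (a [Biostrings::DNAStringSet]).
#' @export
generate_annotation <- function(seed, n_genes = 50L,
                                utr_len_range = c(300L, 1200L),
                                gene_len_range = c(2000L, 4000L),
                                intergenic_gap = 500L,
                                motif = NULL, motif_positions = NULL) {
  check_range(utr_len_range, "utr_len_range", lo = 1)
  check_range(gene_len_range, "gene_len_range", lo = max(utr_len_range))
  check_range(n_genes, "n_genes", lo = 1)
  set.seed(seed)
  gene_len <- sample(gene_len_range[1]:gene_len_range[2], n_genes, replace = TRUE)
  utr_len <- sample(utr_len_range[1]:utr_len_range[2], n_genes, replace = TRUE)
  strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  start <- intergenic_gap + c(0L, cumsum(gene_len[-n_genes] + intergenic_gap)) + 1L
  end <- start + gene_len - 1L
  # 3'UTR sits at the transcriptional end: right edge for +, left edge for -
  utr_start <- ifelse(strand == "+", end - utr_len + 1L, start)
  utr_end <- ifelse(strand == "+", end, start + utr_len - 1L)
  ann <- data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                    chrom = "chrSim",
                    start = start, end = end, strand = strand,
                    utr_start = as.integer(utr_start),
                    utr_end = as.integer(utr_end),
                    stringsAsFactors = FALSE)
  chrom_len <- max(end) + intergenic_gap
  seq_chars <- sample(c("A", "C", "G", "T"), chrom_len, replace = TRUE)
  if (!is.null(motif)) {
    stopifnot(!is.null(motif_positions))
    for (p in motif_positions) {
      stopifnot(p >= 1, p + nchar(motif) - 1 <= chrom_len)
      seq_chars[p:(p + nchar(motif) - 1L)] <- strsplit(motif, "")[[1]]
    }
  }
  genome <- Biostrings::DNAStringSet(paste(seq_chars, collapse = ""))
  names(genome) <- "chrSim"
  list(annotation = ann, genome = genome)
}

# Draw per-site per-sample coverage: NB(mean, dispersion) truncated at >= 1.
rcoverage <- function(n, mean, dispersion) {
  x <- rnbinom(n, mu = mean, size = 1 / dispersion)
  x[x < 1L] <- 1L
  x
}

#' Simulate an ADAR-fusion editing experiment
#'
#' Draws per-site per-sample coverage from an overdispersed count
#' distribution and edited counts binomially from each group's true
#' frequency. True edit sites are A>G on forward-strand genes or T>C on
#' reverse-strand genes within annotated 3'UTRs; SNP-like contaminants show
#' a high group-independent alt fraction; wrong-strand contaminants carry a
#' treatment-specific mismatch of a type the strand rule must reject. The
#' genome sequence is updated so reference bases at simulated sites match
#' their mismatch type.
#'
#' @param config An [edit_sim_config()].
#' @param annotation Output of [generate_annotation()] (list with
#'   `annotation` and `genome`), or just the annotation data.frame plus a
#'   `genome` argument.
#' @param genome Optional [Biostrings::DNAStringSet] when `annotation` is a
#'   plain data.frame.
#' @return List with `counts` (long data.frame: chrom, pos, strand, ref,
#'   alt, sample, group, k, n), `truth` (per-site truth table) and `genome`
#'   (sequence with site reference bases applied).
#' @export
generate_editing_dataset <- function(config, annotation, genome = NULL) {
  stopifnot(inherits(config, "edit_sim_config"))
  if (is.list(annotation) && !is.data.frame(annotation)) {
    genome <- annotation$genome
    annotation <- annotation$annotation
  }
  stopifnot(is.data.frame(annotation), nrow(annotation) > 0, !is.null(genome))
  set.seed(config$seed)

  utr_pos <- unlist(lapply(seq_len(nrow(annotation)), function(i)
    annotation$utr_start[i]:annotation$utr_end[i]))
  utr_gene <- rep(annotation$gene_id, annotation$utr_end - annotation$utr_start + 1L)
  utr_strand <- rep(annotation$strand, annotation$utr_end - annotation$utr_start + 1L)
  if (config$n_sites > length(utr_pos))
    stop(sprintf("n_sites (%d) exceeds available 3'UTR positions (%d)",
                 config$n_sites, length(utr_pos)), call. = FALSE)

  idx <- sample.int(length(utr_pos), config$n_sites)
  n_true <- round(config$n_sites * config$frac_true_edits)
  n_snp <- round(config$n_sites * config$frac_snp_contaminants)
  n_wrong <- round(config$n_sites * config$frac_wrong_strand)
  class <- rep("noise", config$n_sites)
  if (n_true > 0) class[seq_len(n_true)] <- "true_edit"
  if (n_snp > 0) class[n_true + seq_len(n_snp)] <- "snp"
  if (n_wrong > 0) class[n_true + n_snp + seq_len(n_wrong)] <- "wrong_strand"

  pos <- utr_pos[idx]
  gene <- utr_gene[idx]
  strand <- utr_strand[idx]
  # mismatch type by class: edit chemistry A>G (+) / T>C (-); wrong-strand
  # contaminants are C>T on the forward genomic strand
  ref <- ifelse(strand == "+", "A", "T")
  alt <- ifelse(strand == "+", "G", "C")
  ref[class == "wrong_strand"] <- "C"
  alt[class == "wrong_strand"] <- "T"

  freq_t <- rep(config$control_noise_freq, config$n_sites)
  freq_c <- rep(config$control_noise_freq, config$n_sites)
  is_true <- class == "true_edit"
  freq_t[is_true] <- runif(sum(is_true), config$edit_freq_range[1],
                           config$edit_freq_range[2])
  wrong <- class == "wrong_strand"
  freq_t[wrong] <- runif(sum(wrong), config$edit_freq_range[1],
                         config$edit_freq_range[2])
  snp <- class == "snp"
  snp_frac <- sample(c(0.5, 1.0), sum(snp), replace = TRUE)
  freq_t[snp] <- snp_frac
  freq_c[snp] <- snp_frac

  samples <- c(sprintf("treatment_%d", seq_len(config$n_treatment)),
               sprintf("control_%d", seq_len(config$n_control)))
  groups <- rep(c("treatment", "control"),
                c(config$n_treatment, config$n_control))
  n_samp <- length(samples)

  counts <- do.call(rbind, lapply(seq_len(n_samp), function(j) {
    cov <- rcoverage(config$n_sites, config$coverage_mean,
                     config$coverage_dispersion)
    f <- if (groups[j] == "treatment") freq_t else freq_c
    data.frame(chrom = "chrSim", pos = pos, strand = strand,
               ref = ref, alt = alt,
               sample = samples[j], group = groups[j],
               k = rbinom(config$n_sites, cov, f), n = cov,
               stringsAsFactors = FALSE)
  }))
  ord <- order(counts$pos, match(counts$sample, samples))
  counts <- counts[ord, , drop = FALSE]
  rownames(counts) <- NULL

  truth <- data.frame(chrom = "chrSim", pos = pos, strand = strand,
                      ref = ref, alt = alt, gene_id = gene,
                      class = class,
                      is_true_edit = is_true, is_snp = snp,
                      true_freq_treatment = freq_t,
                      true_freq_control = freq_c,
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$pos), , drop = FALSE]
  rownames(truth) <- NULL

  # force the genome reference base at each simulated site
  gseq <- strsplit(as.character(genome[["chrSim"]]), "")[[1]]
  gseq[pos] <- ref
  genome2 <- Biostrings::DNAStringSet(paste(gseq, collapse = ""))
  names(genome2) <- "chrSim"

  list(counts = counts, truth = truth, genome = genome2)
}

#' Simulate a serial-sample CHIP cohort
#'
#' Each person carries one driver mutation with baseline VAF drawn from a
#' scaled Beta distribution, a genotype-dependent latent per-year growth
#' rate, and two blood draws `dt` years apart. The second latent VAF follows
#' the compound-interest law `VAF2 = VAF1 * (1 + r)^dt`, clipped to (0, 1);
#' observed VAFs at both draws are binomial resamples of the latent VAFs at
#' the drawn sequencing depths, with depths and alt-read counts emitted so
#' that calling thresholds can act downstream.
#'
#' @param config A [cohort_sim_config()].
#' @return List with `cohort` (data.frame: id, age, sex, genotype, gene,
#'   vaf1, depth1, alt1, vaf2, depth2, alt2, dt_years) and `truth`
#'   (per-person true growth rate, genotype and latent VAFs).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  n <- config$n_people
  # age and sex independent of genotype: known-null confounding structure
  age <- round(pmin(pmax(rnorm(n, 65, 10), 40), 90))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  genotype <- rbinom(n, 1L, config$carrier_freq)
  gene <- sample(names(config$driver_genes), n, replace = TRUE,
                 prob = config$driver_genes)
  bv <- config$baseline_vaf_dist
  vaf1_true <- bv$lo + (bv$hi - bv$lo) * rbeta(n, bv$shape1, bv$shape2)
  r_true <- config$mean_growth_noncarrier +
    genotype * config$genotype_effect +
    rnorm(n, 0, config$residual_sd)
  # a clone cannot lose more than all of itself in a year
  r_true <- pmax(r_true, -0.99)
  dt <- runif(n, config$dt_range[1], config$dt_range[2])
  vaf2_true <- pmin(pmax(vaf1_true * (1 + r_true)^dt, 1e-8), 1 - 1e-8)

  depth1 <- rcoverage(n, config$depth_mean, 0.05)
  depth2 <- rcoverage(n, config$depth_mean, 0.05)
  if (any(depth1 < 0) || any(depth2 < 0)) stop("negative depths", call. = FALSE)
  alt1 <- rbinom(n, depth1, vaf1_true)
  alt2 <- rbinom(n, depth2, vaf2_true)

  cohort <- data.frame(id = sprintf("P%05d", seq_len(n)),
                       age = age, sex = sex, genotype = genotype,
                       gene = gene,
                       vaf1 = alt1 / depth1, depth1 = depth1, alt1 = alt1,
                       vaf2 = alt2 / depth2, depth2 = depth2, alt2 = alt2,
                       dt_years = dt, stringsAsFactors = FALSE)
  truth <- data.frame(id = cohort$id, genotype = genotype,
                      true_r = r_true,
                      true_vaf1 = vaf1_true, true_vaf2 = vaf2_true,
                      stringsAsFactors = FALSE)
  list(cohort = cohort, truth = truth)
}

#' Simulate a two-group single-cell-style expression matrix
#'
#' Draws per-gene baseline means from a log-normal distribution and counts
#' from a negative binomial per cell; genes named in `target_genes` have
#' their mean multiplied by `effect` in the perturbed group (e.g. 0.8 for a
#' 20% down-regulation). No batch or library-size structure beyond
#' cell-level NB noise is simulated.
#'
#' @param seed Integer seed.
#' @param gene_ids Character vector of gene ids (rows).
#' @param target_genes Genes down- (or up-)regulated in the perturbed group.
#' @param n_cells_per_group Cells per group (default 100).
#' @param effect Multiplicative effect on target-gene means in the
#'   perturbed group (default 0.8).
#' @param mean_log Mean/sd of log base-mean (defaults give per-gene means
#'   ~10-100 counts, i.e. the well-captured stratum DE gates act on).
#' @param dispersion NB dispersion (size = 1/dispersion, default 0.05).
#' @return List: `expr` (genes x cells count matrix), `groups` (column
#'   labels "perturbed"/"control"), `truth` (gene_id, is_target).
#' @export
generate_expression <- function(seed, gene_ids, target_genes = character(0),
                                n_cells_per_group = 100L, effect = 0.8,
                                mean_log = c(3.5, 0.6), dispersion = 0.05) {
  set.seed(seed)
  ng <- length(gene_ids)
  base <- rlnorm(ng, mean_log[1], mean_log[2])
  is_target <- gene_ids %in% target_genes
  groups <- rep(c("perturbed", "control"), each = n_cells_per_group)
  mu <- cbind(matrix(base * ifelse(is_target, effect, 1), ng,
                     n_cells_per_group),
              matrix(base, ng, n_cells_per_group))
  expr <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                 nrow = ng,
                 dimnames = list(gene_ids,
                                 sprintf("cell%03d", seq_along(groups))))
  list(expr = expr, groups = groups,
       truth = data.frame(gene_id = gene_ids, is_target = is_target,
                          stringsAsFactors = FALSE))
}
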