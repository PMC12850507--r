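# Pipeline configuration and the end-to-end driver binding the stages:
# simulate -> filter -> model -> score -> network; simulate-cohort ->
# classify -> fit; motif; assoc. Every run writes its artifacts, a resolved
# copy of the configuration, and a JSON manifest with per-artifact row
# counts and truth-recovery summaries.

#' Build and validate a pipeline configuration
#'
#' Collects every stage threshold (defaulting to the values the analysis is
#' defined with), the seed, and the synthetic-data settings. Invalid values
#' raise an error naming the offending field.
#'
#' @param seed Integer seed driving all simulation stages.
#' @param out_dir Output directory.
#' @param stages Stages to run, a subset of
#'   `c("editing", "motif", "cohort", "assoc")`.
#' @param min_coverage,min_maf Per-sample discovery thresholds (10 reads,
#'   MAF 0.01).
#' @param min_treatment_samples Treatment samples a candidate must be
#'   discovered in (2).
#' @param min_diff,max_control_freq,max_fdr Edit-site retention criteria
#'   (0.1, 0.02, 0.05).
#' @param min_score,max_rel,max_adj_p Network thresholds (0.2, 0.95, 0.05).
#' @param min_depth,min_alt,min_vaf CHIP calling thresholds (100x, 3 reads,
#'   VAF 0.02).
#' @param flank,background_width,kmer_lengths Motif-window settings
#'   (+/-100 bp, 201 bp, lengths 6/7/8).
#' @param n_background Background segments for motif enrichment (default
#'   200).
#' @param edit_sim,cohort_sim Optional lists of overrides passed to
#'   [edit_sim_config()] / [cohort_sim_config()].
#' @param n_genes Genes in the synthetic annotation (default 50).
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, out_dir,
                            stages = c("editing", "motif", "cohort", "assoc"),
                            min_coverage = 10, min_maf = 0.01,
                            min_treatment_samples = 2,
                            min_diff = 0.1, max_control_freq = 0.02,
                            max_fdr = 0.05,
                            min_score = 0.2, max_rel = 0.95,
                            max_adj_p = 0.05,
                            min_depth = 100, min_alt = 3, min_vaf = 0.02,
                            flank = 100, background_width = 201,
                            kmer_lengths = c(6L, 7L, 8L),
                            n_background = 200L,
                            edit_sim = list(), cohort_sim = list(),
                            n_genes = 50L) {
  stopifnot(all(stages %in% c("editing", "motif", "cohort", "assoc")))
  check_range(seed, "seed")
  check_range(min_coverage, "min_coverage", lo = 1)
  check_range(min_maf, "min_maf", 0, 1)
  check_range(min_treatment_samples, "min_treatment_samples", lo = 1)
  check_range(min_diff, "min_diff", 0, 1)
  check_range(max_control_freq, "max_control_freq", 0, 1)
  check_range(max_fdr, "max_fdr", 0, 1)
  check_range(min_score, "min_score", lo = 0)
  check_range(max_rel, "max_rel", lo = 0)
  check_range(max_adj_p, "max_adj_p", 0, 1)
  check_range(min_depth, "min_depth", lo = 1)
  check_range(min_alt, "min_alt", lo = 0)
  check_range(min_vaf, "min_vaf", 0, 1)
  check_range(flank, "flank", lo = 1)
  check_range(background_width, "background_width", lo = 10)
  check_range(kmer_lengths, "kmer_lengths", lo = 1, hi = 12)
  check_range(n_background, "n_background", lo = 1)
  cfg <- c(list(seed = as.integer(seed), out_dir = out_dir, stages = stages,
                edit_sim = edit_sim, cohort_sim = cohort_sim,
                n_genes = as.integer(n_genes)),
           mget(c("min_coverage", "min_maf", "min_treatment_samples",
                  "min_diff", "max_control_freq", "max_fdr",
                  "min_score", "max_rel", "max_adj_p",
                  "min_depth", "min_alt", "min_vaf",
                  "flank", "background_width", "kmer_lengths",
                  "n_background")))
  structure(cfg, class = "pipeline_config")
}

put <- function(manifest, name, path, df) {
  manifest$artifacts[[name]] <- list(path = path, rows = nrow(df))
  manifest
}

#' Run the full synthetic-data pipeline
#'
#' Executes the requested stages in dependency order on seeded synthetic
#' inputs, writes every artifact as TSV/BED/FASTA/JSON under
#' `config$out_dir`, plus a resolved configuration copy
#' (`resolved-config.yaml`) and a `manifest.json` listing each artifact
#' with its row count and the recall of true edit sites against the
#' simulation truth table. Reruns with the same configuration are
#' byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)
  manifest <- list(seed = config$seed, stages = config$stages,
                   artifacts = list(), warnings = character(0))
  note <- function(w) {
    manifest$warnings <<- c(manifest$warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  if (any(c("editing", "motif") %in% config$stages)) {
    ann <- generate_annotation(config$seed, n_genes = config$n_genes)
    ecfg <- do.call(edit_sim_config,
                    c(list(seed = config$seed + 1L), config$edit_sim))
    ed <- generate_editing_dataset(ecfg, ann)
    write_annotation_bed(ann$annotation, out("annotation.bed"))
    write_fasta(ed$genome, out("genome.fa"))
    write_tsv(ed$counts, out("site-counts.tsv"),
              provenance = sprintf("synthetic editing dataset, seed %d",
                                   ecfg$seed))
    write_tsv(ed$truth, out("truth-sites.tsv"))
    manifest <- put(manifest, "site_counts", out("site-counts.tsv"),
                    ed$counts)

    blacklist <- ed$truth[ed$truth$is_snp,
                          c("chrom", "pos", "alt"), drop = FALSE]
    counts <- filter_known_variants(ed$counts, blacklist)
    candidates <- select_candidates(counts,
                                    min_coverage = config$min_coverage,
                                    min_maf = config$min_maf,
                                    min_treatment_samples =
                                      config$min_treatment_samples)
    if (nrow(candidates) == 0)
      stop("no candidate sites survived filtering; run 'editing' with a ",
           "larger or less noisy simulation", call. = FALSE)
    matrix_long <- withCallingHandlers(
      assemble_count_matrix(candidates, counts), warning = note)
    write_tsv(matrix_long, out("candidate-counts.tsv"))
    manifest <- put(manifest, "candidate_counts",
                    out("candidate-counts.tsv"), matrix_long)

    results <- test_edit_sites(matrix_long)
    retained <- call_edit_sites(results, min_diff = config$min_diff,
                                max_control_freq = config$max_control_freq,
                                max_fdr = config$max_fdr)
    write_tsv(results, out("site-results.tsv"))
    write_tsv(retained, out("retained-sites.tsv"))
    manifest <- put(manifest, "site_results", out("site-results.tsv"),
                    results)
    manifest <- put(manifest, "retained_sites", out("retained-sites.tsv"),
                    retained)

    truth_edit <- ed$truth[ed$truth$is_true_edit, ]
    tkey <- paste(truth_edit$chrom, truth_edit$pos)
    rkey <- paste(retained$chrom, retained$pos)
    manifest$edit_site_recovery <- list(
      n_true = nrow(truth_edit), n_retained = nrow(retained),
      recall = if (nrow(truth_edit)) mean(tkey %in% rkey) else NA,
      false_discoveries = sum(!rkey %in% tkey))

    mapped <- withCallingHandlers(
      map_sites_to_genes(retained, ann$annotation), warning = note)
    scores <- hypertribe_scores(mapped)
    write_tsv(scores, out("gene-scores.tsv"))
    manifest <- put(manifest, "gene_scores", out("gene-scores.tsv"), scores)

    # perturbation scRNA-seq analogue: bound targets are down-regulated
    bound <- scores$gene_id[scores$score >= config$min_score]
    ex <- generate_expression(config$seed + 2L, ann$annotation$gene_id,
                              target_genes = bound)
    de <- rank_sum_de(ex$expr, ex$groups,
                      min_abs_change = 1 - config$max_rel,
                      max_adj_p = config$max_adj_p)
    network <- define_network(scores, de, min_score = config$min_score,
                              max_rel = config$max_rel,
                              max_adj_p = config$max_adj_p)
    write_tsv(de, out("de-results.tsv"))
    write_tsv(network, out("network.tsv"))
    manifest <- put(manifest, "de_results", out("de-results.tsv"), de)
    manifest <- put(manifest, "network", out("network.tsv"), network)

    if ("motif" %in% config$stages && nrow(retained) > 0) {
      targets <- withCallingHandlers(
        build_windows(retained, ann$annotation, ed$genome,
                      flank = config$flank), warning = note)
      background <- sample_background(ann$annotation, ed$genome, targets,
                                      n_segments = config$n_background,
                                      seed = config$seed + 3L,
                                      width = config$background_width)
      motifs <- kmer_enrichment(targets, background,
                                k = config$kmer_lengths)
      write_tsv(targets, out("motif-targets.tsv"))
      write_tsv(background, out("motif-background.tsv"))
      write_tsv(motifs, out("motif-enrichment.tsv"))
      manifest <- put(manifest, "motif_enrichment",
                      out("motif-enrichment.tsv"), motifs)
    }
  }

  if ("cohort" %in% config$stages) {
    ccfg <- do.call(cohort_sim_config,
                    c(list(seed = config$seed + 4L), config$cohort_sim))
    ch <- generate_cohort(ccfg)
    classified <- classify_trajectories(ch$cohort,
                                        min_depth = config$min_depth,
                                        min_alt = config$min_alt,
                                        min_vaf = config$min_vaf)
    write_tsv(ch$cohort, out("cohort.tsv"))
    write_tsv(ch$truth, out("truth-cohort.tsv"))
    write_tsv(classified, out("cohort-classified.tsv"))
    manifest <- put(manifest, "cohort_classified",
                    out("cohort-classified.tsv"), classified)
    growth <- fit_growth_model(classified)
    transience <- fit_transience_model(classified)
    models <- list(
      n_persistent = sum(classified$class == "persistent"),
      n_transient = sum(classified$class == "transient"),
      n_uncalled = sum(classified$class == "uncalled"),
      growth_genotype_coef = growth$genotype$estimate,
      growth_genotype_ci = c(growth$genotype$ci_lo, growth$genotype$ci_hi),
      transience_or = transience$or,
      transience_or_ci = transience$or_ci)
    jsonlite::write_json(models, out("cohort-models.json"),
                         auto_unbox = TRUE, digits = NA)
    manifest$artifacts$cohort_models <- list(path = out("cohort-models.json"),
                                             rows = length(models))
    manifest$cohort_models <- models
  }

  if ("assoc" %in% config$stages) {
    set.seed(config$seed + 5L)
    # heterozygote read skew at one regulatory site, then a three-cohort
    # fixed-effect pooling of simulated log-OR estimates
    reads <- rbinom(1L, 200L, 0.61)
    skew <- allelic_skew(reads, 200L - reads, ref_label = "C",
                         alt_label = "T")
    se <- c(0.05, 0.08, 0.12)
    beta <- rnorm(3, log(0.84), se)
    meta <- ivw_meta(beta, se, labels = c("cohortA", "cohortB", "cohortC"))
    assoc <- list(skew = skew[c("ref_label", "alt_label", "ref_fraction",
                                "alt_fraction", "fold", "fold_rounded",
                                "p_value")],
                  meta = meta[c("beta", "se", "or", "or_ci", "p_value",
                                "n_studies")])
    jsonlite::write_json(assoc, out("assoc.json"), auto_unbox = TRUE,
                         digits = NA)
    manifest$artifacts$assoc <- list(path = out("assoc.json"), rows = 2L)
  }

  resolved <- unclass(config)
  yaml::write_yaml(resolved, out("resolved-config.yaml"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
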