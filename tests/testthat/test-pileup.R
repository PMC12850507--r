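# Candidate-site discovery and filtering rules.

toy_counts <- function(rows) {
  do.call(rbind, lapply(rows, function(r)
    data.frame(chrom = "chr1", pos = r[[1]], strand = r[[2]], ref = r[[3]],
               alt = r[[4]], sample = r[[5]], group = r[[6]],
               k = r[[7]], n = r[[8]], stringsAsFactors = FALSE)))
}

test_that("per-sample discovery applies coverage and MAF thresholds", {
  df <- data.frame(chrom = "chr1", pos = 1:4, strand = "+", ref = "A",
                   alt = "G", sample = "s1", group = "treatment",
                   k = c(5L, 1L, 5L, 0L), n = c(9L, 10L, 1000L, 0L))
  d <- discover_sites(df)
  expect_identical(d$discovered, c(FALSE, TRUE, FALSE, FALSE))
  expect_error(discover_sites(transform(df, k = -1)), "negative")
})

test_that("blacklist filtering is exact-key and leaves other rows intact", {
  sites <- data.frame(chrom = "chr1", pos = c(100L, 100L, 200L),
                      alt = c("G", "T", "G"))
  expect_identical(filter_known_variants(sites, NULL), sites)
  expect_identical(filter_known_variants(sites,
                                         sites[0, , drop = FALSE]), sites)
  bl <- data.frame(chrom = "chr1", pos = 100L, alt = "G")
  out <- filter_known_variants(sites, bl)
  expect_equal(nrow(out), 2)
  expect_true(all(paste(out$pos, out$alt) %in% c("100 T", "200 G")))
  # blacklist with a different alt does not remove the site
  bl2 <- data.frame(chrom = "chr1", pos = 200L, alt = "T")
  expect_equal(nrow(filter_known_variants(sites, bl2)), 3)
})

test_that("candidate selection enforces the two-sample, allele and control-majority rules", {
  mk <- function(pos, strand, ref, alt, kt, ct_k = c(1L, 1L, 1L),
                 ct_n = c(100L, 100L, 100L)) {
    rbind(
      toy_counts(lapply(1:3, function(i)
        list(pos, strand, ref, alt, paste0("t", i), "treatment",
             kt[i], 100L))),
      toy_counts(lapply(1:3, function(i)
        list(pos, strand, ref, alt, paste0("c", i), "control",
             ct_k[i], ct_n[i]))))
  }
  counts <- rbind(
    mk(10L, "+", "A", "G", c(20L, 0L, 0L)),   # only 1 treatment sample
    mk(20L, "+", "A", "G", c(20L, 30L, 0L)),  # kept
    mk(30L, "+", "C", "T", c(20L, 30L, 40L)), # wrong mismatch type
    mk(40L, "-", "T", "C", c(20L, 30L, 0L)),  # kept (reverse strand T>C)
    mk(50L, "+", "A", "G", c(20L, 30L, 0L),   # alt is control major
       ct_k = c(60L, 70L, 80L)),
    mk(60L, "+", "A", "G", c(20L, 30L, 0L),   # zero control coverage
       ct_k = c(0L, 0L, 0L), ct_n = c(0L, 0L, 0L)))
  cand <- select_candidates(counts)
  expect_setequal(cand$pos, c(20L, 40L))
})

test_that("count-matrix assembly completes the sample grid and flags gaps", {
  counts <- rbind(
    toy_counts(list(list(10L, "+", "A", "G", "t1", "treatment", 20L, 100L),
                    list(10L, "+", "A", "G", "t2", "treatment", 25L, 120L),
                    list(10L, "+", "A", "G", "c1", "control", 0L, 200L),
                    list(10L, "+", "A", "G", "c2", "control", 1L, 90L))))
  cand <- data.frame(chrom = "chr1", pos = 10L, strand = "+", ref = "A",
                     alt = "G", stringsAsFactors = FALSE)
  # c2 exists; a third sample never observed at the site gets n = 0
  counts_extra <- rbind(counts,
                        toy_counts(list(list(99L, "+", "A", "G", "t3",
                                             "treatment", 15L, 80L))))
  mat <- assemble_count_matrix(cand, counts_extra)
  expect_equal(nrow(mat), 5)   # 5 samples seen across the table
  t3 <- mat[mat$sample == "t3", ]
  expect_equal(t3$n, 0L)
  expect_false(t3$usable)
  unedited <- mat[mat$sample == "c1", ]
  expect_equal(unedited$k, 0L)
  expect_equal(unedited$n, 200L)

  expect_error(assemble_count_matrix(cand[0, ], counts), "empty")
})

test_that("sites with zero coverage across a whole group are dropped loudly", {
  counts <- toy_counts(list(
    list(10L, "+", "A", "G", "t1", "treatment", 20L, 100L),
    list(10L, "+", "A", "G", "t2", "treatment", 25L, 120L)))
  cand <- data.frame(chrom = "chr1", pos = 10L, strand = "+", ref = "A",
                     alt = "G", stringsAsFactors = FALSE)
  counts$group <- "treatment"
  counts2 <- rbind(counts,
                   toy_counts(list(list(10L, "+", "A", "G", "c1", "control",
                                        0L, 0L))))
  expect_warning(out <- assemble_count_matrix(cand, counts2),
                 "zero coverage")
  expect_equal(nrow(out), 0)
})

test_that("10 candidates x 6 samples assemble to 60 rows", {
  ann <- generate_annotation(5, n_genes = 20)
  ed <- generate_editing_dataset(
    edit_sim_config(seed = 6, n_sites = 40, frac_true_edits = 0.5,
                    edit_freq_range = c(0.4, 0.6)), ann)
  cand <- select_candidates(ed$counts)
  cand10 <- head(cand, 10)
  mat <- assemble_count_matrix(cand10, ed$counts)
  expect_equal(nrow(mat), 60)
})

test_that("filtering order does not change the candidate set, and filters never alter counts", {
  ann <- generate_annotation(6, n_genes = 25)
  ed <- generate_editing_dataset(edit_sim_config(seed = 7, n_sites = 120),
                                 ann)
  bl <- ed$truth[ed$truth$is_snp, c("chrom", "pos", "alt")]
  a <- select_candidates(filter_known_variants(ed$counts, bl))
  pre <- select_candidates(ed$counts)
  b <- filter_known_variants(pre, bl)
  expect_identical(a[order(a$pos), ], b[order(b$pos), ])
  # no k/n mutation
  f <- filter_known_variants(ed$counts, bl)
  key <- paste(f$chrom, f$pos, f$sample)
  orig <- ed$counts
  m <- match(key, paste(orig$chrom, orig$pos, orig$sample))
  expect_identical(f$k, orig$k[m])
  expect_identical(f$n, orig$n[m])
})

test_that("a truth-complete blacklist removes every simulated SNP site", {
  ann <- generate_annotation(8, n_genes = 25)
  ed <- generate_editing_dataset(
    edit_sim_config(seed = 9, n_sites = 150, frac_snp_contaminants = 0.2),
    ann)
  bl <- ed$truth[ed$truth$is_snp, c("chrom", "pos", "alt")]
  expect_gt(nrow(bl), 0)
  filtered <- filter_known_variants(ed$counts, bl)
  snp_keys <- paste(bl$chrom, bl$pos)
  expect_false(any(paste(filtered$chrom, filtered$pos) %in% snp_keys))
})
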