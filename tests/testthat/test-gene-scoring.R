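# Site-to-gene mapping, HyperTRIBE scores, rank-sum DE and the network.

toy_annotation <- data.frame(
  gene_id = c("gA", "gB", "gC"),
  chrom = "chr1",
  start = c(100L, 400L, 450L), end = c(390L, 900L, 800L),
  strand = c("+", "+", "+"),
  utr_start = c(300L, 700L, 600L), utr_end = c(390L, 900L, 800L),
  stringsAsFactors = FALSE)

test_that("sites map to all overlapping genes on the matching strand", {
  sites <- data.frame(chrom = "chr1", pos = c(200L, 460L, 1500L),
                      strand = "+", diff_freq = c(0.5, 0.3, 0.2),
                      stringsAsFactors = FALSE)
  expect_warning(mapped <- map_sites_to_genes(sites, toy_annotation),
                 "overlap no annotated gene")
  expect_equal(sum(mapped$pos == 200), 1)       # one gene
  expect_setequal(mapped$gene_id[mapped$pos == 460], c("gB", "gC"))
  expect_false(1500 %in% mapped$pos)            # intergenic dropped
  # strand mismatch is not an assignment
  minus <- data.frame(chrom = "chr1", pos = 200L, strand = "-",
                      diff_freq = 0.5)
  expect_warning(m2 <- map_sites_to_genes(minus, toy_annotation))
  expect_equal(nrow(m2), 0)
})

test_that("HyperTRIBE scores sum differential frequencies per gene", {
  mapped <- data.frame(gene_id = c("gA", "gA", "gB"),
                       diff_freq = c(0.5, 0.7, 0.3))
  sc <- hypertribe_scores(mapped)
  expect_equal(sc$score[sc$gene_id == "gA"], 1.2)
  expect_equal(sc$n_sites[sc$gene_id == "gA"], 2L)
  expect_equal(sc$score[sc$gene_id == "gB"], 0.3)
  expect_false("gC" %in% sc$gene_id)  # unedited genes absent (score 0)
})

test_that("scores are additive over site batches", {
  set.seed(123)
  mapped <- data.frame(gene_id = sample(sprintf("g%02d", 1:10), 60,
                                        replace = TRUE),
                       diff_freq = runif(60, 0.1, 0.9))
  whole <- hypertribe_scores(mapped)
  half <- sample(c(TRUE, FALSE), 60, replace = TRUE)
  s1 <- hypertribe_scores(mapped[half, ])
  s2 <- hypertribe_scores(mapped[!half, ])
  merged <- merge(s1, s2, by = "gene_id", all = TRUE)
  merged[is.na(merged)] <- 0
  recombined <- merged$score.x + merged$score.y
  names(recombined) <- merged$gene_id
  expect_equal(recombined[whole$gene_id], setNames(whole$score,
                                                   whole$gene_id))
})

test_that("rank-sum p-values equal exhaustive label-permutation enumeration", {
  expr <- rbind(g1 = c(12, 15, 18, 30, 2, 4, 6, 1),
                g2 = c(5, 9, 20, 11, 8, 14, 3, 17))
  groups <- rep(c("perturbed", "control"), each = 4)
  de <- rank_sum_de(expr, groups, min_pct = 0, min_abs_change = 0)
  for (g in c("g1", "g2")) {
    # enumeration must act on the same normalized values the test ranks
    size <- pmax(colSums(expr), 1)
    norm <- log1p(sweep(expr, 2, 10000 / size, `*`))
    p_exact <- ranksum_enum_oracle(norm[g, 1:4], norm[g, 5:8])
    expect_equal(de$p_value[de$gene_id == g], p_exact, tolerance = 1e-12)
  }
})

test_that("genes below the expressed-cell threshold are not tested", {
  set.seed(5)
  expr <- matrix(rpois(40 * 100, 3), nrow = 40,
                 dimnames = list(sprintf("g%02d", 1:40), NULL))
  expr[1, ] <- 0
  expr[1, c(1, 2, 51, 52)] <- 1  # 4% of cells in each group
  groups <- rep(c("perturbed", "control"), each = 50)
  de <- rank_sum_de(expr, groups)
  expect_false("g01" %in% de$gene_id)
  expect_true("g02" %in% de$gene_id)
})

test_that("permuted labels of one population give a uniform-ish null", {
  set.seed(11)
  ngene <- 500
  expr <- matrix(rnbinom(ngene * 120, mu = 8, size = 2), nrow = ngene,
                 dimnames = list(sprintf("g%03d", seq_len(ngene)), NULL))
  groups <- sample(rep(c("perturbed", "control"), each = 60))
  de <- rank_sum_de(expr, groups)
  expect_equal(median(de$rel_expr), 1, tolerance = 0.05)
  ks <- suppressWarnings(ks.test(de$p_value, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_equal(sum(de$significant), 0)
})

test_that("swapping group labels inverts relative expression and keeps p", {
  set.seed(12)
  expr <- matrix(rnbinom(200 * 60, mu = 6, size = 2), nrow = 200,
                 dimnames = list(sprintf("g%03d", 1:200), NULL))
  groups <- rep(c("perturbed", "control"), each = 30)
  de1 <- rank_sum_de(expr, groups, pseudocount = 0)
  de2 <- rank_sum_de(expr, groups, perturbed = "control",
                     control = "perturbed", pseudocount = 0)
  m <- match(de1$gene_id, de2$gene_id)
  expect_equal(de1$rel_expr, 1 / de2$rel_expr[m], tolerance = 1e-12)
  expect_equal(de1$p_value, de2$p_value[m], tolerance = 1e-12)
})

test_that("network thresholds apply with the stated inclusivity", {
  scores <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                       score = c(0.19, 0.25, 0.2, 1.0))
  de <- data.frame(gene_id = c("g1", "g2", "g3", "g4"),
                   rel_expr = c(0.90, 0.95, 0.80, 0.96),
                   adj_p = c(0.001, 0.01, 0.05, 0.001))
  net <- define_network(scores, de)
  # g1: score below 0.2 -> out; g2: rel exactly 0.95 -> in (inclusive);
  # g3: adj_p exactly 0.05 -> out (strict); g4: rel above 0.95 -> out
  expect_identical(net$gene_id, "g2")
  # disjoint tables give an empty network
  expect_equal(nrow(define_network(scores,
                                   transform(de, gene_id = paste0("x", 1:4)))),
               0)
})

test_that("planted bound-and-downregulated targets are recovered by the network", {
  genes <- sprintf("g%03d", 1:500)
  planted <- genes[1:40]
  set.seed(202)
  scores <- data.frame(
    gene_id = genes[1:300],   # only some genes are edited at all
    score = c(runif(40, 0.3, 1.5), runif(260, 0.01, 0.19)))
  ex <- generate_expression(303, genes, target_genes = planted,
                            n_cells_per_group = 100, effect = 0.8)
  de <- rank_sum_de(ex$expr, ex$groups)
  net <- define_network(scores, de)
  recall <- mean(planted %in% net$gene_id)
  precision <- if (nrow(net)) mean(net$gene_id %in% planted) else NA
  expect_gte(recall, 0.90)
  expect_gte(precision, 0.80)
})
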