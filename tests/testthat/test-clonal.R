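# Trajectory classification, compound-interest growth rates, and the
# covariate-adjusted growth / transience regressions.

mk_record <- function(vaf1, vaf2, depth1 = 1000L, depth2 = 1000L,
                      dt = 5, age = 65, sex = "F", genotype = 0L,
                      gene = "DNMT3A") {
  data.frame(id = "p", age = age, sex = sex, genotype = genotype,
             gene = gene, vaf1 = vaf1, depth1 = depth1,
             alt1 = round(vaf1 * depth1), vaf2 = vaf2, depth2 = depth2,
             alt2 = round(vaf2 * depth2), dt_years = dt,
             stringsAsFactors = FALSE)
}

test_that("calling thresholds and persistence classes are applied exactly", {
  recs <- rbind(
    mk_record(0.05, 0.06, depth1 = 99L, depth2 = 99L),  # depth fails
    mk_record(0.025, 0.015),                            # transient
    mk_record(0.03, 0.05),                              # persistent
    mk_record(0.002, 0.001),                            # VAF below 2%
    mk_record(0.05, NA, depth2 = NA))                   # missing 2nd draw
  recs$alt2[5] <- NA
  cl <- classify_trajectories(recs)
  expect_identical(cl$class, c("uncalled", "transient", "persistent",
                               "uncalled", "uncalled"))
  expect_true(is.na(cl$r[2]))
  expect_false(is.na(cl$r[3]))
  # low variant reads fail calling even with VAF >= 2%
  lowalt <- mk_record(0.02, 0.03, depth1 = 100L, depth2 = 100L)
  lowalt$alt1 <- 2L; lowalt$alt2 <- 2L
  expect_identical(classify_trajectories(lowalt)$class, "uncalled")
})

test_that("persistent plus transient equals the baseline-called count", {
  ch <- generate_cohort(cohort_sim_config(seed = 41, n_people = 2000))
  cl <- classify_trajectories(ch$cohort)
  pass1 <- ch$cohort$depth1 >= 100 & ch$cohort$alt1 >= 3 &
    ch$cohort$vaf1 >= 0.02
  expect_equal(sum(cl$class %in% c("persistent", "transient")), sum(pass1))
})

test_that("growth rate follows the compound-interest closed form", {
  expect_equal(growth_rate(0.05, 0.05, 3), 0)
  expect_equal(growth_rate(0.02, 0.08, 2), 1.0)
  expect_equal(growth_rate(0.04, 0.02, 1), -0.5)
  expect_error(growth_rate(0, 0.05, 1), "positive")
  expect_error(growth_rate(0.05, 0.05, 0), "positive")
  # scale equivariance
  expect_equal(growth_rate(0.02, 0.05, 4), growth_rate(0.06, 0.15, 4))
})

test_that("growth-rate inversion holds to 1e-10 on random triples", {
  set.seed(42)
  v1 <- runif(10000, 0.005, 0.5)
  v2 <- runif(10000, 0.005, 0.5)
  t <- runif(10000, 0.5, 13)
  r <- growth_rate(v1, v2, t)
  expect_equal(v1 * (1 + r)^t, v2, tolerance = 1e-10)
})

test_that("growth model equals the normal-equations oracle on a toy fixture", {
  recs <- data.frame(
    age = c(50, 60, 70, 55, 65, 75, 62, 58),
    sex = c("F", "M", "F", "M", "F", "M", "F", "M"),
    genotype = c(0L, 1L, 0L, 1L, 0L, 1L, 0L, 0L),
    gene = c("DNMT3A", "DNMT3A", "TET2", "TET2",
             "DNMT3A", "TET2", "TET2", "DNMT3A"),
    vaf1 = c(0.05, 0.10, 0.03, 0.20, 0.08, 0.04, 0.12, 0.06),
    r = c(0.10, -0.05, 0.08, -0.10, 0.12, 0.02, 0.05, 0.09),
    stringsAsFactors = FALSE)
  fit <- fit_growth_model(recs)
  X <- cbind(1, recs$age, recs$age^2, recs$vaf1,
             as.integer(recs$sex == "M"), recs$genotype,
             as.integer(recs$gene == "TET2"))
  beta <- drop(ols_oracle(X, recs$r))
  got <- fit$coefficients$estimate
  names(got) <- fit$coefficients$term
  expect_equal(unname(got[c("(Intercept)", "age", "age2", "vaf", "sexM",
                            "genotype", "geneTET2")]),
               beta, tolerance = 1e-8)
  expect_equal(fit$genotype$estimate, beta[6], tolerance = 1e-8)
})

test_that("rank-deficient growth designs fail naming the aliased columns", {
  recs <- data.frame(age = 60, sex = "F", genotype = c(0L, 1L, 0L, 1L),
                     gene = "DNMT3A", vaf1 = 0.05,
                     r = c(0.1, 0.2, 0.15, 0.12))
  expect_error(fit_growth_model(recs, covariates = c("age", "age2")),
               "aliased")
})

test_that("covariate-free transience odds ratio equals ad/bc", {
  tab <- expand.grid(genotype = c(0L, 1L), transient = c(0L, 1L))
  counts <- c(a = 40L, c = 12L, b = 8L, d = 9L) # rows: g0/p, g1/p, g0/t, g1/t
  recs <- tab[rep(seq_len(4), counts), ]
  recs$age <- 60; recs$sex <- "F"; recs$gene <- "DNMT3A"; recs$vaf1 <- 0.05
  fit <- fit_transience_model(recs, covariates = character(0))
  or_expected <- (9 / 12) / (8 / 40)
  expect_equal(fit$or, or_expected, tolerance = 1e-6)
  # matches the independent Newton oracle with covariates too
  set.seed(31)
  recs$age <- sample(45:80, nrow(recs), replace = TRUE)
  fit2 <- fit_transience_model(recs, covariates = "age")
  X <- cbind(1, recs$age, recs$genotype)
  b <- logistic_newton_oracle(X, recs$transient)
  expect_equal(fit2$genotype$estimate, b[3], tolerance = 1e-6)
})

test_that("complete separation raises an informative error", {
  recs <- data.frame(genotype = rep(c(0L, 1L), each = 20),
                     transient = rep(c(0L, 1L), each = 20),
                     age = 60, sex = "F", gene = "DNMT3A", vaf1 = 0.05)
  expect_error(fit_transience_model(recs, covariates = character(0)),
               "separation")
})

test_that("per-gene refits drop the driver-gene covariate", {
  ch <- generate_cohort(cohort_sim_config(seed = 55, n_people = 4000,
                                          genotype_effect = -0.05))
  cl <- classify_trajectories(ch$cohort)
  fit <- fit_transience_model(cl, gene = "DNMT3A")
  expect_false(any(grepl("^gene", fit$coefficients$term)))
  expect_equal(fit$n, sum(cl$gene == "DNMT3A" & cl$class != "uncalled"))
})

test_that("permuting genotype against outcome drives the OR to 1", {
  ors <- vapply(1:11, function(s) {
    ch <- generate_cohort(cohort_sim_config(seed = 500 + s,
                                            n_people = 4000,
                                            genotype_effect = -0.05))
    cl <- classify_trajectories(ch$cohort)
    cl <- cl[cl$class != "uncalled", ]
    set.seed(9000 + s)
    cl$genotype <- sample(cl$genotype)
    fit_transience_model(cl)$or
  }, numeric(1))
  expect_gte(median(ors), 0.9)
  expect_lte(median(ors), 1.1)
})
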