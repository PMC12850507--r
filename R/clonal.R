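# Serial-sample CHIP trajectory classification, compound-interest growth
# rates, and covariate-adjusted growth / transience regressions.

#' Classify CHIP mutation trajectories
#'
#' A mutation is called if at least one blood draw passes all three calling
#' thresholds (total depth >= `min_depth`, variant reads >= `min_alt`,
#' VAF >= `min_vaf`). Among mutations called at baseline (first draw passes
#' the thresholds), the trajectory is *persistent* if the second-draw VAF
#' is still >= `min_vaf` and *transient* if it has fallen below; everything
#' else — including records missing the second draw — is *uncalled*.
#' Annualized growth rates ([growth_rate()]) are computed for persistent
#' trajectories only.
#'
#' @param records Cohort data.frame with columns `vaf1`, `depth1`, `alt1`,
#'   `vaf2`, `depth2`, `alt2`, `dt_years`.
#' @param min_depth Minimum total depth (default 100 reads).
#' @param min_alt Minimum variant reads (default 3).
#' @param min_vaf Minimum variant allele fraction (default 0.02).
#' @return `records` with `class` (persistent/transient/uncalled) and `r`
#'   (per-year growth rate, `NA` unless persistent) columns added.
#' @export
classify_trajectories <- function(records, min_depth = 100, min_alt = 3,
                                  min_vaf = 0.02) {
  need <- c("vaf1", "depth1", "alt1", "vaf2", "depth2", "alt2", "dt_years")
  stopifnot(all(need %in% names(records)))
  pass <- function(depth, alt, vaf)
    !is.na(depth) & !is.na(alt) & !is.na(vaf) &
      depth >= min_depth & alt >= min_alt & vaf >= min_vaf
  pass1 <- pass(records$depth1, records$alt1, records$vaf1)
  pass2 <- pass(records$depth2, records$alt2, records$vaf2)
  called <- pass1 | pass2
  baseline <- called & pass1
  has2 <- !is.na(records$vaf2)

  class <- rep("uncalled", nrow(records))
  class[baseline & has2 & records$vaf2 >= min_vaf] <- "persistent"
  class[baseline & has2 & records$vaf2 < min_vaf] <- "transient"
  records$class <- class
  records$r <- NA_real_
  p <- class == "persistent"
  records$r[p] <- growth_rate(records$vaf1[p], records$vaf2[p],
                              records$dt_years[p])
  records
}

#' Annualized compound-interest clonal growth rate
#'
#' `r = (VAF2 / VAF1)^(1/t) - 1`, the constant per-year rate at which a
#' clone at `VAF1` reaches `VAF2` after `t` years.
#'
#' @param vaf1,vaf2 Variant allele fractions at the two draws (must be > 0).
#' @param t Years between draws (must be > 0).
#' @return Per-year growth rate(s).
#' @examples
#' growth_rate(0.02, 0.08, 2) # doubles yearly: r = 1
#' @export
growth_rate <- function(vaf1, vaf2, t) {
  if (any(vaf1 <= 0) || any(vaf2 <= 0) || any(t <= 0))
    stop("growth_rate requires positive VAF1, VAF2 and t", call. = FALSE)
  (vaf2 / vaf1)^(1 / t) - 1
}

# Shared design: r-or-transience ~ age + age^2 + VAF1 + sex + dosage + gene.
# Driver gene is a factor releveled to its most frequent level.
build_model_frame <- function(records, covariates) {
  df <- data.frame(age = records$age, age2 = records$age^2,
                   vaf = records$vaf1,
                   sex = factor(records$sex),
                   genotype = records$genotype)
  if ("gene" %in% covariates) {
    g <- factor(records$gene)
    ref <- names(which.max(table(g)))
    df$gene <- relevel(g, ref = ref)
  }
  keep <- c(intersect(c("age", "age2", "vaf", "sex"), covariates),
            "genotype", intersect("gene", covariates))
  df[, keep, drop = FALSE]
}

coef_table <- function(fit, level = 0.95) {
  s <- summary(fit)$coefficients
  zq <- qnorm(1 - (1 - level) / 2)
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             statistic = s[, 3],
             p_value = s[, 4],
             ci_lo = s[, 1] - zq * s[, 2],
             ci_hi = s[, 1] + zq * s[, 2],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Covariate-adjusted clonal growth model
#'
#' Ordinary least squares of the per-year growth rate of persistent CHIP
#' mutations on age, age squared, baseline VAF, sex, protective-allele
#' dosage, and driver gene (factor, most-frequent reference level):
#' `r ~ age + age^2 + VAF + sex + dosage + gene`. The genotype (dosage)
#' coefficient is the quantity of interest.
#'
#' @param records Classified records ([classify_trajectories()]); only rows
#'   with `class == "persistent"` are fitted. Must carry `age`, `sex`,
#'   `genotype`, `gene`, `vaf1` and `r`.
#' @param covariates Covariates to include besides genotype (default all).
#' @return List: `coefficients` (term/estimate/se/p/CI table), `genotype`
#'   (the genotype row), `fit` (the `lm` object), `n`.
#' @export
fit_growth_model <- function(records,
                             covariates = c("age", "age2", "vaf", "sex",
                                            "gene")) {
  if ("class" %in% names(records))
    records <- records[records$class == "persistent", , drop = FALSE]
  if (!"r" %in% names(records) || any(is.na(records$r)))
    stop("records must carry growth rate r for persistent trajectories",
         call. = FALSE)
  df <- build_model_frame(records, covariates)
  df$r <- records$r
  X <- stats::model.matrix(r ~ ., data = df)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    aliased <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop(sprintf("rank-deficient design; aliased columns: %s",
                 paste(aliased, collapse = ", ")), call. = FALSE)
  }
  fit <- lm(r ~ ., data = df)
  tab <- coef_table(fit)
  list(coefficients = tab,
       genotype = tab[tab$term == "genotype", , drop = FALSE],
       fit = fit, n = nrow(df))
}

#' Covariate-adjusted transience model
#'
#' Logistic regression (maximum likelihood via IRLS) of transient CHIP
#' (1 = second-draw VAF below threshold) on the same covariates as
#' [fit_growth_model()], over all baseline-called mutations. The odds ratio
#' of transience per protective allele is the exponentiated genotype
#' coefficient, with a Wald CI exponentiated from the log-odds scale.
#' Per-driver-gene refits (`gene` argument) subset to that gene and drop
#' the driver-gene covariate. Complete separation raises an error.
#'
#' @param records Classified records; rows with `class` persistent or
#'   transient are fitted.
#' @param covariates Covariates besides genotype (default all; use
#'   `character(0)` for an unadjusted model).
#' @param gene Optional driver gene: subset to it and drop the `gene`
#'   covariate.
#' @param level CI level (default 0.95).
#' @return List: `coefficients`, `genotype`, `or` (odds ratio), `or_ci`,
#'   `fit`, `n`.
#' @export
fit_transience_model <- function(records,
                                 covariates = c("age", "age2", "vaf", "sex",
                                                "gene"),
                                 gene = NULL, level = 0.95) {
  if (!is.null(gene)) {
    records <- records[records$gene == gene, , drop = FALSE]
    covariates <- setdiff(covariates, "gene")
  }
  if ("class" %in% names(records))
    records <- records[records$class %in% c("persistent", "transient"), ,
                       drop = FALSE]
  y <- if ("transient" %in% names(records)) as.integer(records$transient)
       else as.integer(records$class == "transient")
  if (length(unique(y)) < 2)
    stop("both persistent and transient outcomes must be present",
         call. = FALSE)
  df <- build_model_frame(records, covariates)
  df$transient <- y
  fit <- withCallingHandlers(
    glm(transient ~ ., data = df, family = binomial()),
    warning = function(w) invokeRestart("muffleWarning"))
  # separation manifests as fitted log-odds diverging toward +/- infinity
  eta <- abs(stats::predict(fit, type = "link"))
  if (!fit$converged || max(eta) > 15)
    stop(paste0("logistic fit shows (quasi-)complete separation: fitted ",
                "log-odds reach ", format(max(eta), digits = 3),
                "; consider pooling or removing covariates"), call. = FALSE)
  tab <- coef_table(fit, level)
  g <- tab[tab$term == "genotype", , drop = FALSE]
  list(coefficients = tab, genotype = g,
       or = exp(g$estimate), or_ci = c(exp(g$ci_lo), exp(g$ci_hi)),
       fit = fit, n = nrow(df))
}
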