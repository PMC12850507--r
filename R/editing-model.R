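# Per-site negative-binomial GLM test for differential editing, no-intercept
# group-frequency estimation, BH correction across all tested sites, and the
# three-criterion retention rule.

#' Fit the per-site negative-binomial GLM
#'
#' Models a site's edited counts as `k_i ~ NegBinom(mu_i, theta)` with
#' `log(mu_i) = beta0 + beta1 * group_i + log(n_i)` (log coverage as offset),
#' fitted by maximum likelihood via [MASS::glm.nb()]. `beta1` is the
#' treatment log-rate effect; its two-sided Wald p-value is returned. When
#' the NB fit fails to converge or errors (theta is often unidentifiable
#' with six observations), the model is refit as a Poisson GLM
#' (`theta = Inf`) and flagged `converged = FALSE`. Sites with all-zero
#' edited counts are degenerate: `p = 1`, coefficients `NA`, flagged.
#'
#' When every count in one group is zero the design quasi-separates: the
#' group coefficient diverges, its standard error explodes, and the Wald
#' p-value collapses toward 1 no matter how strong the signal (the
#' Hauck-Donner effect). For such sites the group p-value is computed
#' instead from the likelihood-ratio test at the fitted dispersion, and the
#' result carries `test = "lrt"`; all other sites use the Wald test
#' (`test = "wald"`).
#'
#' @param k Edited (alt-allele) read counts per sample.
#' @param n Coverage per sample (rows with `n = 0` are excluded).
#' @param group 0/1, logical, or "control"/"treatment" labels.
#' @return List: `beta0`, `beta1`, `theta`, `se_beta1`, `p_value`, `test`,
#'   `converged`.
#' @export
fit_nb_glm <- function(k, n, group) {
  if (is.character(group)) group <- as.integer(group == "treatment")
  group <- as.integer(group)
  keep <- n >= 1
  k <- k[keep]; n <- n[keep]; group <- group[keep]
  stopifnot(length(k) == length(n), length(k) == length(group))
  if (sum(group == 1) < 2 || sum(group == 0) < 2)
    stop("need at least 2 usable samples per group", call. = FALSE)
  if (all(k == 0)) {
    return(list(beta0 = NA_real_, beta1 = NA_real_, theta = NA_real_,
                se_beta1 = NA_real_, p_value = 1, test = "degenerate",
                converged = FALSE))
  }
  separated <- all(k[group == 1] == 0) || all(k[group == 0] == 0)
  df <- data.frame(k = k, logn = log(n), group = group)
  nb <- tryCatch(
    withCallingHandlers(
      MASS::glm.nb(k ~ group + offset(logn), data = df),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (!is.null(nb) && isTRUE(nb$converged)) {
    fam <- MASS::negative.binomial(nb$theta)
    cf <- coef(nb); theta <- nb$theta; converged <- TRUE
    se <- sqrt(diag(vcov(nb)))[["group"]]
    fit <- nb
  } else {
    # Poisson fallback (theta -> Inf), flagged
    fam <- stats::poisson()
    fit <- glm(k ~ group + offset(logn), data = df, family = fam)
    cf <- coef(fit); theta <- Inf; converged <- FALSE
    se <- sqrt(diag(vcov(fit)))[["group"]]
  }
  if (separated) {
    # deviance drop at fixed dispersion, chi-squared on 1 df
    dev_fit <- suppressWarnings(
      glm(k ~ group + offset(logn), data = df, family = fam))
    p <- stats::pchisq(dev_fit$null.deviance - dev_fit$deviance, df = 1,
                       lower.tail = FALSE)
    test <- "lrt"
  } else {
    p <- 2 * pnorm(-abs(cf[["group"]] / se))
    test <- "wald"
  }
  list(beta0 = unname(cf[1]), beta1 = unname(cf[2]), theta = theta,
       se_beta1 = se, p_value = unname(p), test = test,
       converged = converged)
}

#' Estimate per-group editing frequencies
#'
#' Per group, regresses edited counts on coverage without an intercept
#' (`k ~ 0 + n`); the least-squares slope is
#' `sum(k_i * n_i) / sum(n_i^2)`, clipped to `[0, 1]`. The pooled ratio
#' `sum(k)/sum(n)` is returned alongside as a diagnostic — the two differ
#' under unequal coverages.
#'
#' @inheritParams fit_nb_glm
#' @return List: `freq_treatment`, `freq_control`, `pooled_treatment`,
#'   `pooled_control`.
#' @export
estimate_group_frequencies <- function(k, n, group) {
  if (is.character(group)) group <- as.integer(group == "treatment")
  slope <- function(kk, nn) {
    if (length(nn) == 0 || all(nn == 0))
      stop("cannot estimate frequency: group has no coverage", call. = FALSE)
    min(max(sum(kk * nn) / sum(nn^2), 0), 1)
  }
  list(freq_treatment = slope(k[group == 1], n[group == 1]),
       freq_control = slope(k[group == 0], n[group == 0]),
       pooled_treatment = sum(k[group == 1]) / sum(n[group == 1]),
       pooled_control = sum(k[group == 0]) / sum(n[group == 0]))
}

#' Test all candidate sites for differential editing
#'
#' Fits the per-site NB GLM and the no-intercept frequency regressions for
#' every candidate site in an assembled count matrix, then applies
#' Benjamini-Hochberg adjustment once across all tested sites.
#'
#' @param site_counts Long table from [assemble_count_matrix()] (or any
#'   table with chrom, pos, strand, ref, alt, sample, group, k, n and
#'   optionally `usable`).
#' @return Data.frame with one row per site: coordinates, `beta0`, `beta1`,
#'   `theta`, `se_beta1`, `p_value`, `fdr`, `freq_treatment`,
#'   `freq_control`, `diff_freq`, `converged`.
#' @export
test_edit_sites <- function(site_counts) {
  if (!"usable" %in% names(site_counts)) site_counts$usable <- site_counts$n > 0
  sc <- site_counts[site_counts$usable, , drop = FALSE]
  key <- site_key(sc)
  idx <- split(seq_len(nrow(sc)), key)
  # keep genomic order
  first <- vapply(idx, `[`, integer(1), 1L)
  idx <- idx[order(sc$chrom[first], sc$pos[first])]

  rows <- lapply(idx, function(i) {
    d <- sc[i, , drop = FALSE]
    g <- as.integer(d$group == "treatment")
    fit <- fit_nb_glm(d$k, d$n, g)
    fr <- estimate_group_frequencies(d$k, d$n, g)
    data.frame(chrom = d$chrom[1], pos = d$pos[1], strand = d$strand[1],
               ref = d$ref[1], alt = d$alt[1],
               beta0 = fit$beta0, beta1 = fit$beta1, theta = fit$theta,
               se_beta1 = fit$se_beta1, p_value = fit$p_value,
               test = fit$test,
               freq_treatment = fr$freq_treatment,
               freq_control = fr$freq_control,
               diff_freq = fr$freq_treatment - fr$freq_control,
               pooled_treatment = fr$pooled_treatment,
               pooled_control = fr$pooled_control,
               converged = fit$converged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res$fdr <- p.adjust(res$p_value, method = "BH")
  res
}

#' Retain significant edit sites
#'
#' Applies the three retention criteria to a tested-site table: the
#' treatment-minus-control editing-frequency difference is at least
#' `min_diff` (inclusive), the control editing frequency is strictly below
#' `max_control_freq`, and the BH-adjusted p-value is strictly below
#' `max_fdr`. BH adjustment must already have been computed over all tested
#' sites ([test_edit_sites()] does this).
#'
#' @param results Output of [test_edit_sites()].
#' @param min_diff Minimum differential editing frequency (default 0.1).
#' @param max_control_freq Maximum control editing frequency (default 0.02,
#'   exclusive).
#' @param max_fdr FDR threshold (default 0.05, exclusive).
#' @return The retained subset of `results`.
#' @export
call_edit_sites <- function(results, min_diff = 0.1, max_control_freq = 0.02,
                            max_fdr = 0.05) {
  stopifnot(all(c("diff_freq", "freq_control", "fdr") %in% names(results)))
  keep <- results$diff_freq >= min_diff &
    results$freq_control < max_control_freq &
    results$fdr < max_fdr
  keep[is.na(keep)] <- FALSE
  out <- results[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
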