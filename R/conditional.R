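#' Per-sample APOE epsilon-4 conditioning covariate
#'
#' Returns the epsilon-4 allele count (0/1/2) when a genotyped
#' `apoe_e4` column is present, otherwise the imputed dosage column
#' `apoe_e4_dosage` in `[0, 2]` (the fallback used for studies without
#' direct epsilon-4 genotypes).  When both are present the count is
#' preferred.
#'
#' @param samples Covariate data.frame.
#' @return Numeric vector of epsilon-4 values.
#' @export
apoe_covariate <- function(samples) {
  if ("apoe_e4" %in% names(samples) &&
      !all(is.na(samples$apoe_e4)))
    return(as.numeric(samples$apoe_e4))
  if ("apoe_e4_dosage" %in% names(samples))
    return(as.numeric(samples$apoe_e4_dosage))
  stop("samples table has neither apoe_e4 nor apoe_e4_dosage")
}

#' Variance inflation factor of a gene dosage against the confounder
#'
#' Regresses the gene dosage `D` on the epsilon-4 covariate plus the
#' other model covariates by least squares and returns
#' `VIF = 1 / (1 - R^2)`.  A VIF near 1 means the gene signal is not
#' collinear with the confounder; `R^2 = 1` is reported as `Inf`.
#'
#' @param d Per-sample gene dosage (positive variance).
#' @param e4 Epsilon-4 covariate ([apoe_covariate()]).
#' @param covariates Optional data.frame/matrix of additional
#'   regressors (age, sex, education, PCs).
#' @return The VIF (>= 1, possibly `Inf`).
#' @examples
#' set.seed(1)
#' vif(rnorm(100), rbinom(100, 2, 0.15))  # ~1
#' @export
vif <- function(d, e4, covariates = NULL) {
  stopifnot(length(d) == length(e4))
  if (length(d) < 3) stop("need at least 3 samples")
  X <- cbind(1, e4)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  ok <- complete.cases(X) & !is.na(d)
  X <- X[ok, , drop = FALSE]; d <- d[ok]
  if (var(d) == 0) stop("gene dosage has zero variance")
  fit <- stats::lm.fit(X, d)
  rss <- sum(fit$residuals^2)
  tss <- sum((d - mean(d))^2)
  r2 <- 1 - rss / tss
  if (r2 >= 1 - 1e-12) return(Inf)
  max(1, 1 / (1 - r2))
}

#' Conditional (epsilon-4 adjusted) re-scan of selected genes
#'
#' For each requested gene, reruns the per-study burden regressions
#' with the epsilon-4 covariate appended, re-meta-analyzes, and pairs
#' the result with the unadjusted scan, together with the per-study
#' VIF of the gene dosage against epsilon-4 (computed within the full
#' covariate design).  A signal independent of the confounder keeps
#' its meta Z; a signal riding on linkage with the confounder
#' collapses after adjustment.
#'
#' @param cohorts Named list of [study_cohort()] objects.
#' @param gene_intervals Gene interval table.
#' @param genes Gene symbols to examine.
#' @param maf_max,maf_min,info_min Variant selection window (as in
#'   [select_rare_variants()]).
#' @param family Regression family passed to [fit_association()].
#' @return data.frame of class `conditional_report`: per gene the
#'   unadjusted and adjusted meta Z / P and direction strings, plus
#'   one `vif_<study>` column per study.
#' @export
adjusted_scan <- function(cohorts, gene_intervals, genes,
                          maf_max = 0.03, maf_min = 0, info_min = 0.4,
                          family = c("logistic", "linear")) {
  family <- match.arg(family)
  n_eff <- vapply(cohorts, function(co)
    effective_sample_size(co$n_cases, co$n_controls), 0)
  sel <- lapply(cohorts, select_rare_variants, gene_intervals,
                maf_max = maf_max, maf_min = maf_min,
                info_min = info_min)
  rows <- lapply(genes, function(g) {
    z_u <- z_a <- rep(NA_real_, length(cohorts))
    vifs <- rep(NA_real_, length(cohorts))
    for (s in seq_along(cohorts)) {
      ids <- sel[[s]][[g]]
      if (is.null(ids) || length(ids) == 0) next
      co <- cohorts[[s]]
      fu <- fit_gene(co, ids, g, adjust_apoe = FALSE, family = family)
      fa <- fit_gene(co, ids, g, adjust_apoe = TRUE, family = family)
      if (fu$estimable) z_u[s] <- fu$z
      if (fa$estimable) z_a[s] <- fa$z
      gd <- gene_dosage(co, ids, gene = g)
      covars <- impute_education(co$samples)
      vifs[s] <- tryCatch(
        vif(gd$d, apoe_covariate(covars),
            covars[, default_covariates(covars), drop = FALSE]),
        error = function(e) NA_real_)
    }
    mu <- weighted_z_meta(z_u, n_eff)
    ma <- weighted_z_meta(z_a, n_eff)
    out <- data.frame(gene = g,
                      z_meta_unadjusted = mu$z_meta,
                      p_meta_unadjusted = mu$p_meta,
                      direction_unadjusted = mu$direction,
                      z_meta_adjusted = ma$z_meta,
                      p_meta_adjusted = ma$p_meta,
                      direction_adjusted = ma$direction,
                      stringsAsFactors = FALSE)
    for (s in seq_along(cohorts))
      out[[paste0("vif_", names(cohorts)[s])]] <- vifs[s]
    out
  })
  res <- do.call(rbind, rows)
  class(res) <- c("conditional_report", class(res))
  res
}
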