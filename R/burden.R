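#' Minor allele frequency from a dosage column
#'
#' Estimated allele frequency is the mean dosage over non-missing
#' samples divided by 2; the MAF folds it onto `[0, 0.5]`.
#'
#' @param dosage Numeric dosage vector in `[0, 2]` (NA = missing).
#' @return MAF in `[0, 0.5]`.
#' @examples
#' compute_maf(c(0, 0, 1, 1))  # 0.25
#' @export
compute_maf <- function(dosage) {
  if (all(is.na(dosage))) stop("all dosages missing")
  p <- mean(dosage, na.rm = TRUE) / 2
  min(p, 1 - p)
}

#' Select qualifying rare variants per gene
#'
#' A variant qualifies for a gene iff its position lies inside the
#' gene's interval (1-based inclusive, matching chromosome), its
#' study-level MAF satisfies `maf_min <= MAF <= maf_max` (both bounds
#' inclusive: MAF exactly 3\% is rare), and its INFO score is at least
#' `info_min`.  Genes with no qualifying variant get an empty set and
#' are reported untestable downstream (the `"?"` of direction
#' strings).  The stage-2 MAF floor of 0.5\% is obtained with
#' `maf_min = 0.005`.
#'
#' @param cohort A [study_cohort()].
#' @param gene_intervals data.frame from [read_gene_intervals()] or
#'   [simulate_cohorts()].
#' @param maf_max,maf_min Inclusive MAF window (defaults 3\% and 0).
#' @param info_min Minimum INFO score (inclusive).
#' @return Named list (one element per gene) of variant id vectors.
#' @export
select_rare_variants <- function(cohort, gene_intervals,
                                 maf_max = 0.03, maf_min = 0,
                                 info_min = 0.4) {
  stopifnot(inherits(cohort, "study_cohort"))
  v <- cohort$variants
  pass <- v$maf >= maf_min & v$maf <= maf_max & v$info >= info_min
  out <- lapply(seq_len(nrow(gene_intervals)), function(g)
    v$id[pass & v$chrom == gene_intervals$chrom[g] &
           v$pos >= gene_intervals$start[g] &
           v$pos <= gene_intervals$end[g]])
  names(out) <- gene_intervals$gene
  out
}

#' Collapse rare-variant dosages into a per-gene dosage
#'
#' Computes the gene dosage `D = sum(G_i) / n`, the mean of the
#' included variants' dosages per sample.  A sample missing some
#' included variants averages over its non-missing ones (its
#' effective `n` adjusts); a sample missing all of them gets `NA` and
#' is excluded from that gene's test.
#'
#' @param cohort A [study_cohort()].
#' @param variant_ids Ids of the included variants (n >= 1).
#' @param gene Optional gene symbol carried through.
#' @return An object of class `gene_dosage`: list with `gene`, `n`
#'   (number of included variants), `d` (named per-sample dosage in
#'   `[0, 2]`), `variant_ids`.
#' @export
gene_dosage <- function(cohort, variant_ids, gene = NA_character_) {
  stopifnot(inherits(cohort, "study_cohort"))
  if (length(variant_ids) < 1) stop("need at least one variant")
  idx <- match(variant_ids, cohort$variants$id)
  if (anyNA(idx)) stop("unknown variant id(s): ",
                       paste(variant_ids[is.na(idx)], collapse = ", "))
  d <- rowMeans(cohort$dosage[, idx, drop = FALSE], na.rm = TRUE)
  d[is.nan(d)] <- NA_real_
  structure(list(gene = gene, n = length(variant_ids), d = d,
                 variant_ids = variant_ids), class = "gene_dosage")
}

# default covariate columns present in a samples table
default_covariates <- function(samples) {
  pcs <- grep("^PC[0-9]+$", names(samples), value = TRUE)
  intersect(c("age", "sex", "edu", pcs), names(samples))
}

#' Covariate-adjusted association regression for a gene or SNP dosage
#'
#' Regresses case/control status on the predictor (a gene dosage `D`
#' or a single-SNP dosage) with covariate adjustment, by maximum
#' likelihood logistic regression (default) or ordinary least squares
#' (`family = "linear"`).  Reports the Wald estimate, standard error,
#' `z = beta / se` and the two-sided normal P value.  Degenerate fits
#' (zero-variance predictor, separation, non-convergence,
#' collinearity) are returned flagged non-estimable rather than as
#' errors, and become `"?"` in meta-analysis direction strings.
#'
#' @param predictor Numeric vector (a [gene_dosage()]'s `d` or a raw
#'   dosage column); NA entries are dropped.
#' @param samples Covariate/phenotype data.frame with `status` and the
#'   covariate columns; missing education is mean-imputed.
#' @param covariates Covariate column names; defaults to age, sex,
#'   edu and every `PC<k>` column present.
#' @param adjust_apoe Append the APOE epsilon-4 covariate from
#'   [apoe_covariate()].
#' @param family `"logistic"` or `"linear"`.
#' @param gene,study,n_variants Bookkeeping fields copied into the
#'   result row.
#' @return One-row data.frame: `study`, `gene`, `beta`, `se`, `z`,
#'   `p`, `n_variants`, `n_samples`, `estimable`.
#' @export
fit_association <- function(predictor, samples, covariates = NULL,
                            adjust_apoe = FALSE,
                            family = c("logistic", "linear"),
                            gene = NA_character_, study = NA_character_,
                            n_variants = NA_integer_) {
  family <- match.arg(family)
  if (inherits(predictor, "gene_dosage")) {
    if (is.na(gene)) gene <- predictor$gene
    if (is.na(n_variants)) n_variants <- predictor$n
    predictor <- predictor$d
  }
  stopifnot(length(predictor) == nrow(samples))
  if (is.null(covariates)) covariates <- default_covariates(samples)
  samples <- impute_education(samples)
  X <- cbind(`(Intercept)` = 1, d = predictor,
             as.matrix(samples[, covariates, drop = FALSE]))
  if (adjust_apoe) X <- cbind(X, apoe = apoe_covariate(samples))
  y <- samples$status
  ok <- complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  y <- y[ok]
  if (length(unique(y)) < 2)
    stop("phenotype has a single class; need both cases and controls")
  not_estimable <- function() data.frame(
    study = study, gene = gene, beta = NA_real_, se = NA_real_,
    z = NA_real_, p = NA_real_, n_variants = n_variants,
    n_samples = length(y), estimable = FALSE, stringsAsFactors = FALSE)
  if (var(X[, "d"]) == 0) return(not_estimable())
  fam <- if (family == "logistic") binomial() else gaussian()
  fit <- tryCatch(
    suppressWarnings(glm.fit(X, y, family = fam,
                             control = list(maxit = 50))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$converged) return(not_estimable())
  beta <- fit$coefficients["d"]
  if (is.na(beta)) return(not_estimable())      # aliased / collinear
  p_rank <- fit$rank
  piv <- fit$qr$pivot[seq_len(p_rank)]
  Rmat <- fit$qr$qr[seq_len(p_rank), seq_len(p_rank), drop = FALSE]
  Rmat[lower.tri(Rmat)] <- 0
  covm <- chol2inv(Rmat)
  disp <- if (family == "logistic") 1
          else sum(fit$residuals^2 * fit$weights) / fit$df.residual
  se_all <- rep(NA_real_, ncol(X))
  se_all[piv] <- sqrt(diag(covm) * disp)
  se <- se_all[match("d", colnames(X))]
  if (!is.finite(se) || se > 100 || abs(beta) > 15)
    return(not_estimable())                     # separation guard
  z <- beta / se
  data.frame(study = study, gene = gene, beta = as.numeric(beta),
             se = as.numeric(se), z = as.numeric(z),
             p = 2 * pnorm(-abs(z)), n_variants = n_variants,
             n_samples = length(y), estimable = TRUE,
             stringsAsFactors = FALSE)
}

#' Per-study burden regression for one gene
#'
#' Convenience wrapper: collapse the given variants with
#' [gene_dosage()] and fit [fit_association()].  Genes with no
#' qualifying variants yield a non-estimable row.
#'
#' @param cohort A [study_cohort()] (samples table required).
#' @param variant_ids Included variant ids (may be empty).
#' @param gene Gene symbol.
#' @inheritParams fit_association
#' @return One-row data.frame as in [fit_association()].
#' @export
fit_gene <- function(cohort, variant_ids, gene,
                     adjust_apoe = FALSE,
                     family = c("logistic", "linear"),
                     covariates = NULL) {
  family <- match.arg(family)
  if (length(variant_ids) == 0)
    return(data.frame(study = cohort$study, gene = gene,
                      beta = NA_real_, se = NA_real_, z = NA_real_,
                      p = NA_real_, n_variants = 0L,
                      n_samples = nrow(cohort$dosage),
                      estimable = FALSE, stringsAsFactors = FALSE))
  gd <- gene_dosage(cohort, variant_ids, gene = gene)
  fit_association(gd, cohort$samples, covariates = covariates,
                  adjust_apoe = adjust_apoe, family = family,
                  study = cohort$study)
}
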