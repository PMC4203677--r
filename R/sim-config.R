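#' Configuration for the synthetic multi-study cohort generator
#'
#' Bundles and validates every parameter of the generator.  The
#' defaults describe the study conditions the package is calibrated
#' against: six case-control studies with the post-QC sizes of
#' [reference_study_sizes()], rare variants with a MAF spectrum
#' concentrated below 3\%, one causal gene with odds ratio 1.7 per unit
#' of gene dosage, a strong independent confounder locus standing in
#' for APOE \eqn{\varepsilon}4, and mild imputation noise.
#'
#' @param study_names Character vector of study labels; also fixes the
#'   study order of meta-analysis direction strings.
#' @param n_cases,n_controls Integer vectors, one entry per study:
#'   target number of cases / controls after ascertainment.
#' @param n_genes Number of genes on the synthetic coordinate system.
#' @param variants_per_gene Length-2 integer range; the variant count of
#'   each gene is drawn uniformly from it.
#' @param maf_spectrum List with elements `shape1`, `shape2`, `min`,
#'   `max`: population MAFs are Beta(shape1, shape2) draws truncated to
#'   `[min, max]`.  Defaults put roughly three quarters of the mass
#'   below 3\%.
#' @param causal_genes Character vector of gene ids carrying a true
#'   effect (may be empty for null simulations).
#' @param causal_log_or Numeric vector, one log odds ratio per causal
#'   gene, applied per unit of true gene dosage \eqn{D = \sum G_i / n}.
#' @param confounder_log_or Log odds ratio per copy of the confounder
#'   (\eqn{\varepsilon}4-like) allele.
#' @param confounder_maf Population frequency of the confounder allele.
#' @param confounder_ld_gene Optional gene id whose variants are drawn
#'   in linkage with the confounder allele (alleles occur only on
#'   confounder haplotypes), to exercise the conditional analysis.
#'   `NULL` (default) keeps the confounder independent of all genes.
#' @param covariate_effects Named numeric vector of log odds ratios for
#'   `age` (per year, centered at 75), `sex` (female = 1), `edu` (per
#'   education category) and `pc` (per unit of each principal
#'   component).
#' @param n_pcs Number of standard-normal principal components.
#' @param edu_probs Multinomial probabilities of education categories
#'   1-4.
#' @param edu_missing_rate Fraction of samples with missing education
#'   (exercises mean-imputation downstream).
#' @param imputation_error Per-variant genotype-posterior miscall rate
#'   in `[0, 0.5)`; either a scalar (all variants) or a length-2 range
#'   from which per-variant rates are drawn uniformly.
#' @param intercept Baseline log-odds of disease (at zero covariates,
#'   no risk alleles).
#' @param seed Integer seed; identical config + seed reproduces
#'   byte-identical cohorts.
#'
#' @return An object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(study_names = c("A", "B"),
#'                   n_cases = c(200, 100), n_controls = c(200, 300),
#'                   n_genes = 10, seed = 42)
#' cfg$n_studies
#' @export
sim_config <- function(study_names = reference_study_sizes()$study,
                       n_cases = reference_study_sizes()$n_cases,
                       n_controls = reference_study_sizes()$n_controls,
                       n_genes = 50L,
                       variants_per_gene = c(3L, 8L),
                       maf_spectrum = list(shape1 = 0.8, shape2 = 35,
                                           min = 0.001, max = 0.05),
                       causal_genes = "G0001",
                       causal_log_or = log(1.7),
                       confounder_log_or = log(3),
                       confounder_maf = 0.15,
                       confounder_ld_gene = NULL,
                       covariate_effects = c(age = 0.03, sex = 0.3,
                                             edu = -0.1, pc = 0),
                       n_pcs = 2L,
                       edu_probs = c(0.05, 0.30, 0.40, 0.25),
                       edu_missing_rate = 0.05,
                       imputation_error = 0.05,
                       intercept = -1.2,
                       seed = 1L) {
  n_studies <- length(study_names)
  stopifnot(n_studies >= 1, !anyDuplicated(study_names))
  if (length(n_cases) != n_studies || length(n_controls) != n_studies)
    stop("n_cases and n_controls must have one entry per study")
  if (any(n_cases < 1) || any(n_controls < 1))
    stop("all case and control counts must be positive")
  if (n_genes < 1) stop("n_genes must be positive")
  variants_per_gene <- as.integer(variants_per_gene)
  if (length(variants_per_gene) == 1L)
    variants_per_gene <- rep(variants_per_gene, 2L)
  if (length(variants_per_gene) != 2L || any(variants_per_gene < 1) ||
      variants_per_gene[1] > variants_per_gene[2])
    stop("variants_per_gene must be a positive range c(lo, hi)")
  needed <- c("shape1", "shape2", "min", "max")
  if (!is.list(maf_spectrum) || !all(needed %in% names(maf_spectrum)))
    stop("maf_spectrum needs elements shape1, shape2, min, max")
  if (maf_spectrum$shape1 <= 0 || maf_spectrum$shape2 <= 0)
    stop("maf_spectrum shape parameters must be positive")
  if (maf_spectrum$min <= 0 || maf_spectrum$max >= 0.5 ||
      maf_spectrum$min > maf_spectrum$max)
    stop("maf_spectrum support must lie within (0, 0.5)")
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  causal_genes <- as.character(causal_genes)
  if (length(causal_genes) && !all(causal_genes %in% gene_ids))
    stop("causal_genes must be gene ids of the form G0001..G", n_genes)
  if (length(causal_log_or) == 1L)
    causal_log_or <- rep(causal_log_or, length(causal_genes))
  if (length(causal_log_or) != length(causal_genes))
    stop("causal_log_or must match causal_genes in length")
  if (!is.null(confounder_ld_gene) &&
      !(confounder_ld_gene %in% gene_ids))
    stop("confounder_ld_gene must be one of the gene ids")
  if (confounder_maf <= 0 || confounder_maf >= 0.5)
    stop("confounder_maf must lie in (0, 0.5)")
  for (nm in c("age", "sex", "edu", "pc"))
    if (!nm %in% names(covariate_effects))
      stop("covariate_effects needs named entries age, sex, edu, pc")
  if (length(edu_probs) != 4L || any(edu_probs < 0) ||
      abs(sum(edu_probs) - 1) > 1e-8)
    stop("edu_probs must be 4 probabilities summing to 1")
  if (edu_missing_rate < 0 || edu_missing_rate >= 1)
    stop("edu_missing_rate must lie in [0, 1)")
  if (length(imputation_error) == 1L)
    imputation_error <- rep(imputation_error, 2L)
  if (length(imputation_error) != 2L || any(imputation_error < 0) ||
      any(imputation_error >= 0.5) ||
      imputation_error[1] > imputation_error[2])
    stop("imputation_error must be a scalar or range within [0, 0.5)")
  structure(list(
    study_names = as.character(study_names),
    n_studies = n_studies,
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    n_genes = as.integer(n_genes),
    gene_ids = gene_ids,
    variants_per_gene = variants_per_gene,
    maf_spectrum = maf_spectrum,
    causal_genes = causal_genes,
    causal_log_or = as.numeric(causal_log_or),
    confounder_log_or = as.numeric(confounder_log_or),
    confounder_maf = as.numeric(confounder_maf),
    confounder_ld_gene = confounder_ld_gene,
    covariate_effects = covariate_effects,
    n_pcs = as.integer(n_pcs),
    edu_probs = as.numeric(edu_probs),
    edu_missing_rate = as.numeric(edu_missing_rate),
    imputation_error = as.numeric(imputation_error),
    intercept = as.numeric(intercept),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d studies: %s\n", x$n_studies,
              paste(x$study_names, collapse = ", ")))
  cat(sprintf("  cases/controls: %s\n",
              paste(x$n_cases, x$n_controls, sep = "/", collapse = ", ")))
  cat(sprintf("  %d genes, %d-%d variants each, MAF ~ Beta(%.2g, %.2g) on [%g, %g]\n",
              x$n_genes, x$variants_per_gene[1], x$variants_per_gene[2],
              x$maf_spectrum$shape1, x$maf_spectrum$shape2,
              x$maf_spectrum$min, x$maf_spectrum$max))
  if (length(x$causal_genes))
    cat(sprintf("  causal: %s (log OR %s per unit D)\n",
                paste(x$causal_genes, collapse = ", "),
                paste(signif(x$causal_log_or, 3), collapse = ", ")))
  else cat("  no causal genes (null model)\n")
  cat(sprintf("  confounder: MAF %.2f, log OR %.3g%s\n",
              x$confounder_maf, x$confounder_log_or,
              if (is.null(x$confounder_ld_gene)) " (independent of genes)"
              else paste0(" (in LD with ", x$confounder_ld_gene, ")")))
  cat(sprintf("  imputation error %.3g-%.3g, seed %d\n",
              x$imputation_error[1], x$imputation_error[2], x$seed))
  invisible(x)
}
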