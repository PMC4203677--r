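#' Effective sample size of a case-control study
#'
#' `N_E = 4 / (1/N_cases + 1/N_controls)`, the harmonic-mean-based
#' weight used by sample-size-weighted meta-analysis.  Equals
#' `2 * N` for a balanced study with `N` per arm, and is bounded above
#' by the total sample size (equality iff balanced).
#'
#' @param n_cases,n_controls Positive counts (vectorized).
#' @return Effective sample size(s).
#' @examples
#' effective_sample_size(2098, 2095)  # ~4192.998
#' @export
effective_sample_size <- function(n_cases, n_controls) {
  if (any(n_cases <= 0) || any(n_controls <= 0))
    stop("case and control counts must be positive")
  4 / (1 / n_cases + 1 / n_controls)
}

#' Sample-size-weighted fixed-effects Z-score meta-analysis
#'
#' Stouffer combination with weights `w_i = sqrt(N_E_i)`:
#' `z_meta = sum(w_i * z_i) / sqrt(sum(w_i^2))` over the available
#' studies, with a two-sided P value.  Unavailable studies (missing
#' `z`, failed fits, filtered variants) get the `"?"` character in the
#' direction string and zero weight; available studies contribute
#' `"+"` (z > 0) or `"-"`.
#'
#' @param z Per-study Z scores (NA = unavailable).
#' @param n_eff Per-study effective sample sizes
#'   ([effective_sample_size()]).
#' @param available Logical availability flags; defaults to
#'   `!is.na(z)`.
#' @return One-row data.frame of class `meta_result`: `z_meta`,
#'   `p_meta`, `direction`, `n_studies_used`, with the per-study
#'   weights in attribute `"weights"`.  All-unavailable input yields
#'   an untestable row (`NA` statistics, all-`"?"` direction).
#' @examples
#' weighted_z_meta(c(1.2, 2.0, NA), c(400, 900, 500))
#' @export
weighted_z_meta <- function(z, n_eff, available = !is.na(z)) {
  stopifnot(length(z) == length(n_eff))
  available <- available & !is.na(z)
  dir <- ifelse(!available, "?", ifelse(z < 0, "-", "+"))
  w <- ifelse(available, sqrt(n_eff), 0)
  if (!any(available)) {
    out <- data.frame(z_meta = NA_real_, p_meta = NA_real_,
                      direction = paste(dir, collapse = ""),
                      n_studies_used = 0L, stringsAsFactors = FALSE)
  } else {
    z_meta <- sum(w[available] * z[available]) /
      sqrt(sum(w[available]^2))
    out <- data.frame(z_meta = z_meta,
                      p_meta = 2 * pnorm(-abs(z_meta)),
                      direction = paste(dir, collapse = ""),
                      n_studies_used = sum(available),
                      stringsAsFactors = FALSE)
  }
  attr(out, "weights") <- w
  class(out) <- c("meta_result", class(out))
  out
}

#' Genome-wide gene-based significance threshold
#'
#' Bonferroni threshold `alpha / n_genes`; with the 28,517 genes of
#' the human genome annotation this is 0.05 / 28517 = 1.8e-6 at two
#' significant figures.
#'
#' @param n_genes Number of genes tested (>= 1).
#' @param alpha Family-wise error rate.
#' @return The per-gene significance threshold.
#' @examples
#' genomewide_threshold(28517)  # 1.75e-06
#' @export
genomewide_threshold <- function(n_genes, alpha = 0.05) {
  if (n_genes < 1) stop("n_genes must be at least 1")
  alpha / n_genes
}

#' Genomic inflation factor lambda
#'
#' `lambda_GC` = median of the 1-df chi-square statistics implied by
#' the P values, divided by the null median `qchisq(0.5, 1)`
#' (about 0.4549).  Values near 1 indicate a calibrated scan; values
#' well above 1 indicate inflated type-I error (e.g. unmodelled
#' stratification).
#'
#' @param p P values in (0, 1]; at least 10 required.
#' @return The inflation factor.
#' @export
genomic_inflation <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) < 10) stop("need at least 10 P values")
  if (any(p <= 0 | p > 1)) stop("P values must lie in (0, 1]")
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}
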