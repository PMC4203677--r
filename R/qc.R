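#' QC thresholds
#'
#' Bundles the genotype- and sample-level quality-control thresholds:
#' genotyped variants are dropped at MAF < 1\%, call rate < 95\% or
#' Hardy-Weinberg exact P < 1e-6; imputed variants at INFO < 0.4
#' (strict: INFO = 0.4 is kept); samples at call rate < 95\%,
#' heterozygosity outliers at Benjamini-Hochberg FDR < 1\%, and
#' relatedness at pairwise IBS > 0.95.
#'
#' @param maf_min_genotyped,variant_call_rate_min,hwe_p_min Genotyped
#'   variant thresholds.
#' @param sample_call_rate_min,het_fdr,ibs_max Sample thresholds.
#' @param info_min Imputed-variant INFO threshold.
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(maf_min_genotyped = 0.01,
                          variant_call_rate_min = 0.95,
                          hwe_p_min = 1e-6,
                          sample_call_rate_min = 0.95,
                          het_fdr = 0.01,
                          ibs_max = 0.95,
                          info_min = 0.4) {
  th <- list(maf_min_genotyped = maf_min_genotyped,
             variant_call_rate_min = variant_call_rate_min,
             hwe_p_min = hwe_p_min,
             sample_call_rate_min = sample_call_rate_min,
             het_fdr = het_fdr, ibs_max = ibs_max, info_min = info_min)
  if (any(unlist(th) < 0) || any(unlist(th) > 1))
    stop("all QC thresholds must lie in [0, 1]")
  structure(th, class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact conditional test on observed genotype counts: given the
#' allele totals, the P value is the sum of probabilities of all
#' heterozygote counts whose conditional probability does not exceed
#' that of the observed count.  Computed in log space over the full
#' support, so it is exact for any sample size.
#'
#' @param n_AA,n_Aa,n_aa Observed genotype counts (non-negative, not
#'   all zero).
#' @return The exact P value in (0, 1].  Monomorphic input gives 1.
#' @examples
#' hwe_exact_test(57, 14, 50)   # strong deviation, tiny P
#' hwe_exact_test(25, 50, 25)   # perfect HWE proportions
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0) || any(c(n_AA, n_Aa, n_aa) %% 1 != 0))
    stop("genotype counts must be non-negative integers")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("all genotype counts are zero")
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  nr <- min(nA, na)
  if (nr == 0) return(1)                    # monomorphic
  h <- seq.int(nr %% 2, nr, by = 2L)        # possible het counts
  lp <- lfactorial(n) - lfactorial((nA - h) / 2) - lfactorial(h) -
    lfactorial((na - h) / 2) + h * log(2) +
    lfactorial(nA) + lfactorial(na) - lfactorial(2 * n)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  p_obs <- pr[match(n_Aa, h)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-12)]))
}

hardcalls_of <- function(cohort) {
  if (!is.null(cohort$hardcall)) cohort$hardcall
  else {
    g <- round(cohort$dosage)
    storage.mode(g) <- "integer"
    g
  }
}

#' Variant-level QC
#'
#' Applies the genotyped-panel filters (MAF, call rate, Hardy-Weinberg
#' exact test on hard calls) to variants flagged `"genotyped"` and the
#' imputation-quality filter (INFO) to variants flagged `"imputed"`.
#' Each dropped variant carries the first failing reason code among
#' `maf`, `call_rate`, `hwe` (genotyped) or `info` (imputed).
#' Idempotent: re-running on the kept subset drops nothing further.
#'
#' @param cohort A [study_cohort()]; hard calls are taken from
#'   `cohort$hardcall` when present, else from rounded dosages.
#' @param thresholds A [qc_thresholds()].
#' @return data.frame with columns `id`, `type`, `keep`, `reason`.
#' @export
variant_qc <- function(cohort, thresholds = qc_thresholds()) {
  stopifnot(inherits(cohort, "study_cohort"))
  v <- cohort$variants
  G <- hardcalls_of(cohort)
  keep <- rep(TRUE, nrow(v))
  reason <- rep(NA_character_, nrow(v))
  for (j in seq_len(nrow(v))) {
    if (v$type[j] == "genotyped") {
      g <- G[, j]
      ok <- !is.na(g)
      call_rate <- mean(ok)
      if (sum(ok) == 0) { keep[j] <- FALSE; reason[j] <- "call_rate"; next }
      p <- mean(g[ok]) / 2
      maf <- min(p, 1 - p)
      if (maf < thresholds$maf_min_genotyped) {
        keep[j] <- FALSE; reason[j] <- "maf"
      } else if (call_rate < thresholds$variant_call_rate_min) {
        keep[j] <- FALSE; reason[j] <- "call_rate"
      } else {
        hwe_p <- hwe_exact_test(sum(g[ok] == 0), sum(g[ok] == 1),
                                sum(g[ok] == 2))
        if (hwe_p < thresholds$hwe_p_min) {
          keep[j] <- FALSE; reason[j] <- "hwe"
        }
      }
    } else {
      if (v$info[j] < thresholds$info_min) {
        keep[j] <- FALSE; reason[j] <- "info"
      }
    }
  }
  data.frame(id = v$id, type = v$type, keep = keep, reason = reason,
             stringsAsFactors = FALSE)
}

#' Mean identity-by-state between two samples
#'
#' Mean over shared non-missing variants of `(2 - |g1 - g2|) / 2`.
#'
#' @param g1,g2 Integer hard-call vectors in \{0, 1, 2\} (NA allowed).
#' @return Mean IBS in `[0, 1]`.
#' @examples
#' pairwise_ibs(c(0, 1, 2), c(0, 1, 0))  # 2/3
#' @export
pairwise_ibs <- function(g1, g2) {
  stopifnot(length(g1) == length(g2))
  ok <- !is.na(g1) & !is.na(g2)
  if (!any(ok)) stop("no variants genotyped in both samples")
  mean((2 - abs(g1[ok] - g2[ok])) / 2)
}

# full pairwise IBS matrix via indicator cross-products
ibs_matrix <- function(G) {
  M <- (!is.na(G)) * 1
  I0 <- (G == 0 & !is.na(G)) * 1
  I1 <- (G == 1 & !is.na(G)) * 1
  I2 <- (G == 2 & !is.na(G)) * 1
  d1 <- I0 %*% t(I1) + I1 %*% t(I2)
  sumdiff <- d1 + t(d1) + 2 * (I0 %*% t(I2) + I2 %*% t(I0))
  shared <- M %*% t(M)
  ibs <- 1 - sumdiff / (2 * shared)
  ibs[shared == 0] <- NA
  ibs
}

#' Sample-level QC
#'
#' Excludes samples with hard-call rate below threshold; flags
#' autosomal heterozygosity outliers by converting each sample's
#' heterozygosity rate to a two-sided P under a normal approximation
#' of the cohort distribution and applying Benjamini-Hochberg at the
#' configured FDR; and, for each sample pair with mean IBS above
#' threshold, excludes the member with the lower call rate (ties
#' broken by sample order: the later sample is dropped).  With fewer
#' than 3 samples the heterozygosity and relatedness steps are skipped
#' with a warning.
#'
#' @param cohort A [study_cohort()] with hard calls available.
#' @param thresholds A [qc_thresholds()].
#' @param max_ibs_variants Thin the hard-call matrix to at most this
#'   many evenly spaced variants for the IBS computation.
#' @return A list with `keep` (character vector of retained sample
#'   ids) and `report` (per-sample data.frame with call rate,
#'   heterozygosity statistics and exclusion reasons).
#' @export
sample_qc <- function(cohort, thresholds = qc_thresholds(),
                      max_ibs_variants = Inf) {
  stopifnot(inherits(cohort, "study_cohort"))
  G <- hardcalls_of(cohort)
  ids <- if (!is.null(cohort$samples)) cohort$samples$sample_id
         else if (!is.null(rownames(G))) rownames(G)
         else sprintf("S%04d", seq_len(nrow(G)))
  n <- nrow(G)
  call_rate <- rowMeans(!is.na(G))
  excluded <- call_rate < thresholds$sample_call_rate_min
  reason <- ifelse(excluded, "call_rate", NA_character_)
  het_rate <- rowMeans(G == 1, na.rm = TRUE)
  het_p <- het_q <- rep(NA_real_, n)
  if (n < 3) {
    warning("fewer than 3 samples: heterozygosity and relatedness QC skipped")
  } else {
    mu <- mean(het_rate[!excluded])
    s <- sd(het_rate[!excluded])
    if (is.finite(s) && s > 0) {
      het_p <- 2 * pnorm(-abs((het_rate - mu) / s))
      het_q <- p.adjust(het_p, method = "BH")
      bad <- !excluded & het_q < thresholds$het_fdr
      reason[bad] <- "heterozygosity"
      excluded <- excluded | bad
    }
    surv <- which(!excluded)
    if (length(surv) >= 2) {
      Gs <- G[surv, , drop = FALSE]
      if (ncol(Gs) > max_ibs_variants) {
        pick <- unique(round(seq(1, ncol(Gs),
                                 length.out = max_ibs_variants)))
        Gs <- Gs[, pick, drop = FALSE]
      }
      ibs <- ibs_matrix(Gs)
      for (a in seq_along(surv)) for (b in seq_len(a - 1L)) {
        ia <- surv[a]; ib <- surv[b]
        if (excluded[ia] || excluded[ib]) next
        if (!is.na(ibs[a, b]) && ibs[a, b] > thresholds$ibs_max) {
          drop <- if (call_rate[ia] < call_rate[ib]) ia
                  else if (call_rate[ib] < call_rate[ia]) ib
                  else max(ia, ib)   # tie: later sample dropped
          excluded[drop] <- TRUE
          reason[drop] <- "relatedness"
        }
      }
    }
  }
  report <- data.frame(sample_id = ids, call_rate = call_rate,
                       het_rate = het_rate, het_p = het_p,
                       het_q = het_q, excluded = excluded,
                       reason = reason, stringsAsFactors = FALSE)
  list(keep = ids[!excluded], report = report)
}
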