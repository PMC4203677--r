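#' Stage 1: genome-wide gene-based scan with meta-analysis
#'
#' For every gene interval, selects qualifying rare variants per study
#' ([select_rare_variants()]), collapses them into a gene dosage, fits
#' the covariate-adjusted association regression per study
#' ([fit_gene()]) and combines the per-study Z scores by
#' sample-size-weighted meta-analysis ([weighted_z_meta()]).  Studies
#' in which a gene has no qualifying variants, or whose fit is
#' degenerate, carry `"?"` in the direction string and zero weight.
#'
#' @param cohorts Named list of [study_cohort()] objects; the list
#'   order fixes the direction-string study order.
#' @param gene_intervals Gene interval table (1-based inclusive).
#' @param maf_max,maf_min,info_min Variant selection window.
#' @param alpha Family-wise error rate for the significance flag.
#' @param n_genes_genome Denominator of the Bonferroni threshold;
#'   defaults to the number of genes scanned (use 28517 for the full
#'   genome-wide annotation).
#' @param adjust_apoe Adjust every regression for the epsilon-4
#'   covariate.
#' @param family Regression family.
#' @return A data.frame of class `stage1_table`, sorted by ascending
#'   meta P (untestable genes last): columns `gene`, `chrom`, `start`,
#'   `n_variants` (largest per-study count), `z_meta`, `p_meta`,
#'   `direction`, `n_studies_used`, `significant`.  The threshold used
#'   is stored in attribute `"threshold"`.
#' @export
stage1_scan <- function(cohorts, gene_intervals, maf_max = 0.03,
                        maf_min = 0, info_min = 0.4, alpha = 0.05,
                        n_genes_genome = NULL, adjust_apoe = FALSE,
                        family = c("logistic", "linear")) {
  family <- match.arg(family)
  stopifnot(length(cohorts) >= 1)
  if (nrow(gene_intervals) == 0) {
    warning("no genes to test")
    out <- data.frame(gene = character(), chrom = character(),
                      start = integer(), n_variants = integer(),
                      z_meta = numeric(), p_meta = numeric(),
                      direction = character(), n_studies_used = integer(),
                      significant = logical(), stringsAsFactors = FALSE)
    attr(out, "threshold") <- NA_real_
    class(out) <- c("stage1_table", class(out))
    return(out)
  }
  if (is.null(n_genes_genome)) n_genes_genome <- nrow(gene_intervals)
  threshold <- genomewide_threshold(n_genes_genome, alpha)
  n_eff <- vapply(cohorts, function(co)
    effective_sample_size(co$n_cases, co$n_controls), 0)
  sel <- lapply(cohorts, select_rare_variants, gene_intervals,
                maf_max = maf_max, maf_min = maf_min,
                info_min = info_min)
  rows <- lapply(seq_len(nrow(gene_intervals)), function(g) {
    gname <- gene_intervals$gene[g]
    z <- rep(NA_real_, length(cohorts))
    nv <- 0L
    for (s in seq_along(cohorts)) {
      ids <- sel[[s]][[gname]]
      nv <- max(nv, length(ids))
      fit <- fit_gene(cohorts[[s]], ids, gname, family = family,
                      adjust_apoe = adjust_apoe)
      if (fit$estimable) z[s] <- fit$z
    }
    m <- weighted_z_meta(z, n_eff)
    data.frame(gene = gname, chrom = gene_intervals$chrom[g],
               start = gene_intervals$start[g], n_variants = nv,
               z_meta = m$z_meta, p_meta = m$p_meta,
               direction = m$direction,
               n_studies_used = m$n_studies_used,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$significant <- !is.na(out$p_meta) & out$p_meta < threshold
  out <- out[order(out$p_meta, method = "radix", na.last = TRUE), ]
  rownames(out) <- NULL
  if (all(out$n_studies_used == 0))
    warning("no gene was testable in any study")
  attr(out, "threshold") <- threshold
  class(out) <- c("stage1_table", class(out))
  out
}

#' Stage 2: select confirmatory risk SNPs within a gene
#'
#' Runs a classical per-SNP association scan and meta-analysis over
#' every variant of the gene, then applies the three selection
#' criteria: meta P below `p_max`, meta Z positive (risk direction),
#' and study-level MAF inside `[maf_min, maf_max]` (the floor of 0.5\%
#' reflects degrading imputation accuracy at very low MAF).  The MAF
#' and INFO windows are evaluated per study: a SNP outside the window
#' in one study is `"?"` there but may still contribute elsewhere.
#'
#' @param cohorts Named list of [study_cohort()] objects.
#' @param gene_intervals Gene interval table.
#' @param gene The stage-1 gene symbol.
#' @param maf_min,maf_max Per-study MAF window (defaults 0.5\%-3\%).
#' @param info_min Per-study INFO floor.
#' @param p_max Meta P criterion.
#' @param family Regression family.
#' @return A list of class `stage2_selection`: `gene`, `snps` (per-SNP
#'   table with meta Z/P, direction and `selected` flag),
#'   `selected_ids`, `per_study` (per-SNP per-study MAF, INFO, beta,
#'   SE, P), and `status` (`"ok"` or `"no SNP passed selection"`).
#' @export
select_risk_snps <- function(cohorts, gene_intervals, gene,
                             maf_min = 0.005, maf_max = 0.03,
                             info_min = 0.4, p_max = 0.05,
                             family = c("logistic", "linear")) {
  family <- match.arg(family)
  gi <- gene_intervals[gene_intervals$gene == gene, , drop = FALSE]
  if (nrow(gi) != 1) stop("gene not found in intervals: ", gene)
  n_eff <- vapply(cohorts, function(co)
    effective_sample_size(co$n_cases, co$n_controls), 0)
  # candidate SNPs: union over studies of variants inside the interval
  cand <- unique(unlist(lapply(cohorts, function(co)
    co$variants$id[co$variants$chrom == gi$chrom &
                     co$variants$pos >= gi$start &
                     co$variants$pos <= gi$end])))
  snp_rows <- list(); per_study <- list()
  for (snp in cand) {
    z <- rep(NA_real_, length(cohorts))
    for (s in seq_along(cohorts)) {
      co <- cohorts[[s]]
      vi <- match(snp, co$variants$id)
      if (is.na(vi)) next
      maf_s <- co$variants$maf[vi]
      info_s <- co$variants$info[vi]
      in_window <- maf_s >= maf_min & maf_s <= maf_max &
        info_s >= info_min
      fit <- if (in_window)
        fit_association(co$dosage[, vi], co$samples, family = family,
                        gene = snp, study = co$study, n_variants = 1L)
      else NULL
      if (!is.null(fit) && fit$estimable) z[s] <- fit$z
      per_study[[length(per_study) + 1L]] <- data.frame(
        snp = snp, study = co$study, maf = maf_s, info = info_s,
        in_window = in_window,
        beta = if (is.null(fit)) NA_real_ else fit$beta,
        se = if (is.null(fit)) NA_real_ else fit$se,
        p = if (is.null(fit)) NA_real_ else fit$p,
        stringsAsFactors = FALSE)
    }
    m <- weighted_z_meta(z, n_eff)
    snp_rows[[length(snp_rows) + 1L]] <- data.frame(
      snp = snp, z_meta = m$z_meta, p_meta = m$p_meta,
      direction = m$direction, n_studies_used = m$n_studies_used,
      selected = !is.na(m$p_meta) && m$p_meta < p_max && m$z_meta > 0,
      stringsAsFactors = FALSE)
  }
  snps <- if (length(snp_rows)) do.call(rbind, snp_rows) else
    data.frame(snp = character(), z_meta = numeric(),
               p_meta = numeric(), direction = character(),
               n_studies_used = integer(), selected = logical(),
               stringsAsFactors = FALSE)
  structure(list(
    gene = gene, snps = snps,
    selected_ids = snps$snp[snps$selected],
    per_study = if (length(per_study)) do.call(rbind, per_study)
                else NULL,
    status = if (any(snps$selected)) "ok" else "no SNP passed selection"
  ), class = "stage2_selection")
}

#' Stage 2: confirmatory gene-based meta-analysis on selected SNPs
#'
#' Restricts the gene dosage to the selected SNPs (a SNP contributes
#' in a study only where it passes that study's MAF/INFO window),
#' refits the per-study burden regressions with and without the
#' epsilon-4 adjustment, and meta-analyzes both.  Stage 2 reuses the
#' stage-1 data, so its P values are confirmatory-in-sample, not
#' independent replication; the output labels them accordingly.
#'
#' @param cohorts Named list of [study_cohort()] objects.
#' @param selection A [select_risk_snps()] result (or a character
#'   vector of SNP ids together with `gene`).
#' @param gene Gene symbol (taken from `selection` when omitted).
#' @param maf_min,maf_max,info_min Per-study contribution window
#'   (stage-2 defaults).
#' @param family Regression family.
#' @return A list of class `stage2_confirm`: `gene`, `snp_ids`,
#'   `per_study` (per-study unadjusted/adjusted beta and P),
#'   `meta_unadjusted` and `meta_adjusted` ([weighted_z_meta()] rows),
#'   and `evidence = "confirmatory-in-sample"`.
#' @export
stage2_confirm <- function(cohorts, selection, gene = NULL,
                           maf_min = 0.005, maf_max = 0.03,
                           info_min = 0.4,
                           family = c("logistic", "linear")) {
  family <- match.arg(family)
  if (inherits(selection, "stage2_selection")) {
    gene <- selection$gene
    snp_ids <- selection$selected_ids
  } else snp_ids <- as.character(selection)
  if (length(snp_ids) == 0) stop("no selected SNPs to confirm")
  z_u <- z_a <- rep(NA_real_, length(cohorts))
  per_study <- list()
  n_eff <- vapply(cohorts, function(co)
    effective_sample_size(co$n_cases, co$n_controls), 0)
  for (s in seq_along(cohorts)) {
    co <- cohorts[[s]]
    vi <- match(snp_ids, co$variants$id)
    ok <- !is.na(vi)
    use <- ok & co$variants$maf[vi] >= maf_min &
      co$variants$maf[vi] <= maf_max & co$variants$info[vi] >= info_min
    ids <- snp_ids[which(use)]
    fu <- fit_gene(co, ids, gene, adjust_apoe = FALSE, family = family)
    fa <- fit_gene(co, ids, gene, adjust_apoe = TRUE, family = family)
    if (fu$estimable) z_u[s] <- fu$z
    if (fa$estimable) z_a[s] <- fa$z
    per_study[[s]] <- data.frame(
      study = co$study, n_snps_used = length(ids),
      beta_unadjusted = fu$beta, p_unadjusted = fu$p,
      beta_adjusted = fa$beta, p_adjusted = fa$p,
      stringsAsFactors = FALSE)
  }
  structure(list(
    gene = gene, snp_ids = snp_ids,
    per_study = do.call(rbind, per_study),
    meta_unadjusted = weighted_z_meta(z_u, n_eff),
    meta_adjusted = weighted_z_meta(z_a, n_eff),
    evidence = "confirmatory-in-sample"
  ), class = "stage2_confirm")
}

#' Look up candidate genes in a stage-1 scan table
#'
#' Extracts the rows of the requested gene symbols (e.g. the top genes
#' of a disease database) from a [stage1_scan()] table, preserving the
#' input order; absent symbols are reported separately.
#'
#' @param stage1 A `stage1_table`.
#' @param genes Character vector of gene symbols.
#' @return A list with `table` (rows in input order) and `not_found`.
#' @export
candidate_gene_lookup <- function(stage1, genes) {
  idx <- match(genes, stage1$gene)
  found <- !is.na(idx)
  tab <- stage1[idx[found], , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, not_found = genes[!found])
}

#' Run the full two-stage pipeline on a cohort set
#'
#' Convenience orchestration over a (typically simulated) cohort set:
#' variant QC per study, stage-1 genome-wide gene scan, conditional
#' epsilon-4 analysis of the top genes, stage-2 SNP selection and
#' confirmatory meta-analysis for the best gene, and a per-study
#' forest table with the effective-sample-size weights.
#'
#' @param cohort_set A [simulate_cohorts()] result, or a list with
#'   elements `cohorts` and `gene_intervals`.
#' @param n_genes_genome Bonferroni denominator (defaults to the
#'   number of genes scanned).
#' @param run_sample_qc Also run [sample_qc()] per study and drop
#'   flagged samples (off by default; the generator does not plant
#'   sample-level artefacts).
#' @param top_genes How many top genes enter the conditional analysis.
#' @param family Regression family.
#' @return A list with `qc` (per-study variant QC tables), `stage1`,
#'   `conditional`, `selection`, `confirm` (NULL when stage 1 found
#'   no testable gene), and `forest` (per-study weights for the top
#'   gene).
#' @export
run_pipeline <- function(cohort_set, n_genes_genome = NULL,
                         run_sample_qc = FALSE, top_genes = 3L,
                         family = c("logistic", "linear")) {
  family <- match.arg(family)
  cohorts <- cohort_set$cohorts
  gene_intervals <- cohort_set$gene_intervals
  qc <- lapply(cohorts, variant_qc)
  cohorts <- lapply(seq_along(cohorts), function(s) {
    co <- subset_cohort(cohorts[[s]], variants = which(qc[[s]]$keep))
    if (run_sample_qc) {
      sq <- sample_qc(co)
      co <- subset_cohort(co, samples = match(sq$keep,
                                              co$samples$sample_id))
    }
    co
  })
  names(cohorts) <- names(cohort_set$cohorts)
  stage1 <- stage1_scan(cohorts, gene_intervals,
                        n_genes_genome = n_genes_genome,
                        family = family)
  testable <- stage1$gene[!is.na(stage1$p_meta)]
  if (length(testable) == 0)
    return(list(qc = qc, stage1 = stage1, conditional = NULL,
                selection = NULL, confirm = NULL, forest = NULL))
  top <- head(testable, top_genes)
  conditional <- adjusted_scan(cohorts, gene_intervals, top,
                               family = family)
  selection <- select_risk_snps(cohorts, gene_intervals, top[1],
                                family = family)
  confirm <- if (length(selection$selected_ids))
    stage2_confirm(cohorts, selection, family = family) else NULL
  forest <- data.frame(
    study = vapply(cohorts, `[[`, "", "study"),
    n_cases = vapply(cohorts, `[[`, 0L, "n_cases"),
    n_controls = vapply(cohorts, `[[`, 0L, "n_controls"),
    weight = vapply(cohorts, function(co)
      effective_sample_size(co$n_cases, co$n_controls), 0),
    stringsAsFactors = FALSE)
  rownames(forest) <- NULL
  list(qc = qc, stage1 = stage1, conditional = conditional,
       selection = selection, confirm = confirm, forest = forest)
}
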