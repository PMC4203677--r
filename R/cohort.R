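#' Assemble and validate a per-study cohort
#'
#' A `study_cohort` holds one study's dosage matrix (samples x
#' variants, entries in `[0, 2]`, `NA` = missing), the variant metadata
#' table, the sample covariate/phenotype table, case/control counts and
#' optionally the genotyped hard-call matrix used by sample-level QC.
#'
#' @param study Study label.
#' @param dosage Numeric matrix, samples x variants; entries in
#'   `[0, 2]` or `NA`.
#' @param variants data.frame with columns `id`, `chrom`, `pos`,
#'   `ref`, `alt`, `maf`, `info`, `type` (`"genotyped"` or
#'   `"imputed"`); one row per dosage column.
#' @param samples Optional data.frame with columns `sample_id`,
#'   `status` (1 = case, 0 = control) and covariates; one row per
#'   dosage row.
#' @param n_cases,n_controls Case/control counts; derived from
#'   `samples$status` when omitted.
#' @param hardcall Optional integer matrix of hard calls in
#'   \{0, 1, 2\} (`NA` = missing), same shape as `dosage`.
#' @return An object of class `study_cohort`.
#' @export
study_cohort <- function(study, dosage, variants, samples = NULL,
                         n_cases = NULL, n_controls = NULL,
                         hardcall = NULL) {
  stopifnot(is.matrix(dosage), is.data.frame(variants))
  if (ncol(dosage) != nrow(variants))
    stop("dosage has ", ncol(dosage), " columns but variants has ",
         nrow(variants), " rows")
  if (length(dosage) && any(dosage < 0 | dosage > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  need <- c("id", "chrom", "pos", "maf", "info")
  miss <- setdiff(need, names(variants))
  if (length(miss))
    stop("variants table lacks column(s): ", paste(miss, collapse = ", "))
  if (!"type" %in% names(variants)) variants$type <- "imputed"
  if (is.null(colnames(dosage)) && nrow(variants) > 0)
    colnames(dosage) <- variants$id
  if (!is.null(samples)) {
    if (nrow(samples) != nrow(dosage))
      stop("samples table has ", nrow(samples), " rows but dosage has ",
           nrow(dosage))
    if (!all(c("sample_id", "status") %in% names(samples)))
      stop("samples table needs sample_id and status columns")
    if (is.null(n_cases)) n_cases <- sum(samples$status == 1)
    if (is.null(n_controls)) n_controls <- sum(samples$status == 0)
    if (n_cases + n_controls != nrow(samples))
      stop("n_cases + n_controls must equal the sample count")
  }
  if (!is.null(hardcall)) {
    stopifnot(identical(dim(hardcall), dim(dosage)))
    if (!all(hardcall %in% c(0L, 1L, 2L, NA)))
      stop("hardcall entries must be in {0, 1, 2} or NA")
  }
  structure(list(study = study, dosage = dosage, variants = variants,
                 samples = samples, n_cases = n_cases,
                 n_controls = n_controls, hardcall = hardcall),
            class = "study_cohort")
}

#' @export
print.study_cohort <- function(x, ...) {
  cat(sprintf("study_cohort '%s': %d samples (%s cases / %s controls), %d variants\n",
              x$study, nrow(x$dosage),
              if (is.null(x$n_cases)) "?" else x$n_cases,
              if (is.null(x$n_controls)) "?" else x$n_controls,
              ncol(x$dosage)))
  invisible(x)
}

#' Subset a cohort by variants and/or samples
#'
#' @param cohort A [study_cohort()].
#' @param variants Variant ids (or logical/integer index) to keep.
#' @param samples Sample ids (or logical/integer index) to keep.
#' @return The subsetted [study_cohort()].
#' @export
subset_cohort <- function(cohort, variants = NULL, samples = NULL) {
  stopifnot(inherits(cohort, "study_cohort"))
  vi <- if (is.null(variants)) seq_len(ncol(cohort$dosage))
        else if (is.character(variants)) match(variants, cohort$variants$id)
        else variants
  si <- if (is.null(samples)) seq_len(nrow(cohort$dosage))
        else if (is.character(samples)) match(samples, cohort$samples$sample_id)
        else samples
  if (anyNA(vi)) stop("unknown variant id(s)")
  if (anyNA(si)) stop("unknown sample id(s)")
  study_cohort(
    study = cohort$study,
    dosage = cohort$dosage[si, vi, drop = FALSE],
    variants = cohort$variants[vi, , drop = FALSE],
    samples = if (is.null(cohort$samples)) NULL
              else cohort$samples[si, , drop = FALSE],
    hardcall = if (is.null(cohort$hardcall)) NULL
               else cohort$hardcall[si, vi, drop = FALSE]
  )
}
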