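#' Write a study cohort to disk
#'
#' Serializes a [study_cohort()] in one of two dosage formats plus a
#' covariate TSV.  `format = "vcf"` writes a VCF 4.2 file with a
#' per-sample `DS` (dosage) FORMAT field and per-variant `MAF=`,
#' `INFO=` and `TYPED` keys in the INFO column.  `format = "gen"`
#' writes an IMPUTE2-style `.gen` (three genotype probabilities per
#' sample) with companion `.sample` and `.gen_info` files; the
#' probability triple is the minimal-entropy triple consistent with the
#' dosage.  Dosages are written with 3 decimals; variant metadata
#' round-trips exactly.
#'
#' @param cohort A [study_cohort()].
#' @param dir Output directory (created if needed).
#' @param format `"vcf"` or `"gen"`.
#' @return Invisibly, the character vector of files written.
#' @seealso [read_dosages()], [read_study()]
#' @export
write_study <- function(cohort, dir, format = c("vcf", "gen")) {
  stopifnot(inherits(cohort, "study_cohort"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, cohort$study)
  files <- switch(format,
                  vcf = write_dosage_vcf(cohort, paste0(base, ".vcf")),
                  gen = write_dosage_gen(cohort, base))
  if (!is.null(cohort$samples)) {
    covf <- paste0(base, ".covar.tsv")
    write.table(cohort$samples, covf, sep = "\t", quote = FALSE,
                row.names = FALSE)
    files <- c(files, covf)
  }
  invisible(files)
}

fmt_num <- function(x) sprintf("%.17g", x)

write_dosage_vcf <- function(cohort, path) {
  v <- cohort$variants
  ids <- if (is.null(cohort$samples)) {
    rn <- rownames(cohort$dosage)
    if (is.null(rn)) sprintf("S%04d", seq_len(nrow(cohort$dosage))) else rn
  } else cohort$samples$sample_id
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=rareburden (study %s)", cohort$study),
    "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Minor allele frequency\">",
    "##INFO=<ID=INFO,Number=1,Type=Float,Description=\"Imputation quality score\">",
    "##INFO=<ID=TYPED,Number=0,Type=Flag,Description=\"Directly genotyped variant\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Estimated alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", ids), collapse = "\t")
  )
  lines <- hdr
  if (nrow(v) > 0) {
    info_col <- paste0("MAF=", fmt_num(v$maf), ";INFO=", fmt_num(v$info),
                       ifelse(v$type == "genotyped", ";TYPED", ""))
    ds <- apply(cohort$dosage, 2, function(col)
      ifelse(is.na(col), ".", sprintf("%.3f", col)))
    ds <- matrix(ds, ncol = nrow(v))  # samples x variants even for n=1
    body <- vapply(seq_len(nrow(v)), function(j)
      paste(c(v$chrom[j], v$pos[j], v$id[j], v$ref[j], v$alt[j], ".",
              "PASS", info_col[j], "DS", ds[, j]), collapse = "\t"), "")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  path
}

# dosage -> probability triple (P(0), P(1), P(2)) with matching mean
dosage_to_probs <- function(d) {
  p2 <- pmax(d - 1, 0)
  p1 <- ifelse(d <= 1, d, 2 - d)
  p0 <- pmax(1 - d, 0)
  cbind(p0, p1, p2)
}

write_dosage_gen <- function(cohort, base) {
  v <- cohort$variants
  ids <- if (is.null(cohort$samples)) {
    rn <- rownames(cohort$dosage)
    if (is.null(rn)) sprintf("S%04d", seq_len(nrow(cohort$dosage))) else rn
  } else cohort$samples$sample_id
  genf <- paste0(base, ".gen")
  samf <- paste0(base, ".sample")
  inff <- paste0(base, ".gen_info")
  n <- nrow(cohort$dosage)
  lines <- character(0)
  if (nrow(v) > 0) {
    lines <- vapply(seq_len(nrow(v)), function(j) {
      d <- cohort$dosage[, j]
      pr <- dosage_to_probs(ifelse(is.na(d), 0, d))
      # missing dosage encoded as the all-zero probability triple
      pr[is.na(d), ] <- 0
      paste(c(v$chrom[j], v$id[j], v$pos[j], v$ref[j], v$alt[j],
              sprintf("%.4f", t(pr))), collapse = " ")
    }, "")
  }
  writeLines(lines, genf)
  writeLines(c("ID_1 ID_2 missing", "0 0 0",
               if (n > 0) paste(ids, ids, "0")), samf)
  info_df <- data.frame(id = v$id, maf = fmt_num(v$maf),
                        info = fmt_num(v$info), type = v$type)
  write.table(info_df, inff, sep = "\t", quote = FALSE, row.names = FALSE)
  c(genf, samf, inff)
}

#' Write gene intervals as a BED file
#'
#' Internal 1-based inclusive intervals are converted to BED's 0-based
#' half-open convention on write.
#'
#' @param gene_intervals data.frame with columns `gene`, `chrom`,
#'   `start`, `end` (1-based inclusive).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gene_intervals <- function(gene_intervals, path) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in%
                names(gene_intervals)))
  bed <- data.frame(chrom = gene_intervals$chrom,
                    start = gene_intervals$start - 1L,
                    end = gene_intervals$end,
                    name = gene_intervals$gene)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
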