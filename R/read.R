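#' Read a dosage file into a cohort (without covariates)
#'
#' Parses either a VCF 4.2 file whose FORMAT includes a `DS` dosage
#' field, or an IMPUTE2-style `.gen` file (with companion `.sample`
#' and, if present, `.gen_info` files next to it).  Dosages are
#' validated to lie in `[0, 2]`; missing dosages become `NA`, never 0.
#' Malformed or truncated records raise an error naming the offending
#' line.
#'
#' @param path Path to the `.vcf` or `.gen` file.
#' @param format `"vcf"` or `"gen"`; guessed from the file extension
#'   when omitted.
#' @param study Study label; defaults to the file's base name.
#' @return A [study_cohort()] without a samples table (`n_cases` /
#'   `n_controls` unset); attach covariates with [read_covariates()]
#'   or use [read_study()].
#' @export
read_dosages <- function(path, format = NULL, study = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format))
    format <- if (grepl("\\.vcf$", path)) "vcf"
              else if (grepl("\\.gen$", path)) "gen"
              else stop("cannot guess format of ", path)
  format <- match.arg(format, c("vcf", "gen"))
  if (is.null(study))
    study <- sub("\\.(vcf|gen)$", "", basename(path))
  switch(format,
         vcf = read_dosage_vcf(path, study),
         gen = read_dosage_gen(path, study))
}

parse_info_field <- function(info, key) {
  m <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
  out <- rep(NA_real_, length(info))
  hit <- lengths(regmatches(info, gregexpr(paste0("(^|;)", key, "="),
                                           info))) > 0
  out[hit] <- as.numeric(sub(paste0(".*", key, "="), "", m))
  out
}

read_dosage_vcf <- function(path, study) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "##")
  hdr_i <- which(startsWith(lines, "#CHROM"))
  if (length(hdr_i) != 1)
    stop("not a VCF: missing #CHROM header line in ", path)
  hdr <- strsplit(lines[hdr_i], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 9)
    stop("line ", hdr_i, ": VCF header has fewer than 9 columns")
  sample_ids <- hdr[-(1:9)]
  body_i <- setdiff(which(!is_meta), hdr_i)
  n_fields <- length(hdr)
  vrows <- list(); dcols <- list()
  for (k in seq_along(body_i)) {
    i <- body_i[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != n_fields)
      stop("line ", i, ": expected ", n_fields, " fields, found ",
           length(f), " (truncated or malformed record)")
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    ds_i <- match("DS", fmt)
    if (is.na(ds_i))
      stop("line ", i, ": FORMAT has no DS dosage field")
    vals <- vapply(strsplit(f[-(1:9)], ":", fixed = TRUE),
                   `[`, "", ds_i)
    d <- suppressWarnings(as.numeric(ifelse(vals == ".", NA, vals)))
    if (any(is.na(d) & vals != "."))
      stop("line ", i, ": non-numeric dosage value")
    if (any(d < 0 | d > 2, na.rm = TRUE))
      stop("line ", i, ": dosage outside [0, 2] for variant ", f[3])
    vrows[[k]] <- data.frame(
      id = f[3], chrom = f[1], pos = as.integer(f[2]),
      ref = f[4], alt = f[5],
      maf = parse_info_field(f[8], "MAF"),
      info = parse_info_field(f[8], "INFO"),
      type = if (grepl("(^|;)TYPED(;|$)", f[8])) "genotyped" else "imputed",
      stringsAsFactors = FALSE
    )
    dcols[[k]] <- d
  }
  assemble_read_cohort(study, vrows, dcols, sample_ids)
}

read_dosage_gen <- function(path, study) {
  samf <- sub("\\.gen$", ".sample", path)
  if (!file.exists(samf)) stop("companion .sample file not found: ", samf)
  sam <- readLines(samf)
  if (length(sam) < 2) stop("malformed .sample file: ", samf)
  sample_ids <- vapply(strsplit(sam[-(1:2)], "[ \t]+"), `[`, "", 1)
  n <- length(sample_ids)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vrows <- list(); dcols <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 5 + 3 * n)
      stop("line ", i, ": expected ", 5 + 3 * n, " fields (5 + 3 per sample), found ",
           length(f), " (truncated or malformed record)")
    pr <- matrix(as.numeric(f[-(1:5)]), ncol = 3, byrow = TRUE)
    if (anyNA(pr)) stop("line ", i, ": non-numeric genotype probability")
    tot <- rowSums(pr)
    d <- ifelse(tot == 0, NA_real_, pr[, 2] + 2 * pr[, 3])
    if (any(d < 0 | d > 2, na.rm = TRUE))
      stop("line ", i, ": dosage outside [0, 2] for variant ", f[2])
    vrows[[i]] <- data.frame(
      id = f[2], chrom = f[1], pos = as.integer(f[3]),
      ref = f[4], alt = f[5], maf = NA_real_, info = NA_real_,
      type = "imputed", stringsAsFactors = FALSE
    )
    dcols[[i]] <- d
  }
  cohort <- assemble_read_cohort(study, vrows, dcols, sample_ids)
  inff <- sub("\\.gen$", ".gen_info", path)
  if (file.exists(inff)) {
    inf <- read.table(inff, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
    idx <- match(cohort$variants$id, inf$id)
    cohort$variants$maf <- as.numeric(inf$maf[idx])
    cohort$variants$info <- as.numeric(inf$info[idx])
    cohort$variants$type <- inf$type[idx]
  }
  cohort
}

assemble_read_cohort <- function(study, vrows, dcols, sample_ids) {
  if (length(vrows) == 0) {
    variants <- data.frame(id = character(), chrom = character(),
                           pos = integer(), ref = character(),
                           alt = character(), maf = numeric(),
                           info = numeric(), type = character(),
                           stringsAsFactors = FALSE)
    dosage <- matrix(numeric(0), nrow = length(sample_ids), ncol = 0,
                     dimnames = list(sample_ids, NULL))
    return(study_cohort(study, dosage, variants))
  }
  variants <- do.call(rbind, vrows)
  dosage <- do.call(cbind, dcols)
  dimnames(dosage) <- list(sample_ids, variants$id)
  # fall back to the dosage-estimated MAF when the file carries none
  no_maf <- is.na(variants$maf)
  if (any(no_maf))
    variants$maf[no_maf] <- apply(dosage[, no_maf, drop = FALSE], 2,
                                  function(d) {
                                    p <- mean(d, na.rm = TRUE) / 2
                                    min(p, 1 - p)
                                  })
  variants$info[is.na(variants$info)] <- 1
  study_cohort(study, dosage, variants)
}

#' Read gene intervals from a BED file
#'
#' BED's 0-based half-open coordinates are converted to the package's
#' internal 1-based inclusive convention: a BED line
#' `chr19 100 200 GENE1` becomes the interval `[101, 200]`.  A variant
#' belongs to a gene iff `start <= pos <= end`; overlapping genes are
#' allowed (a variant may belong to several genes).
#'
#' @param path Path to a BED file (columns chrom, start, end, name).
#' @return data.frame with columns `gene`, `chrom`, `start`, `end`.
#' @export
read_gene_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    return(data.frame(gene = character(), chrom = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "[ \t]+")
  bad <- which(lengths(f) < 4)
  if (length(bad))
    stop("line ", bad[1], ": BED record needs 4 fields (chrom start end name)")
  start0 <- as.integer(vapply(f, `[`, "", 2))
  end0 <- as.integer(vapply(f, `[`, "", 3))
  bad <- which(start0 >= end0)
  if (length(bad))
    stop("line ", bad[1], ": BED start must be less than end")
  data.frame(gene = vapply(f, `[`, "", 4),
             chrom = vapply(f, `[`, "", 1),
             start = start0 + 1L, end = end0,
             stringsAsFactors = FALSE)
}

#' Categorize years of education
#'
#' Maps years of schooling to the four-level scheme used for
#' cross-study harmonization: category 1 for at most 4 years, 2 for
#' more than 4 and at most 10, 3 for more than 10 and at most 15, and
#' 4 beyond 15 years.
#'
#' @param years Numeric vector of years of education (NA allowed).
#' @return Integer categories in 1-4.
#' @export
categorize_education <- function(years) {
  as.integer(cut(years, breaks = c(-Inf, 4, 10, 15, Inf),
                 labels = FALSE))
}

#' Read a sample covariate/phenotype table
#'
#' Expects a TSV with header columns `sample_id`, `status` (1 = case,
#' 0 = control), `age`, `sex`, and either `edu` (categories 1-4) or
#' `edu_years` (years, converted via [categorize_education()]).
#' Optional columns: `PC1`, `PC2`, ... and `apoe_e4` (count) or
#' `apoe_e4_dosage`.  Missing education is imputed to the study mean
#' category and education is treated as a single continuous covariate
#' downstream.
#'
#' @param path Path to the TSV file.
#' @return data.frame of covariates with education categorized and
#'   mean-imputed; the number of imputed values is recorded in the
#'   `"n_edu_imputed"` attribute.
#' @export
read_covariates <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- read.table(path, header = TRUE, sep = "\t",
                  stringsAsFactors = FALSE)
  for (col in c("sample_id", "status", "age", "sex"))
    if (!col %in% names(x))
      stop("covariate table lacks required column: ", col)
  if (!"edu" %in% names(x)) {
    if (!"edu_years" %in% names(x))
      stop("covariate table lacks required column: edu (or edu_years)")
    x$edu <- categorize_education(x$edu_years)
  }
  n_miss <- sum(is.na(x$edu))
  x <- impute_education(x)
  attr(x, "n_edu_imputed") <- n_miss
  x
}

# mean-impute missing education categories (single continuous covariate)
impute_education <- function(samples) {
  miss <- is.na(samples$edu)
  if (any(miss)) {
    if (all(miss)) stop("education is missing for every sample")
    samples$edu <- as.numeric(samples$edu)
    samples$edu[miss] <- mean(samples$edu[!miss])
  }
  samples
}

#' Read a complete study (dosages + covariates) from a directory
#'
#' Convenience wrapper pairing [read_dosages()] with
#' [read_covariates()] for files written by [write_study()]:
#' `<study>.vcf` (or `.gen`/`.sample`) and `<study>.covar.tsv`.
#'
#' @param dir Directory containing the study files.
#' @param study Study label (file base name).
#' @param format `"vcf"` or `"gen"`.
#' @return A [study_cohort()] with the samples table attached.
#' @export
read_study <- function(dir, study, format = c("vcf", "gen")) {
  format <- match.arg(format)
  dosf <- file.path(dir, paste0(study, ".", format))
  cohort <- read_dosages(dosf, format, study = study)
  covf <- file.path(dir, paste0(study, ".covar.tsv"))
  if (file.exists(covf)) {
    samples <- read_covariates(covf)
    idx <- match(rownames(cohort$dosage), samples$sample_id)
    if (anyNA(idx))
      stop("samples in ", dosf, " missing from ", covf)
    samples <- samples[idx, , drop = FALSE]
    rownames(samples) <- NULL
    cohort <- study_cohort(cohort$study, cohort$dosage, cohort$variants,
                           samples = samples, hardcall = cohort$hardcall)
  }
  cohort
}
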