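#' @title Synthetic multi-study cohort generation
#' @name simulate
#' @description
#' The generator draws population individuals under Hardy-Weinberg
#' proportions, assigns case/control status from a logistic disease
#' model, ascertains each study to its configured case/control quotas
#' by rejection sampling, and finally degrades the true genotypes into
#' imputed dosages with a per-variant INFO quality score.  Ground truth
#' (true genotypes, linear predictors, causal flags) is retained for
#' parameter-recovery and calibration tests.
NULL

# variant table + gene intervals on a synthetic coordinate system:
# gene g occupies [(g-1)*20000 + 1, (g-1)*20000 + 10000] on chrom "1"
sim_variant_table <- function(config) {
  gene_len <- 10000L
  gene_gap <- 20000L
  m_per_gene <- sample(config$variants_per_gene[1]:config$variants_per_gene[2],
                       config$n_genes, replace = TRUE)
  genes <- data.frame(
    gene = config$gene_ids,
    chrom = "1",
    start = (seq_len(config$n_genes) - 1L) * gene_gap + 1L,
    end = (seq_len(config$n_genes) - 1L) * gene_gap + gene_len,
    stringsAsFactors = FALSE
  )
  sp <- config$maf_spectrum
  draw_maf <- function(k) {
    if (sp$min == sp$max) return(rep(sp$min, k))  # point-mass spectrum
    # truncated beta: redraw values outside [min, max]
    x <- rbeta(k, sp$shape1, sp$shape2)
    bad <- x < sp$min | x > sp$max
    while (any(bad)) {
      x[bad] <- rbeta(sum(bad), sp$shape1, sp$shape2)
      bad <- x < sp$min | x > sp$max
    }
    x
  }
  rows <- lapply(seq_len(config$n_genes), function(g) {
    m <- m_per_gene[g]
    pos <- sort(sample(genes$start[g]:genes$end[g], m))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), "")
    data.frame(
      id = paste0(config$gene_ids[g], "_", seq_len(m)),
      chrom = "1", pos = pos, ref = ref, alt = alt,
      maf_pop = draw_maf(m), gene = config$gene_ids[g],
      stringsAsFactors = FALSE
    )
  })
  variants <- do.call(rbind, rows)
  rownames(variants) <- NULL
  list(variants = variants, gene_intervals = genes)
}

# n x m genotype matrix under HWE at the population MAFs; columns of the
# LD-linked gene (if any) are drawn conditional on the confounder count
sim_geno_matrix <- function(n, variants, config, e4 = NULL) {
  m <- nrow(variants)
  G <- matrix(rbinom(n * m, 2L, rep(variants$maf_pop, each = n)),
              nrow = n, ncol = m)
  if (!is.null(config$confounder_ld_gene) && !is.null(e4)) {
    ld_cols <- which(variants$gene == config$confounder_ld_gene)
    for (j in ld_cols) {
      # allele occurs only on confounder haplotypes: marginal freq
      # f * q = maf as long as maf <= f
      q <- min(1, variants$maf_pop[j] / config$confounder_maf)
      G[, j] <- rbinom(n, e4, q)
    }
  }
  colnames(G) <- variants$id
  storage.mode(G) <- "integer"
  G
}

sim_covariates <- function(n, config) {
  edu <- sample.int(4L, n, replace = TRUE, prob = config$edu_probs)
  data.frame(
    age = round(rnorm(n, 75, 6), 1),
    sex = rbinom(n, 1L, 0.5),
    edu = edu,
    matrix(rnorm(n * config$n_pcs), nrow = n,
           dimnames = list(NULL, paste0("PC", seq_len(config$n_pcs)))),
    apoe_e4 = rbinom(n, 2L, config$confounder_maf)
  )
}

# per-sample true gene dosage D = mean true genotype over a gene's variants
true_gene_dosage <- function(G, variants, gene) {
  cols <- which(variants$gene == gene)
  rowMeans(G[, cols, drop = FALSE])
}

sim_linear_predictor <- function(G, covars, variants, config) {
  eff <- config$covariate_effects
  lp <- config$intercept +
    eff[["age"]] * (covars$age - 75) +
    eff[["sex"]] * covars$sex +
    eff[["edu"]] * covars$edu +
    config$confounder_log_or * covars$apoe_e4
  if (config$n_pcs > 0) {
    pcs <- as.matrix(covars[, paste0("PC", seq_len(config$n_pcs)),
                            drop = FALSE])
    lp <- lp + drop(pcs %*% rep(eff[["pc"]], config$n_pcs))
  }
  for (k in seq_along(config$causal_genes))
    lp <- lp + config$causal_log_or[k] *
      true_gene_dosage(G, variants, config$causal_genes[k])
  as.numeric(lp)
}

#' Draw true genotypes for every study under Hardy-Weinberg proportions
#'
#' Lays out `n_genes` contiguous gene intervals on a synthetic
#' coordinate system, draws a population MAF per variant from the
#' configured spectrum, and samples unascertained genotype matrices of
#' size (cases + controls) per study.  Intended for inspecting the
#' genotype model on its own; [simulate_cohorts()] is the full
#' generator including ascertainment and imputation noise.
#'
#' @param config A [sim_config()] object.
#' @return A list with `variants` (data.frame: id, chrom, pos, ref,
#'   alt, maf_pop, gene), `gene_intervals` (data.frame: gene, chrom,
#'   start, end; 1-based inclusive), and `genotypes` (named list of
#'   integer matrices in \{0,1,2\}, one per study).
#' @examples
#' g <- simulate_true_genotypes(sim_config(study_names = "A",
#'         n_cases = 50, n_controls = 50, n_genes = 3, seed = 7))
#' dim(g$genotypes$A)
#' @export
simulate_true_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vt <- sim_variant_table(config)
  genos <- lapply(seq_len(config$n_studies), function(s) {
    n <- config$n_cases[s] + config$n_controls[s]
    e4 <- rbinom(n, 2L, config$confounder_maf)
    G <- sim_geno_matrix(n, vt$variants, config, e4 = e4)
    redraw_monomorphic(G, vt$variants, config, e4 = e4)
  })
  names(genos) <- config$study_names
  list(variants = vt$variants, gene_intervals = vt$gene_intervals,
       genotypes = genos)
}

# redraw monomorphic columns (up to 100 attempts each), leaving causal
# and LD-linked gene columns untouched so truth stays consistent
redraw_monomorphic <- function(G, variants, config, e4 = NULL) {
  protected <- variants$gene %in%
    c(config$causal_genes, config$confounder_ld_gene)
  n <- nrow(G)
  for (j in seq_len(ncol(G))) {
    if (protected[j]) next
    tries <- 0L
    while (length(unique(G[, j])) == 1L && tries < 100L) {
      G[, j] <- rbinom(n, 2L, variants$maf_pop[j])
      tries <- tries + 1L
    }
  }
  G
}

#' Assign case/control status and ascertain a study to its quotas
#'
#' Computes each pool individual's disease probability from the
#' logistic model (intercept + causal gene dosages + confounder +
#' covariates), draws status, and keeps individuals in draw order until
#' the study's configured case and control counts are both reached.  If
#' the supplied pool is too small, additional population individuals
#' are drawn internally; after a bounded number of augmentation rounds
#' an error is raised (unreachable quotas, e.g. an extreme intercept).
#'
#' @param genotypes Integer matrix of true genotypes (pool individuals
#'   x variants), as from [simulate_true_genotypes()].
#' @param variants The matching variant table.
#' @param config A [sim_config()] object.
#' @param study Study index or name selecting the quotas.
#' @param covariates Optional pre-drawn covariate table for the pool
#'   (drawn internally when `NULL`).
#' @param max_rounds Maximum number of augmentation rounds.
#' @return A list with `samples` (covariate/phenotype data.frame with
#'   `status` 1 = case), `genotypes` (rows aligned with `samples`), and
#'   `lp` (true linear predictors).  Cases come first, then controls.
#' @export
simulate_phenotypes <- function(genotypes, variants, config, study = 1L,
                                covariates = NULL, max_rounds = 100L) {
  stopifnot(inherits(config, "sim_config"))
  if (is.character(study)) study <- match(study, config$study_names)
  n_ca <- config$n_cases[study]
  n_co <- config$n_controls[study]
  pool_g <- genotypes
  pool_cov <- if (is.null(covariates)) {
    cv <- sim_covariates(nrow(pool_g), config)
    if (!is.null(config$confounder_ld_gene)) {
      # LD-linked columns must be conditional on this pool's e4 counts
      ld <- which(variants$gene == config$confounder_ld_gene)
      for (j in ld) {
        q <- min(1, variants$maf_pop[j] / config$confounder_maf)
        pool_g[, j] <- rbinom(nrow(pool_g), cv$apoe_e4, q)
      }
    }
    cv
  } else covariates
  keep_g <- keep_cov <- keep_lp <- keep_status <- NULL
  got_ca <- got_co <- 0L
  round <- 0L
  repeat {
    lp <- sim_linear_predictor(pool_g, pool_cov, variants, config)
    status <- rbinom(nrow(pool_g), 1L, plogis(lp))
    take_ca <- which(status == 1L)[seq_len(min(n_ca - got_ca, sum(status == 1L)))]
    take_co <- which(status == 0L)[seq_len(min(n_co - got_co, sum(status == 0L)))]
    take <- c(take_ca, take_co)
    keep_g <- rbind(keep_g, pool_g[take, , drop = FALSE])
    keep_cov <- rbind(keep_cov, pool_cov[take, , drop = FALSE])
    keep_lp <- c(keep_lp, lp[take])
    keep_status <- c(keep_status, status[take])
    got_ca <- got_ca + length(take_ca)
    got_co <- got_co + length(take_co)
    if (got_ca >= n_ca && got_co >= n_co) break
    round <- round + 1L
    if (round >= max_rounds)
      stop("could not reach ", n_ca, " cases / ", n_co, " controls after ",
           max_rounds, " sampling rounds; check intercept and effects")
    n_new <- max(1000L, n_ca + n_co)
    pool_cov <- sim_covariates(n_new, config)
    pool_g <- sim_geno_matrix(n_new, variants, config,
                              e4 = pool_cov$apoe_e4)
  }
  ord <- order(-keep_status)  # cases first, stable
  keep_g <- keep_g[ord, , drop = FALSE]
  keep_cov <- keep_cov[ord, , drop = FALSE]
  samples <- data.frame(
    sample_id = sprintf("%s_S%04d", config$study_names[study],
                        seq_len(nrow(keep_cov))),
    status = keep_status[ord],
    keep_cov,
    stringsAsFactors = FALSE
  )
  # mask education after the linear predictor used the true value
  if (config$edu_missing_rate > 0) {
    miss <- runif(nrow(samples)) < config$edu_missing_rate
    samples$edu[miss] <- NA_integer_
  }
  rownames(samples) <- NULL
  rownames(keep_g) <- samples$sample_id
  list(samples = samples, genotypes = keep_g, lp = keep_lp[ord])
}

#' Degrade true genotypes into imputed dosages with an INFO score
#'
#' Emulates genotype imputation uncertainty with a parametric
#' miscall model: with probability `imputation_error` a variant's hard
#' call is replaced by a random Hardy-Weinberg draw at the estimated
#' allele frequency, and every reported dosage is the posterior mean
#' `(1 - e) * call + e * 2 * theta`.  The per-variant INFO score is
#' `1 - mean(posterior variance) / (2 * theta * (1 - theta))`, the
#' ratio-of-variances quality measure of imputation pipelines, clamped
#' to `[0, 1]`; monomorphic variants get INFO 0 by convention.
#'
#' @param genotypes Integer matrix in \{0,1,2\} (samples x variants).
#' @param imputation_error Miscall rate(s) in `[0, 0.5)`: a scalar, a
#'   length-2 range (per-variant rates drawn uniformly), or one value
#'   per variant.
#' @return A list with `dosage` (numeric matrix in `[0, 2]`), `info`
#'   (per-variant quality in `[0, 1]`) and `error_rates` (the
#'   per-variant rates used).
#' @examples
#' g <- matrix(rbinom(200, 2, 0.1), 100, 2)
#' noiseless <- apply_imputation_noise(g, 0)
#' stopifnot(identical(noiseless$dosage, g + 0), all(noiseless$info == 1))
#' @export
apply_imputation_noise <- function(genotypes, imputation_error) {
  if (!all(genotypes %in% c(0L, 1L, 2L)))
    stop("genotypes must be hard calls in {0, 1, 2}")
  m <- ncol(genotypes)
  n <- nrow(genotypes)
  err <- imputation_error
  if (any(err < 0) || any(err >= 0.5))
    stop("imputation_error must lie in [0, 0.5)")
  rates <- if (length(err) == 1L) rep(err, m)
           else if (length(err) == 2L) runif(m, err[1], err[2])
           else if (length(err) == m) as.numeric(err)
           else stop("imputation_error must be scalar, a range, or per-variant")
  dosage <- matrix(0, n, m, dimnames = dimnames(genotypes))
  info <- numeric(m)
  for (j in seq_len(m)) {
    g <- genotypes[, j]
    theta <- mean(g) / 2
    e <- rates[j]
    if (theta <= 0 || theta >= 1) {      # monomorphic: nothing to impute
      dosage[, j] <- as.numeric(g)
      info[j] <- 0
      next
    }
    obs <- g
    if (e > 0) {
      flip <- runif(n) < e
      obs[flip] <- rbinom(sum(flip), 2L, theta)
    }
    d <- (1 - e) * obs + e * 2 * theta
    m2 <- (1 - e) * obs^2 + e * (2 * theta * (1 - theta) + 4 * theta^2)
    pvar <- pmax(m2 - d^2, 0)
    theta_d <- mean(d) / 2
    denom <- 2 * theta_d * (1 - theta_d)
    info[j] <- if (denom <= 0) 0 else
      min(1, max(0, 1 - mean(pvar) / denom))
    dosage[, j] <- d
  }
  names(info) <- colnames(genotypes)
  list(dosage = dosage, info = info, error_rates = rates)
}

#' Generate a complete multi-study synthetic cohort set
#'
#' Runs the full generator: variant table and gene intervals, per-study
#' ascertained case/control samples with covariates and an APOE
#' \eqn{\varepsilon}4-like confounder, true genotypes (kept as the
#' hard-call matrix), and imputed dosages with per-variant INFO.
#' Deterministic given `config$seed`.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `cohort_set`: a list with `cohorts`
#'   (named list of [study_cohort()] objects), `gene_intervals`,
#'   `variants` (population-level table with true MAFs), `truth`
#'   (causal gene ids and log ORs, per-study linear predictors), and
#'   `config`.
#' @examples
#' cs <- simulate_cohorts(sim_config(study_names = c("A", "B"),
#'         n_cases = c(60, 40), n_controls = c(60, 80),
#'         n_genes = 5, seed = 3))
#' names(cs$cohorts)
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  vt <- sim_variant_table(config)
  cohorts <- list()
  lps <- list()
  for (s in seq_len(config$n_studies)) {
    n_tot <- config$n_cases[s] + config$n_controls[s]
    # initial pool sized generously; simulate_phenotypes augments if short
    pool_n <- max(2L * n_tot, 500L)
    pool_cov <- sim_covariates(pool_n, config)
    pool_g <- sim_geno_matrix(pool_n, vt$variants, config,
                              e4 = pool_cov$apoe_e4)
    ph <- simulate_phenotypes(pool_g, vt$variants, config, study = s,
                              covariates = pool_cov)
    G <- redraw_monomorphic(ph$genotypes, vt$variants, config,
                            e4 = ph$samples$apoe_e4)
    noise <- apply_imputation_noise(G, config$imputation_error)
    maf <- apply(noise$dosage, 2, function(d) {
      p <- mean(d) / 2
      min(p, 1 - p)
    })
    variants <- data.frame(
      id = vt$variants$id, chrom = vt$variants$chrom,
      pos = vt$variants$pos, ref = vt$variants$ref,
      alt = vt$variants$alt, maf = as.numeric(maf),
      info = as.numeric(noise$info), type = "imputed",
      stringsAsFactors = FALSE
    )
    cohorts[[config$study_names[s]]] <- study_cohort(
      study = config$study_names[s],
      dosage = noise$dosage,
      variants = variants,
      samples = ph$samples,
      n_cases = config$n_cases[s],
      n_controls = config$n_controls[s],
      hardcall = G
    )
    lps[[config$study_names[s]]] <- ph$lp
  }
  structure(list(
    cohorts = cohorts,
    gene_intervals = vt$gene_intervals,
    variants = vt$variants,
    truth = list(causal_genes = config$causal_genes,
                 causal_log_or = config$causal_log_or,
                 confounder_ld_gene = config$confounder_ld_gene,
                 lp = lps),
    config = config
  ), class = "cohort_set")
}

#' @export
print.cohort_set <- function(x, ...) {
  cat(sprintf("Synthetic cohort set: %d studies, %d genes, %d variants\n",
              length(x$cohorts), nrow(x$gene_intervals), nrow(x$variants)))
  for (co in x$cohorts)
    cat(sprintf("  %-12s %d cases / %d controls\n", co$study,
                co$n_cases, co$n_controls))
  invisible(x)
}
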