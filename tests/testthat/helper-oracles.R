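# Independent oracles used across the suite.

# Exact HWE enumeration via binomial-coefficient products (a different
# route from the package's log-factorial implementation): conditional
# on the allele totals, P(h het) = multinom(n; nAA, h, naa) * 2^h /
# choose(2n, nA), and the P value sums probabilities no larger than
# the observed one.
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  na <- 2 * n_aa + n_Aa
  nr <- min(nA, na)
  if (nr == 0) return(1)
  h <- seq.int(nr %% 2, nr, by = 2L)
  lp <- lchoose(n, (nA - h) / 2) +
    lchoose(n - (nA - h) / 2, h) + h * log(2) - lchoose(2 * n, nA)
  lp <- lp - max(lp)
  pr <- exp(lp) / sum(exp(lp))
  min(1, sum(pr[pr <= pr[match(n_Aa, h)] * (1 + 1e-12)]))
}

# Brute-force Stouffer combination: explicit loop, no vectorization.
stouffer_oracle <- function(z, w) {
  num <- 0; den <- 0
  for (i in seq_along(z)) {
    if (is.na(z[i])) next
    num <- num + w[i] * z[i]
    den <- den + w[i]^2
  }
  num / sqrt(den)
}

# Small-but-complete simulation config for fast tests.
quick_config <- function(...) {
  args <- list(...)
  defaults <- list(study_names = c("A", "B"),
                   n_cases = c(120, 80), n_controls = c(120, 160),
                   n_genes = 6L, variants_per_gene = c(2L, 5L),
                   imputation_error = 0, edu_missing_rate = 0,
                   seed = 401L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# Hand-built single-study cohort with fully controlled dosage columns.
toy_cohort <- function(dosage, maf = NULL, info = NULL, type = "imputed",
                       pos = NULL, status = NULL, seed = 1) {
  set.seed(seed)
  n <- nrow(dosage)
  m <- ncol(dosage)
  if (is.null(maf)) maf <- apply(dosage, 2, compute_maf)
  if (is.null(info)) info <- rep(1, m)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = m)
  if (is.null(status)) status <- rep(c(1L, 0L), length.out = n)
  colnames(dosage) <- sprintf("v%02d", seq_len(m))
  variants <- data.frame(id = colnames(dosage), chrom = "1", pos = pos,
                         ref = "A", alt = "C", maf = maf, info = info,
                         type = rep(type, length.out = m),
                         stringsAsFactors = FALSE)
  samples <- data.frame(sample_id = sprintf("S%03d", seq_len(n)),
                        status = status,
                        age = round(rnorm(n, 75, 5), 1),
                        sex = rbinom(n, 1, 0.5),
                        edu = sample(1:4, n, replace = TRUE),
                        PC1 = rnorm(n),
                        apoe_e4 = rbinom(n, 2, 0.15),
                        stringsAsFactors = FALSE)
  study_cohort("TOY", dosage, variants, samples)
}
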