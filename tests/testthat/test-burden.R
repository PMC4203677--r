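test_that("MAF estimation folds the allele frequency", {
  expect_equal(compute_maf(c(0, 0, 1, 1)), 0.25)
  expect_equal(compute_maf(rep(2, 10)), 0)
  expect_equal(compute_maf(c(NA, 1, 1)), 0.5)
  expect_error(compute_maf(c(NA_real_, NA_real_)), "missing")
  set.seed(41)
  d <- rbinom(1000, 2, 0.02) + 0
  expect_lt(abs(compute_maf(d) - 0.02), 3 * sqrt(0.02 * 0.98 / 2000))
})

test_that("rare-variant selection windows are inclusive where stated", {
  dos <- matrix(rep(0, 60), 10, 6)
  co <- toy_cohort(dos,
                   maf = c(0.030, 0.031, 0.004, 0.02, 0.02, 0.02),
                   info = c(1, 1, 1, 0.40, 0.39, 1),
                   pos = c(100, 150, 200, 250, 300, 5000))
  genes <- data.frame(gene = c("GA", "GB"), chrom = "1",
                      start = c(100, 4000), end = c(300, 4500),
                      stringsAsFactors = FALSE)
  sel <- select_rare_variants(co, genes)
  # MAF 0.03 in, 0.031 out; INFO 0.40 in, 0.39 out; pos 5000 outside GA
  expect_setequal(sel$GA, c("v01", "v03", "v04"))
  # stage-2 floor: MAF 0.004 now excluded
  sel2 <- select_rare_variants(co, genes, maf_min = 0.005)
  expect_setequal(sel2$GA, c("v01", "v04"))
  # GB covers no variant -> untestable
  expect_length(sel$GB, 0)
})

test_that("variants at a gene's exact start/end and overlaps count", {
  dos <- matrix(0, 5, 2)
  co <- toy_cohort(dos, maf = c(0.01, 0.02), pos = c(101, 200))
  genes <- data.frame(gene = c("LEFT", "WIDE"), chrom = "1",
                      start = c(101, 50), end = c(200, 500),
                      stringsAsFactors = FALSE)
  sel <- select_rare_variants(co, genes)
  expect_setequal(sel$LEFT, c("v01", "v02"))   # boundary inclusive
  expect_setequal(sel$WIDE, c("v01", "v02"))   # overlapping gene too
})

test_that("gene dosage averages included variants per sample", {
  dos <- cbind(v1 = c(0.5, 1, NA, NA), v2 = c(1.5, NA, 0.8, NA))
  co <- toy_cohort(dos, maf = c(0.2, 0.2))
  gd <- gene_dosage(co, c("v01", "v02"), gene = "G")
  expect_equal(as.numeric(gd$d), c(1.0, 1, 0.8, NA))  # per-sample n adjusts
  expect_equal(gd$n, 2)
  # invariant to variant ordering
  gd2 <- gene_dosage(co, c("v02", "v01"))
  expect_equal(unname(gd$d), unname(gd2$d))
  # single-variant identity
  gd1 <- gene_dosage(co, "v01")
  expect_equal(unname(gd1$d), unname(dos[, 1]))
  expect_error(gene_dosage(co, character(0)), "at least one")
  expect_error(gene_dosage(co, "nope"), "unknown variant")
})

sim_logistic_cohort <- function(n, beta, maf = 0.15, seed = 1) {
  set.seed(seed)
  d <- rbinom(n, 2, maf) + 0
  age <- rnorm(n, 75, 5); sex <- rbinom(n, 1, 0.5)
  lp <- -0.3 + beta * d + 0.02 * (age - 75) + 0.2 * sex
  samples <- data.frame(sample_id = seq_len(n),
                        status = rbinom(n, 1, plogis(lp)),
                        age = age, sex = sex,
                        edu = sample(1:4, n, TRUE), PC1 = rnorm(n))
  list(d = d, samples = samples)
}

test_that("association fit recovers a simulated effect within 2 SE", {
  sim <- sim_logistic_cohort(4000, log(1.5), seed = 55)
  fit <- fit_association(sim$d, sim$samples)
  expect_true(fit$estimable)
  expect_lt(abs(fit$beta - log(1.5)), 2 * fit$se)
  expect_equal(fit$p, 2 * pnorm(-abs(fit$z)), tolerance = 1e-10)
  expect_equal(sign(fit$z), sign(fit$beta))
})

test_that("Wald statistics agree with stats::glm on the same design", {
  sim <- sim_logistic_cohort(800, 0.4, seed = 56)
  fit <- fit_association(sim$d, sim$samples)
  ref <- glm(status ~ d + age + sex + edu + PC1,
             data = cbind(sim$samples, d = sim$d), family = binomial())
  sm <- summary(ref)$coefficients["d", ]
  expect_equal(fit$beta, unname(sm["Estimate"]), tolerance = 1e-8)
  expect_equal(fit$se, unname(sm["Std. Error"]), tolerance = 1e-8)
  # linear-model option matches lm's coefficient
  fitl <- fit_association(sim$d, sim$samples, family = "linear")
  refl <- lm(status ~ d + age + sex + edu + PC1,
             data = cbind(sim$samples, d = sim$d))
  expect_equal(fitl$beta, unname(coef(refl)["d"]), tolerance = 1e-8)
})

test_that("the null fit stays calibrated (type-I Monte Carlo)", {
  set.seed(57)
  hits <- replicate(200, {
    n <- 400
    d <- rbinom(n, 2, 0.2) + 0
    samples <- data.frame(sample_id = 1:n, status = rbinom(n, 1, 0.5),
                          age = rnorm(n, 75, 5), sex = rbinom(n, 1, 0.5),
                          edu = sample(1:4, n, TRUE))
    abs(fit_association(d, samples)$z) < 2
  })
  expect_gte(mean(hits), 0.90)   # expect ~0.954
})

test_that("degenerate fits are flagged, single-class phenotypes error", {
  sim <- sim_logistic_cohort(100, 0, seed = 58)
  flat <- fit_association(rep(1, 100), sim$samples)
  expect_false(flat$estimable)
  expect_true(is.na(flat$z))
  all_case <- sim$samples; all_case$status <- 1L
  expect_error(fit_association(sim$d, all_case), "single class")
  # all-zero gene dosage refuses through the same flag
  dos <- matrix(0, 100, 2)
  co <- toy_cohort(dos, maf = c(0, 0))
  f <- fit_gene(co, c("v01", "v02"), "G")
  expect_false(f$estimable)
})

test_that("a one-variant gene equals the single-SNP analysis", {
  cfg <- quick_config(study_names = "A", n_cases = 300,
                      n_controls = 300, seed = 61)
  co <- simulate_cohorts(cfg)$cohorts$A
  snp <- co$variants$id[4]
  g <- fit_gene(co, snp, "G")
  s <- fit_association(co$dosage[, 4], co$samples, study = "A",
                       gene = "G", n_variants = 1L)
  expect_equal(g$beta, s$beta)
  expect_equal(g$se, s$se)
  expect_equal(g$p, s$p)
})
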