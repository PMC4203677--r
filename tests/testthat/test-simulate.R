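test_that("identical config and seed reproduce identical cohorts", {
  cfg <- quick_config(imputation_error = 0.1, edu_missing_rate = 0.05)
  a <- simulate_cohorts(cfg)
  b <- simulate_cohorts(cfg)
  expect_identical(a$cohorts$A$dosage, b$cohorts$A$dosage)
  expect_identical(a$cohorts$B$samples, b$cohorts$B$samples)
  expect_identical(a$variants, b$variants)
})

test_that("genotypes at a fixed MAF match binomial sampling", {
  cfg <- quick_config(study_names = "A", n_cases = 5000,
                      n_controls = 5000, n_genes = 3,
                      variants_per_gene = 3L,
                      causal_genes = character(0),
                      maf_spectrum = list(shape1 = 1, shape2 = 1,
                                          min = 0.02, max = 0.02),
                      seed = 17)
  g <- simulate_true_genotypes(cfg)
  freq <- colMeans(g$genotypes$A) / 2
  sd1 <- sqrt(0.02 * 0.98 / (2 * 10000))
  # joint check over ~9 variants: 4-SD per-variant bound (family-wise
  # ~0.06%) plus a 3-SD bound on the pooled estimate
  expect_true(all(abs(freq - 0.02) < 4 * sd1))
  expect_lt(abs(mean(freq) - 0.02), 3 * sd1 / sqrt(length(freq)))
})

test_that("generated genotype frequencies satisfy HWE proportions", {
  cfg <- quick_config(study_names = "A", n_cases = 1000,
                      n_controls = 1000, n_genes = 40,
                      variants_per_gene = 5L,
                      causal_genes = character(0),
                      maf_spectrum = list(shape1 = 1, shape2 = 1,
                                          min = 0.1, max = 0.3),
                      seed = 23)
  G <- simulate_true_genotypes(cfg)$genotypes$A
  # chi-square goodness of fit against p^2 : 2pq : q^2 per variant
  pvals <- apply(G, 2, function(g) {
    p <- mean(g) / 2
    obs <- tabulate(g + 1L, 3L)
    exp <- length(g) * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((obs - exp)^2 / exp)
    pchisq(stat, df = 1, lower.tail = FALSE)
  })
  n_v <- length(pvals)
  expect_lt(sum(pvals < 0.001), 0.001 * n_v + 3 * sqrt(0.001 * n_v) + 1)
})

test_that("monomorphic columns are redrawn (and causal columns protected)", {
  cfg <- quick_config(study_names = "A", n_cases = 100,
                      n_controls = 100, n_genes = 10,
                      variants_per_gene = 4L,
                      causal_genes = character(0),
                      maf_spectrum = list(shape1 = 1, shape2 = 1,
                                          min = 0.002, max = 0.004),
                      seed = 5)
  G <- simulate_true_genotypes(cfg)$genotypes$A
  # P(mono) per draw ~ 0.3-0.45; after up to 100 redraws ~ 0
  expect_true(all(apply(G, 2, function(g) length(unique(g)) > 1)))
})

test_that("null model gives flat linear predictor and exact quotas", {
  cfg <- quick_config(study_names = "ADNI", n_cases = 350,
                      n_controls = 169, n_genes = 3,
                      causal_genes = character(0),
                      confounder_log_or = 0,
                      covariate_effects = c(age = 0, sex = 0, edu = 0,
                                            pc = 0),
                      intercept = 0, seed = 31)
  vt <- simulate_true_genotypes(cfg)
  ph <- simulate_phenotypes(vt$genotypes$ADNI, vt$variants, cfg,
                            study = "ADNI")
  expect_true(all(ph$lp == 0))          # case probability 0.5 everywhere
  expect_equal(sum(ph$samples$status == 1), 350)
  expect_equal(sum(ph$samples$status == 0), 169)
  expect_equal(nrow(ph$genotypes), 519)
})

test_that("unreachable quotas error after bounded attempts", {
  cfg <- quick_config(study_names = "A", n_cases = 200,
                      n_controls = 50, causal_genes = character(0),
                      intercept = -30, seed = 3)
  vt <- simulate_true_genotypes(cfg)
  expect_error(simulate_phenotypes(vt$genotypes$A, vt$variants, cfg,
                                   max_rounds = 3),
               "sampling rounds")
})

test_that("noiseless imputation returns genotypes with INFO 1", {
  set.seed(9)
  g <- matrix(rbinom(3000, 2, 0.05), 1000, 3)
  out <- apply_imputation_noise(g, 0)
  expect_equal(out$dosage, g + 0, ignore_attr = TRUE)
  expect_true(all(out$info == 1))
})

test_that("imputation noise lowers INFO; monomorphic variants get 0", {
  set.seed(10)
  g <- cbind(matrix(rbinom(4000, 2, 0.1), 1000, 4),
             mono = rep(0L, 1000))
  out <- apply_imputation_noise(g, 0.3)
  expect_lt(mean(out$info[1:4]), 1)
  expect_true(all(out$info[1:4] > 0))
  expect_equal(out$info[[5]], 0)
  expect_true(all(out$dosage >= 0 & out$dosage <= 2))
  expect_error(apply_imputation_noise(matrix(0.5, 2, 2), 0.1),
               "hard calls")
})

test_that("per-variant error range produces a spread of INFO scores", {
  cfg <- quick_config(study_names = "A", n_cases = 300, n_controls = 300,
                      imputation_error = c(0, 0.4), seed = 77)
  cs <- simulate_cohorts(cfg)
  info <- cs$cohorts$A$variants$info
  expect_gt(max(info) - min(info), 0.1)
})

test_that("education missingness matches the configured rate", {
  cfg <- quick_config(study_names = "A", n_cases = 1500,
                      n_controls = 1500, edu_missing_rate = 0.1,
                      seed = 12)
  cs <- simulate_cohorts(cfg)
  frac <- mean(is.na(cs$cohorts$A$samples$edu))
  expect_lt(abs(frac - 0.1), 3 * sqrt(0.1 * 0.9 / 3000))
})
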