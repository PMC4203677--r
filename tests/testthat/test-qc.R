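test_that("HWE exact test handles boundary and symmetric cases", {
  expect_equal(hwe_exact_test(40, 0, 0), 1)      # monomorphic
  expect_equal(hwe_exact_test(0, 0, 40), 1)
  expect_equal(hwe_exact_test(57, 14, 50), hwe_exact_test(50, 14, 57))
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
  p <- hwe_exact_test(25, 50, 25)                # ideal proportions
  expect_gt(p, 0.5)
  expect_lte(p, 1)
})

test_that("HWE exact test equals the enumeration oracle", {
  expect_equal(hwe_exact_test(57, 14, 50), hwe_oracle(57, 14, 50),
               tolerance = 1e-12)
  # exhaustive small-case sweep (the full <=200 sweep is in acceptance)
  for (n in 1:40) {
    for (n_aa in 0:n) {
      for (n_het in 0:(n - n_aa)) {
        got <- hwe_exact_test(n - n_aa - n_het, n_het, n_aa)
        want <- hwe_oracle(n - n_aa - n_het, n_het, n_aa)
        if (abs(got - want) > 1e-12)
          fail(sprintf("mismatch at (%d,%d,%d): %g vs %g",
                       n - n_aa - n_het, n_het, n_aa, got, want))
      }
    }
  }
  succeed()
})

test_that("HWE test rejects at the nominal rate under the null", {
  set.seed(71)
  n <- 400
  p_true <- 0.3
  pvals <- replicate(2000, {
    g <- rbinom(n, 2, p_true)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  for (alpha in c(0.05, 0.01)) {
    frac <- mean(pvals < alpha)
    expect_lt(abs(frac - alpha),
              3 * sqrt(alpha * (1 - alpha) / 2000) + 0.003)
  }
})

test_that("variant QC applies panel rules to genotyped, INFO to imputed", {
  set.seed(81)
  n <- 200
  g_ok <- rbinom(n, 2, 0.2)
  g_lowmaf <- rbinom(n, 2, 0.004)           # maf < 1%
  g_lowcall <- rbinom(n, 2, 0.2)
  g_hwe <- c(rep(0L, 100), rep(2L, 100))    # extreme HWE violation
  hard <- cbind(g_ok, g_lowmaf, g_lowcall, g_hwe, g_ok, g_ok, g_ok)
  hard[1:12, 3] <- NA                       # call rate 0.94
  dos <- hard; dos[is.na(dos)] <- 0; dos <- dos + 0
  co <- toy_cohort(dos,
                   maf = c(0.2, 0.004, 0.2, 0.5, 0.2, 0.009, 0.2),
                   info = c(1, 1, 1, 1, 0.40, 1, 0.39),
                   type = c(rep("genotyped", 4), "imputed", "imputed",
                            "imputed"))
  co$hardcall <- hard
  qc <- variant_qc(co)
  expect_equal(qc$keep, c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE))
  expect_equal(qc$reason[!qc$keep], c("maf", "call_rate", "hwe", "info"))
  # INFO = 0.40 exactly is kept (threshold is strict <); imputed
  # low-MAF variants pass this stage (the 1% floor is a panel rule)
  expect_true(qc$keep[5] && qc$keep[6])
  # idempotence
  kept <- subset_cohort(co, variants = which(qc$keep))
  qc2 <- variant_qc(kept)
  expect_true(all(qc2$keep))
})

test_that("pairwise IBS follows the shared-genotype formula", {
  expect_equal(pairwise_ibs(c(0L, 1L, 2L), c(0L, 1L, 2L)), 1)
  expect_equal(pairwise_ibs(c(0L, 2L), c(2L, 0L)), 0)
  expect_equal(pairwise_ibs(c(0L, 1L, 2L), c(0L, 1L, 0L)), 2 / 3)
  expect_equal(pairwise_ibs(c(0L, NA, 2L), c(NA, 1L, 0L)), 0)
  expect_error(pairwise_ibs(c(NA, NA), c(1L, NA)), "no variants")
})

test_that("sample QC removes duplicates, low call rate, het outliers", {
  set.seed(91)
  n <- 40; m <- 400
  hard <- matrix(rbinom(n * m, 2, 0.25), n, m)
  hard[2, ] <- hard[1, ]          # duplicated sample, IBS = 1
  hard[1, 1:3] <- NA              # sample 1 has the lower call rate
  hard[5, 1:(0.1 * m)] <- NA      # 10% missing -> call rate 0.90
  dos <- hard; dos[is.na(dos)] <- 0; dos <- dos + 0
  co <- toy_cohort(dos, info = rep(1, m))
  co$hardcall <- hard
  out <- sample_qc(co)
  rep_ <- out$report
  expect_true(rep_$excluded[5] && rep_$reason[5] == "call_rate")
  # exactly one of the duplicate pair removed: the lower-call-rate one
  expect_true(xor(rep_$excluded[1], rep_$excluded[2]))
  expect_true(rep_$excluded[1] && rep_$reason[1] == "relatedness")
})

test_that("constant heterozygosity removes nobody; tiny cohorts warn", {
  hard <- matrix(rep(c(0L, 1L, 0L, 1L), 25), 10, 10)  # identical het
  co <- toy_cohort(hard + 0)
  co$hardcall <- hard
  out <- sample_qc(co)
  expect_false(any(out$report$reason %in% "heterozygosity"))
  co2 <- toy_cohort(matrix(c(0, 1, 1, 0), 2, 2))
  co2$hardcall <- matrix(c(0L, 1L, 1L, 0L), 2, 2)
  expect_warning(sample_qc(co2), "fewer than 3")
})
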