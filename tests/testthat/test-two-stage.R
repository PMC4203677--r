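# A deliberately well-powered detection scenario: few variants per
# gene near the 3% MAF ceiling and a strong per-D effect across two
# studies.  Power analysis: sd(D) ~ 0.12, sum(N_E) ~ 3900, so the
# expected meta Z is ~ 1.7 * 0.12 * sqrt(3900/4) ~ 6.4, far beyond
# both the Bonferroni cut at 30 genes (|z| > 3.1) and the expected
# maximum null |z| (~2.8): the causal gene should rank first.
powered_config <- function(seed) {
  sim_config(study_names = c("A", "B"),
             n_cases = c(1000, 800), n_controls = c(1000, 1200),
             n_genes = 30L, variants_per_gene = c(2L, 3L),
             maf_spectrum = list(shape1 = 1, shape2 = 1,
                                 min = 0.015, max = 0.03),
             causal_genes = "G0007", causal_log_or = 1.7,
             imputation_error = 0.02, seed = seed)
}

test_that("stage 1 detects and top-ranks a strongly causal gene", {
  cs <- simulate_cohorts(powered_config(501))
  s1 <- stage1_scan(cs$cohorts, cs$gene_intervals)
  expect_s3_class(s1, "stage1_table")
  expect_false(is.unsorted(s1$p_meta, na.rm = TRUE))
  expect_equal(s1$gene[1], "G0007")
  expect_true(s1$significant[1])
  expect_equal(attr(s1, "threshold"), 0.05 / 30)
  expect_true(all(s1$significant ==
                    (!is.na(s1$p_meta) & s1$p_meta < 0.05 / 30)))
  expect_true(all(nchar(s1$direction) == 2))
})

test_that("genes with no qualifying variants are reported untestable", {
  cfg <- quick_config(study_names = "A", n_cases = 150,
                      n_controls = 150, n_genes = 4, seed = 71)
  cs <- simulate_cohorts(cfg)
  extra <- rbind(cs$gene_intervals,
                 data.frame(gene = "EMPTY", chrom = "1",
                            start = 900000, end = 901000))
  s1 <- stage1_scan(cs$cohorts, extra)
  row <- s1[s1$gene == "EMPTY", ]
  expect_equal(row$direction, "?")
  expect_true(is.na(row$p_meta))
  expect_equal(which(s1$gene == "EMPTY"), nrow(s1))  # NA sorts last
  expect_warning(stage1_scan(cs$cohorts, cs$gene_intervals[0, ]),
                 "no genes")
})

test_that("stage-2 selection enforces direction, P and MAF windows", {
  cs <- simulate_cohorts(powered_config(502))
  sel <- select_risk_snps(cs$cohorts, cs$gene_intervals, "G0007")
  expect_s3_class(sel, "stage2_selection")
  expect_gt(length(sel$selected_ids), 0)
  picked <- sel$snps[sel$snps$selected, ]
  expect_true(all(picked$p_meta < 0.05))
  expect_true(all(picked$z_meta > 0))
  # selected SNP ids are a subset of the gene's stage-1 variant pool
  pool <- unique(unlist(lapply(cs$cohorts, function(co)
    select_rare_variants(co, cs$gene_intervals)$G0007)))
  expect_true(all(sel$selected_ids %in% pool))
  # every per-study contribution respects the stage-2 MAF window
  used <- sel$per_study[sel$per_study$in_window, ]
  expect_true(all(used$maf >= 0.005 & used$maf <= 0.03))
})

test_that("an out-of-window SNP is unavailable in that study", {
  # one study; the lone variant's MAF 0.004 sits below the 0.5% floor
  set.seed(3)
  dos <- matrix(rbinom(2000, 1, 0.004) + 0, 1000, 2)
  co <- toy_cohort(dos, maf = c(0.004, 0.004), pos = c(100, 200))
  genes <- data.frame(gene = "G", chrom = "1", start = 1, end = 1000,
                      stringsAsFactors = FALSE)
  sel <- select_risk_snps(list(TOY = co), genes, "G")
  expect_true(all(!sel$per_study$in_window))
  expect_true(all(sel$snps$direction == "?"))
  expect_length(sel$selected_ids, 0)
  expect_match(sel$status, "no SNP")
})

test_that("confirmatory analysis on the full stage-1 set equals stage 1", {
  cs <- simulate_cohorts(powered_config(503))
  s1 <- stage1_scan(cs$cohorts, cs$gene_intervals)
  pool <- unique(unlist(lapply(cs$cohorts, function(co)
    select_rare_variants(co, cs$gene_intervals)$G0007)))
  conf <- stage2_confirm(cs$cohorts, pool, gene = "G0007",
                         maf_min = 0, maf_max = 0.03, info_min = 0.4)
  expect_equal(conf$meta_unadjusted$z_meta,
               s1$z_meta[s1$gene == "G0007"], tolerance = 1e-12)
  expect_equal(conf$evidence, "confirmatory-in-sample")
})

test_that("a single selected SNP reproduces its single-SNP result", {
  cs <- simulate_cohorts(powered_config(504))
  co <- cs$cohorts$A
  snp <- select_rare_variants(co, cs$gene_intervals)$G0007[1]
  conf <- stage2_confirm(cs$cohorts["A"], snp, gene = "G0007",
                         maf_min = 0, maf_max = 0.03)
  single <- fit_association(co$dosage[, match(snp, co$variants$id)],
                            co$samples, study = "A")
  expect_equal(conf$per_study$beta_unadjusted, single$beta)
  expect_equal(conf$per_study$p_unadjusted, single$p)
})

test_that("candidate gene lookup preserves order and reports misses", {
  cs <- simulate_cohorts(powered_config(505))
  s1 <- stage1_scan(cs$cohorts, cs$gene_intervals)
  ask <- c("G0010", "G0002", "NOT_A_GENE", "G0007")
  out <- candidate_gene_lookup(s1, ask)
  expect_equal(out$table$gene, c("G0010", "G0002", "G0007"))
  expect_equal(out$not_found, "NOT_A_GENE")
})

test_that("the full pipeline is reproducible end to end", {
  cfg <- powered_config(506)
  r1 <- run_pipeline(simulate_cohorts(cfg))
  r2 <- run_pipeline(simulate_cohorts(cfg))
  expect_identical(r1$stage1, r2$stage1)
  expect_identical(r1$confirm$meta_unadjusted,
                   r2$confirm$meta_unadjusted)
  expect_equal(r1$stage1$gene[1], "G0007")
  # forest weights are the effective sample sizes
  expect_equal(r1$forest$weight,
               effective_sample_size(c(1000, 800), c(1000, 1200)))
})
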