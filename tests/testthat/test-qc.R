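test_that("hwe_exact_test handles the worked cases", {
  expect_identical(hwe_exact_test(5, 0, 0), 1)
  # (1,0,1): allele counts 2/2, het counts {0,2} with conditional
  # probabilities {1/3, 2/3}; observed 0 has p = 1/3 -> p-value 1/3
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  # extreme all-het and balanced-hom configurations at equal allele counts
  expect_equal(hwe_exact_test(0, 50, 0), hwe_oracle(0, 50, 0),
               tolerance = 1e-12)
  expect_equal(hwe_exact_test(25, 0, 25), hwe_oracle(25, 0, 25),
               tolerance = 1e-12)
  expect_error(hwe_exact_test(0, 0, 0), "no data")
  expect_error(hwe_exact_test(-1, 2, 0), "non-negative")
})

test_that("hwe conditional distribution sums to 1 on small totals", {
  for (n in c(2, 5, 9, 17)) for (n1 in 1:n) {
    pr <- snppop:::.hwe_het_distribution(n, n1)
    expect_equal(sum(pr), 1, tolerance = 1e-12)
  }
})

test_that("hwe_exact_test equals the enumeration oracle on a sample grid", {
  # a pseudo-random subset of triples; the exhaustive total <= 30 sweep is
  # in test-acceptance.R
  set.seed(8)
  for (i in 1:200) {
    n0 <- sample(0:12, 1); n1 <- sample(0:12, 1); n2 <- sample(0:12, 1)
    if (n0 + n1 + n2 == 0) n0 <- 1
    expect_equal(hwe_exact_test(n0, n1, n2), hwe_oracle(n0, n1, n2),
                 tolerance = 1e-12)
  }
})

test_that("compute_qc_metrics reports call rates, MAF and HWE", {
  calls <- rbind(c(0L, 0L, NA), c(0L, 1L, NA), c(1L, 1L, NA),
                 c(1L, 2L, 0L), c(2L, 2L, NA), c(2L, NA, 0L))
  gm <- make_gm(calls, pops = rep(c("A", "B"), each = 3))
  met <- compute_qc_metrics(gm)
  expect_equal(unname(met$indiv_call_rate),
               c(2, 2, 2, 3, 2, 2) / 3)
  # marker 1 pooled calls (0,0,1,1,2,2): p = 0.5, MAF = 0.5
  expect_equal(unname(met$maf[1]), 0.5)
  expect_equal(unname(met$snp_call_rate[, 1]), c(1, 1))
  expect_equal(unname(met$snp_call_rate["B", 3]), 2 / 3)
  # marker 3 unseen in population A -> call rate 0 there
  expect_equal(unname(met$snp_call_rate["A", 3]), 0)
  expect_equal(unname(met$hwe_p["A", 3]), 1)  # no data, no evidence
  expect_true(all(met$hwe_p > 0 & met$hwe_p <= 1))
})

test_that("apply_qc removes planted violations at the right stages", {
  # 20 individuals in 2 pops, 40 markers in exact HWE proportions
  calls <- matrix(rep(c(0L, 1L, 1L, 2L), 5 * 40), 20, 40)
  # individual 1: 20 of 40 calls missing
  calls[1, 1:20] <- NA
  # marker 5: low call rate in pop B (8 of 10 missing)
  calls[11:18, 5] <- NA
  # marker 10: monomorphic -> MAF 0
  calls[, 10] <- 2L
  # marker 15: gross HWE violation (all het in both pops)
  calls[, 15] <- 1L
  gm <- make_gm(calls, pops = rep(c("A", "B"), each = 10))
  res <- apply_qc(gm, qc_thresholds(snp_call_rate_per_pop = 0.75,
                                    indiv_call_rate = 0.95,
                                    maf_min = 0.01, hwe_p_min = 0.05))
  rep <- res$report
  expect_identical(rep$removed_individuals$sample_id, "S01")
  expect_identical(rep$removed_markers_by_stage$pop_call_rate, "M005")
  expect_identical(rep$removed_markers_by_stage$maf, "M010")
  expect_true("M015" %in% rep$removed_markers_by_stage$hwe)
  expect_equal(rep$n_samples_out,
               rep$n_samples_in - nrow(rep$removed_individuals))
  expect_equal(rep$n_markers_out, rep$n_markers_in -
                 sum(lengths(rep$removed_markers_by_stage)))
  # stages are disjoint
  ids <- unlist(rep$removed_markers_by_stage)
  expect_false(anyDuplicated(ids) > 0)
})

test_that("vacuous thresholds pass everything through unchanged", {
  set.seed(31)
  calls <- matrix(rbinom(60, 2, 0.4), 6, 10)
  calls[2, 3] <- NA
  gm <- make_gm(calls, pops = rep(c("A", "B"), each = 3))
  res <- apply_qc(gm, qc_thresholds(0, 0, 0, 0))
  expect_identical(res$gm, gm)
  expect_identical(nrow(res$report$removed_individuals), 0L)
  expect_identical(sum(lengths(res$report$removed_markers_by_stage)), 0L)
})

test_that("apply_qc is idempotent on complete data", {
  set.seed(32)
  cfg <- simulation_config(n_pops = 2, pop_sizes = c(20, 20),
                           n_loci = 500, bn_F = c(0.05, 0.05),
                           fis = c(0, 0), missing_rate_snp = 0,
                           missing_rate_indiv = 0, seed = 32L)
  gm <- simulate_dataset(cfg)$gm
  r1 <- apply_qc(gm)
  r2 <- apply_qc(r1$gm)
  expect_identical(r2$gm, r1$gm)
  expect_identical(sum(lengths(r2$report$removed_markers_by_stage)), 0L)
})

test_that("a forced-monomorphic marker is removed at the MAF stage", {
  cfg <- simulation_config(n_pops = 2, pop_sizes = c(15, 15),
                           n_loci = 200, bn_F = c(0.05, 0.05),
                           fis = c(0, 0), missing_rate_snp = 0,
                           missing_rate_indiv = 0, seed = 33L)
  gm <- simulate_dataset(cfg)$gm
  gm$calls[, 7] <- 0L
  res <- apply_qc(gm, qc_thresholds(maf_min = 0.01, hwe_p_min = 0))
  expect_true("SNP000007" %in% res$report$removed_markers_by_stage$maf)
})

test_that("apply_qc errors when a filter removes everything", {
  calls <- matrix(c(1L, NA, NA, NA), 2, 2)
  gm <- make_gm(calls)
  expect_error(apply_qc(gm, qc_thresholds(indiv_call_rate = 1,
                                          snp_call_rate_per_pop = 0,
                                          maf_min = 0, hwe_p_min = 0)),
               "all samples removed")
})
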