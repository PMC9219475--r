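test_that("heterozygosity matches closed forms", {
  # 4 individuals all heterozygous at 10 loci
  gm <- make_gm(matrix(1L, 4, 10))
  het <- heterozygosity(gm, "P1")
  expect_equal(het$Ho, 1)
  expect_equal(het$n_loci_used, 10L)

  # one locus, genotypes {0, 2}: n = 2, p = 0.5,
  # he = (2n/(2n-1)) 2 p (1-p) = (4/3) * 0.5
  gm2 <- make_gm(matrix(c(0L, 2L), 2, 1))
  expect_equal(heterozygosity(gm2, "P1")$He, 2 / 3, tolerance = 1e-12)

  # Hardy-Weinberg simulation at p = 0.5: Ho and He both near 0.5
  set.seed(50)
  g <- simulate_genotypes(rep(0.5, 2000), 500)
  gm3 <- make_gm(g)
  h <- heterozygosity(gm3, "P1")
  expect_lt(abs(h$Ho - 0.5), 0.01)
  expect_lt(abs(h$He - 0.5), 0.01)

  expect_error(heterozygosity(gm, "NOPE"), "not present")
})

test_that("fis_within has the right sign behaviour and recovery", {
  # all-heterozygote population: excess heterozygosity, f < 0
  gm_het <- make_gm(matrix(1L, 6, 20))
  expect_lt(fis_within(gm_het, "P1")$Fis, 0)

  # fully inbred lines: every individual homozygous, loci polymorphic
  # between lines -> Ho = 0, He > 0, f = 1
  set.seed(51)
  inbred <- matrix(2L * rbinom(8 * 30, 1, 0.5), 8, 30)
  inbred[1:4, ] <- 0L; inbred[5:8, ] <- 2L
  expect_equal(fis_within(make_gm(inbred), "P1")$Fis, 1, tolerance = 1e-12)

  # parameter recovery at fis = 0.5
  set.seed(52)
  g <- simulate_genotypes(stats::runif(5000, 0.05, 0.5), 500, fis = 0.5)
  f <- fis_within(make_gm(g), "P1")
  expect_lt(abs(f$Fis - 0.5), 0.03)

  # all monomorphic -> undefined
  expect_error(fis_within(make_gm(matrix(2L, 4, 5)), "P1"),
               "monomorphic")
})

test_that("pairwise_fst matches fixed-difference and null expectations", {
  # opposite fixation at every locus -> theta = 1
  gm <- make_gm(rbind(matrix(2L, 5, 50), matrix(0L, 5, 50)),
                pops = rep(c("A", "B"), each = 5))
  expect_equal(pairwise_fst(gm, "A", "B"), 1, tolerance = 1e-12)
  # label-swap symmetry is exact
  expect_identical(pairwise_fst(gm, "A", "B"), pairwise_fst(gm, "B", "A"))

  # two halves of one panmictic population -> theta ~ 0
  set.seed(53)
  g <- simulate_genotypes(stats::runif(5000, 0.05, 0.5), 100)
  gm0 <- make_gm(g, pops = rep(c("A", "B"), each = 50))
  expect_lt(abs(pairwise_fst(gm0, "A", "B")), 0.01)

  expect_error(pairwise_fst(make_gm(matrix(2L, 6, 5),
                                    pops = rep(c("A", "B"), each = 3)),
                            "A", "B"), "undefined")
})

test_that("pairwise_fst agrees with the naive scalar oracle to 1e-10", {
  set.seed(54)
  for (trial in 1:5) {
    nA <- sample(4:12, 1); nB <- sample(4:12, 1)
    pA <- stats::runif(60, 0.05, 0.95); pB <- stats::runif(60, 0.05, 0.95)
    cA <- simulate_genotypes(pA, nA, fis = stats::runif(1, 0, 0.3))
    cB <- simulate_genotypes(pB, nB, missing_rate = 0.1)
    gm <- make_gm(rbind(cA, cB), pops = rep(c("A", "B"), c(nA, nB)))
    expect_equal(pairwise_fst(gm, "A", "B"), wc_theta_oracle(cA, cB),
                 tolerance = 1e-10)
  }
})

test_that("gene_flow_nm implements (1 - Fst)/(4 Fst)", {
  expect_equal(round(gene_flow_nm(0.044), 3), 5.432)
  expect_equal(round(gene_flow_nm(0.028), 3), 8.679)
  expect_equal(gene_flow_nm(0.2), 1)
  expect_true(is.na(gene_flow_nm(0)))
  expect_true(is.na(gene_flow_nm(-0.01)))
  # strictly decreasing on (0, 1]
  x <- seq(0.001, 1, length.out = 200)
  expect_true(all(diff(gene_flow_nm(x)) < 0))
})

test_that("all diversity statistics are invariant under allele relabeling", {
  set.seed(55)
  cfg <- simulation_config(n_pops = 2, pop_sizes = c(15, 15),
                           n_loci = 300, bn_F = c(0.1, 0.05),
                           fis = c(0.1, 0), missing_rate_snp = 0.05,
                           missing_rate_indiv = 0, seed = 55L)
  gm <- simulate_dataset(cfg)$gm
  flip <- sample(n_markers(gm), 150)
  gm2 <- gm_flip_alleles(gm, flip)
  for (p in populations(gm)) {
    expect_equal(heterozygosity(gm2, p), heterozygosity(gm, p))
    expect_equal(fis_within(gm2, p)$Fis, fis_within(gm, p)$Fis)
  }
  expect_equal(pairwise_fst(gm2, "POP1", "POP2"),
               pairwise_fst(gm, "POP1", "POP2"))
})

test_that("diversity_table and pairwise_matrices assemble consistently", {
  cfg <- simulation_config(n_pops = 3, pop_sizes = c(8, 10, 12),
                           n_loci = 300, bn_F = c(0.1, 0.05, 0.02),
                           fis = c(0, 0, 0), seed = 56L)
  gm <- simulate_dataset(cfg)$gm
  div <- diversity_table(gm)
  expect_identical(div$population, c("POP1", "POP2", "POP3"))
  expect_identical(div$n, c(8L, 10L, 12L))
  expect_true(all(div$Ho >= 0 & div$Ho <= 1))
  expect_true(all(div$He >= 0 & div$He <= 1))
  expect_true(all(div$Fis >= -1 & div$Fis <= 1))
  pm <- pairwise_matrices(gm)
  expect_identical(pm$fst, t(pm$fst))
  expect_identical(unname(diag(pm$fst)), rep(0, 3))
  off <- pm$fst[upper.tri(pm$fst)]
  expect_equal(pm$nm[upper.tri(pm$nm)], gene_flow_nm(off))
})
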