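#' Observed and unbiased expected heterozygosity for one population
#'
#' Per locus with at least two genotyped individuals in the population:
#' observed heterozygosity ho is the fraction of heterozygous calls and
#' expected heterozygosity is Nei's unbiased estimator
#' he = 2n/(2n - 1) * 2 p (1 - p), with n the locus's genotyped count and p
#' its sample allele frequency. `Ho` and `He` are unweighted means over the
#' qualifying loci; loci with fewer than two genotyped individuals are
#' excluded and do not count towards `n_loci_used`.
#'
#' @param gm a [genotype_matrix()].
#' @param population population label present in `gm`.
#' @return list with `Ho`, `He`, `n_loci_used`.
#' @export
heterozygosity <- function(gm, population) {
  calls <- .pop_calls(gm, population)
  if (nrow(calls) < 2L)
    stop("population ", population, " has fewer than 2 individuals")
  fc <- .freq_counts(calls)
  use <- fc$n >= 2L
  if (!any(use))
    stop("no locus with >= 2 genotyped individuals in ", population)
  ho <- colMeans(calls == 1L, na.rm = TRUE)[use]
  n <- fc$n[use]; p <- fc$p[use]
  he <- (2 * n / (2 * n - 1)) * 2 * p * (1 - p)
  list(Ho = mean(ho), He = mean(he), n_loci_used = sum(use))
}

#' Within-population fixation index (Weir-Cockerham f)
#'
#' Weir-Cockerham estimator of the within-population inbreeding coefficient
#' f (Fis) from per-locus variance components, combined across loci as a
#' ratio of sums. Per locus with n genotyped individuals, allele frequency
#' p and heterozygote fraction h: c = h/2 (within-individual component) and
#' b = n/(n-1) * (p(1-p) - (2n-1)/(4n) * h) (among-individual component);
#' f = 1 - sum(c) / sum(b + c). The naive 1 - Ho/He is returned alongside
#' as a diagnostic.
#'
#' @param gm a [genotype_matrix()].
#' @param population population label present in `gm`.
#' @return list with `Fis` (Weir-Cockerham f), `fis_naive`
#'   (1 - Ho/He), `n_loci_used`.
#' @export
fis_within <- function(gm, population) {
  calls <- .pop_calls(gm, population)
  if (nrow(calls) < 2L)
    stop("population ", population, " has fewer than 2 individuals")
  fc <- .freq_counts(calls)
  use <- fc$n >= 2L
  if (!any(use))
    stop("no locus with >= 2 genotyped individuals in ", population)
  n <- fc$n[use]; p <- fc$p[use]
  h <- colMeans(calls == 1L, na.rm = TRUE)[use]
  b <- n / (n - 1) * (p * (1 - p) - (2 * n - 1) / (4 * n) * h)
  cc <- h / 2
  denom <- sum(b + cc)
  if (denom <= 0)
    stop("Fis undefined for ", population,
         ": no within-population variation (all loci monomorphic)")
  het <- heterozygosity(gm, population)
  list(Fis = 1 - sum(cc) / denom,
       fis_naive = 1 - het$Ho / het$He,
       n_loci_used = sum(use))
}

#' Pairwise Weir-Cockerham Fst between two populations
#'
#' The two-population Weir-Cockerham theta: per-locus variance components
#' a (among populations), b (among individuals within populations) and c
#' (within individuals) are computed with sample-size weighting and
#' combined across loci as theta = sum(a) / sum(a + b + c) (ratio of sums,
#' the stable multi-locus combination). Loci need at least two genotyped
#' individuals in each population; loci monomorphic across both populations
#' contribute nothing and are excluded. The estimate is unbiased and may be
#' slightly negative; it is not truncated.
#'
#' @param gm a [genotype_matrix()].
#' @param popA,popB distinct population labels present in `gm`.
#' @return the multi-locus theta-hat.
#' @export
pairwise_fst <- function(gm, popA, popB) {
  cA <- .pop_calls(gm, popA)
  cB <- .pop_calls(gm, popB)
  fA <- .freq_counts(cA); fB <- .freq_counts(cB)
  hA <- colMeans(cA == 1L, na.rm = TRUE)
  hB <- colMeans(cB == 1L, na.rm = TRUE)
  comp <- .wc_components(fA$n, fA$p, hA, fB$n, fB$p, hB)
  denom <- sum(comp$a + comp$b + comp$c)
  if (!is.finite(denom) || denom <= 0)
    stop("Fst undefined for pair (", popA, ", ", popB,
         "): zero total variance (all usable loci monomorphic)")
  sum(comp$a) / denom
}

# Weir-Cockerham (1984) variance components for r = 2 populations,
# vectorized over loci. Inputs: per-locus genotyped counts, allele
# frequencies and heterozygote fractions for each population. Loci with
# fewer than 2 genotyped individuals in either population, or monomorphic
# across both, are dropped.
.wc_components <- function(n1, p1, h1, n2, p2, h2) {
  use <- n1 >= 2L & n2 >= 2L &
    !( (p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1) )
  n1 <- n1[use]; p1 <- p1[use]; h1 <- h1[use]
  n2 <- n2[use]; p2 <- p2[use]; h2 <- h2[use]
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc, n_loci = sum(use))
}

#' Wright's island-model gene flow from Fst
#'
#' Nm = (1 - Fst) / (4 Fst): the effective number of migrants per
#' generation under Wright's island model at equilibrium. Defined only for
#' Fst in (0, 1]; non-positive Fst returns `NA` (reported as not available
#' in tables).
#'
#' @param fst differentiation value(s).
#' @return Nm value(s), `NA` where `fst <= 0`.
#' @export
gene_flow_nm <- function(fst) {
  out <- rep(NA_real_, length(fst))
  ok <- !is.na(fst) & fst > 0 & fst <= 1
  out[ok] <- (1 - fst[ok]) / (4 * fst[ok])
  out
}

#' Per-population diversity table
#'
#' One row per population: sample size n, mean observed heterozygosity Ho,
#' mean Nei unbiased expected heterozygosity He, Weir-Cockerham Fis, and
#' the number of loci used.
#'
#' @param gm a [genotype_matrix()].
#' @return data.frame with columns `population`, `n`, `Ho`, `He`, `Fis`,
#'   `n_loci_used`.
#' @export
diversity_table <- function(gm) {
  pops <- populations(gm)
  rows <- lapply(pops, function(p) {
    het <- heterozygosity(gm, p)
    f <- fis_within(gm, p)
    data.frame(population = p, n = sum(gm$population_labels == p),
               Ho = het$Ho, He = het$He, Fis = f$Fis,
               n_loci_used = het$n_loci_used, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pairwise Fst and Nm matrices over all populations
#'
#' @param gm a [genotype_matrix()] with >= 2 populations.
#' @return list with `populations` (label order), `fst` (symmetric matrix,
#'   zero diagonal) and `nm` (symmetric; `NA` diagonal and wherever
#'   Fst <= 0).
#' @export
pairwise_matrices <- function(gm) {
  pops <- populations(gm)
  if (length(pops) < 2L) stop("need at least two populations")
  k <- length(pops)
  fst <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) for (j in seq.int(i + 1L, k)) {
    v <- pairwise_fst(gm, pops[i], pops[j])
    fst[i, j] <- fst[j, i] <- v
  }
  nm <- matrix(gene_flow_nm(fst), k, k, dimnames = dimnames(fst))
  diag(nm) <- NA_real_
  list(populations = pops, fst = fst, nm = nm)
}
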