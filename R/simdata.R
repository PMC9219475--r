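#' Simulation configuration for a multi-population SNP panel
#'
#' Describes a Balding-Nichols simulation of a multi-breed SNP-chip panel:
#' ancestral allele frequencies drawn uniformly from an ascertainment window,
#' per-population frequencies drawn from a Beta distribution around the
#' ancestral value with differentiation parameter F, genotypes drawn with
#' optional within-population inbreeding, and calls masked missing at
#' per-SNP and per-individual rates.
#'
#' Defaults emulate a four-breed village-sheep panel: sample sizes
#' 11/12/12/12, 5000 autosomal SNPs, one strongly differentiated population
#' (F = 0.15) against three weakly differentiated ones, and low inbreeding
#' and missingness typical of an array dataset that has not yet been through
#' QC.
#'
#' @param n_pops number of populations.
#' @param pop_sizes integer vector of diploid individuals per population
#'   (each >= 2).
#' @param n_loci number of biallelic markers.
#' @param bn_F per-population Balding-Nichols differentiation parameter,
#'   each in [0, 1).
#' @param fis per-population within-population inbreeding probability,
#'   each in [0, 1).
#' @param ancestral_maf_range length-2 interval within (0, 0.5] from which
#'   ancestral minor-allele frequencies are drawn uniformly.
#' @param missing_rate_snp per-call SNP-level missingness probability in
#'   [0, 1).
#' @param missing_rate_indiv per-call individual-level missingness
#'   probability in [0, 1).
#' @param seed integer RNG seed; fixed seed gives bit-identical datasets.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_pops = 4L,
                              pop_sizes = c(11L, 12L, 12L, 12L),
                              n_loci = 5000L,
                              bn_F = c(0.15, 0.05, 0.02, 0.02),
                              fis = c(0.03, 0.02, 0.03, 0.02),
                              ancestral_maf_range = c(0.05, 0.5),
                              missing_rate_snp = 0.02,
                              missing_rate_indiv = 0.01,
                              seed = 1L) {
  n_pops <- as.integer(n_pops)
  if (n_pops < 1L) stop("n_pops must be >= 1")
  if (length(pop_sizes) != n_pops || length(bn_F) != n_pops ||
      length(fis) != n_pops)
    stop("pop_sizes, bn_F and fis must each have length n_pops = ", n_pops)
  if (any(pop_sizes < 2L)) stop("every pop_size must be >= 2")
  if (n_loci < 1L) stop("n_loci must be >= 1")
  if (any(bn_F < 0 | bn_F >= 1)) stop("bn_F values must be in [0, 1)")
  if (any(fis < 0 | fis >= 1)) stop("fis values must be in [0, 1)")
  if (length(ancestral_maf_range) != 2L ||
      ancestral_maf_range[1] <= 0 || ancestral_maf_range[2] > 0.5 ||
      ancestral_maf_range[1] > ancestral_maf_range[2])
    stop("ancestral_maf_range must be an interval within (0, 0.5]")
  if (missing_rate_snp < 0 || missing_rate_snp >= 1 ||
      missing_rate_indiv < 0 || missing_rate_indiv >= 1)
    stop("missing rates must be in [0, 1)")
  structure(
    list(n_pops = n_pops, pop_sizes = as.integer(pop_sizes),
         n_loci = as.integer(n_loci), bn_F = as.numeric(bn_F),
         fis = as.numeric(fis),
         ancestral_maf_range = as.numeric(ancestral_maf_range),
         missing_rate_snp = as.numeric(missing_rate_snp),
         missing_rate_indiv = as.numeric(missing_rate_indiv),
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Draw per-population allele frequencies under the Balding-Nichols model
#'
#' For differentiation parameter F > 0, each population frequency is a draw
#' from Beta(p(1-F)/F, (1-p)(1-F)/F), which has mean p and variance
#' F p (1-p) -- F is exactly the quantity the Weir-Cockerham Fst estimator
#' targets. For F = 0 the ancestral frequencies are returned unchanged.
#'
#' Uses the current R RNG stream; seed via [set.seed()] or let
#' [simulate_dataset()] manage seeding.
#'
#' @param ancestral_freqs vector of ancestral frequencies, each in (0, 1).
#' @param F differentiation parameter in [0, 1).
#' @return numeric vector of per-population frequencies, same length.
#' @export
draw_population_freqs <- function(ancestral_freqs, F) {
  if (any(ancestral_freqs <= 0 | ancestral_freqs >= 1))
    stop("ancestral frequencies must lie strictly in (0, 1); ",
         "0 or 1 gives a degenerate Beta")
  if (F < 0 || F >= 1) stop("F must be in [0, 1)")
  if (F == 0) return(ancestral_freqs)
  k <- (1 - F) / F
  stats::rbeta(length(ancestral_freqs),
               shape1 = ancestral_freqs * k,
               shape2 = (1 - ancestral_freqs) * k)
}

#' Simulate a genotype block for one population
#'
#' Per individual per locus: with probability `fis` the two alleles are
#' identical by descent (a single Bernoulli(q) draw copied to both),
#' otherwise two independent Bernoulli(q) draws. Calls are then masked
#' missing independently at `missing_rate`. Output codes are alternate-allele
#' dosage 0/1/2 with `NA` for missing.
#'
#' @param pop_freqs per-locus alternate-allele frequencies in [0, 1].
#' @param n_indiv number of diploid individuals (>= 1).
#' @param fis inbreeding probability in [0, 1].
#' @param missing_rate per-call missingness probability in [0, 1).
#' @return integer matrix, `n_indiv` rows by `length(pop_freqs)` columns.
#' @export
simulate_genotypes <- function(pop_freqs, n_indiv, fis = 0,
                               missing_rate = 0) {
  if (any(pop_freqs < 0 | pop_freqs > 1))
    stop("pop_freqs must be in [0, 1]")
  if (n_indiv < 1L) stop("n_indiv must be >= 1")
  L <- length(pop_freqs)
  q <- matrix(pop_freqs, nrow = n_indiv, ncol = L, byrow = TRUE)
  # draw order per cell: allele1, allele2, IBD indicator, missing mask
  a1 <- matrix(stats::rbinom(n_indiv * L, 1L, q), n_indiv, L)
  a2 <- matrix(stats::rbinom(n_indiv * L, 1L, q), n_indiv, L)
  if (fis > 0) {
    ibd <- matrix(stats::runif(n_indiv * L) < fis, n_indiv, L)
    a2[ibd] <- a1[ibd]
  }
  g <- a1 + a2
  if (missing_rate > 0) {
    miss <- matrix(stats::runif(n_indiv * L) < missing_rate, n_indiv, L)
    g[miss] <- NA_integer_
  }
  storage.mode(g) <- "integer"
  g
}

#' Simulate a complete multi-population SNP dataset with known truth
#'
#' Runs the full Balding-Nichols generative model described in
#' [simulation_config()]: ancestral frequencies, per-population frequencies,
#' genotypes with inbreeding, then independent per-call missingness at rate
#' 1 - (1 - missing_rate_snp)(1 - missing_rate_indiv) (a call survives only
#' if it passes both the SNP-level and the individual-level mask).
#'
#' Individuals are labelled POP1..POPk with ids POP1_001 etc.; markers are
#' SNP000001.. cycled over 26 autosomes with 10 kb spacing and reference/
#' alternate alleles A/G. Output is bit-identical across reruns of the same
#' config (the seed is part of the config).
#'
#' @param config a [simulation_config()].
#' @return list with elements `gm` (a [genotype_matrix()]) and `truth`
#'   (class `truth_record`: `ancestral_freqs`, `pop_freqs` matrix
#'   populations x loci, plus the configured `bn_F`, `fis`, `seed`).
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  L <- config$n_loci
  p_anc <- stats::runif(L, config$ancestral_maf_range[1],
                        config$ancestral_maf_range[2])
  pop_freqs <- matrix(NA_real_, config$n_pops, L)
  miss_rate <- 1 - (1 - config$missing_rate_snp) *
    (1 - config$missing_rate_indiv)
  blocks <- vector("list", config$n_pops)
  for (k in seq_len(config$n_pops)) {
    pop_freqs[k, ] <- draw_population_freqs(p_anc, config$bn_F[k])
    blocks[[k]] <- simulate_genotypes(pop_freqs[k, ], config$pop_sizes[k],
                                      fis = config$fis[k],
                                      missing_rate = miss_rate)
  }
  calls <- do.call(rbind, blocks)
  pop_labels <- rep(paste0("POP", seq_len(config$n_pops)),
                    times = config$pop_sizes)
  sample_ids <- unlist(lapply(seq_len(config$n_pops), function(k)
    sprintf("POP%d_%03d", k, seq_len(config$pop_sizes[k]))))
  chrom <- as.character(rep_len(1:26, L))
  pos <- integer(L)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    pos[i] <- 10000L * seq_along(i)
  }
  gm <- genotype_matrix(
    calls, sample_ids, pop_labels,
    marker_ids = sprintf("SNP%06d", seq_len(L)),
    chromosomes = chrom, positions_bp = pos,
    allele1 = rep("A", L), allele2 = rep("G", L))
  truth <- structure(
    list(ancestral_freqs = p_anc, pop_freqs = pop_freqs,
         bn_F = config$bn_F, fis = config$fis, seed = config$seed),
    class = "truth_record")
  list(gm = gm, truth = truth)
}

#' Write the simulation truth sidecar
#'
#' TSV with one row per locus (marker id, ancestral frequency, one column of
#' true frequencies per population) preceded by `#`-prefixed header lines
#' recording F, fis and the seed.
#'
#' @param truth a `truth_record` from [simulate_dataset()].
#' @param gm the matching `genotype_matrix` (for marker ids).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth_tsv <- function(truth, gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# bn_F\t", paste(truth$bn_F, collapse = "\t")),
    paste0("# fis\t", paste(truth$fis, collapse = "\t")),
    paste0("# seed\t", truth$seed)), con)
  df <- data.frame(marker_id = gm$marker_ids,
                   ancestral_freq = truth$ancestral_freqs)
  for (k in seq_len(nrow(truth$pop_freqs)))
    df[[paste0("POP", k, "_freq")]] <- truth$pop_freqs[k, ]
  utils::write.table(format(df, digits = 10, trim = TRUE), con,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
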