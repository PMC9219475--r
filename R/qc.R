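#' Quality-control thresholds for a SNP-array panel
#'
#' Defaults follow the conventional array-QC cascade for multi-breed panels:
#' SNPs must be genotyped in at least 75% of individuals in every
#' population, animals in at least 95% of SNPs, minor allele frequency at
#' least 1%, and Hardy-Weinberg exact-test p at least 0.001. All filters are
#' strict (`<` removes).
#'
#' @param snp_call_rate_per_pop minimum per-population SNP call rate.
#' @param indiv_call_rate minimum individual call rate.
#' @param maf_min minimum pooled minor allele frequency.
#' @param hwe_p_min minimum Hardy-Weinberg exact-test p-value.
#' @param indiv_call_rate_prefilter optional individual call-rate
#'   pre-filter applied before everything else (e.g. 0.90); `NULL` (the
#'   default) disables it.
#' @param hwe_scope `"per-pop"` (remove if failing in any population, the
#'   default, avoiding Wahlund artifacts) or `"pooled"`.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(snp_call_rate_per_pop = 0.75,
                          indiv_call_rate = 0.95,
                          maf_min = 0.01,
                          hwe_p_min = 0.001,
                          indiv_call_rate_prefilter = NULL,
                          hwe_scope = c("per-pop", "pooled")) {
  hwe_scope <- match.arg(hwe_scope)
  vals <- c(snp_call_rate_per_pop, indiv_call_rate, maf_min, hwe_p_min,
            indiv_call_rate_prefilter)
  if (any(vals < 0 | vals > 1))
    stop("all thresholds must be in [0, 1]")
  structure(list(snp_call_rate_per_pop = snp_call_rate_per_pop,
                 indiv_call_rate = indiv_call_rate,
                 maf_min = maf_min, hwe_p_min = hwe_p_min,
                 indiv_call_rate_prefilter = indiv_call_rate_prefilter,
                 hwe_scope = hwe_scope),
            class = "qc_thresholds")
}

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test of Hardy-Weinberg genotype proportions using the
#' conditional (Levene) distribution of the heterozygote count given the
#' allele counts. The p-value sums the conditional probabilities of every
#' heterozygote count whose probability is less than or equal to that of the
#' observed count, so it lies in (0, 1]. A monomorphic sample returns 1.
#'
#' @param n_hom_ref,n_het,n_hom_alt non-negative genotype counts (total
#'   >= 1).
#' @return the exact p-value.
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  if (n_hom_ref < 0 || n_het < 0 || n_hom_alt < 0)
    stop("genotype counts must be non-negative")
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("no data: all genotype counts are zero")
  n1 <- 2 * min(n_hom_ref, n_hom_alt) + n_het   # rarer allele count
  if (n1 == 0) return(1)                         # monomorphic
  pr <- .hwe_het_distribution(n, n1)
  p_obs <- pr[match(n_het, as.integer(names(pr)))]
  sum(pr[pr <= p_obs * (1 + 1e-12)])
}

# Conditional distribution of the heterozygote count given n genotypes and
# n1 copies of the rarer allele. P(h) = n! / (n11! h! n22!) * 2^h *
# n1! n2! / (2n)!; computed in log space and renormalized so the
# distribution sums to exactly 1.
.hwe_het_distribution <- function(n, n1) {
  hs <- seq.int(n1 %% 2L, min(n1, 2L * n - n1), by = 2L)
  n11 <- (n1 - hs) / 2
  n22 <- n - n11 - hs
  logp <- lfactorial(n) - lfactorial(n11) - lfactorial(hs) -
    lfactorial(n22) + hs * log(2) +
    lfactorial(n1) + lfactorial(2 * n - n1) - lfactorial(2 * n)
  pr <- exp(logp - max(logp))
  pr <- pr / sum(pr)
  names(pr) <- hs
  pr
}

#' Per-dataset QC metrics
#'
#' Computes every quantity the QC cascade filters on: per-individual call
#' rates, per-marker per-population call rates, per-marker pooled minor
#' allele frequency, and per-marker Hardy-Weinberg exact-test p-values
#' (per population and pooled). A marker with zero genotyped individuals in
#' a population gets call rate 0 there and HWE p = 1 (no evidence).
#'
#' @param gm a [genotype_matrix()].
#' @return list with `indiv_call_rate` (named vector),
#'   `snp_call_rate` (populations x markers matrix), `maf` (vector),
#'   `hwe_p` (populations x markers matrix), `hwe_p_pooled` (vector).
#' @export
compute_qc_metrics <- function(gm) {
  if (!n_samples(gm) || !n_markers(gm))
    stop("need at least one sample and one marker")
  pops <- populations(gm)
  icr <- rowMeans(!is.na(gm$calls))
  names(icr) <- gm$sample_ids
  scr <- matrix(NA_real_, length(pops), n_markers(gm),
                dimnames = list(pops, gm$marker_ids))
  hwe <- matrix(NA_real_, length(pops), n_markers(gm),
                dimnames = list(pops, gm$marker_ids))
  for (p in pops) {
    sub <- .pop_calls(gm, p)
    scr[p, ] <- colMeans(!is.na(sub))
    hwe[p, ] <- .hwe_by_marker(sub)
  }
  fc <- .freq_counts(gm$calls)
  maf <- pmin(fc$p, 1 - fc$p)
  maf[fc$n == 0] <- NA_real_
  names(maf) <- gm$marker_ids
  list(indiv_call_rate = icr, snp_call_rate = scr, maf = maf,
       hwe_p = hwe, hwe_p_pooled = .hwe_by_marker(gm$calls))
}

# vector of HWE exact p-values over the columns of a call matrix;
# markers with no genotyped individuals get p = 1
.hwe_by_marker <- function(calls) {
  apply(calls, 2L, function(x) {
    n0 <- sum(x == 0L, na.rm = TRUE)
    n1 <- sum(x == 1L, na.rm = TRUE)
    n2 <- sum(x == 2L, na.rm = TRUE)
    if (n0 + n1 + n2 == 0L) 1 else hwe_exact_test(n0, n1, n2)
  })
}

#' Apply the QC filter cascade
#'
#' Stage order: (0) optional individual call-rate pre-filter, (1) remove
#' individuals with call rate below `indiv_call_rate`, then on the
#' survivors (2) remove markers with call rate below
#' `snp_call_rate_per_pop` in any population, (3) remove markers with
#' pooled MAF below `maf_min`, (4) remove markers failing the
#' Hardy-Weinberg exact test below `hwe_p_min` (per population or pooled,
#' per `hwe_scope`). All comparisons are strict; a marker is attributed to
#' the first stage that removes it; marker metrics are recomputed on the
#' post-individual-filter matrix.
#'
#' @param gm a [genotype_matrix()].
#' @param thresholds a [qc_thresholds()].
#' @return list with `gm` (the filtered matrix) and `report` (class
#'   `qc_report`): in/out counts, removed individual ids with call rates,
#'   removed marker ids keyed by stage, and a copy of the thresholds.
#' @export
apply_qc <- function(gm, thresholds = qc_thresholds()) {
  stopifnot(inherits(gm, "genotype_matrix"),
            inherits(thresholds, "qc_thresholds"))
  n_s_in <- n_samples(gm); n_m_in <- n_markers(gm)
  icr <- rowMeans(!is.na(gm$calls))
  drop_i <- logical(n_s_in)
  if (!is.null(thresholds$indiv_call_rate_prefilter))
    drop_i <- icr < thresholds$indiv_call_rate_prefilter
  drop_i <- drop_i | icr < thresholds$indiv_call_rate
  removed_individuals <- data.frame(
    sample_id = gm$sample_ids[drop_i], call_rate = icr[drop_i],
    row.names = NULL, stringsAsFactors = FALSE)
  gm2 <- gm_subset(gm, samples = !drop_i)
  if (!n_samples(gm2))
    stop(.qc_abort_msg("all samples removed by the individual call-rate filter",
                       n_s_in, n_m_in, removed_individuals))

  met <- compute_qc_metrics(gm2)
  fail_cr <- apply(met$snp_call_rate < thresholds$snp_call_rate_per_pop,
                   2L, any)
  fail_maf <- !is.na(met$maf) & met$maf < thresholds$maf_min
  fail_maf[is.na(met$maf)] <- thresholds$maf_min > 0  # no calls at all
  hwe_mat <- if (thresholds$hwe_scope == "per-pop") met$hwe_p else
    matrix(met$hwe_p_pooled, nrow = 1L)
  fail_hwe <- apply(hwe_mat < thresholds$hwe_p_min, 2L, any)

  st_cr <- fail_cr
  st_maf <- fail_maf & !st_cr
  st_hwe <- fail_hwe & !st_cr & !st_maf
  removed_markers <- list(
    pop_call_rate = gm2$marker_ids[st_cr],
    maf = gm2$marker_ids[st_maf],
    hwe = gm2$marker_ids[st_hwe])
  keep_m <- !(st_cr | st_maf | st_hwe)
  if (!any(keep_m))
    stop(.qc_abort_msg("all markers removed by the marker filters",
                       n_s_in, n_m_in, removed_individuals))
  out <- gm_subset(gm2, markers = keep_m)
  report <- structure(
    list(n_samples_in = n_s_in, n_samples_out = n_samples(out),
         n_markers_in = n_m_in, n_markers_out = n_markers(out),
         removed_individuals = removed_individuals,
         removed_markers_by_stage = removed_markers,
         thresholds = thresholds),
    class = "qc_report")
  list(gm = out, report = report)
}

.qc_abort_msg <- function(msg, n_s, n_m, removed_individuals) {
  paste0(msg, " (input: ", n_s, " samples x ", n_m, " markers; ",
         nrow(removed_individuals), " individuals removed)")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("QC report\n")
  cat(sprintf("  samples: %d -> %d (%d removed)\n", x$n_samples_in,
              x$n_samples_out, nrow(x$removed_individuals)))
  cat(sprintf("  markers: %d -> %d\n", x$n_markers_in, x$n_markers_out))
  for (s in names(x$removed_markers_by_stage))
    cat(sprintf("    removed at %s: %d\n", s,
                length(x$removed_markers_by_stage[[s]])))
  invisible(x)
}

#' Write a QC report as TSV
#'
#' Long format: one row per removed record (`record_type`, `id`, `stage`,
#' `value`) preceded by `#`-prefixed summary lines.
#'
#' @param report a `qc_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_report_tsv <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  th <- report$thresholds
  writeLines(c(
    sprintf("# samples_in\t%d", report$n_samples_in),
    sprintf("# samples_out\t%d", report$n_samples_out),
    sprintf("# markers_in\t%d", report$n_markers_in),
    sprintf("# markers_out\t%d", report$n_markers_out),
    sprintf("# thresholds\tindiv_call_rate=%g snp_call_rate_per_pop=%g maf_min=%g hwe_p_min=%g hwe_scope=%s",
            th$indiv_call_rate, th$snp_call_rate_per_pop, th$maf_min,
            th$hwe_p_min, th$hwe_scope)), con)
  rows <- data.frame(record_type = character(), id = character(),
                     stage = character(), value = character(),
                     stringsAsFactors = FALSE)
  if (nrow(report$removed_individuals))
    rows <- rbind(rows, data.frame(
      record_type = "individual",
      id = report$removed_individuals$sample_id,
      stage = "indiv_call_rate",
      value = sprintf("%.6f", report$removed_individuals$call_rate),
      stringsAsFactors = FALSE))
  for (s in names(report$removed_markers_by_stage)) {
    ids <- report$removed_markers_by_stage[[s]]
    if (length(ids))
      rows <- rbind(rows, data.frame(record_type = "marker", id = ids,
                                     stage = s, value = "",
                                     stringsAsFactors = FALSE))
  }
  utils::write.table(rows, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
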