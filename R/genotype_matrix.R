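#' Diploid SNP genotype matrix with population labels
#'
#' The central data container of the package: an individuals-by-markers
#' matrix of alternate-allele dosages for diploid biallelic SNPs, together
#' with sample, population and marker metadata. Calls are coded as the
#' number of copies of `allele2` (0, 1 or 2); missing calls are `NA`.
#'
#' @param calls integer matrix, samples in rows, markers in columns; values
#'   in \{0, 1, 2\} or `NA` for missing.
#' @param sample_ids character vector of unique sample identifiers.
#' @param population_labels character vector, one population label per
#'   sample (e.g. breed codes).
#' @param marker_ids character vector of unique marker identifiers.
#' @param chromosomes character vector, one chromosome name per marker
#'   (stored as opaque strings, no species-specific validation).
#' @param positions_bp non-negative integer vector of 1-based bp positions.
#' @param allele1,allele2 character vectors of the two allele states per
#'   marker; calls count copies of `allele2`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, sample_ids, population_labels,
                            marker_ids, chromosomes, positions_bp,
                            allele1, allele2) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  n_s <- length(sample_ids)
  n_m <- length(marker_ids)
  if (!identical(dim(calls), c(n_s, n_m)))
    stop("calls must be a ", n_s, " x ", n_m,
         " matrix (samples x markers); got ",
         paste(dim(calls), collapse = " x "))
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(marker_ids))
    stop("duplicate marker ids: ",
         paste(unique(marker_ids[duplicated(marker_ids)]), collapse = ", "))
  if (length(population_labels) != n_s)
    stop("population_labels must have one entry per sample")
  if (length(chromosomes) != n_m || length(positions_bp) != n_m ||
      length(allele1) != n_m || length(allele2) != n_m)
    stop("marker metadata vectors must have one entry per marker")
  if (any(positions_bp < 0, na.rm = TRUE))
    stop("positions_bp must be non-negative")
  bad <- calls[!is.na(calls)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("non-missing calls must be in {0, 1, 2}")
  # a marker with an observed het (or both hom classes) needs two distinct
  # alleles; monomorphic markers may carry a placeholder second allele
  het_mk <- which(apply(calls, 2L, function(x) any(x == 1L, na.rm = TRUE) ||
                          (any(x == 0L, na.rm = TRUE) &&
                             any(x == 2L, na.rm = TRUE))))
  if (length(het_mk) && any(allele1[het_mk] == allele2[het_mk]))
    stop("allele1 == allele2 at polymorphic marker(s): ",
         paste(utils::head(marker_ids[het_mk[
           allele1[het_mk] == allele2[het_mk]]], 5L), collapse = ", "))
  dimnames(calls) <- list(sample_ids, marker_ids)
  structure(
    list(calls = calls,
         sample_ids = as.character(sample_ids),
         population_labels = as.character(population_labels),
         marker_ids = as.character(marker_ids),
         chromosomes = as.character(chromosomes),
         positions_bp = as.integer(positions_bp),
         allele1 = as.character(allele1),
         allele2 = as.character(allele2)),
    class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  tab <- table(x$population_labels)
  cat("genotype_matrix: ", n_samples(x), " samples x ", n_markers(x),
      " markers\n", sep = "")
  cat("populations: ",
      paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
            collapse = ", "), "\n", sep = "")
  miss <- mean(is.na(x$calls))
  cat(sprintf("missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Number of samples in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(gm) length(gm$sample_ids)

#' Number of markers in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return integer count.
#' @export
n_markers <- function(gm) length(gm$marker_ids)

#' Population labels present in a genotype matrix
#' @param gm a `genotype_matrix`.
#' @return character vector of unique labels in order of first appearance.
#' @export
populations <- function(gm) unique(gm$population_labels)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param gm a `genotype_matrix`.
#' @param samples logical/integer index or character sample ids to keep.
#' @param markers logical/integer index or character marker ids to keep.
#' @return the subsetted `genotype_matrix`.
#' @export
gm_subset <- function(gm, samples = NULL, markers = NULL) {
  si <- seq_along(gm$sample_ids)
  mi <- seq_along(gm$marker_ids)
  if (!is.null(samples)) {
    si <- if (is.character(samples)) match(samples, gm$sample_ids)
          else si[samples]
    if (anyNA(si)) stop("unknown sample id(s) in subset")
  }
  if (!is.null(markers)) {
    mi <- if (is.character(markers)) match(markers, gm$marker_ids)
          else mi[markers]
    if (anyNA(mi)) stop("unknown marker id(s) in subset")
  }
  genotype_matrix(gm$calls[si, mi, drop = FALSE],
                  gm$sample_ids[si], gm$population_labels[si],
                  gm$marker_ids[mi], gm$chromosomes[mi],
                  gm$positions_bp[mi], gm$allele1[mi], gm$allele2[mi])
}

#' Restrict a genotype matrix to a subset of populations
#' @param gm a `genotype_matrix`.
#' @param pops character vector of population labels to keep.
#' @return the subsetted `genotype_matrix`.
#' @export
gm_select_populations <- function(gm, pops) {
  missing_p <- setdiff(pops, gm$population_labels)
  if (length(missing_p))
    stop("population(s) not present: ", paste(missing_p, collapse = ", "))
  gm_subset(gm, samples = gm$population_labels %in% pops)
}

# calls submatrix for one population; errors if absent
.pop_calls <- function(gm, population) {
  idx <- which(gm$population_labels == population)
  if (!length(idx)) stop("population not present: ", population)
  gm$calls[idx, , drop = FALSE]
}

# per-marker alternate-allele frequency and genotyped count from a call
# submatrix (rows = individuals)
.freq_counts <- function(calls) {
  n <- colSums(!is.na(calls))
  p <- ifelse(n > 0, colSums(calls, na.rm = TRUE) / (2 * n), NA_real_)
  list(p = p, n = n)
}

#' Swap the allele coding of selected markers
#'
#' Relabels `allele1`/`allele2` and flips calls c to 2 - c at the given
#' markers. All diversity statistics in this package are invariant under
#' this operation; it exists mainly to exercise that property in tests.
#'
#' @param gm a `genotype_matrix`.
#' @param markers index or marker ids to flip (default: all markers).
#' @return the recoded `genotype_matrix`.
#' @export
gm_flip_alleles <- function(gm, markers = seq_len(n_markers(gm))) {
  mi <- if (is.character(markers)) match(markers, gm$marker_ids)
        else seq_len(n_markers(gm))[markers]
  if (anyNA(mi)) stop("unknown marker id(s)")
  calls <- gm$calls
  calls[, mi] <- 2L - calls[, mi]
  a1 <- gm$allele1; a2 <- gm$allele2
  tmp <- a1[mi]; a1[mi] <- a2[mi]; a2[mi] <- tmp
  genotype_matrix(calls, gm$sample_ids, gm$population_labels,
                  gm$marker_ids, gm$chromosomes, gm$positions_bp, a1, a2)
}
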