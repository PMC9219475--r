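#' Genotype principal component analysis
#'
#' Eigenanalysis of the genotype matrix after per-locus normalization:
#' calls are centered by twice the observed allele frequency and, under the
#' default Patterson scaling, divided by sqrt(p(1 - p)) -- the normalization
#' used by the classical ancestry-PCA tools, which upweights rare variants
#' to the scale of genetic drift. Missing calls are set to the post-center
#' mean (zero), i.e. mean-imputed. Monomorphic loci are dropped. The
#' decomposition is of the sample covariance K = X X' / L of the normalized
#' matrix; coordinates are eigenvectors scaled by the square root of their
#' eigenvalues. Each component's sign is fixed by forcing its
#' largest-magnitude coordinate positive, so results are deterministic.
#'
#' @param gm a [genotype_matrix()] with >= 2 samples.
#' @param k number of components to return (default 10; truncated to the
#'   positive rank with a warning record in the result).
#' @param scaling `"patterson"` (default) or `"none"` (plain covariance
#'   PCA on centered calls).
#' @return object of class `pca_result`: `coordinates` (samples x k, row
#'   names = sample ids), `eigenvalues` (descending), `percent_variance`
#'   (eigenvalue / sum of positive eigenvalues * 100), `loci_used`,
#'   `populations`, `truncated` (logical: k exceeded rank).
#' @export
run_pca <- function(gm, k = 10L, scaling = c("patterson", "none")) {
  scaling <- match.arg(scaling)
  if (n_samples(gm) < 2L) stop("need at least 2 samples")
  fc <- .freq_counts(gm$calls)
  poly <- !is.na(fc$p) & fc$p > 0 & fc$p < 1
  if (sum(poly) < 2L) stop("need at least 2 polymorphic loci")
  g <- gm$calls[, poly, drop = FALSE]
  p <- fc$p[poly]
  X <- sweep(g, 2L, 2 * p)
  if (scaling == "patterson")
    X <- sweep(X, 2L, sqrt(p * (1 - p)), `/`)
  X[is.na(X)] <- 0
  L <- ncol(X)
  K <- tcrossprod(X) / L
  eig <- eigen(K, symmetric = TRUE)
  pos <- eig$values > max(eig$values) * 1e-10
  rank <- sum(pos)
  truncated <- k > rank
  k_eff <- min(k, rank)
  vals <- eig$values[seq_len(k_eff)]
  vecs <- eig$vectors[, seq_len(k_eff), drop = FALSE]
  coords <- vecs %*% diag(sqrt(vals), k_eff, k_eff)
  for (j in seq_len(k_eff)) {
    top <- which.max(abs(coords[, j]))
    if (coords[top, j] < 0) coords[, j] <- -coords[, j]
  }
  dimnames(coords) <- list(gm$sample_ids, paste0("PC", seq_len(k_eff)))
  structure(
    list(coordinates = coords,
         eigenvalues = vals,
         percent_variance = 100 * vals / sum(eig$values[pos]),
         loci_used = L,
         populations = gm$population_labels,
         truncated = truncated,
         total_variance = sum(eig$values[pos])),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- length(x$eigenvalues)
  cat("pca_result: ", nrow(x$coordinates), " samples, ", x$loci_used,
      " loci, ", k, " components\n", sep = "")
  cat("percent variance:",
      paste(sprintf("%.2f", x$percent_variance), collapse = " "), "\n")
  invisible(x)
}
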