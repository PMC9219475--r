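#' Allele-sharing distance matrix between individuals
#'
#' Per locus the allele-sharing score between dosage calls ci and cj is
#' s = 1 - |ci - cj| / 2: identical genotypes share 1, heterozygote vs
#' homozygote 0.5, opposite homozygotes 0. The proportion of alleles alike
#' in state, x_ij, is the mean of s over the loci genotyped in both
#' individuals (pairwise-complete loci), and ASD(i, j) = 1 - x_ij.
#'
#' @param gm a [genotype_matrix()] with >= 2 samples.
#' @param min_overlap minimum number of pairwise-complete loci per pair;
#'   any pair below it is a hard error (default 100).
#' @return object of class `asd_dist`: list with `labels` (sample ids),
#'   `populations` (labels per sample), `values` (symmetric matrix, zero
#'   diagonal, entries in [0, 1]) and `n_overlap` (per-pair counts).
#' @export
asd_matrix <- function(gm, min_overlap = 100L) {
  if (n_samples(gm) < 2L) stop("need at least 2 samples")
  g <- gm$calls
  M <- !is.na(g)                               # non-missing indicator
  G0 <- M & g == 0L; G1 <- M & g == 1L; G2 <- M & g == 2L
  mode(M) <- "numeric"; mode(G0) <- "numeric"
  mode(G1) <- "numeric"; mode(G2) <- "numeric"
  n_overlap <- M %*% t(M)
  # sum over shared loci of |ci - cj|: 1 for 0/1 and 1/2 pairs, 2 for 0/2
  absdiff <- G0 %*% t(G1) + G1 %*% t(G0) + G1 %*% t(G2) + G2 %*% t(G1) +
    2 * (G0 %*% t(G2) + G2 %*% t(G0))
  low <- which(n_overlap < min_overlap & upper.tri(n_overlap),
               arr.ind = TRUE)
  if (nrow(low))
    stop("pair(s) with fewer than ", min_overlap,
         " shared genotyped loci: ",
         paste(sprintf("(%s, %s: %d)", gm$sample_ids[low[, 1]],
                       gm$sample_ids[low[, 2]],
                       as.integer(n_overlap[low])),
               collapse = ", "))
  asd <- absdiff / (2 * n_overlap)
  diag(asd) <- 0
  dimnames(asd) <- list(gm$sample_ids, gm$sample_ids)
  structure(list(labels = gm$sample_ids,
                 populations = gm$population_labels,
                 values = asd, n_overlap = n_overlap),
            class = "asd_dist")
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Studier-Keppler selection criterion
#' Q(i, j) = (m - 2) d(i, j) - R_i - R_j, standard branch-length formulas,
#' and distance update d(u, k) = (d(i, k) + d(j, k) - d(i, j)) / 2. Exact
#' ties in Q are resolved by the lowest (row, column) index pair, so the
#' output is deterministic. A negative computed branch length is clamped to
#' 0 and the deficit transferred to its sister branch, preserving the path
#' length between the joined nodes. The root is the (arbitrary)
#' trifurcating node left by the final join.
#'
#' @param dm an `asd_dist`, a symmetric numeric matrix with labelled rows,
#'   or a [stats::dist] object; >= 3 taxa, non-negative entries.
#' @return object of class `nj_tree`: `root` (nested node list), `labels`.
#' @export
nj_tree <- function(dm) {
  D <- if (inherits(dm, "asd_dist")) dm$values
       else if (inherits(dm, "dist")) as.matrix(dm)
       else as.matrix(dm)
  m <- nrow(D)
  if (m < 3L) stop("neighbour joining needs at least 3 taxa")
  if (is.null(rownames(D))) rownames(D) <- colnames(D) <-
      paste0("t", seq_len(m))
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("distance matrix has negative entries")
  labels <- rownames(D)
  nodes <- lapply(labels, function(l) list(leaf = TRUE, label = l))

  while (m > 3L) {
    R <- rowSums(D)
    Q <- (m - 2) * D - outer(R, R, `+`)
    diag(Q) <- Inf
    Q[lower.tri(Q)] <- Inf
    hit <- which(Q == min(Q), arr.ind = TRUE)
    hit <- hit[order(hit[, 1L], hit[, 2L]), , drop = FALSE]
    i <- hit[1L, 1L]; j <- hit[1L, 2L]
    li <- D[i, j] / 2 + (R[i] - R[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    new_node <- list(leaf = FALSE,
                     children = list(list(node = nodes[[i]], length = li),
                                     list(node = nodes[[j]], length = lj)))
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    lab2 <- c(rownames(D)[keep], sprintf(".u%d", m))
    rownames(D2) <- colnames(D2) <- lab2
    nodes <- c(nodes[keep], list(new_node))
    D <- D2
    m <- m - 1L
  }
  # final trifurcation: three-point formulas
  l1 <- max((D[1, 2] + D[1, 3] - D[2, 3]) / 2, 0)
  l2 <- max((D[1, 2] + D[2, 3] - D[1, 3]) / 2, 0)
  l3 <- max((D[1, 3] + D[2, 3] - D[1, 2]) / 2, 0)
  root <- list(leaf = FALSE,
               children = list(list(node = nodes[[1]], length = l1),
                               list(node = nodes[[2]], length = l2),
                               list(node = nodes[[3]], length = l3)))
  structure(list(root = root, labels = labels), class = "nj_tree")
}

#' Serialize a tree as a Newick string
#'
#' Standard Newick with branch lengths at 6 significant digits and a
#' terminating semicolon. Labels containing whitespace, quotes or Newick
#' punctuation are single-quoted, with embedded single quotes doubled.
#'
#' @param tree an `nj_tree`.
#' @return a single Newick string.
#' @export
to_newick <- function(tree) {
  stopifnot(inherits(tree, "nj_tree"))
  paste0(.newick_node(tree$root), ";")
}

.newick_label <- function(label) {
  # quote anything beyond plain identifier characters
  if (grepl("[^A-Za-z0-9_.|/-]", label))
    paste0("'", gsub("'", "''", label), "'")
  else label
}

.newick_node <- function(node) {
  if (node$leaf) return(.newick_label(node$label))
  parts <- vapply(node$children, function(ch)
    paste0(.newick_node(ch$node), ":", sprintf("%.6g", ch$length)), "")
  paste0("(", paste(parts, collapse = ","), ")")
}

#' Leaf-to-leaf path-length matrix of a tree
#'
#' @param tree an `nj_tree`.
#' @return symmetric matrix of summed branch lengths between every pair of
#'   leaves, in `tree$labels` order.
#' @export
path_length_matrix <- function(tree) {
  stopifnot(inherits(tree, "nj_tree"))
  n <- length(tree$labels)
  Dm <- matrix(0, n, n, dimnames = list(tree$labels, tree$labels))
  walk <- function(node) {
    if (node$leaf)
      return(stats::setNames(0, node$label))
    depths <- lapply(node$children, function(ch) walk(ch$node) + ch$length)
    for (i in seq_along(depths)[-1]) for (j in seq_len(i - 1L)) {
      di <- depths[[i]]; dj <- depths[[j]]
      block <- outer(di, dj, `+`)
      Dm[names(di), names(dj)] <<- block
      Dm[names(dj), names(di)] <<- t(block)
    }
    unlist(depths)
  }
  walk(tree$root)
  Dm
}

#' Leaf bipartitions (splits) induced by the internal edges of a tree
#'
#' @param tree an `nj_tree`.
#' @return list of character vectors, each the smaller-or-equal side of a
#'   non-trivial split, sorted; useful for topology comparison.
#' @export
tree_splits <- function(tree) {
  stopifnot(inherits(tree, "nj_tree"))
  all_leaves <- sort(tree$labels)
  splits <- list()
  walk <- function(node) {
    if (node$leaf) return(node$label)
    below <- unlist(lapply(node$children, function(ch) walk(ch$node)))
    if (length(below) > 1L && length(below) < length(all_leaves) - 1L) {
      side <- sort(below)
      other <- setdiff(all_leaves, side)
      key <- if (length(side) < length(other) ||
                 (length(side) == length(other) &&
                    paste(side, collapse = "|") <=
                    paste(other, collapse = "|"))) side else other
      splits[[length(splits) + 1L]] <<- key
    }
    below
  }
  walk(tree$root)
  unique(splits)
}
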