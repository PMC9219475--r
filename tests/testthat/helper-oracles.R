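# Independent oracles and toy-data builders shared across the suite.
# Everything here is deliberately written WITHOUT reusing the package's
# internal code paths, so agreement is a real cross-check.

# quick genotype_matrix from a calls matrix (rows = samples)
make_gm <- function(calls, pops = rep("P1", nrow(calls))) {
  n_s <- nrow(calls); n_m <- ncol(calls)
  genotype_matrix(calls,
                  sample_ids = sprintf("S%02d", seq_len(n_s)),
                  population_labels = pops,
                  marker_ids = sprintf("M%03d", seq_len(n_m)),
                  chromosomes = rep("1", n_m),
                  positions_bp = seq_len(n_m) * 1000L,
                  allele1 = rep("A", n_m), allele2 = rep("C", n_m))
}

# HWE exact-test oracle: plain-factorial enumeration of the conditional
# distribution of the heterozygote count given the allele counts
hwe_oracle <- function(n0, n1het, n2) {
  n <- n0 + n1het + n2
  nA <- 2 * n0 + n1het
  na <- 2 * n2 + n1het
  n_rare <- min(nA, na)
  if (n_rare == 0) return(1)
  hs <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  probs <- vapply(hs, function(h) {
    nrr <- (n_rare - h) / 2
    ncc <- n - nrr - h
    factorial(n) / (factorial(nrr) * factorial(h) * factorial(ncc)) *
      2^h * factorial(n_rare) * factorial(2 * n - n_rare) /
      factorial(2 * n)
  }, 0)
  p_obs <- probs[hs == n1het]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# naive scalar transcription of the two-population Weir-Cockerham theta
# (ratio of sums over loci), looping locus by locus
wc_theta_oracle <- function(callsA, callsB) {
  num <- den <- 0
  for (l in seq_len(ncol(callsA))) {
    xa <- callsA[, l]; xa <- xa[!is.na(xa)]
    xb <- callsB[, l]; xb <- xb[!is.na(xb)]
    n1 <- length(xa); n2 <- length(xb)
    if (n1 < 2 || n2 < 2) next
    p1 <- sum(xa) / (2 * n1); p2 <- sum(xb) / (2 * n2)
    if ((p1 == 0 && p2 == 0) || (p1 == 1 && p2 == 1)) next
    h1 <- mean(xa == 1); h2 <- mean(xb == 1)
    r <- 2
    nbar <- (n1 + n2) / 2
    nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc *
      (s2 - 1 / (nbar - 1) *
         (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
    b <- nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 -
         (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# infinite-sample-size theta from the true per-population frequencies of a
# Balding-Nichols draw (the parameter the estimator targets, locus by locus
# as a ratio of sums)
wc_theta_truth <- function(p1, p2) {
  keep <- !((p1 == 0 & p2 == 0) | (p1 == 1 & p2 == 1))
  p1 <- p1[keep]; p2 <- p2[keep]
  pbar <- (p1 + p2) / 2
  s2 <- (p1 - p2)^2 / 2
  hbar <- p1 * (1 - p1) + p2 * (1 - p2)   # HWE within each population
  a <- s2
  b <- pbar * (1 - pbar) - s2 / 2 - hbar / 2
  cc <- hbar / 2
  sum(a) / sum(a + b + cc)
}

# random unrooted binary tree with positive branch lengths, plus its
# leaf-to-leaf path-length matrix computed directly during construction
# (independent of the package's tree code)
random_additive_tree <- function(n_leaves, min_len = 0.1, max_len = 1) {
  labels <- sprintf("L%02d", seq_len(n_leaves))
  D <- matrix(0, n_leaves, n_leaves, dimnames = list(labels, labels))
  # active subtrees: list of leaf-depth vectors (depth to subtree root)
  parts <- lapply(labels, function(l) stats::setNames(0, l))
  while (length(parts) > 3) {
    pick <- sample.int(length(parts), 2)
    la <- stats::runif(1, min_len, max_len)
    lb <- stats::runif(1, min_len, max_len)
    da <- parts[[pick[1]]] + la
    db <- parts[[pick[2]]] + lb
    cross <- outer(da, db, `+`)
    D[names(da), names(db)] <- cross
    D[names(db), names(da)] <- t(cross)
    parts <- c(parts[-pick], list(c(da, db)))
  }
  lens <- stats::runif(3, min_len, max_len)
  for (i in 1:3) parts[[i]] <- parts[[i]] + lens[i]
  for (i in 1:2) for (j in (i + 1):3) {
    cross <- outer(parts[[i]], parts[[j]], `+`)
    D[names(parts[[i]]), names(parts[[j]])] <- cross
    D[names(parts[[j]]), names(parts[[i]])] <- t(cross)
  }
  D
}

# splits of a tree from its Newick string via ape (external oracle route)
ape_splits <- function(newick) {
  tr <- ape::read.tree(text = newick)
  tr <- ape::unroot(tr)
  bp <- ape::prop.part(tr)
  labs <- attr(bp, "labels")
  all_sorted <- sort(labs)
  keep <- Filter(function(s) length(s) > 1 && length(s) < length(labs) - 1,
                 lapply(bp, function(i) sort(labs[i])))
  canon <- lapply(keep, function(side) {
    other <- setdiff(all_sorted, side)
    if (length(side) < length(other) ||
        (length(side) == length(other) &&
           paste(side, collapse = "|") <= paste(other, collapse = "|")))
      side else other
  })
  unique(canon)
}

split_key <- function(splits)
  sort(vapply(splits, paste, "", collapse = "|"))
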