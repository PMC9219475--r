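#' Read PLINK text PED/MAP files into a genotype matrix
#'
#' Parses the whitespace-delimited PLINK text dialect: MAP with four columns
#' (chromosome, marker id, genetic distance, bp position) and PED rows with
#' six leading columns (family, individual, father, mother, sex, phenotype)
#' followed by two allele columns per marker. The family-ID column becomes
#' the population label. `"0"` denotes a missing allele; a half-missing
#' genotype (one allele `"0"`) is treated as fully missing.
#'
#' Per marker, `allele2` is the lexicographically larger of the observed
#' non-missing alleles and calls are coded as copies of `allele2`; a marker
#' at which only one allele state is observed is coded as fixed for
#' `allele2` (all calls 2).
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return a [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  if (length(map_fields) && any(lengths(map_fields) != 4L))
    stop("MAP file must have 4 whitespace-separated columns; line ",
         which(lengths(map_fields) != 4L)[1], " has ",
         lengths(map_fields)[which(lengths(map_fields) != 4L)[1]])
  n_mark <- length(map_fields)
  chrom <- vapply(map_fields, `[[`, "", 1L)
  marker_ids <- vapply(map_fields, `[[`, "", 2L)
  pos <- as.integer(vapply(map_fields, `[[`, "", 4L))
  if (anyDuplicated(marker_ids))
    stop("duplicate marker id in MAP: ",
         marker_ids[duplicated(marker_ids)][1])

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n_samp <- length(ped_lines)
  pop <- character(n_samp)
  ids <- character(n_samp)
  alle <- matrix(NA_character_, n_samp, 2L * n_mark)
  for (i in seq_len(n_samp)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * n_mark)
      stop("PED/MAP marker count mismatch: PED row ", i, " has ",
           (length(f) - 6L) %/% 2L, " genotype(s), MAP lists ", n_mark)
    pop[i] <- f[1L]
    ids[i] <- f[2L]
    if (n_mark) alle[i, ] <- f[-(1:6)]
  }
  if (anyDuplicated(ids))
    stop("duplicate sample id in PED: ", ids[duplicated(ids)][1])

  calls <- matrix(NA_integer_, n_samp, n_mark)
  allele1 <- allele2 <- rep(NA_character_, n_mark)
  for (j in seq_len(n_mark)) {
    a <- alle[, 2L * j - 1L]
    b <- alle[, 2L * j]
    half <- xor(a == "0", b == "0")
    a[half] <- "0"; b[half] <- "0"
    obs <- setdiff(sort(unique(c(a, b))), "0")
    if (length(obs) > 2L)
      stop("more than 2 distinct alleles at marker ", marker_ids[j], ": ",
           paste(obs, collapse = ", "))
    if (length(obs) == 0L) {
      allele1[j] <- "A"; allele2[j] <- "G"      # all-missing placeholder
      next
    }
    a2 <- obs[length(obs)]                       # lexicographically larger
    a1 <- if (length(obs) == 2L) obs[1L] else "0"
    allele1[j] <- a1; allele2[j] <- a2
    ok <- a != "0"
    calls[ok, j] <- (a[ok] == a2) + (b[ok] == a2)
  }
  genotype_matrix(calls, ids, pop, marker_ids, chrom, pos, allele1, allele2)
}

#' Write a genotype matrix as PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()]: family ID is the population label;
#' father/mother/sex/phenotype are emitted as `0 0 0 -9`; missing calls
#' become `0 0`. The MAP genetic-distance column is written as 0. Output is
#' re-readable into an equal matrix (up to the fixed-marker allele
#' convention documented in [read_ped_map()]).
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output file paths.
#' @return invisibly, `c(ped_path, map_path)`.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  map <- paste(gm$chromosomes, gm$marker_ids, 0L, gm$positions_bp,
               sep = "\t")
  writeLines(map, map_path)
  n_m <- n_markers(gm)
  geno_strings <- character(n_samples(gm))
  a1 <- gm$allele1; a2 <- gm$allele2
  for (i in seq_len(n_samples(gm))) {
    ci <- gm$calls[i, ]
    g <- character(n_m)
    g[!is.na(ci) & ci == 0L] <- paste(a1, a1)[!is.na(ci) & ci == 0L]
    g[!is.na(ci) & ci == 1L] <- paste(a1, a2)[!is.na(ci) & ci == 1L]
    g[!is.na(ci) & ci == 2L] <- paste(a2, a2)[!is.na(ci) & ci == 2L]
    g[is.na(ci)] <- "0 0"
    geno_strings[i] <- paste(g, collapse = " ")
  }
  if (n_samples(gm) == 0L) {
    writeLines(character(), ped_path)
    return(invisible(c(ped_path, map_path)))
  }
  lead <- paste(gm$population_labels, gm$sample_ids, 0L, 0L, 0L, -9L)
  writeLines(if (n_m) paste(lead, geno_strings) else lead, ped_path)
  invisible(c(ped_path, map_path))
}
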