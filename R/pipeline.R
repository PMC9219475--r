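#' Configuration for a full pipeline run
#'
#' Exactly one of (`ped_path` + `map_path`) or `sim_config` must be given:
#' the pipeline either loads an existing PED/MAP dataset or simulates one.
#'
#' @param out_dir output directory (created if needed).
#' @param ped_path,map_path input PLINK text files, or `NULL`.
#' @param sim_config a [simulation_config()], or `NULL`.
#' @param thresholds a [qc_thresholds()].
#' @param populations optional character vector restricting the analysis to
#'   a subset of populations (applied before QC).
#' @param pca_k number of principal components (default 10).
#' @param min_overlap minimum pairwise-complete loci for ASD (default 100).
#' @param seed integer seed echoed into the manifest; for simulated input
#'   it overrides `sim_config$seed` so one flag controls the run.
#' @return an object of class `run_config`.
#' @export
run_config <- function(out_dir, ped_path = NULL, map_path = NULL,
                       sim_config = NULL, thresholds = qc_thresholds(),
                       populations = NULL, pca_k = 10L,
                       min_overlap = 100L, seed = 1L) {
  have_files <- !is.null(ped_path) || !is.null(map_path)
  if (have_files && (is.null(ped_path) || is.null(map_path)))
    stop("ped_path and map_path must be given together")
  if (have_files == !is.null(sim_config))
    stop("exactly one of (ped_path, map_path) or sim_config must be set")
  if (!is.null(sim_config)) {
    stopifnot(inherits(sim_config, "simulation_config"))
    sim_config$seed <- as.integer(seed)
  }
  structure(list(out_dir = out_dir, ped_path = ped_path,
                 map_path = map_path, sim_config = sim_config,
                 thresholds = thresholds, populations = populations,
                 pca_k = as.integer(pca_k),
                 min_overlap = as.integer(min_overlap),
                 seed = as.integer(seed)),
            class = "run_config")
}

.log_stage <- function(fmt, ...) {
  message(sprintf(paste0("[snppop] ", fmt), ...))
}

.write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf(paste0("%.", digits, "f"), x))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

# Table-3-style mixed-triangle file: Fst below the diagonal, Nm above,
# "-" on the diagonal.
.write_fst_nm_matrix <- function(pm, path) {
  k <- length(pm$populations)
  cells <- matrix("-", k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i > j) cells[i, j] <- sprintf("%.4f", pm$fst[i, j])
    if (i < j) cells[i, j] <- if (is.na(pm$nm[i, j])) "NA"
               else sprintf("%.3f", pm$nm[i, j])
  }
  lines <- c(paste(c("", pm$populations), collapse = "\t"),
             vapply(seq_len(k), function(i)
               paste(c(pm$populations[i], cells[i, ]), collapse = "\t"),
               ""))
  writeLines(lines, path)
}

#' Run the full diversity-analysis pipeline
#'
#' Orchestrates simulate/load, QC, per-population diversity, pairwise
#' Fst/Nm, allele-sharing distances, neighbour-joining tree and PCA, and
#' writes all report files plus a run manifest into `config$out_dir`:
#' `qc_report.tsv`, `diversity.tsv`, `fst_nm_matrix.tsv` (Fst lower
#' triangle, Nm upper), `fst_nm_long.tsv`, `asd_matrix.tsv`, `tree.nwk`,
#' `pca_coords.tsv`, `pca_eigen.tsv`, `manifest.txt`. Identical config and
#' seed give byte-identical outputs. Stage progress is logged to standard
#' error; a stage failure aborts with the stage name after writing a
#' partial manifest.
#'
#' @param config a [run_config()].
#' @return invisibly, the manifest as a named list (paths and per-stage
#'   record counts).
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(
    utils::packageVersion("snppop")), seed = config$seed)
  stage <- "load"
  out <- function(f) file.path(config$out_dir, f)
  res <- tryCatch({
    if (!is.null(config$sim_config)) {
      .log_stage("simulate: %d pops, %d loci, seed %d",
                 config$sim_config$n_pops, config$sim_config$n_loci,
                 config$sim_config$seed)
      sim <- simulate_dataset(config$sim_config)
      gm <- sim$gm
      write_ped_map(gm, out("input.ped"), out("input.map"))
      write_truth_tsv(sim$truth, gm, out("truth.tsv"))
      manifest$input <- "simulated"
    } else {
      .log_stage("load: %s", config$ped_path)
      gm <- read_ped_map(config$ped_path, config$map_path)
      manifest$input <- config$ped_path
    }
    if (!is.null(config$populations))
      gm <- gm_select_populations(gm, config$populations)
    manifest$n_samples_in <- n_samples(gm)
    manifest$n_markers_in <- n_markers(gm)

    stage <- "qc"
    .log_stage("qc: %d samples x %d markers in", n_samples(gm),
               n_markers(gm))
    qc <- apply_qc(gm, config$thresholds)
    gm <- qc$gm
    write_qc_report_tsv(qc$report, out("qc_report.tsv"))
    manifest$n_samples_qc <- qc$report$n_samples_out
    manifest$n_markers_qc <- qc$report$n_markers_out

    stage <- "diversity"
    .log_stage("diversity: %d populations", length(populations(gm)))
    div <- diversity_table(gm)
    .write_tsv(stats::setNames(
      div[, c("population", "n", "Ho", "He", "Fis")],
      c("Breed", "Nb", "Ho", "He", "Fis")), out("diversity.tsv"), 4)
    manifest$n_populations <- nrow(div)

    stage <- "fst"
    pm <- pairwise_matrices(gm)
    .write_fst_nm_matrix(pm, out("fst_nm_matrix.tsv"))
    pairs <- which(upper.tri(pm$fst), arr.ind = TRUE)
    .write_tsv(data.frame(
      pop_a = pm$populations[pairs[, 1]],
      pop_b = pm$populations[pairs[, 2]],
      fst = pm$fst[pairs], nm = pm$nm[pairs]), out("fst_nm_long.tsv"))

    stage <- "asd"
    dm <- asd_matrix(gm, min_overlap = config$min_overlap)
    am <- dm$values
    lines <- c(paste(c("", dm$labels), collapse = "\t"),
               vapply(seq_along(dm$labels), function(i)
                 paste(c(dm$labels[i], sprintf("%.6f", am[i, ])),
                       collapse = "\t"), ""))
    writeLines(lines, out("asd_matrix.tsv"))

    stage <- "tree"
    tree <- nj_tree(dm)
    writeLines(to_newick(tree), out("tree.nwk"))

    stage <- "pca"
    pca <- run_pca(gm, k = config$pca_k)
    co <- as.data.frame(pca$coordinates)
    .write_tsv(cbind(data.frame(sample = rownames(co),
                                population = pca$populations), co),
               out("pca_coords.tsv"))
    .write_tsv(data.frame(component = seq_along(pca$eigenvalues),
                          eigenvalue = pca$eigenvalues,
                          percent_variance = pca$percent_variance),
               out("pca_eigen.tsv"))
    manifest$pca_components <- length(pca$eigenvalues)
    manifest$status <- "ok"
    manifest
  }, error = function(e) {
    manifest$status <- paste0("failed at stage ", stage, ": ",
                              conditionMessage(e))
    .write_manifest(manifest, out("manifest.txt"))
    stop("pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  .write_manifest(res, out("manifest.txt"))
  .log_stage("done: outputs in %s", config$out_dir)
  invisible(res)
}

.write_manifest <- function(manifest, path) {
  writeLines(paste0(names(manifest), "=",
                    vapply(manifest, function(v)
                      paste(as.character(v), collapse = ","), "")),
             path)
}
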