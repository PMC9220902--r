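# CSV readers/writers for the documented schemas, plus the end-to-end
# pipeline orchestrator. All files are comma-separated UTF-8 with a header
# row; violations of the type invariants are reported with row numbers.

#' Write / read an NFI matrix as CSV
#'
#' Schema: one row per protein with columns `protein`, `pathway`, then one
#' numeric column per sample id.
#'
#' @param m an [nfi_matrix()].
#' @param path file path.
#' @param scale scale tag of the stored values (reader only).
#' @return `read_nfi_csv` returns an [nfi_matrix()]; `write_nfi_csv`
#'   returns `path` invisibly.
#' @export
write_nfi_csv <- function(m, path) {
  stopifnot(inherits(m, "nfi_matrix"))
  v <- nfi_values(m)
  df <- data.frame(protein = rownames(v),
                   pathway = nfi_pathways(m)[rownames(v)],
                   v, check.names = FALSE, row.names = NULL)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nfi_csv
#' @export
read_nfi_csv <- function(path, scale = c("raw_linear", "centered_log2")) {
  scale <- match.arg(scale)
  df <- utils::read.csv(path, check.names = FALSE)
  .require_columns(df, c("protein", "pathway"), sprintf("'%s'", path))
  if (ncol(df) < 3L)
    stop(sprintf("'%s' has no sample columns", path), call. = FALSE)
  dup <- which(duplicated(df$protein))
  if (length(dup))
    stop(sprintf("'%s': duplicate protein id '%s' (row %d)",
                 path, df$protein[dup[1L]], dup[1L] + 1L), call. = FALSE)
  v <- as.matrix(df[, setdiff(names(df), c("protein", "pathway")),
                    drop = FALSE])
  if (!is.numeric(v))
    stop(sprintf("'%s': non-numeric sample values", path), call. = FALSE)
  rownames(v) <- df$protein
  nfi_matrix(v, pathway = stats::setNames(df$pathway, df$protein),
             scale = scale)
}

#' Write / read a cytotoxicity plate table as CSV
#'
#' Schema: columns `model`, `drug`, `dose_uM`, `time_h`, `replicate`,
#' `rfu`, `is_vehicle`. On read, the CytotoxTable invariants are checked:
#' non-negative RFU and at least 3 replicates per stratum.
#'
#' @param plate data.frame in the plate schema.
#' @param path file path.
#' @return `read_plate_csv` returns the validated data.frame.
#' @export
write_plate_csv <- function(plate, path) {
  .require_columns(plate, c("model", "drug", "dose_uM", "time_h",
                            "replicate", "rfu", "is_vehicle"), "plate table")
  utils::write.csv(plate, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_plate_csv
#' @export
read_plate_csv <- function(path) {
  df <- utils::read.csv(path)
  .require_columns(df, c("model", "drug", "dose_uM", "time_h", "replicate",
                         "rfu", "is_vehicle"), sprintf("'%s'", path))
  bad <- which(!is.finite(df$rfu) | df$rfu < 0)
  if (length(bad))
    stop(sprintf("'%s': negative or missing RFU at row %d", path,
                 bad[1L] + 1L), call. = FALSE)
  df$is_vehicle <- as.logical(df$is_vehicle)
  .validate_cytotox(df)
  df
}

#' Write / read a co-culture killing table as CSV
#'
#' Schema: columns `arm`, `well`, `pdm_id`, `fi_total_dead`, `fi_dead_til`,
#' `fi_viable_pdm`. On read, the KillingRecord invariants are checked per
#' row (non-negative sums, viable > 0, dead-TIL <= total-dead) and
#' violations are reported with their row number.
#'
#' @param records data.frame in the killing schema.
#' @param path file path.
#' @return `read_killing_csv` returns the validated data.frame.
#' @export
write_killing_csv <- function(records, path) {
  .require_columns(records, c("arm", "well", "pdm_id", "fi_total_dead",
                              "fi_dead_til", "fi_viable_pdm"),
                   "killing table")
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_killing_csv
#' @export
read_killing_csv <- function(path) {
  df <- utils::read.csv(path)
  .require_columns(df, c("arm", "well", "pdm_id", "fi_total_dead",
                         "fi_dead_til", "fi_viable_pdm"),
                   sprintf("'%s'", path))
  num <- c("fi_total_dead", "fi_dead_til", "fi_viable_pdm")
  for (cn in num) {
    bad <- which(!is.finite(df[[cn]]) | df[[cn]] < 0)
    if (length(bad))
      stop(sprintf("'%s': invalid %s at row %d", path, cn, bad[1L] + 1L),
           call. = FALSE)
  }
  bad <- which(df$fi_viable_pdm <= 0)
  if (length(bad))
    stop(sprintf("'%s': fi_viable_pdm must be > 0 (row %d)", path,
                 bad[1L] + 1L), call. = FALSE)
  bad <- which(df$fi_dead_til > df$fi_total_dead)
  if (length(bad))
    stop(sprintf("'%s': fi_dead_til exceeds fi_total_dead (row %d)", path,
                 bad[1L] + 1L), call. = FALSE)
  df
}

#' Run the end-to-end PDM profiling pipeline
#'
#' Chains the analysis stages in assay order on in-memory objects or CSV
#' paths: blank filter, median-center/log2, hierarchical clustering, plate
#' fold changes and sensitivity grading, responder/non-responder split, 20%
#' signature filter, pathway Mann-Whitney tests, per-protein sensitivity
#' correlations, and optionally TR time-course and co-culture killing
#' analyses. Result tables are written as CSV plus one JSON summary; every
#' threshold applied is recorded in `log.txt` so a run is reproducible from
#' its log and inputs.
#'
#' @param nfi an [nfi_matrix()] (raw linear) or path to its CSV.
#' @param plate plate data.frame or CSV path.
#' @param drug drug of interest for grading and signatures.
#' @param killing optional killing data.frame or CSV path.
#' @param tr optional list with `treated` and `vehicle` time-point lists for
#'   [compute_tr()].
#' @param out_dir output directory (created if needed); `NULL` for no file
#'   output.
#' @param blank,signature_ratio,tr_threshold,z_cutoff,p_cuts thresholds:
#'   blank NFI level (0.02), signature mean-ratio (1.2), TR change fraction
#'   (0.5), outlier modified Z cutoff (3.5), grade p-cuts
#'   (0.05/0.01/0.001).
#' @param hcl_k,hcl_metric,hcl_linkage clustering options.
#' @param adjust multiplicity adjustment for the dose-time comparisons.
#' @return (invisibly) a list bundle with every stage's result and the JSON
#'   summary as a list.
#' @export
run_pipeline <- function(nfi, plate, drug,
                         killing = NULL, tr = NULL, out_dir = NULL,
                         blank = 0.02, signature_ratio = 1.2,
                         tr_threshold = 0.5, z_cutoff = 3.5,
                         p_cuts = c(0.05, 0.01, 0.001),
                         hcl_k = 2L, hcl_metric = "pearson",
                         hcl_linkage = "average", adjust = "holm") {
  if (is.character(nfi)) nfi <- read_nfi_csv(nfi)
  if (is.character(plate)) plate <- read_plate_csv(plate)
  if (is.character(killing)) killing <- read_killing_csv(killing)

  log_lines <- c(
    "pdmprofiler pipeline run",
    sprintf("blank NFI level: %g", blank),
    sprintf("signature mean-ratio threshold: %g", signature_ratio),
    sprintf("TR change threshold fraction: %g", tr_threshold),
    sprintf("outlier modified Z cutoff: %g", z_cutoff),
    sprintf("grade p-cuts: %s", paste(p_cuts, collapse = "/")),
    sprintf("HCL: %s distance, %s linkage, k = %d",
            hcl_metric, hcl_linkage, hcl_k),
    sprintf("post-hoc adjustment: %s", adjust),
    sprintf("drug of interest: %s", drug))

  bf <- apply_blank_filter(nfi, blank = blank)
  log_lines <- c(log_lines,
                 sprintf("blank filter: %d/%d proteins excluded (%s)",
                         length(bf$excluded), nrow(nfi),
                         paste(bf$excluded, collapse = ", ")))
  centered <- center_log2(bf$nfi)
  clust <- hcl_cluster(centered, k = min(hcl_k, ncol(centered)),
                       metric = hcl_metric, linkage = hcl_linkage)
  panels <- pathway_summarize(centered)

  grades <- grade_all_models(plate, drug, z_cutoff = z_cutoff,
                             adjust = adjust, p_cuts = p_cuts)
  graded_m <- nfi_select_samples(centered,
                                 intersect(colnames(centered), grades$model))
  split <- split_groups(grades, graded_m)
  sig <- filter_20pct(graded_m, split, min_ratio = signature_ratio)
  path_tests <- withCallingHandlers(
    test_pathways(sig, graded_m, split),
    warning = function(w) invokeRestart("muffleWarning"))
  correlations <- do.call(rbind, lapply(
    sig$protein[sig$passes_20pct],
    function(pr) correlate_with_grade(graded_m, grades, pr)))

  tr_res <- NULL
  if (!is.null(tr)) {
    profile <- compute_tr(tr$treated, tr$vehicle, drug = drug,
                          threshold_fraction = tr_threshold)
    thr <- threshold_tr(profile)
    tests <- withCallingHandlers(test_timecourse(thr$profile),
                                 warning = function(w)
                                   invokeRestart("muffleWarning"))
    tr_res <- list(profile = profile, thresholded = thr, tests = tests)
  }
  kill_res <- if (!is.null(killing)) summarize_arms(killing) else NULL

  summary <- list(
    n_proteins_in = nrow(nfi),
    n_proteins_analyzed = nrow(centered),
    blank_excluded = as.list(bf$excluded),
    cluster_partition = as.list(clust$partition),
    grades = grades[, c("model", "drug", "grade", "responder")],
    n_responders = sum(grades$responder),
    n_signature_proteins = sum(sig$passes_20pct),
    pathway_p = stats::setNames(as.list(path_tests$p), path_tests$pathway),
    thresholds = list(blank = blank, signature_ratio = signature_ratio,
                      tr_threshold = tr_threshold, z_cutoff = z_cutoff,
                      p_cuts = p_cuts))
  if (!is.null(tr_res))
    summary$tr_retained <- length(tr_res$thresholded$retained)
  if (!is.null(kill_res))
    summary$killing_arm_means <- stats::setNames(as.list(kill_res$arms$mean),
                                                 kill_res$arms$arm)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_nfi_csv(centered, file.path(out_dir, "nfi_centered_log2.csv"))
    utils::write.csv(data.frame(sample = names(clust$partition),
                                cluster = clust$partition),
                     file.path(out_dir, "clusters.csv"), row.names = FALSE)
    utils::write.csv(panels$medians, file.path(out_dir, "pathway_medians.csv"),
                     row.names = FALSE)
    utils::write.csv(grades, file.path(out_dir, "sensitivity_grades.csv"),
                     row.names = FALSE)
    utils::write.csv(sig, file.path(out_dir, "signature_table.csv"),
                     row.names = FALSE)
    utils::write.csv(path_tests, file.path(out_dir, "pathway_tests.csv"),
                     row.names = FALSE)
    if (!is.null(correlations))
      utils::write.csv(correlations,
                       file.path(out_dir, "sensitivity_correlations.csv"),
                       row.names = FALSE)
    if (!is.null(tr_res)) {
      utils::write.csv(data.frame(protein = rownames(tr_res$profile),
                                  unclass(tr_res$profile),
                                  check.names = FALSE),
                       file.path(out_dir, "tr_profile.csv"),
                       row.names = FALSE)
      utils::write.csv(tr_res$tests$pairwise,
                       file.path(out_dir, "tr_pairwise_tests.csv"),
                       row.names = FALSE)
    }
    if (!is.null(kill_res)) {
      utils::write.csv(kill_res$arms, file.path(out_dir, "killing_arms.csv"),
                       row.names = FALSE)
      utils::write.csv(kill_res$comparisons,
                       file.path(out_dir, "killing_comparisons.csv"),
                       row.names = FALSE)
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    writeLines(log_lines, file.path(out_dir, "log.txt"))
    if (requireNamespace("pheatmap", quietly = TRUE)) {
      try({
        grDevices::png(file.path(out_dir, "heatmap.png"),
                       width = 900, height = 1200)
        pheatmap::pheatmap(nfi_values(centered),
                           clustering_distance_cols = "correlation",
                           clustering_method = hcl_linkage,
                           show_rownames = nrow(centered) <= 60)
        grDevices::dev.off()
      }, silent = TRUE)
    }
  }

  invisible(list(filtered = bf, centered = centered, cluster = clust,
                 pathway_summary = panels, grades = grades, split = split,
                 signature = sig, pathway_tests = path_tests,
                 correlations = correlations, timecourse = tr_res,
                 killing = kill_res, summary = summary, log = log_lines))
}
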