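#' Configuration for the synthetic PDM cohort generators
#'
#' Builds and validates the single configuration object shared by the four
#' generators ([simulate_rppa()], [simulate_plate()], [simulate_tr_pair()],
#' [simulate_killing()]). Defaults mirror the shape of the study the package
#' models: 7 ovarian-cancer PDM models (4 carboplatin responders, 3
#' non-responders) plus one contrasting breast-cancer sample, 116 proteins
#' over eight pathway panels, cytotoxicity plates at 3 doses and 24/48/72 h
#' with 3-8 replicates, treated/vehicle RPPA pairs at 0.5/4/72 h, and
#' TIL-PDM co-culture killing assays with 9 imaged PDM per arm.
#'
#' NFI values are reported as the log2-scale average of `n_tech` technical
#' replicate measurements (two on the real platform), so `noise_sd_log2` is
#' the spread of a single technical measurement and the effective per-sample
#' spread is `noise_sd_log2 / sqrt(n_tech)`.
#'
#' @param seed integer seed; every generator derives its own substream from
#'   it, so components are individually reproducible.
#' @param n_models number of PDM models in the cohort.
#' @param n_proteins number of proteins on the array.
#' @param pathway_sizes named integer vector over the eight pathway panels;
#'   must sum to `n_proteins`.
#' @param model_ids,responder_models character ids of all models and of the
#'   planted responder subset.
#' @param include_contrast add one contrasting (non-graded) sample, as the
#'   study's breast-cancer PDM, used only for centering/clustering.
#' @param effect_log2 named per-pathway planted responder-vs-non-responder
#'   shift in log2 units (default all 0 = null cohort).
#' @param noise_sd_log2 residual spread of one technical measurement (log2).
#' @param n_tech technical replicates averaged per reported NFI value.
#' @param blank_fraction fraction of proteins planted at blank level
#'   (around or below 0.02 linear NFI) to exercise the quality filter.
#' @param plate_drug drug label for the cytotoxicity plate.
#' @param plate_doses numeric dose levels (uM), 3 by default.
#' @param plate_times assay read times in hours.
#' @param n_replicates replicates per plate stratum, must lie in 3..8.
#' @param plate_fc planted true fold change vs vehicle: a scalar or a
#'   doses x times matrix (1 = no effect).
#' @param plate_noise_sd_log2 log2-scale spread of a single RFU measurement.
#' @param outlier_rate probability in \[0, 1) that a plate record is an
#'   injected artifact.
#' @param outlier_magnitude multiplicative size of an injected artifact.
#' @param tr_times treatment times (h) of the mode-of-action RPPA pairs.
#' @param tr_profiles planted log2 treated/vehicle ratio trajectories: a
#'   pathways x times matrix (rownames = pathway names, one column per
#'   `tr_times`); 0 = no effect.
#' @param tr_noise_sd_log2 log2 spread of a single TR-arm measurement.
#' @param killing_arms named numeric vector of treatment arms with planted
#'   mean dead:viable ratio per arm (fractions, not percent).
#' @param killing_wells,killing_pdm_per_well wells per arm and imaged PDM
#'   per well (3 x 3 = 9 imaged PDM per arm as in the assay).
#' @param killing_noise_sd additive spread of the per-PDM realized ratio.
#'
#' @return a validated list of class `sim_config`.
#' @seealso [simulate_rppa()], [simulate_plate()], [simulate_tr_pair()],
#'   [simulate_killing()]
#' @export
sim_config <- function(seed = 1L,
                       n_models = 7L,
                       n_proteins = 116L,
                       pathway_sizes = NULL,
                       model_ids = NULL,
                       responder_models = NULL,
                       include_contrast = FALSE,
                       effect_log2 = NULL,
                       noise_sd_log2 = 0.25,
                       n_tech = 2L,
                       blank_fraction = 0,
                       plate_drug = "carboplatin",
                       plate_doses = c(75, 150, 300),
                       plate_times = c(24, 48, 72),
                       n_replicates = 6L,
                       plate_fc = 1,
                       plate_noise_sd_log2 = 0.1,
                       outlier_rate = 0,
                       outlier_magnitude = 5,
                       tr_times = c(0.5, 4, 72),
                       tr_profiles = NULL,
                       tr_noise_sd_log2 = 0.1,
                       killing_arms = c(untreated = 0.10, IgG4 = 0.12,
                                        CPI_combo = 0.40),
                       killing_wells = 3L,
                       killing_pdm_per_well = 3L,
                       killing_noise_sd = 0.05) {
  .assert_scalar_number(seed, "seed")
  n_models <- as.integer(.assert_scalar_number(n_models, "n_models", lower = 1))
  n_proteins <- as.integer(.assert_scalar_number(n_proteins, "n_proteins",
                                                 lower = 1))
  if (is.null(pathway_sizes)) pathway_sizes <- default_pathway_sizes(n_proteins)
  if (is.null(names(pathway_sizes)) || any(!nzchar(names(pathway_sizes))))
    stop("'pathway_sizes' must be a named vector of panel sizes", call. = FALSE)
  if (any(pathway_sizes < 0) || any(pathway_sizes != round(pathway_sizes)))
    stop("'pathway_sizes' must be non-negative integers", call. = FALSE)
  if (sum(pathway_sizes) != n_proteins)
    stop(sprintf("'pathway_sizes' must sum to n_proteins (%d), got %d",
                 n_proteins, sum(pathway_sizes)), call. = FALSE)

  if (is.null(model_ids))
    model_ids <- paste0("OvCa", seq_len(n_models))
  if (length(model_ids) != n_models || anyDuplicated(model_ids))
    stop("'model_ids' must be ", n_models, " unique ids", call. = FALSE)
  if (is.null(responder_models))
    responder_models <- model_ids[seq_len(min(4L, max(1L, n_models - 3L)))]
  if (!all(responder_models %in% model_ids))
    stop("'responder_models' must be a subset of model_ids", call. = FALSE)

  eff <- stats::setNames(rep(0, length(pathway_sizes)), names(pathway_sizes))
  if (!is.null(effect_log2)) {
    if (is.null(names(effect_log2)))
      stop("'effect_log2' must be named by pathway", call. = FALSE)
    bad <- setdiff(names(effect_log2), names(pathway_sizes))
    if (length(bad))
      stop("effect_log2 names unknown pathway(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    eff[names(effect_log2)] <- effect_log2
  }
  if (any(!is.finite(eff))) stop("'effect_log2' must be finite", call. = FALSE)

  .assert_scalar_number(noise_sd_log2, "noise_sd_log2", lower = 0)
  n_tech <- as.integer(.assert_scalar_number(n_tech, "n_tech", lower = 1))
  .assert_scalar_number(blank_fraction, "blank_fraction", lower = 0, upper = 0.5)
  n_replicates <- as.integer(
    .assert_scalar_number(n_replicates, "n_replicates", lower = 3, upper = 8))
  .assert_scalar_number(outlier_rate, "outlier_rate", lower = 0, upper = 1 - 1e-12)
  .assert_scalar_number(outlier_magnitude, "outlier_magnitude", lower = 0)
  .assert_scalar_number(plate_noise_sd_log2, "plate_noise_sd_log2", lower = 0)
  .assert_scalar_number(tr_noise_sd_log2, "tr_noise_sd_log2", lower = 0)
  .assert_scalar_number(killing_noise_sd, "killing_noise_sd", lower = 0)
  if (length(plate_doses) < 1 || anyDuplicated(plate_doses))
    stop("'plate_doses' must be distinct dose levels", call. = FALSE)
  if (length(plate_times) < 1 || anyDuplicated(plate_times))
    stop("'plate_times' must be distinct times", call. = FALSE)

  if (is.matrix(plate_fc)) {
    if (!all(dim(plate_fc) == c(length(plate_doses), length(plate_times))))
      stop("'plate_fc' matrix must be doses x times", call. = FALSE)
  } else {
    .assert_scalar_number(plate_fc, "plate_fc", lower = 0)
    plate_fc <- matrix(plate_fc, length(plate_doses), length(plate_times))
  }
  dimnames(plate_fc) <- list(as.character(plate_doses),
                             as.character(plate_times))
  if (any(!is.finite(plate_fc)) || any(plate_fc <= 0))
    stop("planted fold changes must be finite and > 0", call. = FALSE)

  if (is.null(tr_profiles)) {
    tr_profiles <- matrix(0, length(pathway_sizes), length(tr_times),
                          dimnames = list(names(pathway_sizes),
                                          as.character(tr_times)))
  } else {
    if (!is.matrix(tr_profiles) ||
        !all(rownames(tr_profiles) %in% names(pathway_sizes)) ||
        ncol(tr_profiles) != length(tr_times))
      stop("'tr_profiles' must be a pathways x tr_times matrix with pathway rownames",
           call. = FALSE)
    full <- matrix(0, length(pathway_sizes), length(tr_times),
                   dimnames = list(names(pathway_sizes),
                                   as.character(tr_times)))
    full[rownames(tr_profiles), ] <- tr_profiles
    tr_profiles <- full
  }
  if (any(!is.finite(tr_profiles)))
    stop("'tr_profiles' must be finite", call. = FALSE)

  if (is.null(names(killing_arms)) || length(killing_arms) < 1)
    stop("'killing_arms' must be a named vector of planted arm ratios",
         call. = FALSE)
  if (any(!is.finite(killing_arms)) || any(killing_arms < 0))
    stop("planted killing ratios must be finite and >= 0", call. = FALSE)

  structure(list(
    seed = as.integer(seed),
    n_models = n_models, n_proteins = n_proteins,
    pathway_sizes = pathway_sizes,
    model_ids = model_ids, responder_models = responder_models,
    include_contrast = isTRUE(include_contrast),
    effect_log2 = eff, noise_sd_log2 = noise_sd_log2, n_tech = n_tech,
    blank_fraction = blank_fraction,
    plate_drug = plate_drug, plate_doses = plate_doses,
    plate_times = plate_times, n_replicates = n_replicates,
    plate_fc = plate_fc, plate_noise_sd_log2 = plate_noise_sd_log2,
    outlier_rate = outlier_rate, outlier_magnitude = outlier_magnitude,
    tr_times = tr_times, tr_profiles = tr_profiles,
    tr_noise_sd_log2 = tr_noise_sd_log2,
    killing_arms = killing_arms, killing_wells = as.integer(killing_wells),
    killing_pdm_per_well = as.integer(killing_pdm_per_well),
    killing_noise_sd = killing_noise_sd
  ), class = "sim_config")
}

#' Default pathway panel sizes
#'
#' The eight panels of the RPPA array with a default allocation of proteins
#' summing to `n_proteins` (116 by default, the array size of the platform
#' modeled here).
#'
#' @param n_proteins total protein count to allocate.
#' @return named integer vector of panel sizes.
#' @export
default_pathway_sizes <- function(n_proteins = 116L) {
  base <- c("cell cycle" = 20L,
            "DNA damage response" = 12L,
            "apoptosis" = 15L,
            "chromatin regulation" = 10L,
            "MAPK/RTK" = 18L,
            "PI3K/AKT-mTOR-Wnt-NFkB" = 22L,
            "tumor/stem cell markers" = 12L,
            "other" = 7L)
  if (n_proteins == sum(base)) return(base)
  # rescale proportionally, dumping the remainder into "other"
  sizes <- pmax(1L, as.integer(floor(base / sum(base) * n_proteins)))
  sizes["other"] <- sizes["other"] + (n_proteins - sum(sizes))
  if (sizes["other"] < 1L)
    stop("n_proteins too small for eight panels", call. = FALSE)
  sizes
}
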