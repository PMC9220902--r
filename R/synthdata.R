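#' Simulate a synthetic RPPA cohort with known ground truth
#'
#' Draws a proteins x samples matrix of linear NFI values emulating the
#' structure of a PDM RPPA screen: per-protein log-normal baselines, additive
#' log2-scale noise per technical replicate (averaged over `n_tech`
#' replicates), planted per-pathway group shifts between responder and
#' non-responder models, an optional contrasting sample, and a configurable
#' fraction of proteins parked at blank assay level (<= 0.02 NFI) to exercise
#' the quality filter.
#'
#' @param cfg a [sim_config()].
#' @return list with `nfi` (an [nfi_matrix()], raw linear scale) and `truth`,
#'   a list recording the planted responder set, the per-protein differential
#'   flag, the per-protein planted shift, and the blank-protein ids.
#' @examples
#' sim <- simulate_rppa(sim_config(seed = 7,
#'   effect_log2 = c("cell cycle" = 0.8)))
#' dim(sim$nfi)
#' head(sim$truth$differential_proteins)
#' @export
simulate_rppa <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.substream_seed(cfg$seed, 1L))

  pw <- rep(names(cfg$pathway_sizes), cfg$pathway_sizes)
  protein_ids <- sprintf("prot%03d", seq_len(cfg$n_proteins))
  names(pw) <- protein_ids

  samples <- cfg$model_ids
  if (cfg$include_contrast) samples <- c(samples, "BC1")
  is_resp <- cfg$model_ids %in% cfg$responder_models

  baseline_log2 <- stats::rnorm(cfg$n_proteins, mean = 0, sd = 1)
  shift <- cfg$effect_log2[pw]                       # per protein planted shift

  vals <- matrix(0, cfg$n_proteins, length(samples),
                 dimnames = list(protein_ids, samples))
  for (j in seq_along(samples)) {
    mu <- baseline_log2
    if (j <= cfg$n_models && is_resp[j]) mu <- mu + shift
    if (cfg$include_contrast && j == length(samples)) {
      # contrasting histotype: its own pathway-level offsets, fixed draw
      contrast_shift <- stats::rnorm(length(cfg$pathway_sizes), 0, 0.5)
      names(contrast_shift) <- names(cfg$pathway_sizes)
      mu <- mu + contrast_shift[pw]
    }
    tech <- matrix(stats::rnorm(cfg$n_proteins * cfg$n_tech, mean = mu,
                                sd = cfg$noise_sd_log2),
                   cfg$n_proteins, cfg$n_tech)
    vals[, j] <- 2^rowMeans(tech)
  }

  n_blank <- floor(cfg$blank_fraction * cfg$n_proteins)
  blank_ids <- character(0)
  if (n_blank > 0) {
    blank_idx <- sample.int(cfg$n_proteins, n_blank)
    blank_ids <- protein_ids[blank_idx]
    vals[blank_idx, ] <- matrix(
      stats::runif(n_blank * length(samples), 0.004, 0.018),
      n_blank, length(samples))
  }

  truth <- list(
    responder_models = cfg$model_ids[is_resp],
    differential_proteins = stats::setNames(shift != 0 & !(protein_ids %in% blank_ids),
                                            protein_ids),
    planted_shift_log2 = stats::setNames(unname(shift), protein_ids),
    blank_proteins = blank_ids
  )
  list(nfi = nfi_matrix(vals, pathway = pw, scale = "raw_linear"),
       truth = truth)
}

#' Simulate a cytotoxicity plate table with injected outliers
#'
#' Generates long-format plate-reader records (model, drug, dose, time,
#' replicate, RFU) plus matched DMSO vehicle records per model and time.
#' Treated RFU is the vehicle level scaled by the planted fold change for the
#' dose/time cell, applied to the planted responder models only (so the
#' cohort carries a responder/non-responder contrast whenever
#' `plate_fc != 1`); measurement noise is log-normal; artifacts are injected by
#' multiplying records by `outlier_magnitude` with probability `outlier_rate`,
#' and their row positions are recorded in the truth object.
#'
#' @param cfg a [sim_config()].
#' @return list with `plate` (data.frame with columns `model`, `drug`,
#'   `dose_uM`, `time_h`, `replicate`, `rfu`, `is_vehicle`) and `truth`
#'   (planted fold-change matrix and integer row indices of injected
#'   outliers).
#' @export
simulate_plate <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.substream_seed(cfg$seed, 2L))

  base_rfu <- 1000
  rows <- list()
  for (m in cfg$model_ids) {
    for (t in cfg$plate_times) {
      veh <- base_rfu * 2^stats::rnorm(cfg$n_replicates, 0,
                                       cfg$plate_noise_sd_log2)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, drug = "DMSO", dose_uM = NA_real_, time_h = t,
        replicate = seq_len(cfg$n_replicates), rfu = veh, is_vehicle = TRUE)
      for (d in cfg$plate_doses) {
        fc <- if (m %in% cfg$responder_models)
          cfg$plate_fc[as.character(d), as.character(t)] else 1
        trt <- base_rfu * fc * 2^stats::rnorm(cfg$n_replicates, 0,
                                              cfg$plate_noise_sd_log2)
        rows[[length(rows) + 1L]] <- data.frame(
          model = m, drug = cfg$plate_drug, dose_uM = d, time_h = t,
          replicate = seq_len(cfg$n_replicates), rfu = trt, is_vehicle = FALSE)
      }
    }
  }
  plate <- do.call(rbind, rows)
  rownames(plate) <- NULL

  outlier_rows <- integer(0)
  if (cfg$outlier_rate > 0) {
    hit <- stats::runif(nrow(plate)) < cfg$outlier_rate
    outlier_rows <- which(hit)
    plate$rfu[outlier_rows] <- plate$rfu[outlier_rows] * cfg$outlier_magnitude
  }

  list(plate = plate,
       truth = list(planted_fc = cfg$plate_fc, outlier_rows = outlier_rows))
}

#' Simulate treated/vehicle RPPA pairs over treatment times
#'
#' For each treatment time (0.5, 4 and 72 h by default) draws a vehicle and a
#' treated NFI matrix sharing per-protein baselines; the treated arm carries
#' the planted per-pathway log2 treated/vehicle trajectory from
#' `cfg$tr_profiles`. Each matrix has `n_tech` technical replicate columns,
#' to be averaged on the log2 scale by [compute_tr()].
#'
#' @param cfg a [sim_config()].
#' @return list with `treated` and `vehicle` (each a named list over times of
#'   [nfi_matrix()] objects with technical-replicate columns) and `truth`
#'   (the planted per-protein log2 trajectory matrix).
#' @export
simulate_tr_pair <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.substream_seed(cfg$seed, 3L))

  pw <- rep(names(cfg$pathway_sizes), cfg$pathway_sizes)
  protein_ids <- sprintf("prot%03d", seq_len(cfg$n_proteins))
  names(pw) <- protein_ids
  baseline_log2 <- stats::rnorm(cfg$n_proteins, 0, 1)

  planted <- cfg$tr_profiles[pw, , drop = FALSE]
  rownames(planted) <- protein_ids

  draw <- function(mu, tag, tpt) {
    tech <- matrix(stats::rnorm(cfg$n_proteins * cfg$n_tech, mean = mu,
                                sd = cfg$tr_noise_sd_log2),
                   cfg$n_proteins, cfg$n_tech,
                   dimnames = list(protein_ids,
                                   sprintf("%s_t%s_rep%d", tag, tpt,
                                           seq_len(cfg$n_tech))))
    nfi_matrix(2^tech, pathway = pw, scale = "raw_linear")
  }

  treated <- vehicle <- stats::setNames(
    vector("list", length(cfg$tr_times)), as.character(cfg$tr_times))
  for (k in seq_along(cfg$tr_times)) {
    tpt <- as.character(cfg$tr_times[k])
    vehicle[[tpt]] <- draw(baseline_log2, "veh", tpt)
    treated[[tpt]] <- draw(baseline_log2 + planted[, k], "trt", tpt)
  }
  list(treated = treated, vehicle = vehicle,
       truth = list(planted_log2_tr = planted))
}

#' Simulate co-culture killing-assay mask sums
#'
#' Emulates the image-based TIL-mediated killing readout: per treatment arm,
#' `killing_wells` wells x `killing_pdm_per_well` imaged PDM (9 per arm by
#' default). For each imaged PDM three fluorescence mask sums are drawn
#' (total dead, dead TIL, viable PDM) such that the expected
#' dead-vs-viable-PDM ratio `(total_dead - dead_til) / viable` equals the
#' arm's planted value; the realized per-PDM ratio is the planted value plus
#' Gaussian noise truncated at 0.
#'
#' @param cfg a [sim_config()].
#' @return list with `killing` (data.frame with columns `arm`, `well`,
#'   `pdm_id`, `fi_total_dead`, `fi_dead_til`, `fi_viable_pdm`) and `truth`
#'   (planted per-arm ratios).
#' @export
simulate_killing <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(.substream_seed(cfg$seed, 4L))

  viable_base <- 4000; til_base <- 1500
  rows <- list()
  for (arm in names(cfg$killing_arms)) {
    planted <- cfg$killing_arms[[arm]]
    for (w in seq_len(cfg$killing_wells)) {
      for (p in seq_len(cfg$killing_pdm_per_well)) {
        viable <- viable_base * 2^stats::rnorm(1, 0, 0.15)
        dead_til <- til_base * 2^stats::rnorm(1, 0, 0.15)
        ratio <- max(planted + stats::rnorm(1, 0, cfg$killing_noise_sd), 0)
        rows[[length(rows) + 1L]] <- data.frame(
          arm = arm, well = sprintf("%s_w%d", arm, w),
          pdm_id = sprintf("%s_w%d_pdm%d", arm, w, p),
          fi_total_dead = dead_til + ratio * viable,
          fi_dead_til = dead_til, fi_viable_pdm = viable)
      }
    }
  }
  killing <- do.call(rbind, rows)
  rownames(killing) <- NULL
  list(killing = killing, truth = list(planted_ratios = cfg$killing_arms))
}
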