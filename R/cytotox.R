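#' Modified Z-scores for robust multiple-outlier detection
#'
#' Implements the Iglewicz-Hoaglin robust test for multiple outliers:
#' `M_i = 0.6745 * (x_i - median(x)) / MAD`, where MAD is the median absolute
#' deviation from the median. A point is flagged when `|M_i| >= 3.5`
#' (the recommended cutoff). All points are scored in a single pass; the
#' test is not iterated.
#'
#' When MAD is 0 (at least half the values identical) the standard fallback
#' `M_i = (x_i - median) / (1.253314 * meanAD)` is used; if the mean absolute
#' deviation is also 0 all values are identical and nothing is flagged.
#'
#' @param x numeric vector, length >= 3 (the test is undefined for smaller
#'   samples).
#' @param cutoff absolute modified Z-score at or above which a point is an
#'   outlier; default 3.5.
#' @return data.frame with columns `value`, `m` (the modified Z-score) and
#'   `is_outlier`, in input order.
#' @examples
#' modified_zscores(c(1, 2, 3, 4, 100))  # only 100 is flagged, M = 65.4265
#' @export
modified_zscores <- function(x, cutoff = 3.5) {
  if (!is.numeric(x) || length(x) < 3L)
    stop("modified Z-score outlier test needs a numeric vector of length >= 3",
         call. = FALSE)
  if (any(!is.finite(x))) stop("'x' must be finite", call. = FALSE)
  .assert_scalar_number(cutoff, "cutoff", lower = 0)
  med <- stats::median(x)
  dev <- x - med
  mad0 <- stats::median(abs(dev))
  if (mad0 > 0) {
    m <- 0.6745 * dev / mad0
  } else {
    mean_ad <- mean(abs(dev))
    m <- if (mean_ad > 0) dev / (1.253314 * mean_ad) else rep(0, length(x))
  }
  data.frame(value = x, m = m, is_outlier = abs(m) >= cutoff)
}

# Validate the long plate table shape shared by compute_fold_changes and
# the reader; returns the table invisibly.
.validate_cytotox <- function(plate, min_replicates = 3L) {
  .require_columns(plate,
                   c("model", "drug", "dose_uM", "time_h", "replicate",
                     "rfu", "is_vehicle"),
                   "cytotoxicity table")
  if (any(!is.finite(plate$rfu)) || any(plate$rfu < 0))
    stop("RFU values must be finite and non-negative", call. = FALSE)
  # NA doses (vehicle rows) must still count as a stratum
  key <- paste(plate$model, plate$drug,
               ifelse(is.na(plate$dose_uM), "vehicle", plate$dose_uM),
               plate$time_h, sep = "|")
  sizes <- table(key)
  if (any(sizes < min_replicates))
    stop(sprintf(
      "stratum '%s' has %d replicate(s); at least %d are required",
      names(sizes)[which.min(sizes)], min(sizes), min_replicates),
      call. = FALSE)
  invisible(plate)
}

#' DMSO-normalized fold changes with robust outlier removal
#'
#' Converts a long cytotoxicity plate table into treatment fold changes (FC)
#' relative to the matched vehicle control, separately for each time point.
#' Within every replicate stratum (treated and vehicle alike) outlier
#' replicates are removed by the modified Z-score rule
#' ([modified_zscores()]); the stratum FC is then the mean retained treated
#' RFU divided by the mean retained vehicle RFU of the same model and time.
#' Replicate-level FCs (each retained replicate over the vehicle stratum
#' mean) are kept for significance testing, including the vehicle's own
#' replicates, which act as the reference level.
#'
#' @param plate data.frame with columns `model`, `drug`, `dose_uM`, `time_h`,
#'   `replicate`, `rfu`, `is_vehicle`; every treated stratum needs a vehicle
#'   stratum at the same model and time, and every stratum >= 3 replicates.
#' @param z_cutoff modified Z-score cutoff for outlier removal; default 3.5.
#' @return object of class `fc_table`: list with `strata` (per treated
#'   stratum: FC, replicate counts), `replicate_fc` (replicate-level FCs for
#'   treated and vehicle strata) and `outliers` (removed records with their
#'   modified Z-scores).
#' @export
compute_fold_changes <- function(plate, z_cutoff = 3.5) {
  .validate_cytotox(plate)

  veh <- plate[plate$is_vehicle, , drop = FALSE]
  trt <- plate[!plate$is_vehicle, , drop = FALSE]
  if (!nrow(trt)) stop("no treated records in plate table", call. = FALSE)
  if (!nrow(veh)) stop("no vehicle records in plate table", call. = FALSE)

  outliers <- list(); veh_means <- list(); veh_fc <- list()
  veh_key <- function(model, time) paste(model, time, sep = "|")

  for (key in unique(veh_key(veh$model, veh$time_h))) {
    sub <- veh[veh_key(veh$model, veh$time_h) == key, , drop = FALSE]
    z <- modified_zscores(sub$rfu, cutoff = z_cutoff)
    keep <- !z$is_outlier
    if (any(!keep))
      outliers[[length(outliers) + 1L]] <- cbind(sub[!keep, , drop = FALSE],
                                                 m = z$m[!keep])
    mu <- mean(sub$rfu[keep])
    if (!is.finite(mu) || mu <= 0)
      stop(sprintf("vehicle mean RFU <= 0 for stratum '%s'", key),
           call. = FALSE)
    veh_means[[key]] <- mu
    veh_fc[[key]] <- data.frame(
      model = sub$model[keep], drug = sub$drug[keep], dose_uM = NA_real_,
      time_h = sub$time_h[keep], replicate = sub$replicate[keep],
      fc = sub$rfu[keep] / mu, is_vehicle = TRUE)
  }

  strata <- list(); rep_fc <- list()
  tkey <- interaction(trt$model, trt$drug, trt$dose_uM, trt$time_h, drop = TRUE)
  for (key in levels(tkey)) {
    sub <- trt[tkey == key, , drop = FALSE]
    vk <- veh_key(sub$model[1L], sub$time_h[1L])
    if (is.null(veh_means[[vk]]))
      stop(sprintf(
        "no vehicle stratum matches treated stratum model '%s' at %s h",
        sub$model[1L], format(sub$time_h[1L])), call. = FALSE)
    z <- modified_zscores(sub$rfu, cutoff = z_cutoff)
    keep <- !z$is_outlier
    if (any(!keep))
      outliers[[length(outliers) + 1L]] <- cbind(sub[!keep, , drop = FALSE],
                                                 m = z$m[!keep])
    strata[[length(strata) + 1L]] <- data.frame(
      model = sub$model[1L], drug = sub$drug[1L], dose_uM = sub$dose_uM[1L],
      time_h = sub$time_h[1L],
      fc = mean(sub$rfu[keep]) / veh_means[[vk]],
      n_used = sum(keep), n_removed = sum(!keep))
    rep_fc[[length(rep_fc) + 1L]] <- data.frame(
      model = sub$model[keep], drug = sub$drug[keep],
      dose_uM = sub$dose_uM[keep], time_h = sub$time_h[keep],
      replicate = sub$replicate[keep],
      fc = sub$rfu[keep] / veh_means[[vk]], is_vehicle = FALSE)
  }

  out <- list(
    strata = do.call(rbind, strata),
    replicate_fc = rbind(do.call(rbind, rep_fc), do.call(rbind, veh_fc)),
    outliers = if (length(outliers)) do.call(rbind, outliers) else
      data.frame())
  rownames(out$strata) <- rownames(out$replicate_fc) <- NULL
  class(out) <- "fc_table"
  out
}

#' @export
print.fc_table <- function(x, ...) {
  cat(sprintf("<fc_table> %d treated strata, %d replicate-level FCs, %d outliers removed\n",
              nrow(x$strata), nrow(x$replicate_fc),
              if (nrow(x$outliers)) nrow(x$outliers) else 0L))
  invisible(x)
}

#' Two-way ANOVA treatment testing against vehicle control
#'
#' Tests treatment effects for one model and drug on replicate-level fold
#' changes by a two-factor (dose x time) fixed-effects ANOVA that includes
#' the vehicle as reference dose level. Each dose-time cell is then compared
#' against the vehicle cell at the same time point (Dunnett-style contrast
#' using the pooled ANOVA error variance), and the resulting p-values are
#' Holm-adjusted within the model x drug family.
#'
#' @param fc an `fc_table` from [compute_fold_changes()].
#' @param model,drug the model id and drug to test.
#' @param adjust multiplicity adjustment across the dose-time cells, any
#'   method of [stats::p.adjust()]; default `"holm"`.
#' @return data.frame with one row per dose-time cell: `model`, `drug`,
#'   `dose_uM`, `time_h`, `n`, `mean_fc`, `t`, `p`, `p_adj`.
#' @export
test_treatment_effects <- function(fc, model, drug, adjust = "holm") {
  stopifnot(inherits(fc, "fc_table"))
  rf <- fc$replicate_fc
  dat <- rf[rf$model == model & (rf$drug == drug | rf$is_vehicle), ,
            drop = FALSE]
  if (!nrow(dat))
    stop(sprintf("no replicate-level FCs for model '%s', drug '%s'",
                 model, drug), call. = FALSE)
  dat$dose_f <- ifelse(dat$is_vehicle, "vehicle", as.character(dat$dose_uM))
  doses <- setdiff(unique(dat$dose_f), "vehicle")
  times <- sort(unique(dat$time_h))
  if (length(doses) < 2L || length(times) < 2L)
    stop("two-way ANOVA needs >= 2 doses and >= 2 time points", call. = FALSE)

  cell <- interaction(dat$dose_f, dat$time_h, drop = TRUE)
  sizes <- tapply(dat$fc, cell, length)
  if (any(sizes < 2L))
    stop(sprintf("stratum '%s' has a single replicate-level FC; cannot test",
                 names(sizes)[which.min(sizes)]), call. = FALSE)
  cell_means <- tapply(dat$fc, cell, mean)
  resid_ss <- sum((dat$fc - cell_means[as.character(cell)])^2)
  df_err <- nrow(dat) - length(cell_means)
  mse <- resid_ss / df_err

  res <- list()
  for (t in times) {
    vk <- paste("vehicle", t, sep = ".")
    if (!vk %in% names(cell_means))
      stop(sprintf("no vehicle cell at %s h for model '%s'", format(t), model),
           call. = FALSE)
    n_v <- sizes[[vk]]
    for (d in doses) {
      ck <- paste(d, t, sep = ".")
      if (!ck %in% names(cell_means)) next
      n_c <- sizes[[ck]]
      se <- sqrt(mse * (1 / n_c + 1 / n_v))
      tstat <- (cell_means[[ck]] - cell_means[[vk]]) / se
      res[[length(res) + 1L]] <- data.frame(
        model = model, drug = drug, dose_uM = as.numeric(d), time_h = t,
        n = n_c, mean_fc = cell_means[[ck]], t = tstat,
        p = 2 * stats::pt(-abs(tstat), df_err))
    }
  }
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  out <- out[order(out$time_h, out$dose_uM), ]
  rownames(out) <- NULL
  out
}

#' Ordinal 0-3 drug-sensitivity grade from adjusted p-values
#'
#' Maps the treatment-effect p-values of one model x drug to the ordinal
#' sensitivity grade used for responder calling: grade 0 for p > 0.05, 1 for
#' p < 0.05, 2 for p < 0.01, 3 for p < 0.001. The grade is driven by the
#' minimum adjusted p-value across doses at the final time point (72 h by
#' default), so a model responding only at a higher dose still counts as a
#' responder. `responder` is `TRUE` iff grade >= 1.
#'
#' @param pvals data.frame from [test_treatment_effects()] (columns
#'   `dose_uM`, `time_h`, `p_adj`, plus `model`/`drug` if available).
#' @param final_time time point (h) the grade is read at; default 72.
#' @param p_cuts strictly decreasing significance cuts for grades 1, 2, 3.
#' @return one-row data.frame of class `sensitivity_grade` with columns
#'   `model`, `drug`, `grade`, `responder`, `min_p_adj`; the backing
#'   per-cell p-values are attached as attribute `"pvalues"`.
#' @examples
#' pv <- data.frame(model = "m", drug = "d", dose_uM = c(75, 150),
#'                  time_h = 72, p_adj = c(0.004, 0.2))
#' grade_sensitivity(pv)$grade   # 2
#' @export
grade_sensitivity <- function(pvals, final_time = 72,
                              p_cuts = c(0.05, 0.01, 0.001)) {
  .require_columns(pvals, c("dose_uM", "time_h", "p_adj"), "p-value table")
  if (length(p_cuts) != 3L || any(diff(p_cuts) >= 0) || any(p_cuts <= 0))
    stop("'p_cuts' must be three strictly decreasing positive cuts",
         call. = FALSE)
  fin <- pvals[pvals$time_h == final_time, , drop = FALSE]
  if (!nrow(fin))
    stop(sprintf("no adjusted p-values at the final time point (%s h); cannot grade",
                 format(final_time)), call. = FALSE)
  minp <- min(fin$p_adj)
  grade <- sum(minp < p_cuts)
  out <- data.frame(
    model = if ("model" %in% names(pvals)) pvals$model[1L] else NA_character_,
    drug = if ("drug" %in% names(pvals)) pvals$drug[1L] else NA_character_,
    grade = grade, responder = grade >= 1L, min_p_adj = minp)
  attr(out, "pvalues") <- pvals
  class(out) <- c("sensitivity_grade", class(out))
  out
}

#' Grade drug sensitivity for every model in a plate table
#'
#' Convenience wrapper chaining [compute_fold_changes()],
#' [test_treatment_effects()] and [grade_sensitivity()] over all models for
#' one drug.
#'
#' @inheritParams compute_fold_changes
#' @inheritParams test_treatment_effects
#' @inheritParams grade_sensitivity
#' @param drug drug to grade.
#' @return data.frame with one graded row per model (see
#'   [grade_sensitivity()]).
#' @export
grade_all_models <- function(plate, drug, z_cutoff = 3.5, adjust = "holm",
                             final_time = 72, p_cuts = c(0.05, 0.01, 0.001)) {
  fc <- compute_fold_changes(plate, z_cutoff = z_cutoff)
  models <- unique(fc$strata$model[fc$strata$drug == drug])
  if (!length(models))
    stop(sprintf("drug '%s' absent from plate table", drug), call. = FALSE)
  out <- lapply(models, function(m) {
    pv <- test_treatment_effects(fc, m, drug, adjust = adjust)
    g <- grade_sensitivity(pv, final_time = final_time, p_cuts = p_cuts)
    attr(g, "pvalues") <- NULL
    as.data.frame(g)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
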