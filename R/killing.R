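#' Dead-vs-viable-PDM killing ratio from fluorescence mask sums
#'
#' The image-based killing readout of the TIL-PDM co-culture assay: for one
#' imaged PDM with mask fluorescence-intensity (FI) sums for total dead
#' cells, dead TILs, and viable PDM,
#' `R = (total dead FI - dead TIL FI) / viable PDM FI`,
#' i.e. dead PDM signal relative to viable PDM signal, reported as percent.
#'
#' @param fi_total_dead,fi_dead_til,fi_viable_pdm non-negative FI sums
#'   (vectorized); `fi_viable_pdm` must be strictly positive and
#'   `fi_dead_til` must not exceed `fi_total_dead`.
#' @param as_percent return percent (default) instead of a fraction.
#' @return numeric vector of killing ratios.
#' @examples
#' killing_ratio(300, 100, 400)   # 50
#' @export
killing_ratio <- function(fi_total_dead, fi_dead_til, fi_viable_pdm,
                          as_percent = TRUE) {
  if (any(!is.finite(fi_total_dead)) || any(!is.finite(fi_dead_til)) ||
      any(!is.finite(fi_viable_pdm)))
    stop("mask FI sums must be finite", call. = FALSE)
  if (any(fi_total_dead < 0) || any(fi_dead_til < 0))
    stop("mask FI sums must be non-negative", call. = FALSE)
  if (any(fi_viable_pdm <= 0))
    stop("viable-PDM FI sum must be strictly positive", call. = FALSE)
  if (any(fi_dead_til > fi_total_dead))
    stop("dead-TIL FI exceeds total-dead FI; mask invariant violated",
         call. = FALSE)
  r <- (fi_total_dead - fi_dead_til) / fi_viable_pdm
  if (as_percent) 100 * r else r
}

#' Summarize and compare treatment arms of a killing assay
#'
#' Computes the per-PDM killing ratio ([killing_ratio()]) for every record,
#' summarizes each treatment arm (mean, SD, n), and compares all arm pairs
#' with unpaired two-tailed Mann-Whitney U tests (exact for small samples
#' without ties). Each imaged PDM is one observation; PDM are pooled across
#' the triplicate wells of an arm (well effects are not modeled).
#'
#' @param records data.frame with columns `arm`, `well`, `pdm_id`,
#'   `fi_total_dead`, `fi_dead_til`, `fi_viable_pdm`.
#' @param as_percent report ratios as percent (default) or fractions.
#' @return list of class `killing_result`: `ratios` (records plus their
#'   ratio), `arms` (per-arm summary), `comparisons` (pairwise `arm_a`,
#'   `arm_b`, `U`, `p`). Arms with fewer than 3 records are excluded with a
#'   warning; fewer than 2 usable arms is an error.
#' @export
summarize_arms <- function(records, as_percent = TRUE) {
  .require_columns(records,
                   c("arm", "well", "pdm_id", "fi_total_dead", "fi_dead_til",
                     "fi_viable_pdm"),
                   "killing table")
  records$ratio <- killing_ratio(records$fi_total_dead, records$fi_dead_til,
                                 records$fi_viable_pdm,
                                 as_percent = as_percent)
  sizes <- table(records$arm)
  small <- names(sizes)[sizes < 3L]
  if (length(small)) {
    warning("arm(s) with < 3 imaged PDM excluded: ",
            paste(small, collapse = ", "))
    records <- records[!records$arm %in% small, , drop = FALSE]
  }
  arms <- sort(unique(records$arm))
  if (length(arms) < 2L)
    stop("arm comparison needs at least 2 arms with >= 3 imaged PDM each",
         call. = FALSE)
  summ <- do.call(rbind, lapply(arms, function(a) {
    r <- records$ratio[records$arm == a]
    data.frame(arm = a, n = length(r), mean = mean(r),
               sd = stats::sd(r), median = stats::median(r))
  }))
  comp <- list()
  for (i in seq_len(length(arms) - 1L)) {
    for (j in seq((i + 1L), length(arms))) {
      ra <- records$ratio[records$arm == arms[i]]
      rb <- records$ratio[records$arm == arms[j]]
      wt <- suppressWarnings(
        stats::wilcox.test(ra, rb, alternative = "two.sided"))
      comp[[length(comp) + 1L]] <- data.frame(
        arm_a = arms[i], arm_b = arms[j], U = unname(wt$statistic),
        p = wt$p.value)
    }
  }
  structure(list(ratios = records, arms = summ,
                 comparisons = do.call(rbind, comp)),
            class = "killing_result")
}

#' @export
print.killing_result <- function(x, ...) {
  cat(sprintf("<killing_result> %d arms, %d imaged PDM\n",
              nrow(x$arms), nrow(x$ratios)))
  print(x$arms, row.names = FALSE)
  invisible(x)
}

#' Dead-cell volume fraction with viability QC flag
#'
#' Live/dead quantification of untreated PDM from 3D image volumes: the dead
#' fraction is `dead / (dead + viable)`. Fractions above the QC threshold
#' (default 0.07, i.e. more than 7% of the total cell mass dead) are
#' flagged as failing the viability check.
#'
#' @param dead,viable non-negative cell volumes in the same units, not both
#'   zero (vectorized).
#' @param qc_threshold maximum acceptable dead fraction; default 0.07.
#' @return data.frame with `dead_fraction` and `qc_pass`.
#' @examples
#' viability_fraction(7, 93)    # 0.07, passes
#' viability_fraction(20, 80)   # 0.20, flagged
#' @export
viability_fraction <- function(dead, viable, qc_threshold = 0.07) {
  if (any(!is.finite(dead)) || any(!is.finite(viable)) ||
      any(dead < 0) || any(viable < 0))
    stop("volumes must be finite and non-negative", call. = FALSE)
  if (any(dead + viable == 0))
    stop("dead and viable volumes are both zero; fraction undefined",
         call. = FALSE)
  .assert_scalar_number(qc_threshold, "qc_threshold", lower = 0, upper = 1)
  frac <- dead / (dead + viable)
  data.frame(dead_fraction = frac, qc_pass = frac <= qc_threshold)
}
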