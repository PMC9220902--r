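#' Treated-to-vehicle NFI ratio (TR) profiles over treatment times
#'
#' Computes the drug mode-of-action readout: per protein and treatment time,
#' the log2 ratio of treated to vehicle NFI. Technical replicate columns of
#' each matrix are averaged on the log2 scale before the ratio is taken.
#'
#' @param treated,vehicle named lists over treatment times (e.g. `"0.5"`,
#'   `"4"`, `"72"`) of raw linear [nfi_matrix()] objects with matching
#'   protein sets; columns are technical replicates. A single matrix is also
#'   accepted for a one-time-point profile.
#' @param drug,model optional labels carried on the profile.
#' @param threshold_fraction treatment-specific change threshold carried for
#'   [threshold_tr()]; default 0.5 (the carboplatin setting: minimum 50%
#'   difference).
#' @return object of class `tr_profile`: a proteins x times matrix of log2
#'   TR values with attributes `pathway`, `drug`, `model`,
#'   `threshold_fraction`.
#' @export
compute_tr <- function(treated, vehicle, drug = NA_character_,
                       model = NA_character_, threshold_fraction = 0.5) {
  if (inherits(treated, "nfi_matrix")) treated <- list(t = treated)
  if (inherits(vehicle, "nfi_matrix")) vehicle <- list(t = vehicle)
  if (!identical(names(treated), names(vehicle)))
    stop("treated and vehicle time points do not match", call. = FALSE)
  .assert_scalar_number(threshold_fraction, "threshold_fraction",
                        lower = 1e-12, upper = 1)

  log_mean <- function(m, arm, tpt) {
    stopifnot(inherits(m, "nfi_matrix"))
    v <- nfi_values(m)
    if (any(v <= 0))
      stop(sprintf("non-positive NFI in %s arm at time %s", arm, tpt),
           call. = FALSE)
    rowMeans(log2(v))
  }

  cols <- lapply(names(treated), function(tpt) {
    tv <- treated[[tpt]]; vv <- vehicle[[tpt]]
    if (!identical(rownames(tv), rownames(vv)))
      stop(sprintf("protein sets differ between treated and vehicle at time %s",
                   tpt), call. = FALSE)
    log_mean(tv, "treated", tpt) - log_mean(vv, "vehicle", tpt)
  })
  tr <- do.call(cbind, cols)
  colnames(tr) <- names(treated)
  structure(tr, pathway = nfi_pathways(treated[[1L]]), drug = drug,
            model = model, threshold_fraction = threshold_fraction,
            class = c("tr_profile", class(tr)))
}

#' @export
print.tr_profile <- function(x, ...) {
  cat(sprintf(
    "<tr_profile> %d proteins x %d time points (h: %s), threshold %.0f%%\n",
    nrow(x), ncol(x), paste(colnames(x), collapse = ", "),
    100 * attr(x, "threshold_fraction")))
  invisible(x)
}

#' Apply the treatment-specific protein-change threshold to a TR profile
#'
#' A protein is retained when its treated/vehicle ratio differs from 1 by at
#' least the threshold fraction at one or more time points: with threshold
#' 0.5 (the carboplatin setting), `|log2 TR| >= log2(1.5)` somewhere along
#' the trajectory. The full trajectory of a retained protein is kept; the
#' boundary is inclusive.
#'
#' @param p a `tr_profile` from [compute_tr()].
#' @param threshold_fraction minimum fractional change; defaults to the
#'   profile's own setting.
#' @return list with `profile` (the filtered `tr_profile`), `retained` and
#'   `excluded` (protein id vectors).
#' @export
threshold_tr <- function(p, threshold_fraction = NULL) {
  stopifnot(inherits(p, "tr_profile"))
  thr <- threshold_fraction %||% attr(p, "threshold_fraction")
  .assert_scalar_number(thr, "threshold_fraction", lower = 1e-12, upper = 1)
  cut <- log2(1 + thr)
  keep <- apply(abs(unclass(p)), 1L, max) >= cut - 1e-12
  kept <- unclass(p)[keep, , drop = FALSE]
  prof <- structure(kept, pathway = attr(p, "pathway")[rownames(kept)],
                    drug = attr(p, "drug"), model = attr(p, "model"),
                    threshold_fraction = thr,
                    class = c("tr_profile", class(kept)))
  list(profile = prof, retained = rownames(p)[keep],
       excluded = rownames(p)[!keep])
}

# Wilcoxon helpers that return p = 1 on fully degenerate inputs (all paired
# differences zero / all values zero) instead of erroring.
.wilcox_paired_p <- function(a, b) {
  d <- a - b
  if (all(d == 0)) return(1)
  suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))$p.value
}
.wilcox_vs_zero_p <- function(a) {
  if (all(a == 0)) return(1)
  suppressWarnings(stats::wilcox.test(a, mu = 0))$p.value
}

#' Pathway-level tests of TR trajectories across treatment times
#'
#' For each pathway panel with at least two proteins surviving
#' [threshold_tr()], runs (a) Wilcoxon signed-rank tests paired by protein
#' between every pair of time points, and (b) one-sample Wilcoxon tests of
#' the panel's TR values against 0 (i.e. against vehicle) at each time
#' point. All p-values are two-sided.
#'
#' @param p a (typically thresholded) `tr_profile`.
#' @return list with `pairwise` (data.frame `pathway`, `time_a`, `time_b`,
#'   `n`, `p`) and `vs_control` (data.frame `pathway`, `time`, `n`, `p`).
#'   Panels with < 2 proteins are skipped with a warning.
#' @export
test_timecourse <- function(p) {
  stopifnot(inherits(p, "tr_profile"))
  pw <- attr(p, "pathway")
  v <- unclass(p)
  attr(v, "pathway") <- attr(v, "drug") <- attr(v, "model") <- NULL
  attr(v, "threshold_fraction") <- NULL
  times <- colnames(v)
  pairwise <- list(); vs_control <- list()
  for (panel in unique(pw)) {
    members <- names(pw)[pw == panel]
    members <- intersect(members, rownames(v))
    if (length(members) < 2L) {
      warning(sprintf("pathway '%s': < 2 proteins after thresholding; skipped",
                      panel))
      next
    }
    sub <- v[members, , drop = FALSE]
    if (length(times) >= 2L) {
      for (i in seq_len(length(times) - 1L)) {
        for (j in seq((i + 1L), length(times))) {
          pairwise[[length(pairwise) + 1L]] <- data.frame(
            pathway = panel, time_a = times[i], time_b = times[j],
            n = length(members),
            p = .wilcox_paired_p(sub[, i], sub[, j]))
        }
      }
    }
    for (t in times) {
      vs_control[[length(vs_control) + 1L]] <- data.frame(
        pathway = panel, time = t, n = length(members),
        p = .wilcox_vs_zero_p(sub[, t]))
    }
  }
  list(pairwise = if (length(pairwise)) do.call(rbind, pairwise) else
         data.frame(),
       vs_control = if (length(vs_control)) do.call(rbind, vs_control) else
         data.frame())
}
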