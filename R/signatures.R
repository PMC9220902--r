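#' Split cohort samples into responders and non-responders
#'
#' Partitions the samples of an NFI matrix into responder (grade >= 1) and
#' non-responder (grade 0) groups according to their functional sensitivity
#' grades for a chosen drug.
#'
#' @param grades data.frame with columns `model` and `grade` (e.g. from
#'   [grade_all_models()]); every matrix sample must be graded.
#' @param m an [nfi_matrix()] whose samples are the graded models.
#' @return list of class `group_split` with `responders` and
#'   `non_responders` (character sample ids).
#' @export
split_groups <- function(grades, m) {
  .require_columns(grades, c("model", "grade"), "grade table")
  stopifnot(inherits(m, "nfi_matrix"))
  samples <- colnames(m)
  missing <- setdiff(samples, grades$model)
  if (length(missing))
    stop("no sensitivity grade for sample(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  g <- grades$grade[match(samples, grades$model)]
  resp <- samples[g >= 1L]
  nonr <- samples[g < 1L]
  if (!length(resp) || !length(nonr))
    stop("responder signature undefined: one of the groups is empty",
         call. = FALSE)
  structure(list(responders = resp, non_responders = nonr),
            class = "group_split")
}

#' Responder-signature filter: >20% difference between group means
#'
#' Screens proteins for a responder vs non-responder abundance difference.
#' Group means are taken on the centered log2 scale and back-transformed, so
#' the comparison is a ratio of geometric means on the linear NFI scale; a
#' protein passes when the larger-to-smaller mean ratio reaches 1.2 (a >20%
#' difference between the means, boundary inclusive).
#'
#' @param m an [nfi_matrix()] on the `centered_log2` scale.
#' @param split a `group_split` from [split_groups()].
#' @param min_ratio linear-scale mean ratio required to pass; default 1.2.
#' @return data.frame (class `signature_table`) with one row per protein:
#'   `protein`, `pathway`, `mean_responder`, `mean_non_responder` (log2),
#'   `ratio` (linear scale, >= 1), `passes_20pct`, `direction` (`"up"` /
#'   `"down"` in responders).
#' @export
filter_20pct <- function(m, split, min_ratio = 1.2) {
  stopifnot(inherits(m, "nfi_matrix"), inherits(split, "group_split"))
  if (nfi_scale(m) != "centered_log2")
    stop("signature filter expects a centered log2 matrix", call. = FALSE)
  .assert_scalar_number(min_ratio, "min_ratio", lower = 1)
  v <- nfi_values(m)
  bad <- setdiff(c(split$responders, split$non_responders), colnames(v))
  if (length(bad))
    stop("split names unknown sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  mr <- rowMeans(v[, split$responders, drop = FALSE])
  mn <- rowMeans(v[, split$non_responders, drop = FALSE])
  ratio <- 2^abs(mr - mn)
  out <- data.frame(
    protein = rownames(v), pathway = nfi_pathways(m)[rownames(v)],
    mean_responder = mr, mean_non_responder = mn,
    ratio = ratio, passes_20pct = ratio >= min_ratio - 1e-9,
    direction = ifelse(mr >= mn, "up", "down"), row.names = NULL)
  class(out) <- c("signature_table", class(out))
  out
}

#' Pathway-level responder vs non-responder Mann-Whitney tests
#'
#' For each pathway panel, pools the per-protein per-sample centered log2
#' values of signature-passing member proteins and compares responder
#' against non-responder pools with an unpaired two-tailed Mann-Whitney U
#' test (exact where feasible). Values within a panel are pooled across
#' proteins, mirroring the boxplot-and-test presentation of pathway
#' activity; the implied pseudo-replication is recorded in the result.
#'
#' @param sig a `signature_table` from [filter_20pct()].
#' @param m the [nfi_matrix()] (`centered_log2`) the signature was derived
#'   from.
#' @param split the `group_split` used.
#' @param adjust optional p-value adjustment across panels
#'   ([stats::p.adjust()] method); default `"none"` (raw p-values are
#'   reported, as is conventional for these panel comparisons).
#' @return data.frame with per tested panel: `pathway`, `n_proteins`,
#'   `n_responder_values`, `n_non_responder_values`, `U`, `p`, `p_adj`;
#'   attribute `"pooling"` documents the protein x sample pooling. Panels
#'   with no passing proteins are skipped with a warning.
#' @export
test_pathways <- function(sig, m, split, adjust = "none") {
  stopifnot(inherits(sig, "signature_table"), inherits(m, "nfi_matrix"),
            inherits(split, "group_split"))
  v <- nfi_values(m)
  res <- list()
  for (p in unique(sig$pathway)) {
    members <- sig$protein[sig$pathway == p & sig$passes_20pct]
    if (!length(members)) {
      warning(sprintf("pathway '%s': no signature-passing proteins; skipped", p))
      next
    }
    pool_r <- as.vector(v[members, split$responders, drop = FALSE])
    pool_n <- as.vector(v[members, split$non_responders, drop = FALSE])
    wt <- suppressWarnings(
      stats::wilcox.test(pool_r, pool_n, alternative = "two.sided"))
    res[[length(res) + 1L]] <- data.frame(
      pathway = p, n_proteins = length(members),
      n_responder_values = length(pool_r),
      n_non_responder_values = length(pool_n),
      U = unname(wt$statistic), p = wt$p.value)
  }
  if (!length(res))
    stop("no pathway had signature-passing proteins", call. = FALSE)
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, method = adjust)
  rownames(out) <- NULL
  attr(out, "pooling") <-
    "protein x sample values pooled within panel (pseudo-replication)"
  out
}

#' Spearman correlation of protein abundance with sensitivity grade
#'
#' Correlates the per-model centered log2 NFI of one protein with the
#' ordinal 0-3 sensitivity grade by Spearman's rank correlation
#' (average-rank tie handling). The two-sided p-value is computed by exact
#' permutation of the grade vector when n <= `exact_max` (default 8, i.e.
#' up to 40320 permutations), and by the t-approximation otherwise. Zero
#' variance in either vector yields an explicitly flagged undefined result
#' rather than a silent 0.
#'
#' @param m an [nfi_matrix()] on the `centered_log2` scale.
#' @param grades data.frame with `model` and `grade` covering >= 4 matrix
#'   samples.
#' @param protein protein id to correlate.
#' @param exact_max largest n for which the exact permutation null is
#'   enumerated.
#' @return one-row data.frame: `protein`, `n`, `rho`, `p`, `method`,
#'   `undefined` (logical).
#' @export
correlate_with_grade <- function(m, grades, protein, exact_max = 8L) {
  stopifnot(inherits(m, "nfi_matrix"))
  .require_columns(grades, c("model", "grade"), "grade table")
  if (!protein %in% rownames(m))
    stop(sprintf("protein '%s' not in matrix", protein), call. = FALSE)
  common <- intersect(colnames(m), grades$model)
  if (length(common) < 4L)
    stop("need >= 4 graded models for a sensitivity correlation", call. = FALSE)
  x <- nfi_values(m)[protein, common]
  y <- grades$grade[match(common, grades$model)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(data.frame(protein = protein, n = length(x), rho = NA_real_,
                      p = NA_real_, method = "undefined", undefined = TRUE))
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (n <= exact_max) {
    perms <- .permutations(n)
    rx <- rank(x)
    ry <- rank(y)
    rperm <- apply(perms, 1L, function(idx) stats::cor(rx, ry[idx]))
    p <- mean(abs(rperm) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
    method <- "t approximation"
  }
  data.frame(protein = protein, n = n, rho = rho, p = p, method = method,
             undefined = FALSE)
}
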