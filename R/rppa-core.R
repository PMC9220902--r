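#' Exclude blank-level proteins from a raw NFI matrix
#'
#' Proteins whose NFI signal sits at blank assay level carry no usable
#' abundance information and are excluded before normalization. The rule is
#' applied per protein: a protein is removed when its median linear NFI
#' across all samples is at or below `blank` (0.02 NFI, the platform's blank
#' assay level).
#'
#' @param m an [nfi_matrix()] on the raw linear scale.
#' @param blank linear NFI blank level; default 0.02.
#' @return list with `nfi` (the filtered matrix, retained values untouched)
#'   and `excluded` (character vector of removed protein ids).
#' @export
apply_blank_filter <- function(m, blank = 0.02) {
  stopifnot(inherits(m, "nfi_matrix"))
  if (nfi_scale(m) != "raw_linear")
    stop("blank filter applies to raw linear NFI matrices", call. = FALSE)
  .assert_scalar_number(blank, "blank", lower = 0)
  v <- nfi_values(m)
  med <- apply(v, 1L, stats::median)
  drop <- med <= blank
  if (all(drop))
    stop("all proteins fall at or below blank level; empty matrix", call. = FALSE)
  kept <- v[!drop, , drop = FALSE]
  list(nfi = .nfi_like(kept, m), excluded = rownames(v)[drop])
}

#' Median-center and log2-transform an NFI matrix
#'
#' Normalizes a raw linear NFI matrix to relative protein abundance: each
#' protein row is divided by its median across all samples, then
#' log2-transformed (equivalently, the row median is subtracted on the log2
#' scale). Every output row has median 0.
#'
#' @param m an [nfi_matrix()] on the raw linear scale with strictly positive
#'   values (apply [apply_blank_filter()] first).
#' @return an [nfi_matrix()] on the `centered_log2` scale.
#' @examples
#' m <- nfi_matrix(matrix(c(1, 2, 4), 1, 3,
#'                        dimnames = list("p1", c("s1", "s2", "s3"))))
#' nfi_values(center_log2(m))   # -1 0 1
#' @export
center_log2 <- function(m) {
  stopifnot(inherits(m, "nfi_matrix"))
  if (nfi_scale(m) != "raw_linear")
    stop("center_log2 expects a raw linear NFI matrix", call. = FALSE)
  v <- nfi_values(m)
  if (any(v <= 0)) {
    idx <- which(v <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "non-positive NFI value for protein '%s' in sample '%s'; cannot log-transform",
      rownames(v)[idx[1L]], colnames(v)[idx[2L]]), call. = FALSE)
  }
  lv <- log2(v)
  centered <- sweep(lv, 1L, apply(lv, 1L, stats::median))
  .nfi_like(centered, m, scale = "centered_log2")
}

#' Hierarchical clustering of samples by protein profile similarity
#'
#' Agglomerative clustering of samples of a centered log2 NFI matrix, as used
#' to group PDM models by their relative protein signal intensities. The
#' default distance is Pearson correlation distance (1 - r) between sample
#' profiles with average linkage; both are configurable.
#'
#' @param m an [nfi_matrix()] on the `centered_log2` scale (>= 2 samples).
#' @param k requested flat partition size (`1 <= k <=` number of samples).
#' @param metric `"pearson"` (1 - correlation) or `"euclidean"`.
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return list of class `hcl_result` with elements `hclust` (the merge
#'   tree), `order` (sample ids in dendrogram order), `partition` (named
#'   cluster membership at `k`), and `k`.
#' @export
hcl_cluster <- function(m, k = 2L, metric = c("pearson", "euclidean"),
                        linkage = "average") {
  stopifnot(inherits(m, "nfi_matrix"))
  metric <- match.arg(metric)
  v <- nfi_values(m)
  n <- ncol(v)
  if (n < 2L) stop("need at least 2 samples to cluster", call. = FALSE)
  k <- as.integer(.assert_scalar_number(k, "k", lower = 1))
  if (k > n)
    stop(sprintf("k = %d exceeds the number of samples (%d)", k, n),
         call. = FALSE)
  d <- switch(metric,
              pearson = stats::as.dist(1 - stats::cor(v)),
              euclidean = stats::dist(t(v)))
  hc <- stats::hclust(d, method = linkage)
  part <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, order = colnames(v)[hc$order],
                 partition = part, k = k, metric = metric, linkage = linkage),
            class = "hcl_result")
}

#' @export
print.hcl_result <- function(x, ...) {
  cat(sprintf("<hcl_result> %d samples, %s distance, %s linkage, k = %d\n",
              length(x$partition), x$metric, x$linkage, x$k))
  print(x$partition)
  invisible(x)
}

#' Summarize a centered NFI matrix by pathway panel
#'
#' Sorts proteins by their pathway affiliation and reports, per panel and
#' sample, the median log2 NFI of member proteins together with the full set
#' of member values (the sets feed the nonparametric panel comparisons
#' downstream).
#'
#' @param m an [nfi_matrix()] on the `centered_log2` scale with pathway
#'   annotation.
#' @return list with `medians` (data.frame `pathway`, `sample`,
#'   `median_log2`, `n_proteins`) and `values` (named list: per pathway the
#'   proteins x samples submatrix of member values). Empty panels are
#'   skipped with a warning.
#' @export
pathway_summarize <- function(m) {
  stopifnot(inherits(m, "nfi_matrix"))
  v <- nfi_values(m)
  pw <- nfi_pathways(m)
  panels <- unique(pw)
  medians <- list(); values <- list()
  for (p in panels) {
    members <- names(pw)[pw == p]
    if (!length(members)) {
      warning(sprintf("pathway panel '%s' has no member proteins; skipped", p))
      next
    }
    sub <- v[members, , drop = FALSE]
    values[[p]] <- sub
    medians[[p]] <- data.frame(
      pathway = p, sample = colnames(sub),
      median_log2 = apply(sub, 2L, stats::median),
      n_proteins = length(members), row.names = NULL)
  }
  med <- do.call(rbind, medians)
  rownames(med) <- NULL
  list(medians = med, values = values)
}
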