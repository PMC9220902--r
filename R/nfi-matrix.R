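#' NFI matrix: proteins x samples relative protein abundance
#'
#' Container for reverse-phase protein array (RPPA) readouts. Each entry is a
#' protein-normalized, background-corrected mean fluorescence intensity (NFI),
#' either on the raw linear scale or, after processing, as per-protein
#' median-centered log2 values. Every protein carries a pathway-panel
#' annotation used by downstream pathway-level analyses.
#'
#' @param values numeric matrix, proteins in rows (rownames = protein ids,
#'   unique), samples in columns (colnames = sample ids, unique).
#' @param pathway named character vector mapping protein id to pathway panel
#'   name; proteins absent from the map are annotated `"unassigned"`.
#' @param scale `"raw_linear"` (values must be >= 0) or `"centered_log2"`
#'   (values must be finite).
#'
#' @return an object of class `nfi_matrix`: the numeric matrix with
#'   attributes `pathway` and `nfi_scale`.
#' @examples
#' m <- nfi_matrix(matrix(c(1, 2, 4, 8), 2, 2,
#'                        dimnames = list(c("p1", "p2"), c("s1", "s2"))),
#'                 pathway = c(p1 = "cell cycle", p2 = "apoptosis"))
#' nfi_scale(m)
#' @export
nfi_matrix <- function(values, pathway = NULL,
                       scale = c("raw_linear", "centered_log2")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix (proteins x samples)", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have protein rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate protein ids in rownames", call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids in colnames", call. = FALSE)
  if (scale == "raw_linear") {
    if (any(!is.finite(values)) || any(values < 0))
      stop("raw linear NFI values must be finite and >= 0", call. = FALSE)
  } else if (any(!is.finite(values))) {
    stop("centered log2 NFI values must be finite", call. = FALSE)
  }
  pw <- rep("unassigned", nrow(values))
  names(pw) <- rownames(values)
  if (!is.null(pathway)) {
    if (is.null(names(pathway)))
      stop("'pathway' must be a named character vector (protein -> panel)",
           call. = FALSE)
    hit <- intersect(names(pathway), rownames(values))
    pw[hit] <- as.character(pathway[hit])
  }
  structure(values, pathway = pw, nfi_scale = scale,
            class = c("nfi_matrix", class(values)))
}

#' @rdname nfi_matrix
#' @param m an `nfi_matrix`.
#' @export
nfi_values <- function(m) {
  stopifnot(inherits(m, "nfi_matrix"))
  v <- unclass(m)
  attr(v, "pathway") <- NULL
  attr(v, "nfi_scale") <- NULL
  v
}

#' @rdname nfi_matrix
#' @export
nfi_pathways <- function(m) {
  stopifnot(inherits(m, "nfi_matrix"))
  attr(m, "pathway")
}

#' @rdname nfi_matrix
#' @export
nfi_scale <- function(m) {
  stopifnot(inherits(m, "nfi_matrix"))
  attr(m, "nfi_scale")
}

# Rebuild an nfi_matrix with new values but the same annotation (subset ok).
.nfi_like <- function(values, template, scale = nfi_scale(template)) {
  nfi_matrix(values, pathway = nfi_pathways(template)[rownames(values)],
             scale = scale)
}

#' @export
print.nfi_matrix <- function(x, ...) {
  cat(sprintf("<nfi_matrix> %d proteins x %d samples, scale: %s\n",
              nrow(x), ncol(x), nfi_scale(x)))
  panels <- table(nfi_pathways(x))
  cat("pathway panels:",
      paste(sprintf("%s (%d)", names(panels), panels), collapse = ", "), "\n")
  invisible(x)
}

#' Select samples of an NFI matrix by id
#'
#' @param m an `nfi_matrix`.
#' @param samples character vector of sample ids to keep (order preserved).
#' @return an `nfi_matrix` restricted to the requested samples.
#' @export
nfi_select_samples <- function(m, samples) {
  stopifnot(inherits(m, "nfi_matrix"))
  bad <- setdiff(samples, colnames(m))
  if (length(bad))
    stop("unknown sample id(s): ", paste(bad, collapse = ", "), call. = FALSE)
  v <- nfi_values(m)[, samples, drop = FALSE]
  .nfi_like(v, m)
}
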