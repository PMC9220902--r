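# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Derived sub-seed for per-generator substreams: distinct streams for the
# four generators at a common user seed, kept well below .Machine$integer.max.
.substream_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  (as.integer(seed) %% 268435455L) * 8L + as.integer(k)
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (x < lower || x > upper)
    stop(sprintf("'%s' must be in [%s, %s]", name, format(lower), format(upper)),
         call. = FALSE)
  invisible(x)
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    stop(sprintf("%s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  invisible(df)
}

# All permutations of 1..n as an n! x n integer matrix (n <= 8 in practice).
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    idx <- seq(row, row + nrow(sub) - 1L)
    out[idx, 1L] <- k
    out[idx, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
    row <- row + nrow(sub)
  }
  out
}
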