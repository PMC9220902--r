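# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately written from the definitions, not by calling the
# package functions they verify.

# Term-by-term modified Z-score evaluation: M_i = 0.6745 (x_i - med) / MAD,
# flagged at |M_i| >= 3.5. Mirrors the published formula including the
# mean-absolute-deviation fallback when MAD = 0.
oracle_modified_z <- function(x, cutoff = 3.5) {
  med <- sort(x)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0)
    med <- (sort(x)[length(x) / 2] + sort(x)[length(x) / 2 + 1]) / 2
  abs_dev <- abs(x - med)
  mad0 <- sort(abs_dev)[ceiling(length(x) / 2)]
  if (length(x) %% 2 == 0)
    mad0 <- (sort(abs_dev)[length(x) / 2] + sort(abs_dev)[length(x) / 2 + 1]) / 2
  if (mad0 > 0) {
    m <- vapply(x, function(xi) 0.6745 * (xi - med) / mad0, numeric(1))
  } else {
    mean_ad <- sum(abs_dev) / length(x)
    m <- if (mean_ad > 0) (x - med) / (1.253314 * mean_ad) else rep(0, length(x))
  }
  abs(m) >= cutoff
}

# Heap's algorithm for all permutations of 1..n (different construction from
# the package's recursive generator).
oracle_perms <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, factorial(n), n)
  k <- 0L
  c_ <- rep(0L, n)
  k <- k + 1L; out[k, ] <- a
  i <- 1L
  while (i <= n) {
    if (c_[i] < i - 1L) {
      if (i %% 2L == 1L) { tmp <- a[1L]; a[1L] <- a[i]; a[i] <- tmp }
      else { tmp <- a[c_[i] + 1L]; a[c_[i] + 1L] <- a[i]; a[i] <- tmp }
      k <- k + 1L; out[k, ] <- a
      c_[i] <- c_[i] + 1L
      i <- 1L
    } else {
      c_[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# Spearman rho via the classical d^2 formula (valid without ties).
oracle_spearman_rho <- function(x, y) {
  n <- length(x)
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Exhaustive two-sided permutation p-value for Spearman rho, no ties.
oracle_spearman_perm_p <- function(x, y) {
  robs <- oracle_spearman_rho(x, y)
  perms <- oracle_perms(length(y))
  rs <- apply(perms, 1, function(idx) oracle_spearman_rho(x, y[idx]))
  mean(abs(rs) >= abs(robs) - 1e-12)
}

# Nearest-pair agglomeration (average linkage) on a distance matrix;
# returns the sequence of merged cluster member sets. Lowest-index pair
# wins ties.
oracle_agglomerate <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  merges <- list()
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq((i + 1), length(clusters))) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d - 1e-12) { best_d <- dij; best <- c(i, j) }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  merges
}

# An oracle-fed responder/non-responder split from a sim_config (bypasses
# grading, used when the planted truth is the reference).
truth_split <- function(cfg) {
  structure(list(responders = cfg$responder_models,
                 non_responders = setdiff(cfg$model_ids,
                                          cfg$responder_models)),
            class = "group_split")
}
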