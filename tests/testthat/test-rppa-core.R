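make_nfi <- function(values, pathway = NULL, scale = "raw_linear") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("p%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("s%02d", seq_len(ncol(values)))
  nfi_matrix(values, pathway = pathway, scale = scale)
}

test_that("blank filter excludes by per-protein median against the 0.02 level", {
  v <- rbind(blankish = rep(0.01, 3),
             strong = rep(1.0, 3),
             mixed = c(0.01, 0.01, 5.0))   # median 0.01 -> excluded
  m <- make_nfi(v)
  res <- apply_blank_filter(m)
  expect_setequal(res$excluded, c("blankish", "mixed"))
  expect_identical(rownames(res$nfi), "strong")
  # pass-through: retained values untouched
  expect_identical(unname(nfi_values(res$nfi)["strong", ]),
                   unname(v["strong", ]))
  # everything blank -> empty-matrix error
  expect_error(apply_blank_filter(make_nfi(rbind(a = rep(0.01, 3)))),
               "empty matrix|blank")
})

test_that("center_log2 divides by the row median and log2-transforms", {
  m <- make_nfi(rbind(const = rep(3.7, 4)))
  expect_equal(unname(nfi_values(center_log2(m))[1, ]), rep(0, 4))

  m2 <- make_nfi(rbind(r = c(1, 2, 4)))
  expect_equal(unname(nfi_values(center_log2(m2))[1, ]), c(-1, 0, 1))
  expect_identical(nfi_scale(center_log2(m2)), "centered_log2")

  set.seed(1)
  m3 <- make_nfi(matrix(2^rnorm(600), 30, 20))
  cm <- nfi_values(center_log2(m3))
  meds <- apply(cm, 1, function(r) median(r))   # brute-force row medians
  expect_true(all(abs(meds) < 1e-9))
})

test_that("center_log2 is idempotent in effect and rejects non-positive values", {
  set.seed(2)
  m <- make_nfi(matrix(2^rnorm(200), 20, 10))
  c1 <- center_log2(m)
  back <- make_nfi(2^nfi_values(c1))
  c2 <- center_log2(back)
  expect_lt(max(abs(nfi_values(c2) - nfi_values(c1))), 1e-9)

  v <- matrix(c(1, 0, 2, 3), 2, 2,
              dimnames = list(c("pA", "pB"), c("sX", "sY")))
  err <- tryCatch(center_log2(nfi_matrix(v)), error = conditionMessage)
  expect_match(err, "pB")
  expect_match(err, "sX")
})

test_that("hcl_cluster matches brute-force nearest-pair agglomeration on 3 samples", {
  set.seed(3)
  v <- matrix(rnorm(30), 10, 3,
              dimnames = list(sprintf("p%d", 1:10), c("a", "b", "c")))
  m <- nfi_matrix(v, scale = "centered_log2")
  res <- hcl_cluster(m, k = 2)
  d <- 1 - cor(v)
  merges <- oracle_agglomerate(as.dist(d))
  # first oracle merge = closest pair; hclust merge 1 must join the same pair
  first_pair <- merges[[1]]
  hc <- res$hclust
  expect_setequal(-hc$merge[1, ], first_pair)
  # flat partition at k = 2 separates the odd one out
  odd <- setdiff(1:3, first_pair)
  part <- res$partition
  expect_identical(part[[odd]] == part[[first_pair[1]]], FALSE)
  expect_identical(part[[first_pair[1]]], part[[first_pair[2]]])
})

test_that("duplicated sample profiles merge at height 0", {
  set.seed(4)
  prof <- rnorm(12)
  v <- cbind(s1 = prof, s2 = prof, s3 = rnorm(12))
  rownames(v) <- sprintf("p%d", 1:12)
  res <- hcl_cluster(nfi_matrix(v, scale = "centered_log2"), k = 2)
  expect_equal(res$hclust$height[1], 0, tolerance = 1e-12)
  expect_identical(res$partition[["s1"]], res$partition[["s2"]])
})

test_that("hcl_cluster is invariant to sample input order and validates k", {
  set.seed(5)
  cfg <- sim_config(seed = 5, effect_log2 = c("MAPK/RTK" = 1))
  cm <- center_log2(simulate_rppa(cfg)$nfi)
  res1 <- hcl_cluster(cm, k = 2)
  perm <- sample(colnames(cm))
  res2 <- hcl_cluster(nfi_select_samples(cm, perm), k = 2)
  p1 <- res1$partition[perm]
  p2 <- res2$partition[perm]
  # same partition up to label permutation
  expect_true(all((outer(p1, p1, "==") == outer(p2, p2, "=="))))
  expect_error(hcl_cluster(cm, k = 99), "exceeds")
})

test_that("pathway_summarize returns per-panel medians backed by member values", {
  v <- rbind(a = c(-0.2, 1), b = c(0.0, 2), c = c(0.4, 3), lone = c(5, 6))
  colnames(v) <- c("s1", "s2")
  m <- nfi_matrix(v, pathway = c(a = "cell cycle", b = "cell cycle",
                                 c = "cell cycle", lone = "apoptosis"),
                  scale = "centered_log2")
  res <- pathway_summarize(m)
  cc <- res$medians[res$medians$pathway == "cell cycle", ]
  expect_equal(cc$median_log2[cc$sample == "s1"], 0.0)
  lone <- res$medians[res$medians$pathway == "apoptosis", ]
  expect_equal(lone$median_log2, c(5, 6))   # single-protein panel

  # medians match an independent sort-based oracle on a random matrix
  set.seed(6)
  cfg <- sim_config(seed = 6)
  cm <- center_log2(simulate_rppa(cfg)$nfi)
  res2 <- pathway_summarize(cm)
  pw <- nfi_pathways(cm)
  for (p in unique(pw)) {
    sub <- nfi_values(cm)[names(pw)[pw == p], , drop = FALSE]
    oracle <- apply(sub, 2, function(col) {
      s <- sort(col); n <- length(s)
      if (n %% 2) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
    })
    got <- res2$medians[res2$medians$pathway == p, ]
    expect_equal(got$median_log2, unname(oracle[got$sample]))
  }

  # invariant to within-panel protein ordering
  shuf <- nfi_matrix(v[c("c", "a", "lone", "b"), ],
                     pathway = c(a = "cell cycle", b = "cell cycle",
                                 c = "cell cycle", lone = "apoptosis"),
                     scale = "centered_log2")
  res3 <- pathway_summarize(shuf)
  expect_equal(res3$medians[res3$medians$pathway == "cell cycle", "median_log2"],
               cc$median_log2)
})
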