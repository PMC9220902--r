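centered <- function(v, pathway = NULL) {
  if (is.null(rownames(v))) rownames(v) <- sprintf("p%02d", seq_len(nrow(v)))
  nfi_matrix(v, pathway = pathway, scale = "centered_log2")
}

test_that("split_groups partitions by grade >= 1 and requires both groups", {
  v <- matrix(0, 2, 3, dimnames = list(c("p1", "p2"), c("A", "B", "C")))
  m <- centered(v)
  g <- data.frame(model = c("A", "B", "C"), grade = c(3, 2, 0))
  sp <- split_groups(g, m)
  expect_setequal(sp$responders, c("A", "B"))
  expect_identical(sp$non_responders, "C")
  expect_error(split_groups(data.frame(model = c("A", "B", "C"), grade = 0), m),
               "empty")
  expect_error(split_groups(g[1:2, ], m), "no sensitivity grade")
})

test_that("oracle-fed grading round-trips the planted responder set", {
  fcm <- matrix(1, 3, 3); fcm[, 3] <- 3
  cfg <- sim_config(seed = 19, plate_fc = fcm, plate_noise_sd_log2 = 0.08)
  grades <- grade_all_models(simulate_plate(cfg)$plate, "carboplatin")
  cm <- center_log2(simulate_rppa(cfg)$nfi)
  sp <- split_groups(grades, cm)
  expect_setequal(sp$responders, cfg$responder_models)
})

test_that("20% filter works on the ratio of linear-scale group means, boundary inclusive", {
  b <- log2(1.2)   # 0.26303; note 2^0.263 = 1.19997 sits just below the cut
  v <- rbind(null = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.5),
             boundary = c(b, b, b, 0, 0, 0),
             below = c(0.20, 0.20, 0.20, 0, 0, 0))
  colnames(v) <- c("r1", "r2", "r3", "n1", "n2", "n3")
  sp <- structure(list(responders = c("r1", "r2", "r3"),
                       non_responders = c("n1", "n2", "n3")),
                  class = "group_split")
  sig <- filter_20pct(centered(v), sp)
  expect_false(sig$passes_20pct[sig$protein == "null"])
  expect_true(sig$passes_20pct[sig$protein == "boundary"])   # ratio exactly 1.2
  expect_false(sig$passes_20pct[sig$protein == "below"])
  expect_identical(sig$direction[sig$protein == "boundary"], "up")
})

test_that("20% filter is symmetric in group labels up to a direction flip", {
  set.seed(30)
  v <- matrix(rnorm(7 * 10, sd = 0.5), 10, 7)
  colnames(v) <- sprintf("s%d", 1:7)
  m <- centered(v)
  sp <- structure(list(responders = sprintf("s%d", 1:4),
                       non_responders = sprintf("s%d", 5:7)),
                  class = "group_split")
  flip <- structure(list(responders = sp$non_responders,
                         non_responders = sp$responders),
                    class = "group_split")
  a <- filter_20pct(m, sp); b <- filter_20pct(m, flip)
  expect_identical(a$passes_20pct, b$passes_20pct)
  expect_equal(a$ratio, b$ratio)
  expect_true(all(a$direction != b$direction |
                    a$mean_responder == a$mean_non_responder))
})

test_that("pathway Mann-Whitney matches the exact small-sample reference", {
  # single passing protein, pooled sets {1,2,3} vs {4,5,6}: U = 0, p = 0.1
  v <- matrix(c(1, 2, 3, 4, 5, 6), 1, 6,
              dimnames = list("p01", c("r1", "r2", "r3", "n1", "n2", "n3")))
  m <- centered(v, pathway = c(p01 = "cell cycle"))
  sp <- structure(list(responders = c("r1", "r2", "r3"),
                       non_responders = c("n1", "n2", "n3")),
                  class = "group_split")
  sig <- filter_20pct(m, sp)
  res <- test_pathways(sig, m, sp)
  expect_equal(res$U, 0)
  expect_equal(res$p, 0.1)   # 2/20 arrangements as or more extreme

  # identical pooled sets -> p = 1
  v2 <- matrix(c(1, 2, 3, 1, 2, 3), 1, 6,
               dimnames = list("p01", c("r1", "r2", "r3", "n1", "n2", "n3")))
  m2 <- centered(v2, pathway = c(p01 = "cell cycle"))
  sig2 <- filter_20pct(m2, sp, min_ratio = 1)   # force the protein through
  res2 <- test_pathways(sig2, m2, sp)
  expect_equal(res2$p, 1)

  # no passing proteins anywhere -> error; empty panel skipped with warning
  sig3 <- sig; sig3$passes_20pct <- FALSE
  expect_error(suppressWarnings(test_pathways(sig3, m, sp)), "no pathway")
})

test_that("pathway p-values are invariant to a common positive affine map", {
  cfg <- sim_config(seed = 33, effect_log2 = c("apoptosis" = 0.7))
  cm <- center_log2(simulate_rppa(cfg)$nfi)
  sp <- truth_split(cfg)
  sig <- filter_20pct(cm, sp)
  r1 <- suppressWarnings(test_pathways(sig, cm, sp))
  v <- nfi_values(cm) * 3.2 + 0.7
  cm2 <- nfi_matrix(v, pathway = nfi_pathways(cm), scale = "centered_log2")
  r2 <- suppressWarnings(test_pathways(sig, cm2, sp))
  expect_equal(r1$p, r2$p)
  expect_equal(r1$U, r2$U)
})

test_that("sensitivity correlation: perfect concordance, degeneracy, tie handling", {
  v <- matrix(c(0.1, 0.4, 0.9, 1.5, 2.2, 3.0), 1, 6,
              dimnames = list("cyclinB1", sprintf("m%d", 1:6)))
  m <- centered(v)
  g <- data.frame(model = sprintf("m%d", 1:6), grade = c(0, 0, 1, 1, 2, 3))
  res <- correlate_with_grade(m, g, "cyclinB1")
  expect_lt(abs(res$rho - 1), 0.1)   # ties in grades keep rho just below 1
  g2 <- data.frame(model = sprintf("m%d", 1:6), grade = 1:6)
  expect_equal(correlate_with_grade(m, g2, "cyclinB1")$rho, 1)

  gconst <- data.frame(model = sprintf("m%d", 1:6), grade = 2)
  und <- correlate_with_grade(m, gconst, "cyclinB1")
  expect_true(und$undefined)
  expect_true(is.na(und$rho))
  expect_error(correlate_with_grade(m, g[1:3, ], "cyclinB1"), ">= 4")
})

test_that("exact permutation p matches the exhaustive oracle at n = 6", {
  set.seed(44)
  for (i in 1:15) {
    x <- rnorm(6); y <- sample(rnorm(6))
    v <- matrix(x, 1, 6, dimnames = list("p", sprintf("m%d", 1:6)))
    g <- data.frame(model = sprintf("m%d", 1:6), grade = y)
    res <- correlate_with_grade(nfi_matrix(v, scale = "centered_log2"), g, "p")
    expect_equal(res$p, oracle_spearman_perm_p(x, y))
    expect_identical(res$method, "exact permutation")
  }
})

test_that("correlation is invariant under strictly monotone transforms", {
  set.seed(45)
  x <- rnorm(6)
  v1 <- matrix(x, 1, 6, dimnames = list("p", sprintf("m%d", 1:6)))
  v2 <- matrix(exp(2 * x) + 5, 1, 6, dimnames = list("p", sprintf("m%d", 1:6)))
  g <- data.frame(model = sprintf("m%d", 1:6), grade = c(0, 1, 1, 2, 3, 3))
  r1 <- correlate_with_grade(nfi_matrix(v1, scale = "centered_log2"), g, "p")
  r2 <- correlate_with_grade(nfi_matrix(v2, scale = "centered_log2"), g, "p")
  expect_equal(r1$rho, r2$rho)
  expect_equal(r1$p, r2$p)
})
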