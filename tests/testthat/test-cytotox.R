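# Small helper: long plate table from treated/vehicle replicate vectors for
# a single model at given doses/times.
plate_from <- function(model = "m1", drug = "drugX",
                       doses = c(10, 20), times = c(24, 72),
                       treated = NULL, vehicle = NULL) {
  rows <- list()
  for (t in times) {
    veh <- vehicle[[as.character(t)]]
    rows[[length(rows) + 1]] <- data.frame(
      model = model, drug = "DMSO", dose_uM = NA_real_, time_h = t,
      replicate = seq_along(veh), rfu = veh, is_vehicle = TRUE)
    for (d in doses) {
      trt <- treated[[as.character(t)]][[as.character(d)]]
      rows[[length(rows) + 1]] <- data.frame(
        model = model, drug = drug, dose_uM = d, time_h = t,
        replicate = seq_along(trt), rfu = trt, is_vehicle = FALSE)
    }
  }
  do.call(rbind, rows)
}

test_that("modified Z-scores reproduce the hand-computed reference case", {
  z <- modified_zscores(c(1, 2, 3, 4, 100))
  # median 3, MAD 1, M_5 = 0.6745 * 97 = 65.4265
  expect_equal(z$m[5], 65.4265)
  expect_identical(z$is_outlier, c(FALSE, FALSE, FALSE, FALSE, TRUE))
})

test_that("modified Z-scores handle degenerate and shifted inputs", {
  expect_false(any(modified_zscores(c(5, 5, 5, 5))$is_outlier))
  x <- c(2, 7, 4, 9, 4, 4, 100)
  expect_identical(modified_zscores(x)$is_outlier,
                   modified_zscores(x + 1234.5)$is_outlier)
  expect_error(modified_zscores(c(1, 2)), "length >= 3")
  # MAD = 0 with spread: mean-AD fallback engages, no division by zero
  z <- modified_zscores(c(5, 5, 5, 100))
  expect_true(all(is.finite(z$m)))
})

test_that("modified Z-scores agree with a term-by-term oracle on random vectors", {
  set.seed(10)
  for (i in 1:300) {
    n <- sample(3:12, 1)
    scale <- 10^sample(-2:4, 1)
    x <- round(rnorm(n, sd = scale), 3)
    if (runif(1) < 0.3) x[sample(n, 1)] <- x[1] * 50 + scale
    if (runif(1) < 0.2) x[seq_len(ceiling(n / 2))] <- x[1]   # force MAD = 0 sometimes
    expect_identical(modified_zscores(x)$is_outlier, oracle_modified_z(x))
  }
})

test_that("fold changes follow the stated mean-ratio rule", {
  p <- plate_from(
    treated = list("24" = list("10" = c(200, 220, 210), "20" = c(100, 110, 105)),
                   "72" = list("10" = c(100, 110, 105), "20" = c(100, 110, 105))),
    vehicle = list("24" = c(100, 110, 105), "72" = c(100, 110, 105)))
  fc <- compute_fold_changes(p)
  s <- fc$strata
  expect_equal(s$fc[s$dose_uM == 10 & s$time_h == 24], 210 / 105)
  # treated identical to vehicle -> FC = 1
  expect_equal(s$fc[s$dose_uM == 20 & s$time_h == 24], 1)
  expect_true(all(fc$strata$fc > 0))
})

test_that("fold changes are invariant to rescaling a model x time block", {
  cfg <- sim_config(seed = 17, plate_fc = 2)
  p <- simulate_plate(cfg)$plate
  fc1 <- compute_fold_changes(p)
  p2 <- p
  block <- p2$model == "OvCa1" & p2$time_h == 48
  p2$rfu[block] <- p2$rfu[block] * 37.5
  fc2 <- compute_fold_changes(p2)
  expect_equal(fc1$strata$fc, fc2$strata$fc)
})

test_that("planted plate outliers are removed before averaging", {
  # x5 artifact in a treated stratum: FC after removal close to clean FC
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(seed = s, plate_fc = 2, plate_noise_sd_log2 = 0.05)
    clean <- simulate_plate(cfg)$plate
    fc_clean <- compute_fold_changes(clean)
    spiked <- clean
    idx <- which(!spiked$is_vehicle)[1]
    spiked$rfu[idx] <- spiked$rfu[idx] * 5
    fc_spiked <- compute_fold_changes(spiked)
    max(abs(fc_spiked$strata$fc / fc_clean$strata$fc - 1))
  }, numeric(1))
  expect_gte(mean(hits < 0.02), 0.95)
})

test_that("fold-change preconditions are enforced", {
  p <- plate_from(
    treated = list("24" = list("10" = c(1, 2, 3), "20" = c(1, 2, 3)),
                   "72" = list("10" = c(1, 2, 3), "20" = c(1, 2, 3))),
    vehicle = list("24" = c(100, 110, 105), "72" = c(100, 110, 105)))
  unmatched <- p[!(p$is_vehicle & p$time_h == 72), ]
  expect_error(compute_fold_changes(unmatched), "no vehicle stratum")
  zero_veh <- p
  zero_veh$rfu[zero_veh$is_vehicle & zero_veh$time_h == 24] <- 0
  expect_error(compute_fold_changes(zero_veh), "vehicle mean RFU")
  two_reps <- p[!(p$dose_uM %in% 10 & p$replicate == 3), ]
  expect_error(compute_fold_changes(two_reps), "at least 3")
})

test_that("two-way ANOVA control comparisons detect a planted effect and validate input", {
  fcm <- matrix(1, 3, 3); fcm[2, 3] <- 2.0
  cfg <- sim_config(seed = 23, n_models = 1, plate_fc = fcm,
                    plate_noise_sd_log2 = 0.108)
  p <- simulate_plate(cfg)
  fc <- compute_fold_changes(p$plate)
  pv <- test_treatment_effects(fc, "OvCa1", "carboplatin")
  expect_identical(nrow(pv), 9L)
  hit <- pv[pv$dose_uM == 150 & pv$time_h == 72, ]
  expect_lt(hit$p_adj, 0.001)
  expect_gt(min(pv$p_adj[!(pv$dose_uM == 150 & pv$time_h == 72)]), 0.05)
  expect_error(test_treatment_effects(fc, "nope", "carboplatin"),
               "no replicate-level FCs")
})

test_that("single replicate-level FC per cell is rejected", {
  p <- plate_from(
    treated = list("24" = list("10" = c(100, 101, 102), "20" = c(100, 101, 102)),
                   "72" = list("10" = c(100, 101, 102), "20" = c(100, 101, 102))),
    vehicle = list("24" = c(100, 101, 102), "72" = c(100, 101, 102)))
  fc <- compute_fold_changes(p)
  fc$replicate_fc <- fc$replicate_fc[
    !(fc$replicate_fc$dose_uM %in% 10 & fc$replicate_fc$time_h == 24 &
        fc$replicate_fc$replicate > 1), ]
  expect_error(test_treatment_effects(fc, "m1", "drugX"), "single replicate")
})

test_that("sensitivity grading maps p-values to the 0-3 scheme", {
  pv <- function(p) data.frame(model = "m", drug = "d", dose_uM = 75,
                               time_h = 72, p_adj = p)
  expect_identical(grade_sensitivity(pv(0.2))$grade, 0L)
  expect_false(grade_sensitivity(pv(0.2))$responder)
  expect_identical(grade_sensitivity(pv(0.04))$grade, 1L)
  expect_identical(grade_sensitivity(pv(0.004))$grade, 2L)
  expect_identical(grade_sensitivity(pv(0.0004))$grade, 3L)
  expect_true(grade_sensitivity(pv(0.0004))$responder)
  # grade reads the final time point; missing 72 h data cannot be graded
  expect_error(grade_sensitivity(data.frame(dose_uM = 75, time_h = 24,
                                            p_adj = 0.001)),
               "final time point")
  # minimum across doses drives the grade (higher-dose responders count)
  multi <- data.frame(dose_uM = c(75, 150, 300), time_h = 72,
                      p_adj = c(0.5, 0.03, 0.2))
  expect_identical(grade_sensitivity(multi)$grade, 1L)
})

test_that("grade is monotone: decreasing any backing p never decreases it", {
  set.seed(11)
  for (i in 1:50) {
    p_adj <- runif(6, 0, 0.2)
    base <- data.frame(dose_uM = rep(c(75, 150, 300), 2),
                       time_h = rep(c(48, 72), each = 3), p_adj = p_adj)
    g0 <- grade_sensitivity(base)$grade
    j <- sample(6, 1)
    base$p_adj[j] <- base$p_adj[j] * runif(1)
    expect_gte(grade_sensitivity(base)$grade, g0)
  }
})
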