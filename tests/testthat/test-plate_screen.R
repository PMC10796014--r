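test_that("enumerate_ssm yields 19 substitutions per position", {
  wt <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)
  lib <- enumerate_ssm(wt, 1:27)
  expect_equal(nrow(lib), 513L)  # 27 x 19
  expect_equal(nrow(enumerate_ssm(wt, 5L)), 19L)
  one <- enumerate_ssm("NW", 1L)
  expect_false("N" %in% one$substitution)
  expect_equal(one$mutein_id[1], "N1A")
  # declared wild type must match the sequence
  expect_error(enumerate_ssm("NW", data.frame(index = 2, wt = "D")),
               "consistency error")
  expect_silent(enumerate_ssm("NW", data.frame(index = 2, wt = "W")))
  expect_error(enumerate_ssm("NW", 5L), "out of sequence range")
  # no variant duplicates the wild type; deterministic ordering
  expect_true(all(lib$substitution != lib$wt))
  expect_identical(lib, enumerate_ssm(wt, 1:27))
})

test_that("fit_standard recovers exact and noisy lines", {
  conc <- c(0, 75, 150, 250)
  cv <- fit_standard(conc, 100 + 2 * conc)
  expect_equal(cv$slope, 2, tolerance = 1e-12)
  expect_equal(cv$intercept, 100, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-9)
  set.seed(31)
  trip <- data.frame(concentration = rep(conc, each = 3))
  trip$fluorescence <- 100 + 2 * trip$concentration + rnorm(12, 0, 5)
  fit <- fit_standard(trip)
  se <- summary(stats::lm(fluorescence ~ concentration, trip))$coefficients[2, 2]
  expect_lt(abs(fit$slope - 2), 3 * se)
  expect_error(fit_standard(c(100, 100), c(1, 2)), "degenerate-fit")
})

test_that("amine_concentration inverts the curve and clamps below blank", {
  cv <- fit_standard(c(0, 75, 150, 250), 100 + 2 * c(0, 75, 150, 250))
  conc <- amine_concentration(c(300, 100, 50), cv)
  expect_equal(as.numeric(conc), c(100, 0, 0))
  expect_equal(attr(conc, "clamped"), c(FALSE, FALSE, TRUE))
})

test_that("normalize_plate sets the control mean to one", {
  cv <- fit_standard(c(0, 75, 150, 250), 2 * c(0, 75, 150, 250))
  rec <- data.frame(
    well = well_id <- sprintf("A%02d", 1:9),
    role = c(rep("control", 4), rep("mutein", 5)),
    payload = c(rep("nm", 4), paste0("m", 1:5)),
    fluorescence = 2 * c(90, 100, 110, 100, 55, 100, 200, 0, 100))
  out <- normalize_plate(rec, cv)
  expect_equal(out$activity, c(0.55, 1.0, 2.0, 0.0, 1.0))
  # scaling every well by a positive constant leaves activities unchanged
  rec2 <- rec; rec2$fluorescence <- rec2$fluorescence * 7
  cv2 <- fit_standard(c(0, 75, 150, 250), 7 * 2 * c(0, 75, 150, 250))
  expect_equal(normalize_plate(rec2, cv2)$activity, out$activity)
  rec0 <- rec; rec0$fluorescence[1:4] <- 0
  expect_error(normalize_plate(rec0, cv), "normalization error")
})

test_that("robust_mean reproduces the hand-worked keep and withdraw cases", {
  # keep: SD 0.346 > 0.2, removing 1.6 drops SD to 0 (100% decrease)
  r1 <- robust_mean(c(1.0, 1.0, 1.6))
  expect_equal(sd(c(1.0, 1.0, 1.6)), 0.3464102, tolerance = 1e-6)
  expect_true(r1$outlier_removed)
  expect_equal(r1$mean, 1.0)
  expect_equal(r1$sd, 0)
  expect_equal(r1$n_used, 2L)
  expect_equal(r1$removed_value, 1.6)
  # withdraw: bimodal, removal improves SD by < 20%
  r2 <- robust_mean(c(0.0, 0.01, 0.99, 1.0))
  expect_false(r2$outlier_removed)
  expect_equal(r2$mean, 0.5)
  expect_equal(r2$sd, sd(c(0.0, 0.01, 0.99, 1.0)))
  expect_equal(r2$n_used, 4L)
  # below threshold: untouched
  r3 <- robust_mean(c(0.9, 1.0, 1.1))
  expect_false(r3$outlier_removed)
  expect_equal(r3$mean, 1.0)
  # n = 2: rule disabled
  r4 <- robust_mean(c(0, 1))
  expect_false(r4$outlier_removed)
  expect_error(robust_mean(c(1, NA, Inf)), "insufficient-data")
})

test_that("outlier rule never increases SD and is a fixed point", {
  set.seed(606)
  for (i in 1:10000) {
    n <- sample(3:6, 1)
    x <- rnorm(n, 1, runif(1, 0.01, 0.6))
    r <- robust_mean(x)
    expect_lte(r$sd, sd(x) + 1e-12)
    expect_gte(r$n_used, n - 1L)
    if (r$outlier_removed) {
      kept <- x[-which(abs(x - mean(x)) == max(abs(x - mean(x))))[1]]
      # applying the rule to the surviving set changes nothing if its SD
      # is back under threshold; at minimum it cannot resurrect the outlier
      r2 <- robust_mean(setdiff(x, r$removed_value))
      expect_lte(r2$sd, r$sd + 1e-12)
    }
  }
})

test_that("screen pipeline recovers planted activities exactly without noise", {
  truth <- c(N75K = 0.1, N75Q = 0.7, W76F = 1.0, H199Y = 1.4)
  plates <- synth_plate(truth, noise_sd = 0, seed = 1)
  out <- run_screen_workflow(plates)
  got <- setNames(out$results$mean, out$results$mutein_id)
  expect_equal(got[names(truth)], truth, tolerance = 1e-9)
  expect_true(all(out$results$sd < 1e-12))
  mat <- out$matrix
  expect_equal(mat["K", "N75"], 0.1, tolerance = 1e-9)
  expect_equal(mat["Y", "H199"], 1.4, tolerance = 1e-9)
  expect_true(is.na(mat["A", "N75"]))
})

test_that("a planted 3x outlier on one replicate is eliminated", {
  truth <- c(M1K = 1.0)
  plates <- synth_plate(truth, noise_sd = 0.5, seed = 5)
  # scale one replicate's mutein well by 3 (as an outlier well would be)
  i <- which(plates$role == "mutein" & plates$plate == "rep2_plate1")
  cv_slope <- 20; cv_int <- 500
  conc <- (plates$fluorescence[i] - cv_int) / cv_slope
  plates$fluorescence[i] <- cv_int + cv_slope * conc * 3
  out <- screen_activities(plates)
  expect_true(out$results$outlier_removed)
  expect_equal(out$results$mean, 1.0, tolerance = 0.05)
})

test_that("failing plates are skipped and reported, others complete", {
  truth <- c(M1K = 0.5, M2Q = 1.2)
  plates <- synth_plate(truth, noise_sd = 0, seed = 2)
  bad <- plates$plate == "rep3_plate1" & plates$role == "control"
  plates$fluorescence[bad] <- 500  # zero concentration controls
  out <- screen_activities(plates)
  expect_equal(names(out$failed_plates), "rep3_plate1")
  expect_equal(sort(unique(out$results$n_used)), 3L)
  got <- setNames(out$results$mean, out$results$mutein_id)
  expect_equal(got[names(truth)], truth, tolerance = 1e-9)
})

test_that("end-to-end screen recovers activities under realistic noise", {
  set.seed(77)
  wt <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)
  lib <- enumerate_ssm(wt, sample(1:60, 10))
  truth <- setNames(pmax(0, rnorm(nrow(lib), 0.6, 0.4)), lib$mutein_id)
  plates <- synth_plate(truth, noise_sd = 3, outlier_prob = 0.05,
                        outlier_scale = 3, seed = 41)
  out <- run_screen_workflow(plates)
  got <- setNames(out$results$mean, out$results$mutein_id)
  err <- abs(got[names(truth)] - truth)
  expect_gt(mean(err < 0.05), 0.95)
  expect_gt(cor(got[names(truth)], truth, method = "spearman"), 0.95)
})
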