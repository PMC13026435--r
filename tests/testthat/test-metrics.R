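test_that("directional errors are spo2 - sao2 over valid readings only", {
  rec <- make_records(c(92, 95, 90), c(95, NA, 88))
  expect_equal(directional_errors(rec), c(3, -2))
  all_missing <- make_records(c(92, 95), c(NA, NA))
  expect_equal(directional_errors(all_missing), numeric(0))
})

test_that("pooled MDE and A_rms match hand-computed values", {
  expect_equal(mde(c(2, -2)), 0)
  expect_equal(mde(c(1, 2, 3)), 2)
  expect_equal(arms(2), 2)
  expect_equal(arms(c(3, -3)), 3)
  expect_equal(arms(c(1, 2, 3)), sqrt(14 / 3))
  expect_error(mde(numeric(0)), "undefined")
  expect_error(arms(numeric(0)), "undefined")
})

test_that("A_rms squared decomposes into MDE squared plus error variance", {
  set.seed(101)
  for (i in 1:25) {
    e <- stats::rnorm(sample(3:200, 1), mean = stats::runif(1, -5, 5),
                      sd = stats::runif(1, 0, 4))
    pop_var <- mean((e - mean(e))^2)
    expect_equal(arms(e)^2, mde(e)^2 + pop_var, tolerance = 1e-10)
    # both metrics are permutation invariant
    s <- sample(e)
    expect_equal(arms(s), arms(e))
    expect_equal(mde(s), mde(e))
    expect_gte(arms(e), abs(mde(e)))
  }
})

test_that("missingness reproduces the published count-derived percentages", {
  expect_equal(missingness(308, 305), 3 / 308 * 100, tolerance = 1e-12)
  expect_equal(round(missingness(308, 305), 2), 0.97)
  expect_equal(round(missingness(308, 284), 2), 7.79)
  expect_equal(missingness(36, 36), 0)
  expect_equal(missingness(10, c(3, 4)), 30)
  expect_error(missingness(0, 0), "zero attempts")
  expect_error(missingness(10, 11), "\\[0, attempted\\]")
})

test_that("bootstrap A_rms CI brackets the estimate and collapses when degenerate", {
  expect_equal(unname(arms_ci(c(2, 2, 2, 2), reps = 200, seed = 1)), c(2, 2))
  set.seed(7)
  e <- stats::rnorm(200, 1, 1)
  ci <- arms_ci(e, reps = 2000, seed = 3)
  expect_lte(ci["low"], arms(e))
  expect_gte(ci["high"], arms(e))
  expect_identical(arms_ci(e, reps = 500, seed = 9), arms_ci(e, reps = 500, seed = 9))
  expect_error(arms_ci(1), "at least two")
})

test_that("bootstrap CI covers the true RMS at roughly nominal rate", {
  # N(0,1) errors have true RMS 1; percentile bootstrap at n=500 should
  # cover it in at least ~90% of repeats
  set.seed(42)
  hits <- 0L
  for (i in 1:100) {
    e <- stats::rnorm(500)
    ci <- arms_ci(e, reps = 400, seed = i)
    hits <- hits + (ci["low"] <= 1 && 1 <= ci["high"])
  }
  expect_gte(hits, 90)
})

test_that("band categorization is inclusive at the boundary and conserves counts", {
  expect_equal(unname(categorize_errors(c(3, 0, -3))), c(1L, 1L, 1L))
  expect_equal(unname(categorize_errors(2)), c(0L, 1L, 0L))
  expect_equal(unname(categorize_errors(-2)), c(0L, 1L, 0L))
  set.seed(5)
  e <- stats::rnorm(300, 0, 3)
  expect_equal(sum(categorize_errors(e)), length(e))
  expect_error(categorize_errors(1, band = 0), "> 0")
})

test_that("Bland-Altman bias and limits of agreement match hand arithmetic", {
  # differences 1 and 3: bias 2, sample sd sqrt(2), LoA 2 -/+ 1.96*sqrt(2)
  ba <- bland_altman(sao2 = c(90, 90), spo2 = c(91, 93))
  expect_equal(ba$bias, 2)
  expect_equal(ba$sd_diff, sqrt(2))
  expect_equal(ba$loa_low, 2 - 1.96 * sqrt(2))
  expect_equal(ba$loa_high, 2 + 1.96 * sqrt(2))
  expect_equal(ba$points$mean, c(90.5, 91.5))
  same <- bland_altman(c(90, 95, 97), c(90, 95, 97))
  expect_equal(c(same$bias, same$loa_low, same$loa_high), c(0, 0, 0))
  expect_error(bland_altman(90, 91), "at least two")
})

test_that("about 95% of differences fall inside the limits of agreement", {
  set.seed(12)
  sao2 <- stats::runif(4000, 70, 99)
  spo2 <- sao2 + stats::rnorm(4000, 1, 2)
  ba <- bland_altman(sao2, spo2)
  inside <- mean(ba$points$difference >= ba$loa_low &
                 ba$points$difference <= ba$loa_high)
  expect_equal(inside, 0.95, tolerance = 0.015)
})

test_that("saturation bins are half-open with a closed top bin", {
  sao2 <- c(62, 62, 65, 100, 59.9)
  spo2 <- sao2 + 4
  prof <- binned_arms(sao2, spo2, reps = 100, seed = 1)
  expect_equal(prof$n[prof$bin_low == 60], 2L)   # 59.9 out of range
  expect_equal(prof$n[prof$bin_low == 65], 1L)   # 65 goes up, not down
  expect_equal(prof$n[prof$bin_low == 95], 1L)   # 100 in the closed top bin
  expect_equal(prof$arms[prof$bin_low == 60], 4)
  # singleton bin: A_rms reported, CI absent
  expect_true(is.na(prof$ci_low[prof$bin_low == 65]))
  expect_warning(binned_arms(50, 54, reps = 50), "no pairs")
  expect_error(binned_arms(70, 74, edges = c(60, 60)), "increasing")
})

test_that("a bias that grows with desaturation produces the decreasing accuracy profile", {
  dev <- list(sloped = device_error_model(bias_at_full_sat = 0.5,
                                          bias_slope = 0.12, noise_sd = 1,
                                          averaging_window = 10))
  ds <- generate_study_dataset(device_models = dev, seed = 31)
  valid <- ds[!is.na(ds$spo2_pct), ]
  prof <- binned_arms(valid$sao2_pct, valid$spo2_pct, reps = 100, seed = 1)
  expect_gt(prof$arms[prof$bin_low == 60], prof$arms[prof$bin_low == 95])
})

test_that("hypoxemia subset keeps strictly sub-threshold reference values", {
  rec <- make_records(c(87.9, 88.0, 88.1), c(90, 90, 90))
  sub <- hypoxemia_subset(rec)
  expect_equal(sub$sao2_pct, 87.9)
  expect_equal(nrow(hypoxemia_subset(rec[0, ])), 0L)
  expect_lte(nrow(hypoxemia_subset(rec)), nrow(rec))
})

test_that("occult hypoxemia needs strict thresholds on both sides", {
  expect_true(detect_occult_hypoxemia(87.5, 93))
  expect_false(detect_occult_hypoxemia(87.5, 92))
  expect_false(detect_occult_hypoxemia(88.0, 95))
  expect_equal(detect_occult_hypoxemia(c(87, 89), c(95, 95)), c(TRUE, FALSE))
  expect_error(detect_occult_hypoxemia(87, NA), "missing")
})

test_that("simulated bias and noise are recovered by the pooled metrics", {
  dev <- list(biased = device_error_model(bias_at_full_sat = 3, noise_sd = 1,
                                          display_rounding = 1e-6))
  ds <- generate_study_dataset(device_models = dev, seed = 13)
  expect_equal(nrow(ds), 324)
  # away from the 100% display ceiling the configured bias is recovered:
  # MDE -> b within 3*sigma/sqrt(n); A_rms -> sqrt(b^2 + sigma^2)
  mid <- ds[ds$sao2_pct < 93, ]
  e <- directional_errors(mid)
  n <- length(e)
  expect_gt(n, 150)
  expect_lt(abs(mde(e) - 3), 3 * 1 / sqrt(n))
  expect_equal(arms(e), sqrt(3^2 + 1^2), tolerance = 0.1)
  ba <- bland_altman(mid$sao2_pct, mid$spo2_pct)
  expect_equal(ba$bias, 3, tolerance = 3 / sqrt(n))
})

test_that("observed missingness converges to the configured probability", {
  p_miss <- 0.1
  dev <- list(flaky = device_error_model(missingness_base = p_miss))
  ds <- generate_study_dataset(device_models = dev, seed = 17)
  n <- nrow(ds)
  n_valid <- sum(!is.na(ds$spo2_pct))
  obs <- missingness(n, n_valid) / 100
  ci_half <- 1.96 * sqrt(p_miss * (1 - p_miss) / n)
  expect_lt(abs(obs - p_miss), ci_half + 1e-9)
})

test_that("validation_metrics block is internally consistent", {
  ds <- small_study(seed = 6)
  m <- validation_metrics(ds, device = "watch", reps = 300, seed = 2)
  expect_equal(m$n_over + m$n_within + m$n_under, m$n_valid)
  expect_equal(m$missingness, 100 * (m$n_attempted - m$n_valid) / m$n_attempted)
  expect_gte(m$arms, abs(m$mde))
  expect_lte(m$arms_ci["low"], m$arms)
  expect_gte(m$arms_ci["high"], m$arms)
})
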