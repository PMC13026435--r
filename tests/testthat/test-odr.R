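test_that("per-measurement ODR is the reference decline per minute", {
  rec <- make_records(c(90, 86), c(91, 87), dt_s = 120)
  ann <- compute_odr(rec)
  expect_true(is.na(ann$odr[1]))
  expect_equal(ann$odr[2], 2.0)   # 4% drop over 2 minutes

  flat <- compute_odr(make_records(c(90, 90), c(91, 91), dt_s = 60))
  expect_equal(flat$odr[2], 0)

  rising <- compute_odr(make_records(c(85, 90), c(86, 91), dt_s = 60))
  expect_equal(rising$odr[2], -5.0)  # negative = resaturation

  dup <- make_records(c(90, 86), c(91, 87))
  dup$time_s <- c(100L, 100L)
  expect_error(compute_odr(dup), "non-increasing")
})

test_that("ODR can be computed from the device signal instead", {
  rec <- make_records(c(90, 86), c(95, 89), dt_s = 120)
  ann <- compute_odr(rec, basis = "spo2")
  expect_equal(ann$odr[2], 3.0)
})

test_that("exclusion rules: >99% saturation is strict and precedes resaturation", {
  rec <- make_records(c(99.8, 99.0, 85.0, 87.0, 86.0),
                      c(100, 99, 86, 100, 87), dt_s = 120)
  ann <- apply_exclusions(compute_odr(rec))
  expect_equal(ann$exclusion_reason,
               c("fully_saturated",  # sao2 99.8 > 99 (despite no predecessor)
                 "none",             # 99.0 is not "more than 99"
                 "none",
                 "fully_saturated",  # spo2 100 wins over the resaturation match
                 "none"))
  # resaturation alone
  seq2 <- apply_exclusions(compute_odr(make_records(c(85, 87), c(86, 88), dt_s = 120)))
  expect_equal(seq2$exclusion_reason[2], "resaturation")
  # after exclusion every included record's sao2 <= predecessor's
  expect_true(all(ann$odr[!ann$excluded & ann$odr_defined] >= 0))
  expect_error(apply_exclusions(rec), "compute_odr")
})

test_that("stratification is inclusive at the 2%/min threshold and partitions records", {
  rec <- make_records(c(96, 92, 90.02, 86.02, 86.02), c(95, 93, 91, 87, 87),
                      dt_s = 60)
  ann <- stratify_by_odr(apply_exclusions(compute_odr(rec)))
  # drops/min: NA, 4, 1.98, 4, 0
  expect_equal(ann$stratum, c("none", "high", "low", "high", "low"))
  odr2 <- make_records(c(90, 88), c(91, 89), dt_s = 60)   # exactly 2.0
  expect_equal(stratify_by_odr(apply_exclusions(compute_odr(odr2)))$stratum[2],
               "high")
  included <- ann[!ann$excluded & ann$odr_defined, ]
  expect_true(all(included$stratum %in% c("high", "low")))
  expect_error(stratify_by_odr(rec), "apply_exclusions")
})

test_that("exclusion accounting conserves the attempted records", {
  ds <- small_study(seed = 8)
  for (dev in unique(ds$device)) {
    rec <- ds[ds$device == dev, ]
    ann <- stratify_by_odr(apply_exclusions(compute_odr(rec)))
    tab <- table(factor(ann$exclusion_reason,
                        c("none", "fully_saturated", "resaturation",
                          "no_predecessor")))
    expect_equal(sum(tab), nrow(rec))
    # one predecessor-less record per participant, unless its own
    # saturation exclusion took precedence
    expect_lte(unname(tab["no_predecessor"]),
               length(unique(rec$participant_id)))
    expect_equal(sum(ann$stratum != "none"), unname(tab["none"]))
  }
})

test_that("participant-level MDE pairs require both strata", {
  rec <- rbind(
    make_records(c(96, 92, 91.8, 87.8), c(99, 95, 93, 89), participant = "A",
                 dt_s = 60),
    make_records(c(96, 92, 91.8, 87.8), c(97, 93, 93, 89), participant = "B",
                 dt_s = 60),
    make_records(c(96, 92, 88), c(97, 93, 89), participant = "C", dt_s = 60)
  )
  ann <- stratify_by_odr(apply_exclusions(compute_odr(rec)))
  # A: high errors {3, 1.2}, low errors {1.2}; B: high {1, 1.2}, low {1.2}
  # C: only high-stratum records -> dropped with a message
  expect_message(pairs <- participant_mde(ann), "C")
  expect_equal(pairs$participant_id, c("A", "B"))
  expect_equal(pairs$mde_high, c(2.1, 1.1))
  expect_equal(pairs$mde_low, c(1.2, 1.2))
  only_c <- ann[ann$participant_id == "C", ]
  expect_error(suppressMessages(participant_mde(only_c)), "both ODR strata")
})

test_that("nine simulated participants yield nine MDE pairs per device", {
  ds <- generate_study_dataset(seed = 19)
  for (dev in c("finger", "watch")) {
    ann <- stratify_by_odr(apply_exclusions(compute_odr(ds[ds$device == dev, ])))
    pairs <- suppressMessages(participant_mde(ann))
    expect_equal(nrow(pairs), 9)
  }
})

test_that("paired t test matches the textbook computation", {
  # differences 1, 2, 3: t = mean/(sd/sqrt(n)) = 2/(1/sqrt(3)) = 2*sqrt(3)
  pairs <- data.frame(mde_high = c(2, 4, 6), mde_low = c(1, 2, 3))
  res <- paired_t_test(pairs)
  expect_equal(res$t_statistic, 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(res$df, 2L)
  expect_equal(res$p_value, 2 * stats::pt(-2 * sqrt(3), df = 2),
               tolerance = 1e-10)
  expect_equal(res$mean_diff, 2)

  # sign-flip antisymmetry
  flipped <- paired_t_test(data.frame(mde_high = c(1, 2, 3),
                                      mde_low = c(2, 4, 6)))
  expect_equal(flipped$t_statistic, -res$t_statistic, tolerance = 1e-10)
  expect_equal(flipped$p_value, res$p_value, tolerance = 1e-10)
})

test_that("degenerate paired tests follow the documented conventions", {
  same <- paired_t_test(data.frame(mde_high = c(1, 2), mde_low = c(1, 2)))
  expect_equal(same$mean_diff, 0)
  expect_equal(same$p_value, 1)
  expect_warning(
    shifted <- paired_t_test(data.frame(mde_high = c(2, 3), mde_low = c(1, 2))),
    "infinite"
  )
  expect_equal(shifted$t_statistic, Inf)
  expect_equal(shifted$p_value, 0)
  expect_error(paired_t_test(data.frame(mde_high = 1, mde_low = 2)),
               "at least two")
})

test_that("paired test keeps its nominal type-I error under a simulated null", {
  # 9 participants, both strata drawn from the same error distribution
  set.seed(2024)
  reps <- 1000
  rejections <- 0L
  for (r in seq_len(reps)) {
    mde_high <- vapply(1:9, function(i) mean(stats::rnorm(8, 2, 1)), numeric(1))
    mde_low <- vapply(1:9, function(i) mean(stats::rnorm(10, 2, 1)), numeric(1))
    p <- paired_t_test(data.frame(mde_high = mde_high, mde_low = mde_low))$p_value
    rejections <- rejections + (p < 0.05)
  }
  rate <- rejections / reps
  # binomial band around 0.05 at n = 1000
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("a lag-induced MDE difference between strata is detectable", {
  # high stratum shifted by +1% (sigma = 1, 9 participants): rejection rate
  # clearly above the null rate
  set.seed(99)
  reps <- 200
  rej <- 0L
  for (r in seq_len(reps)) {
    mde_high <- vapply(1:9, function(i) mean(stats::rnorm(8, 3, 1)), numeric(1))
    mde_low <- vapply(1:9, function(i) mean(stats::rnorm(10, 2, 1)), numeric(1))
    p <- paired_t_test(data.frame(mde_high = mde_high, mde_low = mde_low))$p_value
    rej <- rej + (p < 0.05)
  }
  expect_gt(rej / reps, 0.5)
})

test_that("QQ coordinates use (i - 1/2)/n normal plotting positions", {
  qq <- qq_points(c(1, -1, 0))
  expect_equal(qq$theoretical_quantile,
               stats::qnorm(c(0.5 / 3, 1.5 / 3, 2.5 / 3)))
  expect_equal(qq$sample_quantile, c(-1, 0, 1))
  expect_equal(qq$theoretical_quantile[2], 0)
  expect_equal(nrow(qq_points(stats::rnorm(50))), 50)
  set.seed(3)
  big <- qq_points(stats::rnorm(1000))
  expect_lt(max(abs(big$sample_quantile - big$theoretical_quantile)), 0.5)
  expect_error(qq_points(c(1, 2)), "at least 3")
})
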