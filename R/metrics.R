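# Accuracy metrics for paired SpO2/SaO2 measurements: mean directional
# error (MDE), missingness, accuracy root-mean-square difference
# (A_rms) with bootstrap CI, 2%-band categorization, Bland-Altman
# analysis, saturation-binned accuracy, and occult hypoxemia detection.
#
# MDE and A_rms are pooled over all valid measurements of all
# participants (the double-sum definition), not means of per-participant
# means; participant-level aggregation belongs to the ODR analysis only.

#' Directional errors for one device
#'
#' One entry per valid (non-missing) reading: `spo2 - sao2`, in stable
#' (participant, time) order. Positive values are overestimates.
#'
#' @param records Measurement data.frame.
#' @param device Device label to extract; `NULL` uses all rows (the
#'   table is then assumed to hold a single device).
#' @return Numeric vector of signed errors in percent.
#' @export
directional_errors <- function(records, device = NULL) {
  if (!is.null(device)) records <- records[records$device == device, ]
  records <- records[order(records$participant_id, records$time_s), ]
  ok <- !is.na(records$spo2_pct)
  records$spo2_pct[ok] - records$sao2_pct[ok]
}

#' Mean directional error
#'
#' Pooled arithmetic mean of the signed errors over all valid
#' measurements of all participants. Positive = overestimation.
#'
#' @param errors Numeric vector from [directional_errors()]; must be
#'   non-empty.
#' @return MDE in percent.
#' @export
mde <- function(errors) {
  if (!length(errors)) stop("MDE undefined for zero valid measurements", call. = FALSE)
  mean(errors)
}

#' Missingness percentage
#'
#' `100 - 100 * sum(valid) / attempted`: the percentage of attempted
#' readings for which the device produced no value.
#'
#' @param n_attempted Total attempted measurements (> 0).
#' @param n_valid Valid measurement counts (scalar total or
#'   per-participant vector, which is summed).
#' @return Missingness in percent.
#' @examples
#' missingness(308, 305) # 0.97...
#' @export
missingness <- function(n_attempted, n_valid) {
  total_valid <- sum(n_valid)
  if (n_attempted <= 0) stop("missingness undefined for zero attempts", call. = FALSE)
  if (total_valid < 0 || total_valid > n_attempted) {
    stop("valid count must lie in [0, attempted]", call. = FALSE)
  }
  100 - 100 * total_valid / n_attempted
}

#' Accuracy root-mean-square difference
#'
#' Square root of the pooled mean squared error over all valid
#' measurements: the regulatory accuracy metric for pulse oximeters.
#'
#' @inheritParams mde
#' @return A_rms in percent.
#' @export
arms <- function(errors) {
  if (!length(errors)) stop("A_rms undefined for zero valid measurements", call. = FALSE)
  sqrt(mean(errors^2))
}

#' Bootstrap confidence interval for A_rms
#'
#' Percentile bootstrap at the measurement level: errors are resampled
#' with replacement, A_rms recomputed per replicate, and the 2.5/97.5
#' percentiles reported. Deterministic given `seed`.
#'
#' @param errors Signed errors; at least two required.
#' @param reps Bootstrap replicates (default 10000).
#' @param seed Integer seed.
#' @param level Confidence level (default 0.95).
#' @return Named numeric vector `c(low, high)` bracketing the point
#'   estimate.
#' @export
arms_ci <- function(errors, reps = 10000, seed = 1L, level = 0.95) {
  n <- length(errors)
  if (n < 2) stop("A_rms CI needs at least two errors", call. = FALSE)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * reps, replace = TRUE), nrow = n)
  boot <- sqrt(colMeans(matrix(errors[idx]^2, nrow = n)))
  alpha <- (1 - level) / 2
  q <- stats::quantile(boot, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(low = q[1], high = q[2])
}

#' Categorize errors against an acceptability band
#'
#' Splits signed errors into overestimated (`error > band`), within the
#' band (`|error| <= band`, boundary inclusive), and underestimated
#' (`error < -band`).
#'
#' @param errors Signed errors in percent.
#' @param band Acceptable absolute error in percent (default 2, the
#'   manufacturer-stated acceptable SpO2 error range).
#' @return Named integer vector `c(n_over, n_within, n_under)`.
#' @export
categorize_errors <- function(errors, band = 2) {
  if (band <= 0) stop("`band` must be > 0", call. = FALSE)
  c(
    n_over = sum(errors > band),
    n_within = sum(abs(errors) <= band),
    n_under = sum(errors < -band)
  )
}

#' Bland-Altman method comparison
#'
#' Bias (mean of SpO2 - SaO2), SD of the differences, and 95% limits of
#' agreement at bias +/- 1.96 SD, together with the (mean, difference)
#' point list for plotting.
#'
#' @param sao2,spo2 Paired reference and device values (valid pairs
#'   only); at least two pairs.
#' @return List of class `oxi_bland_altman` with elements `bias`,
#'   `sd_diff`, `loa_low`, `loa_high`, `n`, and `points` (a data.frame
#'   with columns `mean`, `difference`).
#' @export
bland_altman <- function(sao2, spo2) {
  stopifnot(length(sao2) == length(spo2))
  ok <- !is.na(sao2) & !is.na(spo2)
  sao2 <- sao2[ok]; spo2 <- spo2[ok]
  if (length(sao2) < 2) stop("Bland-Altman needs at least two pairs", call. = FALSE)
  d <- spo2 - sao2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(
    list(
      bias = bias,
      sd_diff = sd_diff,
      loa_low = bias - 1.96 * sd_diff,
      loa_high = bias + 1.96 * sd_diff,
      n = length(d),
      points = data.frame(mean = (sao2 + spo2) / 2, difference = d)
    ),
    class = "oxi_bland_altman"
  )
}

#' @export
print.oxi_bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n=%d): bias %.2f%%, SD %.2f%%, 95%% LoA [%.2f%%, %.2f%%]\n",
    x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high
  ))
  invisible(x)
}

#' Saturation-binned A_rms profile
#'
#' Assigns each valid pair to a 5% reference-saturation bin (half-open
#' `[e_k, e_{k+1})`, top bin closed) and reports per-bin A_rms with a
#' bootstrap CI. Bins with fewer than two pairs report the A_rms but no
#' CI.
#'
#' @param sao2,spo2 Paired values (valid pairs only).
#' @param edges Strictly increasing bin edges in percent (default 60 to
#'   100 by 5).
#' @param reps,seed Bootstrap settings passed to [arms_ci()].
#' @return Data.frame with one row per bin: `bin_low`, `bin_high`, `n`,
#'   `arms`, `ci_low`, `ci_high`.
#' @export
binned_arms <- function(sao2, spo2, edges = seq(60, 100, by = 5),
                        reps = 10000, seed = 1L) {
  if (any(diff(edges) <= 0)) stop("`edges` must be strictly increasing", call. = FALSE)
  ok <- !is.na(sao2) & !is.na(spo2)
  sao2 <- sao2[ok]; spo2 <- spo2[ok]
  nb <- length(edges) - 1L
  out <- data.frame(
    bin_low = edges[-length(edges)], bin_high = edges[-1],
    n = 0L, arms = NA_real_, ci_low = NA_real_, ci_high = NA_real_
  )
  in_range <- sao2 >= edges[1] & sao2 <= edges[length(edges)]
  if (!any(in_range)) {
    warning("no pairs within the binning range", call. = FALSE)
    return(out)
  }
  bin <- findInterval(sao2, edges, rightmost.closed = TRUE)
  for (k in seq_len(nb)) {
    sel <- which(in_range & bin == k)
    out$n[k] <- length(sel)
    if (!length(sel)) next
    e <- spo2[sel] - sao2[sel]
    out$arms[k] <- arms(e)
    if (length(sel) >= 2) {
      ci <- arms_ci(e, reps = reps, seed = seed + k)
      out$ci_low[k] <- ci["low"]
      out$ci_high[k] <- ci["high"]
    }
  }
  out
}

#' Restrict records to the hypoxemic range
#'
#' Keeps records whose reference saturation is strictly below the
#' clinical hypoxemia threshold.
#'
#' @param records Measurement data.frame.
#' @param threshold Hypoxemia threshold in percent (default 88, the
#'   decision point for intensive oxygen therapy).
#' @return The hypoxemic subset of `records`.
#' @export
hypoxemia_subset <- function(records, threshold = 88) {
  records[!is.na(records$sao2_pct) & records$sao2_pct < threshold, ]
}

#' Detect occult hypoxemia
#'
#' A measurement exhibits occult hypoxemia when the arterial saturation
#' is truly hypoxemic (SaO2 < 88, strict) while the oximeter reads
#' normal (SpO2 > 92, strict) - hypoxemia hidden from the device.
#'
#' @param sao2 Reference saturation(s) in percent.
#' @param spo2 Device reading(s) in percent; must be valid (non-NA).
#' @param sao2_threshold,spo2_threshold Rule thresholds.
#' @return Logical vector.
#' @export
detect_occult_hypoxemia <- function(sao2, spo2,
                                    sao2_threshold = 88,
                                    spo2_threshold = 92) {
  if (any(is.na(spo2))) {
    stop("occult hypoxemia undefined for a missing reading", call. = FALSE)
  }
  sao2 < sao2_threshold & spo2 > spo2_threshold
}

#' Full accuracy metric block for one device over one subset
#'
#' Assembles attempted/valid counts, MDE, A_rms with bootstrap CI,
#' missingness, and the 2%-band categorization for a set of records.
#'
#' @param records Measurement data.frame (one device's rows, or pass
#'   `device`).
#' @param device Optional device label filter.
#' @param band Acceptability band in percent.
#' @param reps,seed Bootstrap settings for the A_rms CI.
#' @return List of class `oxi_metrics`.
#' @export
validation_metrics <- function(records, device = NULL, band = 2,
                               reps = 10000, seed = 1L) {
  if (!is.null(device)) records <- records[records$device == device, ]
  errors <- directional_errors(records)
  n_attempted <- nrow(records)
  n_valid <- length(errors)
  bands <- categorize_errors(errors, band = band)
  structure(
    list(
      device = device %||% unique(records$device),
      n_attempted = n_attempted,
      n_valid = n_valid,
      mde = if (n_valid) mde(errors) else NA_real_,
      arms = if (n_valid) arms(errors) else NA_real_,
      arms_ci = if (n_valid >= 2) arms_ci(errors, reps = reps, seed = seed)
                else c(low = NA_real_, high = NA_real_),
      missingness = missingness(n_attempted, n_valid),
      n_over = unname(bands["n_over"]),
      n_within = unname(bands["n_within"]),
      n_under = unname(bands["n_under"])
    ),
    class = "oxi_metrics"
  )
}

#' @export
print.oxi_metrics <- function(x, ...) {
  cat(sprintf("Device: %s\n", paste(x$device, collapse = ", ")))
  cat(sprintf("  attempted %d, valid %d (missingness %.2f%%)\n",
              x$n_attempted, x$n_valid, x$missingness))
  cat(sprintf("  MDE %.2f%%, A_rms %.2f%% (95%% CI %.2f-%.2f%%)\n",
              x$mde, x$arms, x$arms_ci["low"], x$arms_ci["high"]))
  cat(sprintf("  band: %d over / %d within / %d under\n",
              x$n_over, x$n_within, x$n_under))
  invisible(x)
}
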