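# Oxygen desaturation rate (ODR) analysis: per-measurement rate
# computation from consecutive reference samples, the saturation and
# resaturation exclusion rules, 2%/min stratification, participant-level
# MDE aggregation, and the paired test across strata.

#' Per-measurement oxygen desaturation rate
#'
#' For each record, the decline of the reference saturation since the
#' participant's preceding sample, in percent per minute (positive =
#' desaturating, negative = resaturating). The first sample of each
#' participant/device series has no predecessor and gets an undefined
#' rate. The rate is computed from the arterial reference (SaO2) by
#' default, the trusted signal in which the exclusion rules are stated;
#' set `basis = "spo2"` to use the device readings instead.
#'
#' @param records Measurement data.frame, time-sorted within
#'   participant/device (as [read_measurements()] returns).
#' @param basis `"sao2"` (default) or `"spo2"`.
#' @return `records` with columns `odr` (percent/min, `NA` where
#'   undefined) and `odr_defined` appended.
#' @export
compute_odr <- function(records, basis = c("sao2", "spo2")) {
  basis <- match.arg(basis)
  col <- if (basis == "sao2") "sao2_pct" else "spo2_pct"
  records$odr <- NA_real_
  grp <- split(seq_len(nrow(records)),
               paste(records$participant_id, records$device))
  for (idx in grp) {
    idx <- idx[order(records$time_s[idx])]
    t <- records$time_s[idx]
    v <- records[[col]][idx]
    if (any(diff(t) <= 0)) {
      stop("non-increasing timestamps within a participant/device series",
           call. = FALSE)
    }
    if (length(idx) > 1) {
      records$odr[idx[-1]] <- -diff(v) / (diff(t) / 60)
    }
  }
  records$odr_defined <- !is.na(records$odr)
  records
}

#' Apply the desaturation-analysis exclusion rules
#'
#' A measurement is excluded from the ODR analysis when it is fully
#' saturated (its SpO2 or SaO2 exceeds 99%, strict) or was collected
#' during resaturation (its SaO2 increased relative to the
#' participant's preceding sample). Saturation is checked first; the
#' recorded reason is the first rule that matched. Records without a
#' predecessor carry reason `no_predecessor` and are likewise outside
#' the stratified analysis (but remain in the overall accuracy
#' metrics, which never apply these rules).
#'
#' @param records Output of [compute_odr()].
#' @return `records` with logical `excluded` and character
#'   `exclusion_reason` (`none`, `fully_saturated`, `resaturation`,
#'   `no_predecessor`) appended.
#' @export
apply_exclusions <- function(records) {
  if (is.null(records$odr)) {
    stop("run compute_odr() before apply_exclusions()", call. = FALSE)
  }
  sat <- (!is.na(records$spo2_pct) & records$spo2_pct > 99) |
    records$sao2_pct > 99
  resat <- records$odr_defined & records$odr < 0
  reason <- rep("none", nrow(records))
  reason[!records$odr_defined] <- "no_predecessor"
  reason[resat] <- "resaturation"
  reason[sat] <- "fully_saturated"
  records$excluded <- reason != "none"
  records$exclusion_reason <- reason
  records
}

#' Stratify included measurements by desaturation rate
#'
#' Labels each included, rate-defined record `high` when its ODR is at
#' least the threshold (inclusive) and `low` when the rate is
#' non-negative but below it; excluded or rate-undefined records get
#' `none`. Negative rates were already removed by the resaturation
#' exclusion.
#'
#' @param records Output of [apply_exclusions()].
#' @param threshold ODR threshold in percent per minute (default 2,
#'   the per-minute translation of the 4%-in-2-minutes desaturation
#'   index used in sleep apnea screening).
#' @return `records` with a `stratum` column appended.
#' @export
stratify_by_odr <- function(records, threshold = 2.0) {
  if (is.null(records$excluded)) {
    stop("run apply_exclusions() before stratify_by_odr()", call. = FALSE)
  }
  stratum <- rep("none", nrow(records))
  eligible <- !records$excluded & records$odr_defined
  stratum[eligible & records$odr >= threshold] <- "high"
  stratum[eligible & records$odr >= 0 & records$odr < threshold] <- "low"
  records$stratum <- stratum
  records
}

#' Participant-level MDE per ODR stratum
#'
#' Mean-aggregates the signed errors of each participant's valid
#' readings within each stratum, yielding one MDE per person per
#' stratum. Only participants with at least one valid reading in both
#' strata are paired; the rest are dropped with a message.
#'
#' @param records Output of [stratify_by_odr()] for a single device
#'   (or pass `device`).
#' @param device Optional device label filter.
#' @return Data.frame with columns `participant_id`, `mde_high`,
#'   `mde_low`, one row per paired participant.
#' @export
participant_mde <- function(records, device = NULL) {
  if (!is.null(device)) records <- records[records$device == device, ]
  if (is.null(records$stratum)) {
    stop("run stratify_by_odr() before participant_mde()", call. = FALSE)
  }
  valid <- records[!is.na(records$spo2_pct) & records$stratum != "none", ]
  out <- list()
  dropped <- character(0)
  for (pid in unique(records$participant_id)) {
    sub <- valid[valid$participant_id == pid, ]
    e_high <- sub$spo2_pct[sub$stratum == "high"] - sub$sao2_pct[sub$stratum == "high"]
    e_low <- sub$spo2_pct[sub$stratum == "low"] - sub$sao2_pct[sub$stratum == "low"]
    if (length(e_high) && length(e_low)) {
      out[[pid]] <- data.frame(
        participant_id = pid,
        mde_high = mean(e_high),
        mde_low = mean(e_low),
        stringsAsFactors = FALSE
      )
    } else {
      dropped <- c(dropped, pid)
    }
  }
  if (!length(out)) {
    stop("no participant has valid readings in both ODR strata", call. = FALSE)
  }
  if (length(dropped)) {
    message("dropped from pairing (missing a stratum): ",
            paste(dropped, collapse = ", "))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Two-sided paired t test on stratum-level MDE pairs
#'
#' Classical paired t test of the hypothesis that the participant-level
#' MDE differs between the high- and low-ODR strata. Degenerate inputs
#' are handled by convention: all differences zero gives p = 1 with
#' t = 0; identical nonzero differences give an infinite t and p = 0,
#' with a warning.
#'
#' @param pairs Data.frame from [participant_mde()] (columns
#'   `mde_high`, `mde_low`), or a two-column numeric matrix/data.frame.
#' @return List of class `oxi_paired_test` with `n_pairs`, `mean_diff`,
#'   `t_statistic`, `df`, `p_value`, `sidedness`.
#' @export
paired_t_test <- function(pairs) {
  if (is.data.frame(pairs) && all(c("mde_high", "mde_low") %in% names(pairs))) {
    x <- pairs$mde_high; y <- pairs$mde_low
  } else {
    x <- pairs[, 1]; y <- pairs[, 2]
  }
  n <- length(x)
  if (n < 2) stop("paired t test needs at least two pairs", call. = FALSE)
  d <- x - y
  # tolerance guards against float dust from exactly-agreeing strata
  if (stats::sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
    if (abs(mean(d)) <= 1e-12) {
      res <- list(n_pairs = n, mean_diff = 0, t_statistic = 0,
                  df = n - 1L, p_value = 1, sidedness = "two_sided")
    } else {
      warning("all paired differences identical and nonzero: t is infinite",
              call. = FALSE)
      res <- list(n_pairs = n, mean_diff = mean(d),
                  t_statistic = sign(mean(d)) * Inf,
                  df = n - 1L, p_value = 0, sidedness = "two_sided")
    }
    return(structure(res, class = "oxi_paired_test"))
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = "two.sided")
  structure(
    list(
      n_pairs = n,
      mean_diff = unname(tt$estimate),
      t_statistic = unname(tt$statistic),
      df = as.integer(unname(tt$parameter)),
      p_value = tt$p.value,
      sidedness = "two_sided"
    ),
    class = "oxi_paired_test"
  )
}

#' @export
print.oxi_paired_test <- function(x, ...) {
  cat(sprintf(
    "Paired t test (two-sided): n=%d, mean diff %.3f%%, t=%.3f, df=%d, p=%.4f\n",
    x$n_pairs, x$mean_diff, x$t_statistic, x$df, x$p_value
  ))
  invisible(x)
}

#' Normal QQ coordinates for a sample
#'
#' Sorted sample values against standard-normal quantiles at the
#' `(i - 0.5) / n` plotting positions; exported for plotting, with no
#' automatic pass/fail.
#'
#' @param values Numeric vector, at least 3 values.
#' @return Data.frame with columns `theoretical_quantile`,
#'   `sample_quantile`.
#' @export
qq_points <- function(values) {
  n <- length(values)
  if (n < 3) stop("QQ plot needs at least 3 values", call. = FALSE)
  data.frame(
    theoretical_quantile = stats::qnorm((seq_len(n) - 0.5) / n),
    sample_quantile = sort(values)
  )
}
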