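# Validation-report orchestration: simulate or load a measurement
# table, compute every metric block per device, check the regulatory
# thresholds, and serialize a reproducible report.

#' Regulatory A_rms threshold check
#'
#' Compares a device's A_rms against the FDA 510(k) accuracy
#' recommendation: under current guidance, less than 3% for
#' transmissive (finger-clip) sensors and less than 3.5% for
#' reflectance (wrist) sensors; under the 2025 draft guidance both
#' sensor types are held to less than 3%. The inequality is strict.
#'
#' @param arms A_rms value in percent (>= 0).
#' @param sensor_type `"transmissive"` or `"reflectance"`.
#' @param guidance `"current"` or `"draft_2025"`.
#' @return List with `pass` (logical), `threshold` (percent),
#'   `sensor_type`, `guidance`.
#' @examples
#' fda_check(2.98, "transmissive")$pass # TRUE
#' fda_check(3.52, "transmissive")$pass # FALSE
#' @export
fda_check <- function(arms,
                      sensor_type = c("transmissive", "reflectance"),
                      guidance = c("current", "draft_2025")) {
  sensor_type <- match.arg(sensor_type)
  guidance <- match.arg(guidance)
  if (!is.finite(arms) || arms < 0) stop("`arms` must be >= 0", call. = FALSE)
  threshold <- if (guidance == "draft_2025") 3.0
  else if (sensor_type == "transmissive") 3.0 else 3.5
  list(
    pass = arms < threshold,
    threshold = threshold,
    sensor_type = sensor_type,
    guidance = guidance
  )
}

#' Run the full validation pipeline
#'
#' From a configuration list, either simulates a study dataset or loads
#' one from CSV, then computes for every device: overall and hypoxemic
#' accuracy metrics, Bland-Altman blocks, the saturation-binned A_rms
#' profile, occult hypoxemia counts, the ODR-stratified participant
#' MDE pairs with the paired t test, and the regulatory assessment.
#' Deterministic given the configuration and seed.
#'
#' @param config List with either `input_csv` (path to a measurement
#'   table) or `simulate = TRUE` (use the built-in generator; fields
#'   `participants`, `protocol`, `device_models` override the
#'   defaults). Optional analysis fields: `band` (default 2),
#'   `hypoxemia_threshold` (default 88), `odr_threshold` (default 2),
#'   `bootstrap_reps` (default 10000), `seed` (default 1),
#'   `guidance` (default `"current"`), `sensor_types` (named character
#'   vector device -> sensor type; defaults to the device model's, or
#'   `"transmissive"` for loaded data).
#' @return List of class `oxi_report`.
#' @export
run_validation <- function(config = list(simulate = TRUE)) {
  seed <- config$seed %||% 1L
  band <- config$band %||% 2
  hypo_thr <- config$hypoxemia_threshold %||% 88
  odr_thr <- config$odr_threshold %||% 2
  reps <- config$bootstrap_reps %||% 10000
  guidance <- config$guidance %||% "current"
  sensor_types <- config$sensor_types

  if (!is.null(config$input_csv) && isTRUE(config$simulate)) {
    stop("config must give either `input_csv` or `simulate`, not both",
         call. = FALSE)
  }
  if (!is.null(config$input_csv)) {
    records <- read_measurements(config$input_csv)
    source_desc <- config$input_csv
  } else if (isTRUE(config$simulate)) {
    device_models <- config$device_models %||% default_device_models()
    records <- generate_study_dataset(
      participants = config$participants %||% default_participants(),
      protocol = config$protocol %||% build_protocol(),
      device_models = device_models,
      seed = seed
    )
    if (is.null(sensor_types)) {
      sensor_types <- vapply(device_models, `[[`, character(1), "sensor_type")
    }
    source_desc <- "simulated"
  } else {
    stop("config must give `input_csv` or `simulate = TRUE`", call. = FALSE)
  }

  issues <- validate_table(records)
  if (any(issues$severity == "error")) {
    stop("input table has error-severity issues; see validate_table()",
         call. = FALSE)
  }

  devices <- sort(unique(records$device))
  if (is.null(sensor_types)) {
    sensor_types <- stats::setNames(rep("transmissive", length(devices)), devices)
  }

  per_device <- lapply(devices, function(dev) {
    rec <- records[records$device == dev, ]
    overall <- validation_metrics(rec, band = band, reps = reps, seed = seed)
    hypo_rec <- hypoxemia_subset(rec, threshold = hypo_thr)
    hypo <- if (nrow(hypo_rec)) {
      validation_metrics(hypo_rec, band = band, reps = reps, seed = seed + 1L)
    } else NULL
    valid <- rec[!is.na(rec$spo2_pct), ]
    ba_all <- bland_altman(valid$sao2_pct, valid$spo2_pct)
    hypo_valid <- hypoxemia_subset(valid, threshold = hypo_thr)
    ba_hypo <- if (nrow(hypo_valid) >= 2) {
      bland_altman(hypo_valid$sao2_pct, hypo_valid$spo2_pct)
    } else NULL
    profile <- binned_arms(valid$sao2_pct, valid$spo2_pct,
                           reps = reps, seed = seed)
    occult <- detect_occult_hypoxemia(valid$sao2_pct, valid$spo2_pct)
    hypo_valid_n <- nrow(hypo_valid)

    ann <- stratify_by_odr(apply_exclusions(compute_odr(rec)),
                           threshold = odr_thr)
    odr_block <- tryCatch({
      pairs <- suppressMessages(participant_mde(ann))
      list(
        pairs = pairs,
        test = paired_t_test(pairs),
        n_included = sum(!ann$excluded & ann$odr_defined),
        n_excluded_saturated = sum(ann$exclusion_reason == "fully_saturated"),
        n_excluded_resaturation = sum(ann$exclusion_reason == "resaturation"),
        n_high = sum(ann$stratum == "high" & !is.na(ann$spo2_pct)),
        n_low = sum(ann$stratum == "low" & !is.na(ann$spo2_pct))
      )
    }, error = function(e) list(error = conditionMessage(e)))

    list(
      device = dev,
      overall = overall,
      hypoxemia = hypo,
      bland_altman = ba_all,
      bland_altman_hypoxemia = ba_hypo,
      binned_arms = profile,
      occult_hypoxemia = list(
        n = sum(occult),
        n_valid_hypoxemic = hypo_valid_n,
        participant_ids = sort(unique(valid$participant_id[occult]))
      ),
      odr = odr_block,
      fda_assessment = list(
        overall = fda_check(overall$arms, sensor_types[[dev]], guidance),
        hypoxemia = if (!is.null(hypo)) {
          fda_check(hypo$arms, sensor_types[[dev]], guidance)
        } else NULL
      )
    )
  })
  names(per_device) <- devices

  structure(
    list(
      devices = per_device,
      metadata = list(
        source = source_desc,
        n_records = nrow(records),
        n_participants = length(unique(records$participant_id)),
        seed = seed,
        band = band,
        hypoxemia_threshold = hypo_thr,
        odr_threshold = odr_thr,
        bootstrap_reps = reps,
        guidance = guidance,
        arms_ci_method = "percentile bootstrap, measurement-level resampling",
        software_version = as.character(utils::packageVersion("oxival"))
      )
    ),
    class = "oxi_report"
  )
}

#' Serialize a validation report to JSON
#'
#' Machine-readable form carrying full precision; deterministic for a
#' given configuration and seed.
#'
#' @param report An `oxi_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "oxi_report"))
  json <- jsonlite::toJSON(unclass_deep(report), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(x)
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  x
}

#' Render a validation report as text
#'
#' Human-readable summary with metrics displayed at two decimals (full
#' precision lives in the JSON form).
#'
#' @param report An `oxi_report`.
#' @return Character vector of lines, invisibly; also printed.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "oxi_report"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  md <- report$metadata
  add("Pulse oximeter validation report (source: %s, seed %d)", md$source, md$seed)
  add("%d records, %d participants; band %.0f%%, hypoxemia < %.0f%%, ODR threshold %.1f%%/min",
      md$n_records, md$n_participants, md$band, md$hypoxemia_threshold, md$odr_threshold)
  for (dev in names(report$devices)) {
    d <- report$devices[[dev]]
    m <- d$overall
    add("")
    add("== Device: %s ==", dev)
    add("Overall: n=%d attempted, %d valid; MDE %.2f%%; A_rms %.2f%% (95%% CI %.2f-%.2f%%); missingness %.2f%%",
        m$n_attempted, m$n_valid, m$mde, m$arms,
        m$arms_ci["low"], m$arms_ci["high"], m$missingness)
    add("Band (+/-%.0f%%): %d over (%.2f%%), %d within (%.2f%%), %d under (%.2f%%)",
        md$band, m$n_over, 100 * m$n_over / m$n_valid,
        m$n_within, 100 * m$n_within / m$n_valid,
        m$n_under, 100 * m$n_under / m$n_valid)
    if (!is.null(d$hypoxemia)) {
      h <- d$hypoxemia
      add("Hypoxemia (SaO2 < %.0f%%): n=%d valid; MDE %.2f%%; A_rms %.2f%% (95%% CI %.2f-%.2f%%)",
          md$hypoxemia_threshold, h$n_valid, h$mde, h$arms,
          h$arms_ci["low"], h$arms_ci["high"])
    }
    add("Bland-Altman: bias %.2f%%, LoA [%.2f%%, %.2f%%]",
        d$bland_altman$bias, d$bland_altman$loa_low, d$bland_altman$loa_high)
    add("Occult hypoxemia: %d of %d valid hypoxemic readings",
        d$occult_hypoxemia$n, d$occult_hypoxemia$n_valid_hypoxemic)
    if (is.null(d$odr$error)) {
      t <- d$odr$test
      add("ODR strata: %d included (%d high, %d low); excluded %d saturated, %d resaturation",
          d$odr$n_included, d$odr$n_high, d$odr$n_low,
          d$odr$n_excluded_saturated, d$odr$n_excluded_resaturation)
      add("Paired t (MDE high vs low ODR): n=%d, mean diff %.2f%%, t=%.3f, df=%d, p=%.3f",
          t$n_pairs, t$mean_diff, t$t_statistic, t$df, t$p_value)
    } else {
      add("ODR analysis unavailable: %s", d$odr$error)
    }
    f <- d$fda_assessment$overall
    add("FDA check (%s, %s): A_rms %.2f%% vs < %.1f%% -> %s",
        f$sensor_type, f$guidance, m$arms, f$threshold,
        if (f$pass) "PASS" else "FAIL")
    if (!is.null(d$fda_assessment$hypoxemia)) {
      fh <- d$fda_assessment$hypoxemia
      add("FDA check under hypoxemia: A_rms %.2f%% vs < %.1f%% -> %s",
          d$hypoxemia$arms, fh$threshold, if (fh$pass) "PASS" else "FAIL")
    }
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}

#' @export
print.oxi_report <- function(x, ...) {
  render_report(x)
  invisible(x)
}
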