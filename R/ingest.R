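# Measurement-table I/O and validation: the format boundary of the
# pipeline. CSV dialect: comma-separated, UTF-8, "." decimal, mandatory
# header; times are integer seconds from protocol start; SaO2 carries
# one decimal, SpO2 integers, a failed attempt is an empty spo2 field.

.measurement_cols <- c(
  "participant_id", "device", "plateau", "sample", "time_s",
  "petO2_mmHg", "sao2_pct", "spo2_pct", "phase"
)

#' Write a measurement table as CSV
#'
#' Numeric formatting is bit-stable: `sao2_pct` with one decimal,
#' `spo2_pct` as integers with failed attempts as empty fields, so a
#' write/read round trip is the identity.
#'
#' @param records Measurement data.frame (see
#'   [generate_study_dataset()] for the schema).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  stopifnot(all(.measurement_cols %in% names(records)))
  out <- records[, .measurement_cols]
  out$sao2_pct <- sprintf("%.1f", out$sao2_pct)
  out$spo2_pct <- ifelse(is.na(out$spo2_pct), "",
                         sprintf("%d", as.integer(round(out$spo2_pct))))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a measurement table from CSV
#'
#' Header matching is case-insensitive; unknown columns raise a warning
#' and are dropped; an empty `spo2_pct` field becomes `NA` (a failed
#' attempt). Rows are returned sorted by (participant, device, time).
#'
#' @param path CSV file path.
#' @return Measurement data.frame in the canonical column order.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  names(raw) <- tolower(names(raw))
  want <- stats::setNames(.measurement_cols, tolower(.measurement_cols))
  unknown <- setdiff(names(raw), names(want))
  if (length(unknown)) {
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "),
            call. = FALSE)
  }
  missing_cols <- setdiff(names(want), names(raw))
  if (length(missing_cols)) {
    stop("missing required column(s): ",
         paste(want[missing_cols], collapse = ", "), call. = FALSE)
  }
  parse_num <- function(x, col, integer = FALSE) {
    blank <- !nzchar(trimws(x))
    v <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(v) & !blank)
    if (length(bad)) {
      stop(sprintf("unparseable %s at row %d: '%s'", col, bad[1], x[bad[1]]),
           call. = FALSE)
    }
    if (integer) v <- as.integer(round(v))
    v
  }
  rec <- data.frame(
    participant_id = raw[["participant_id"]],
    device = raw[["device"]],
    plateau = parse_num(raw[["plateau"]], "plateau", integer = TRUE),
    sample = parse_num(raw[["sample"]], "sample", integer = TRUE),
    time_s = parse_num(raw[["time_s"]], "time_s", integer = TRUE),
    petO2_mmHg = parse_num(raw[["peto2_mmhg"]], "petO2_mmHg"),
    sao2_pct = parse_num(raw[["sao2_pct"]], "sao2_pct"),
    spo2_pct = parse_num(raw[["spo2_pct"]], "spo2_pct"),
    phase = parse_num(raw[["phase"]], "phase", integer = TRUE),
    stringsAsFactors = FALSE
  )
  if (nrow(rec)) {
    oob <- which(!is.na(rec$spo2_pct) & (rec$spo2_pct < 0 | rec$spo2_pct > 100))
    if (length(oob)) {
      stop(sprintf("spo2_pct out of [0, 100] at row %d", oob[1]), call. = FALSE)
    }
    key <- paste(rec$participant_id, rec$device, rec$plateau, rec$sample)
    if (anyDuplicated(key)) {
      stop(sprintf("duplicate measurement key at row %d", anyDuplicated(key)),
           call. = FALSE)
    }
    rec <- rec[order(rec$participant_id, rec$device, rec$time_s), ]
    rownames(rec) <- NULL
  }
  rec
}

#' Validate a measurement table
#'
#' Screens records for scientifically implausible or structurally
#' inconsistent content. Issues are data, not exceptions: each is a row
#' in the returned table with a severity and a message.
#'
#' Checks: reference `sao2_pct` within (0, 100] (error), non-integer
#' `spo2_pct` (error), non-monotone time within a participant/device
#' series (warning), and attempted readings lacking a reference value
#' (error).
#'
#' @param records Measurement data.frame.
#' @return Data.frame with columns `row`, `column`, `severity`,
#'   `message`; zero rows for a clean table.
#' @export
validate_table <- function(records) {
  issues <- list()
  add <- function(row, column, severity, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      row = row, column = column, severity = severity, message = message,
      stringsAsFactors = FALSE
    )
  }
  for (i in which(is.na(records$sao2_pct) |
                  records$sao2_pct <= 0 | records$sao2_pct > 100)) {
    add(i, "sao2_pct", "error", "reference SaO2 outside (0, 100]")
  }
  valid_spo2 <- !is.na(records$spo2_pct)
  for (i in which(valid_spo2 & records$spo2_pct != round(records$spo2_pct))) {
    add(i, "spo2_pct", "warning", "SpO2 not at integer display resolution")
  }
  for (i in which(valid_spo2 & is.na(records$sao2_pct))) {
    add(i, "sao2_pct", "error", "attempted reading without a reference value")
  }
  if (nrow(records)) {
    grp <- split(seq_len(nrow(records)),
                 paste(records$participant_id, records$device))
    for (idx in grp) {
      t <- records$time_s[idx]
      bad <- which(diff(t) < 0)
      for (b in bad) {
        add(idx[b + 1L], "time_s", "warning",
            "time not monotone within participant/device series")
      }
    }
  }
  if (!length(issues)) {
    return(data.frame(row = integer(0), column = character(0),
                      severity = character(0), message = character(0),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, issues)
  res[order(res$row), , drop = FALSE]
}
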