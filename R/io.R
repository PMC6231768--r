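# Tabular I/O. All tables are plain CSV with a header row; missing values
# are written as empty fields. Day indices are 0-based integers.

#' Write / read a daily-record table
#'
#' One row per patient-day: `patient_id`, `day`, the 8 symptom flags (0/1),
#' `pulse` (bpm), `spo2` (%), `antibiotic`, `corticosteroid`, `admission`
#' (0/1), and the weather covariates when present. Empty fields are missing.
#'
#' @param records daily record table.
#' @param path CSV path.
#' @return invisibly, the path (write) or the table (read).
#' @export
write_daily_records <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_daily_records
#' @export
read_daily_records <- function(path) {
  out <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  need <- c("patient_id", "day", SYMPTOM_VARS, PHYSIOLOGY_VARS,
            MEDICATION_VARS, "admission")
  miss <- setdiff(need, names(out))
  if (length(miss))
    stop("daily-record file lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  out$patient_id <- as.character(out$patient_id)
  out$day <- as.integer(out$day)
  out[order(out$patient_id, out$day), , drop = FALSE]
}

#' Write / read a baseline covariate table
#' @param baseline baseline table.
#' @param path CSV path.
#' @export
write_baseline <- function(baseline, path) {
  utils::write.csv(baseline, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_baseline
#' @export
read_baseline <- function(path) {
  out <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  out$patient_id <- as.character(out$patient_id)
  out
}

#' Write an episode set as wide CSV plus labels CSV
#'
#' The episode table has one row per episode with columns `patient_id`, `t`,
#' then `var_d{offset}` values and `var_d{offset}_imputed` flags; the labels
#' file has `patient_id`, `t`, `label`.
#'
#' @param episodes an episode set.
#' @param path episode CSV path.
#' @param labels_path labels CSV path (default: `path` with `_labels` suffix).
#' @export
write_episodes <- function(episodes, path,
                           labels_path = sub("\\.csv$", "_labels.csv", path)) {
  wide <- cbind(episodes$meta[, c("patient_id", "t")],
                as.data.frame(episodes$values),
                as.data.frame(episodes$flags))
  utils::write.csv(wide, path, row.names = FALSE, na = "")
  utils::write.csv(episodes$meta[, c("patient_id", "t", "label")],
                   labels_path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a feature matrix as CSV
#'
#' Header row of feature names preceded by `patient_id`, `t`, `label`.
#'
#' @param features a `telecopd_features` object.
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  out <- cbind(data.frame(patient_id = features$patient_id, t = features$t,
                          label = features$label),
               as.data.frame(features$x))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
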