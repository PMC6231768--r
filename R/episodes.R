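#' Episode-construction configuration
#'
#' @param window window length W in days (the episode covers days
#'   t-W+1 ... t); default 7.
#' @param max_fill_horizon maximum age in days of a carried-forward
#'   observation (default 15).
#' @param scenario `"complete"` (keep only episodes with no missing symptom
#'   variable in the window) or `"imputed"` (forward-fill first, then drop
#'   episodes still missing a required variable or the outcome).
#' @param outcome `"admission"` or `"corticosteroid"`.
#' @param sparse_patient_threshold drop patients whose missing-field fraction
#'   strictly exceeds this (default 0.95).
#' @return an object of class `telecopd_episode_config`.
#' @export
episode_config <- function(window = 7L, max_fill_horizon = 15L,
                           scenario = c("imputed", "complete"),
                           outcome = c("admission", "corticosteroid"),
                           sparse_patient_threshold = 0.95) {
  scenario <- match.arg(scenario)
  outcome <- match.arg(outcome)
  e <- character()
  e <- check_that(e, is_count(window) && window >= 1, "window must be an integer >= 1")
  e <- check_that(e, is_count(max_fill_horizon), "max_fill_horizon must be an integer >= 0")
  e <- check_that(e, is_prob(sparse_patient_threshold) &&
                    length(sparse_patient_threshold) == 1L,
                  "sparse_patient_threshold must be in [0,1]")
  stop_if_errors(e, "invalid episode configuration")
  structure(list(window = as.integer(window),
                 max_fill_horizon = as.integer(max_fill_horizon),
                 scenario = scenario, outcome = outcome,
                 sparse_patient_threshold = sparse_patient_threshold),
            class = "telecopd_episode_config")
}

#' Exclude patients with almost entirely missing data
#'
#' Removes patients whose fraction of missing maskable fields (symptoms,
#' physiology, medications) across their whole record is strictly greater
#' than the threshold. A patient at exactly the threshold is retained.
#'
#' @param records daily record table.
#' @param threshold fraction in [0,1]; default 0.95.
#' @return the records restricted to retained patients.
#' @export
exclude_sparse_patients <- function(records, threshold = 0.95) {
  if (!nrow(records)) return(records)
  m <- as.matrix(records[, MASKABLE_VARS, drop = FALSE])
  frac <- tapply(rowMeans(is.na(m)), records$patient_id, mean)
  keep <- names(frac)[frac <= threshold]
  out <- records[records$patient_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Forward-fill one variable series with a horizon
#'
#' Replaces each missing value by the most recent observed value of the same
#' variable for the same patient, provided that observation is at most
#' `horizon` days old; older donors (or no donor at all) leave the value
#' missing. Only past values are ever used. Returns the filled series and a
#' 0/1 flag vector marking entries that were imputed.
#'
#' @param x numeric vector for one patient in day order (one entry per
#'   calendar day).
#' @param horizon maximum donor age in days (default 15).
#' @return list with `values` and `flags`.
#' @export
forward_fill <- function(x, horizon = 15L) {
  n <- length(x)
  flags <- integer(n)
  if (n == 0L) return(list(values = x, flags = flags))
  obs <- which(!is.na(x))
  if (!length(obs)) return(list(values = x, flags = flags))
  # index of most recent observation at or before each position
  last_obs <- cummax(ifelse(is.na(x), 0L, seq_len(n)))
  fillable <- is.na(x) & last_obs > 0L & (seq_len(n) - last_obs) <= horizon
  x[fillable] <- x[last_obs[fillable]]
  flags[fillable] <- 1L
  list(values = x, flags = flags)
}

# Insert all-missing rows for calendar days absent from a patient's record,
# so that sliding windows always run over consecutive days.
materialize_day_grid <- function(records) {
  split_recs <- split(records, records$patient_id)
  filled <- lapply(split_recs, function(r) {
    days <- min(r$day):max(r$day)
    if (length(days) == nrow(r)) return(r)
    grid <- data.frame(patient_id = r$patient_id[1], day = days,
                       stringsAsFactors = FALSE)
    out <- merge(grid, r, by = c("patient_id", "day"), all.x = TRUE, sort = FALSE)
    out[order(out$day), , drop = FALSE]
  })
  out <- do.call(rbind, filled)
  rownames(out) <- NULL
  out[order(out$patient_id, out$day), , drop = FALSE]
}

#' Build patient episodes with next-day outcomes
#'
#' Constructs one candidate episode per patient per day `t` with a full
#' `W`-day history (`t >= W-1`, 0-based) and an observed following day, under
#' either scenario:
#' \describe{
#'   \item{complete}{raw values; only episodes with no missing symptom
#'     variable anywhere in the window are kept.}
#'   \item{imputed}{every maskable variable is forward-filled per patient for
#'     up to `max_fill_horizon` days (weather is exogenous and never
#'     filled); episodes still containing a missing required variable
#'     (symptoms, physiology, medications) or a missing outcome are
#'     dropped. A parallel 0/1 flag matrix marks imputed entries.}
#' }
#' The outcome label is the admission flag (or corticosteroid-use flag) on
#' day `t+1`. Episodes are a pure function of the records and config, so the
#' same episode set is shared by every evaluation fold.
#'
#' @param records daily record table (sparse patients already excluded);
#'   calendar gaps are materialized as all-missing days.
#' @param config an [episode_config()].
#' @return an object of class `telecopd_episodes`: list with `meta`
#'   (patient_id, t, label), `values` and `flags` matrices whose columns are
#'   `var_d0` (day t) ... `var_d{W-1}` (day t-W+1), plus attributes
#'   `day_counts` (per-day symptom counts on the scenario's inputs, for the
#'   definition rules) and `config`.
#' @export
build_episodes <- function(records, config) {
  stopifnot(inherits(config, "telecopd_episode_config"))
  W <- config$window
  if (!nrow(records)) return(empty_episodes(config))
  records <- materialize_day_grid(records)
  have_weather <- all(WEATHER_VARS %in% names(records))
  vars <- c(SYMPTOM_VARS, PHYSIOLOGY_VARS, MEDICATION_VARS,
            if (have_weather) WEATHER_VARS)
  req_vars <- MASKABLE_VARS   # weather assumed complete, never a drop reason

  flags_tpl <- NULL
  if (config$scenario == "imputed") {
    for (v in MASKABLE_VARS) {
      filled <- unlist(lapply(split(records[[v]], records$patient_id), function(x)
        forward_fill(x, config$max_fill_horizon)$values), use.names = FALSE)
      fl <- unlist(lapply(split(records[[v]], records$patient_id), function(x)
        forward_fill(x, config$max_fill_horizon)$flags), use.names = FALSE)
      # split() orders by factor level = sorted patient_id; records are sorted
      records[[paste0(".flag_", v)]] <- fl
      records[[v]] <- filled
    }
  } else {
    for (v in MASKABLE_VARS) records[[paste0(".flag_", v)]] <- 0L
  }

  per_patient <- lapply(split(records, records$patient_id), function(r) {
    n <- nrow(r)
    if (n < W + 1L) return(NULL)
    # episode end-days t (1-based row positions W ... n-1; outcome at t+1)
    rows_t <- W:(n - 1L)
    val_cols <- lapply(vars, function(v) {
      E <- stats::embed(r[[v]], W)        # row i: x[t], x[t-1], ..., x[t-W+1]
      E[rows_t - W + 1L, , drop = FALSE]
    })
    flg_cols <- lapply(MASKABLE_VARS, function(v) {
      E <- stats::embed(r[[paste0(".flag_", v)]], W)
      E[rows_t - W + 1L, , drop = FALSE]
    })
    values <- do.call(cbind, val_cols)
    flags <- do.call(cbind, flg_cols)
    label <- switch(config$outcome,
                    admission = r$admission[rows_t + 1L],
                    corticosteroid = r$corticosteroid[rows_t + 1L])
    # day-t value of the corticosteroid flag, for the onset filter
    cort_t <- r$corticosteroid[rows_t]
    list(meta = data.frame(patient_id = r$patient_id[1], t = r$day[rows_t],
                           label = label, cort_t = cort_t,
                           stringsAsFactors = FALSE),
         values = values, flags = flags)
  })
  per_patient <- Filter(Negate(is.null), per_patient)
  if (!length(per_patient)) {
    warning("window of ", W, " days exceeds every patient's record length")
    return(empty_episodes(config))
  }
  meta <- do.call(rbind, lapply(per_patient, `[[`, "meta"))
  values <- do.call(rbind, lapply(per_patient, `[[`, "values"))
  flags <- do.call(rbind, lapply(per_patient, `[[`, "flags"))
  colnames(values) <- paste0(rep(vars, each = W), "_d", 0:(W - 1L))
  colnames(flags) <- paste0(rep(MASKABLE_VARS, each = W), "_d", 0:(W - 1L), "_imputed")
  rownames(meta) <- NULL

  sym_cols <- paste0(rep(SYMPTOM_VARS, each = W), "_d", 0:(W - 1L))
  if (config$scenario == "complete") {
    keep <- rowSums(is.na(values[, sym_cols, drop = FALSE])) == 0 & !is.na(meta$label)
  } else {
    req_cols <- paste0(rep(req_vars, each = W), "_d", 0:(W - 1L))
    keep <- rowSums(is.na(values[, req_cols, drop = FALSE])) == 0 & !is.na(meta$label)
  }
  meta <- meta[keep, , drop = FALSE]
  values <- values[keep, , drop = FALSE]
  flags <- flags[keep, , drop = FALSE]
  rownames(meta) <- NULL

  day_counts <- data.frame(patient_id = records$patient_id, day = records$day,
                           symptom_counts(records, allow_missing = TRUE),
                           stringsAsFactors = FALSE)
  out <- list(meta = meta, values = values, flags = flags)
  class(out) <- "telecopd_episodes"
  attr(out, "day_counts") <- day_counts
  attr(out, "config") <- config
  out
}

empty_episodes <- function(config) {
  out <- list(meta = data.frame(patient_id = character(), t = integer(),
                                label = integer(), cort_t = integer()),
              values = matrix(numeric(0), 0, 0),
              flags = matrix(numeric(0), 0, 0))
  class(out) <- "telecopd_episodes"
  attr(out, "config") <- config
  attr(out, "day_counts") <- data.frame(patient_id = character(), day = integer(),
                                        nMajor = numeric(), nMinor = numeric(),
                                        nAll = numeric())
  out
}

#' @export
print.telecopd_episodes <- function(x, ...) {
  cfg <- attr(x, "config")
  cat("<telecopd_episodes> ", nrow(x$meta), " episodes (",
      sum(x$meta$label == 1, na.rm = TRUE), " events), scenario=", cfg$scenario,
      ", outcome=", cfg$outcome, ", W=", cfg$window, "\n", sep = "")
  invisible(x)
}

#' Restrict corticosteroid episodes to new treatment onsets
#'
#' For the corticosteroid outcome only episodes where the patient reported
#' (or, in the imputed scenario, was imputed as) not taking corticosteroids
#' on day t are retained, so that a positive label means a treatment onset
#' on day t+1 rather than an ongoing course. Episodes with a missing day-t
#' corticosteroid flag are excluded.
#'
#' @param episodes an episode set built with `outcome = "corticosteroid"`.
#' @return the filtered episode set.
#' @export
corticosteroid_filter <- function(episodes) {
  stopifnot(inherits(episodes, "telecopd_episodes"))
  cfg <- attr(episodes, "config")
  if (cfg$outcome != "corticosteroid")
    stop("corticosteroid_filter applies to corticosteroid-outcome episodes",
         call. = FALSE)
  keep <- !is.na(episodes$meta$cort_t) & episodes$meta$cort_t == 0
  subset_episodes(episodes, keep)
}

# Row-subset an episode set, preserving attributes.
subset_episodes <- function(episodes, keep) {
  out <- list(meta = episodes$meta[keep, , drop = FALSE],
              values = episodes$values[keep, , drop = FALSE],
              flags = episodes$flags[keep, , drop = FALSE])
  rownames(out$meta) <- NULL
  class(out) <- "telecopd_episodes"
  attr(out, "day_counts") <- attr(episodes, "day_counts")
  attr(out, "config") <- attr(episodes, "config")
  out
}
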