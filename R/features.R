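#' Default time-series feature catalogue
#'
#' Builds the ordered catalogue of per-episode features for one covariate
#' set. Transforms are standard clinical time-series summaries over the
#' episode window: current value, lag-k value, rolling mean/min/max/SD and
#' event counts, linear trend slope, delta from a lagged value, deviation
#' from the window mean, days since last positive, counts beyond clinical
#' thresholds (SpO2 below 90%, pulse above 100 bpm, symptom score above the
#' alert level 5), imputation-fraction summaries of the flag matrix, and
#' static baseline covariates.
#'
#' Variants: `"telemonitoring"` (symptoms, derived scores, physiology,
#' medications; 153 features with indicators and baseline under the default
#' `W = 7`), `"weather"` (exogenous weather covariates only) and `"joint"`
#' (telemonitoring plus weather, trimmed to the same 153-feature budget).
#' Features whose lag or window cannot fit in `W` are omitted, so with
#' `W = 1` only current-value and imputation-flag features remain.
#'
#' @param variant covariate set.
#' @param W episode window length in days.
#' @param include_indicators add imputation-indicator features (used in the
#'   imputed scenario).
#' @param include_baseline append the static baseline covariates.
#' @return data.frame catalogue with columns `name`, `variable`, `transform`,
#'   `param`, `threshold`, `group`; class `telecopd_catalogue`.
#' @export
default_catalogue <- function(variant = c("telemonitoring", "weather", "joint"),
                              W = 7L,
                              include_indicators = TRUE,
                              include_baseline = !identical(variant, "weather")) {
  variant <- match.arg(variant)
  if (identical(variant, "weather")) {
    include_indicators <- FALSE
    include_baseline <- FALSE
  }
  rows <- list()
  add <- function(variable, transform, param = NA_real_, threshold = NA_real_,
                  group = NA_character_, name = NULL) {
    nm <- name %||% feature_name(variable, transform, param, threshold)
    rows[[length(rows) + 1L]] <<- data.frame(
      name = nm, variable = variable, transform = transform,
      param = param, threshold = threshold, group = group,
      stringsAsFactors = FALSE)
  }
  tele <- variant %in% c("telemonitoring", "joint")
  wthr <- variant %in% c("weather", "joint")

  if (tele) {
    for (v in SYMPTOM_VARS) {
      add(v, "current"); add(v, "lag", 1)
      if (variant == "telemonitoring") add(v, "lag", 2)
      add(v, "roll_count", 3); add(v, "roll_count", 7)
      add(v, "delta", 1); add(v, "days_since", 7)
    }
    for (tf in list(c("current", NA), c("lag", 1), c("lag", 2),
                    c("roll_mean", 3), c("roll_mean", 7), c("roll_max", 7),
                    c("roll_sd", 3), c("roll_sd", 7), c("slope", 3),
                    c("slope", 7), c("delta", 1)))
      add("telescot", tf[1], as.numeric(tf[2]))
    add("telescot", "count_above", 7, threshold = 5)
    add("nMajor", "current"); add("nMajor", "roll_mean", 7)
    add("nMinor", "current")
    add("nAll", "current"); add("nAll", "lag", 1); add("nAll", "roll_mean", 3)
    add("nAll", "roll_mean", 7); add("nAll", "slope", 7); add("nAll", "delta", 1)
    add("nAll", "roll_max", 7)
    for (v in PHYSIOLOGY_VARS) {
      for (tf in list(c("current", NA), c("lag", 1), c("lag", 2),
                      c("roll_mean", 3), c("roll_mean", 7), c("roll_sd", 3),
                      c("roll_sd", 7), c("slope", 3), c("slope", 7),
                      c("delta", 1), c("dev", 7)))
        add(v, tf[1], as.numeric(tf[2]))
      if (variant == "telemonitoring") add(v, "delta", 3)
    }
    add("pulse", "roll_max", 7); add("pulse", "count_above", 7, threshold = 100)
    add("spo2", "roll_min", 7); add("spo2", "count_below", 7, threshold = 90)
    for (v in MEDICATION_VARS) {
      add(v, "current"); add(v, "roll_any", 3); add(v, "roll_any", 7)
      add(v, "roll_count", 7); add(v, "days_since", 7)
    }
    if (variant == "telemonitoring") {
      # pad family keeping the default telemonitoring catalogue at 153
      for (v in SYMPTOM_VARS) add(v, "roll_any", 7)
      add("nMinor", "roll_mean", 7)
      add("telescot", "roll_min", 7)
      add("nMajor", "lag", 1)
    }
  }
  if (wthr) {
    for (v in c("mean_temp", "max_temp")) {
      add(v, "current"); add(v, "lag", 1); add(v, "roll_mean", 3)
      add(v, "roll_mean", 7); add(v, "slope", 7); add(v, "delta", 1)
    }
    for (v in c("temp_mean_lt2", "temp_max_lt4", "temp_max_lt7")) {
      add(v, "current"); add(v, "roll_count", 7)
    }
    add("alert_level", "current"); add("alert_level", "lag", 1)
    add("alert_level", "roll_mean", 7)
  }
  if (include_indicators) {
    for (v in MASKABLE_VARS) add(v, "imputed_fraction")
    add("symptoms", "imputed_fraction", group = "symptoms",
        name = "symptoms_impfrac")
    add("physiology", "imputed_fraction", group = "physiology",
        name = "physiology_impfrac")
    add("medications", "imputed_fraction", group = "medications",
        name = "medications_impfrac")
    add("all", "imputed_count_current", name = "imputed_count_d0")
  }
  if (include_baseline) {
    for (v in c("age", "sex_male", "bmi", "fev1pp", "mrc", "anxiety",
                "depression", "qol", "prior_admissions", "smoker_yes"))
      add(v, "baseline")
  }
  cat_df <- do.call(rbind, rows)
  # drop transforms that cannot fit in the window
  fits <- catalogue_fits_window(cat_df, W)
  cat_df <- cat_df[fits, , drop = FALSE]
  rownames(cat_df) <- NULL
  stopifnot(!anyDuplicated(cat_df$name))
  structure(cat_df, class = c("telecopd_catalogue", "data.frame"),
            variant = variant, W = as.integer(W))
}

feature_name <- function(variable, transform, param, threshold) {
  switch(transform,
    current = paste0(variable, "_current"),
    lag = paste0(variable, "_lag", param),
    roll_mean = paste0(variable, "_mean", param),
    roll_min = paste0(variable, "_min", param),
    roll_max = paste0(variable, "_max", param),
    roll_sd = paste0(variable, "_sd", param),
    slope = paste0(variable, "_slope", param),
    roll_count = paste0(variable, "_count", param),
    roll_any = paste0(variable, "_any", param),
    count_above = paste0(variable, "_above", threshold, "_n", param),
    count_below = paste0(variable, "_below", threshold, "_n", param),
    delta = paste0(variable, "_delta", param),
    dev = paste0(variable, "_dev", param),
    days_since = paste0(variable, "_dayssince", param),
    imputed_fraction = paste0(variable, "_impfrac"),
    baseline = variable,
    stop("unknown transform: ", transform))
}

catalogue_fits_window <- function(cat_df, W) {
  p <- cat_df$param
  ifelse(cat_df$transform == "lag", p <= W - 1L,
         ifelse(cat_df$transform %in% c("delta"), p <= W - 1L,
                ifelse(is.na(p), TRUE, p <= W)))
}

#' Validate a catalogue against an episode window
#'
#' @param catalogue a feature catalogue.
#' @param W window length in days.
#' @return invisibly TRUE; errors if any lag or window exceeds the window.
#' @export
validate_catalogue <- function(catalogue, W) {
  bad <- !catalogue_fits_window(catalogue, W)
  if (any(bad))
    stop("catalogue features exceed window W=", W, ": ",
         paste(catalogue$name[bad], collapse = ", "), call. = FALSE)
  if (anyDuplicated(catalogue$name))
    stop("catalogue feature names are not unique", call. = FALSE)
  invisible(TRUE)
}

#' Impute baseline covariates by population median/mode
#'
#' Missing continuous covariates are replaced by the column median across
#' patients; categorical covariates (character, factor or logical) by the
#' column mode. Baseline covariates are treated as fixed over the study.
#'
#' @param baseline baseline covariate table (one row per patient).
#' @return the table with no missing values.
#' @export
impute_baseline <- function(baseline) {
  for (col in setdiff(names(baseline), "patient_id")) {
    x <- baseline[[col]]
    if (!anyNA(x)) next
    if (all(is.na(x)))
      stop("baseline column '", col, "' is entirely missing", call. = FALSE)
    if (is.numeric(x)) {
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    } else {
      tab <- table(x)
      x[is.na(x)] <- names(tab)[which.max(tab)]
    }
    baseline[[col]] <- x
  }
  baseline
}

# Value matrix (episodes x W offsets) for one variable, including derived
# symptom-count variables.
episode_var_matrix <- function(episodes, var, W) {
  get1 <- function(v) {
    cols <- paste0(v, "_d", 0:(W - 1L))
    if (!all(cols %in% colnames(episodes$values)))
      stop("variable '", v, "' required by the catalogue is absent from the episodes",
           call. = FALSE)
    episodes$values[, cols, drop = FALSE]
  }
  if (var %in% c("telescot", "nMajor", "nMinor", "nAll")) {
    maj <- Reduce(`+`, lapply(MAJOR_SYMPTOMS, get1))
    mnr <- Reduce(`+`, lapply(MINOR_SYMPTOMS, get1))
    switch(var,
           telescot = 2 * maj + mnr,
           nMajor = maj, nMinor = mnr, nAll = maj + mnr)
  } else get1(var)
}

row_slope <- function(V, k) {
  tt <- -(0:(k - 1L))             # day offsets backwards in time
  w <- (tt - mean(tt)) / sum((tt - mean(tt))^2)
  as.numeric(V[, 1:k, drop = FALSE] %*% w)
}

row_sd <- function(V, k) {
  Vk <- V[, 1:k, drop = FALSE]
  m <- rowMeans(Vk)
  sq <- rowSums(Vk^2) - k * m^2
  sqrt(pmax(sq, 0) / (k - 1))
}

days_since_last <- function(V, W) {
  out <- rep(W, nrow(V))
  for (j in W:1) out[V[, j] == 1] <- j - 1L
  out
}

#' Extract feature vectors from an episode set
#'
#' Computes every catalogue feature for every episode, using only days
#' inside the episode window (never day t+1 or later), and appends the
#' imputed baseline covariates. All features are a pure function of the
#' episode values/flags and the baseline row, so they are invariant to any
#' change in records after day t and to translation of the day axis.
#'
#' @param episodes an episode set from [build_episodes()] (all catalogue
#'   variables must be non-missing after imputation).
#' @param catalogue a catalogue from [default_catalogue()].
#' @param baseline baseline table; missing values are imputed by
#'   [impute_baseline()].
#' @return list of class `telecopd_features`: `x` numeric matrix (episodes x
#'   features, named columns in catalogue order), `label`, `patient_id`, `t`.
#' @export
extract_features <- function(episodes, catalogue, baseline = NULL) {
  stopifnot(inherits(episodes, "telecopd_episodes"))
  W <- attr(episodes, "config")$window
  validate_catalogue(catalogue, W)
  n <- nrow(episodes$meta)

  needs_baseline <- any(catalogue$transform == "baseline")
  if (needs_baseline) {
    if (is.null(baseline))
      stop("catalogue contains baseline covariates but no baseline table was given",
           call. = FALSE)
    bl <- impute_baseline(baseline)
    bl$sex_male <- as.numeric(bl$sex == "male")
    bl$smoker_yes <- as.numeric(bl$smoker == "yes")
    bl_idx <- match(episodes$meta$patient_id, bl$patient_id)
    if (anyNA(bl_idx) && n > 0)
      stop("baseline table does not cover all episode patients", call. = FALSE)
  }

  Vcache <- new.env(parent = emptyenv())
  getV <- function(var) {
    if (is.null(Vcache[[var]]))
      Vcache[[var]] <- episode_var_matrix(episodes, var, W)
    Vcache[[var]]
  }
  flag_group_cols <- function(group) {
    vars <- switch(group, symptoms = SYMPTOM_VARS, physiology = PHYSIOLOGY_VARS,
                   medications = MEDICATION_VARS, all = MASKABLE_VARS)
    paste0(rep(vars, each = W), "_d", 0:(W - 1L), "_imputed")
  }

  x <- matrix(NA_real_, n, nrow(catalogue),
              dimnames = list(NULL, catalogue$name))
  for (i in seq_len(nrow(catalogue))) {
    tr <- catalogue$transform[i]
    v <- catalogue$variable[i]
    k <- catalogue$param[i]
    thr <- catalogue$threshold[i]
    x[, i] <- switch(tr,
      current = getV(v)[, 1],
      lag = getV(v)[, k + 1L],
      roll_mean = rowMeans(getV(v)[, 1:k, drop = FALSE]),
      roll_min = do.call(pmin, as.data.frame(getV(v)[, 1:k, drop = FALSE])),
      roll_max = do.call(pmax, as.data.frame(getV(v)[, 1:k, drop = FALSE])),
      roll_sd = row_sd(getV(v), k),
      slope = row_slope(getV(v), k),
      roll_count = rowSums(getV(v)[, 1:k, drop = FALSE]),
      roll_any = as.numeric(rowSums(getV(v)[, 1:k, drop = FALSE]) > 0),
      count_above = rowSums(getV(v)[, 1:k, drop = FALSE] > thr),
      count_below = rowSums(getV(v)[, 1:k, drop = FALSE] < thr),
      delta = getV(v)[, 1] - getV(v)[, k + 1L],
      dev = getV(v)[, 1] - rowMeans(getV(v)[, 1:k, drop = FALSE]),
      days_since = days_since_last(getV(v), W),
      imputed_fraction = {
        cols <- if (!is.na(catalogue$group[i])) flag_group_cols(catalogue$group[i])
                else paste0(v, "_d", 0:(W - 1L), "_imputed")
        rowMeans(episodes$flags[, cols, drop = FALSE])
      },
      imputed_count_current =
        rowSums(episodes$flags[, grepl("_d0_imputed$", colnames(episodes$flags)),
                               drop = FALSE]),
      baseline = as.numeric(bl[[v]])[bl_idx],
      stop("unknown transform: ", tr))
  }
  if (n > 0 && anyNA(x)) {
    bad <- colnames(x)[colSums(is.na(x)) > 0]
    stop("features contain missing values (episodes incomplete for the catalogue): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(x = x, label = episodes$meta$label,
                 patient_id = episodes$meta$patient_id, t = episodes$meta$t),
            class = "telecopd_features")
}

#' @export
print.telecopd_features <- function(x, ...) {
  cat("<telecopd_features> ", nrow(x$x), " episodes x ", ncol(x$x),
      " features (", sum(x$label == 1), " events)\n", sep = "")
  invisible(x)
}
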