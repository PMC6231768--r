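#' Major/minor symptom counts for patient-days
#'
#' Counts present major symptoms (breathlessness, sputum colour, sputum
#' amount), minor symptoms (cold, wheeze, sore throat, cough, fever) and
#' their total for each row of a daily record table.
#'
#' A day with any missing symptom flag has no defined count: by default this
#' is an error; with `allow_missing = TRUE` such days get `NA` counts and the
#' caller decides how the scenario handles them (complete-data analyses drop
#' them, imputed analyses forward-fill upstream).
#'
#' @param days data.frame with the 8 symptom columns coded 0/1/NA.
#' @param allow_missing return NA counts for incomplete days instead of
#'   erroring.
#' @return data.frame with columns `nMajor` (0-3), `nMinor` (0-5), `nAll` (0-8).
#' @export
symptom_counts <- function(days, allow_missing = FALSE) {
  miss_cols <- setdiff(SYMPTOM_VARS, names(days))
  if (length(miss_cols))
    stop("missing symptom columns: ", paste(miss_cols, collapse = ", "), call. = FALSE)
  sm <- as.matrix(days[, SYMPTOM_VARS, drop = FALSE])
  storage.mode(sm) <- "numeric"
  incomplete <- rowSums(is.na(sm)) > 0
  if (any(incomplete) && !allow_missing)
    stop("symptom flags missing on ", sum(incomplete),
         " day(s); use allow_missing = TRUE to propagate NA counts", call. = FALSE)
  nMajor <- rowSums(sm[, MAJOR_SYMPTOMS, drop = FALSE])
  nMinor <- rowSums(sm[, MINOR_SYMPTOMS, drop = FALSE])
  out <- data.frame(nMajor = nMajor, nMinor = nMinor, nAll = nMajor + nMinor)
  out[incomplete, ] <- NA
  out
}

#' Daily telemonitoring symptom score
#'
#' The weighted symptom score used by the telemonitoring service: major
#' symptoms score 2, minor symptoms score 1, giving a 0-11 range. Clinical
#' staff contacted patients when the score rose above 5.
#'
#' @inheritParams symptom_counts
#' @return integer vector of scores (NA where counts are undefined).
#' @export
telescot_score <- function(days, allow_missing = FALSE) {
  cts <- symptom_counts(days, allow_missing = allow_missing)
  as.integer(2L * cts$nMajor + cts$nMinor)
}

#' 'Bad day' predicate for the two-consecutive-bad-day definitions
#'
#' Definition 3 calls a day bad when `nMajor >= 2` or (`nMajor == 1` and
#' `nMinor >= 1`); definition 4 when `nMajor >= 1` and `nAll >= 3`.
#'
#' @param definition 3 or 4.
#' @param counts data.frame from [symptom_counts()].
#' @return logical vector (NA where counts are NA).
#' @export
bad_day <- function(definition, counts) {
  if (!definition %in% c(3, 4))
    stop("bad_day is defined only for definitions 3 and 4", call. = FALSE)
  if (definition == 3)
    counts$nMajor >= 2 | (counts$nMajor == 1 & counts$nMinor >= 1)
  else
    counts$nMajor >= 1 & counts$nAll >= 3
}

#' Which definitions are usable prospectively
#'
#' Definitions 1 and 2 use only day-`t` counts and can genuinely predict the
#' next day. Definitions 3-5 reference day `t+1` (and for 3-4 also `t-1`,
#' `t-2`), so evaluating them as next-day predictors gives an upper bound
#' that assumes early detection.
#'
#' @param definition integer 1-5.
#' @return logical.
#' @export
definition_is_practical <- function(definition) {
  stopifnot(all(definition %in% 1:5))
  definition %in% c(1, 2)
}

#' Detect exacerbation onsets by symptom-count definitions 1-5
#'
#' Applies one of the five count-based exacerbation definitions to a single
#' patient's consecutive-day series of symptom counts:
#' \describe{
#'   \item{1}{`nMajor >= 2` on day t (Anthonisen-type rule).}
#'   \item{2}{`nAll >= 5` on day t.}
#'   \item{3}{days t and t+1 are 'bad' but t-1 and t-2 are not, with bad =
#'     `nMajor >= 2` or (`nMajor == 1` and `nMinor >= 1`).}
#'   \item{4}{as 3, with bad = `nMajor >= 1` and `nAll >= 3`.}
#'   \item{5}{`nAll >= 5` on day t, or `nAll == 4` on day t and
#'     `nAll >= 4` on day t+1.}
#' }
#' Rules 3-5 are evaluated exactly as written, including their references to
#' day t+1: as next-day predictors they are upper bounds, not deployable
#' rules. Boundary days whose required context lies outside the series yield
#' no onset; days whose required context has missing counts yield `NA`
#' (three-valued logic: a known-false conjunct still forces `FALSE`).
#'
#' @param definition integer 1-5.
#' @param counts per-day [symptom_counts()] data.frame for one patient in day
#'   order (consecutive days).
#' @return logical onset vector, same length as the series.
#' @export
detect_onsets <- function(definition, counts) {
  stopifnot(length(definition) == 1L, definition %in% 1:5)
  n <- nrow(counts)
  if (n == 0L) return(logical(0))
  if (definition == 1) return(counts$nMajor >= 2)
  if (definition == 2) return(counts$nAll >= 5)
  if (definition == 5) {
    b1 <- counts$nAll >= 5
    next_ge4 <- c(counts$nAll[-1] >= 4, FALSE)  # last day: branch 2 unavailable
    b2 <- (counts$nAll == 4) & next_ge4
    return(b1 | b2)
  }
  bad <- bad_day(definition, counts)
  onset <- rep(FALSE, n)
  if (n >= 4L) {
    t <- 3:(n - 1)                        # 1-based positions with full context
    onset[t] <- bad[t] & bad[t + 1] & !bad[t - 1] & !bad[t - 2]
  }
  onset
}

#' Turn an onset series into a next-day prediction series
#'
#' The prediction for day t+1 is the onset flag on day t: element `i` of the
#' result is the onset flag at day `i - 1`. The first day has no prediction
#' (`NA`). The output is a 2-valued score usable directly in ROC analysis.
#'
#' @inheritParams detect_onsets
#' @return logical prediction vector aligned to the same day axis.
#' @export
definition_predictor <- function(definition, counts) {
  onsets <- detect_onsets(definition, counts)
  if (!length(onsets)) return(logical(0))
  c(NA, onsets[-length(onsets)])
}

#' Per-episode definition scores
#'
#' Computes, for each episode end-day t in an episode set, the onset flag of
#' the given definition at day t (the next-day prediction for the episode's
#' outcome at t+1). Counts are taken from the episode's own (possibly
#' imputed) day-t and neighbouring-day symptom values, so the complete and
#' imputed scenarios naturally score the same rule on different inputs.
#'
#' @param episodes an episode set from [build_episodes()].
#' @param definition integer 1-5.
#' @return numeric 0/1 score per episode (NA where context is missing).
#' @export
definition_scores <- function(episodes, definition) {
  stopifnot(inherits(episodes, "telecopd_episodes"))
  recs <- attr(episodes, "day_counts")
  if (is.null(recs))
    stop("episode set lacks day-level counts; rebuild with build_episodes()",
         call. = FALSE)
  key <- paste(episodes$meta$patient_id, episodes$meta$t)
  scores <- numeric(nrow(episodes$meta))
  for (pid in unique(episodes$meta$patient_id)) {
    cts <- recs[recs$patient_id == pid, , drop = FALSE]
    onsets <- detect_onsets(definition, cts)
    idx <- match(paste(pid, episodes$meta$t[episodes$meta$patient_id == pid]),
                 paste(pid, cts$day))
    scores[episodes$meta$patient_id == pid] <- as.numeric(onsets[idx])
  }
  scores
}
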