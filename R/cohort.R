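#' Configuration for a synthetic telemonitoring cohort
#'
#' Builds a validated configuration object for the cohort simulator. The
#' defaults describe a cohort resembling a year-long COPD telemonitoring
#' service for patients with moderate-to-severe disease and at least one
#' admission in the prior year: 135 patients followed for 363 days, daily
#' hospital-admission risk of order 10^-3 per patient-day and corticosteroid
#' onsets of order 10^-2.
#'
#' The generative model is a per-patient 3-state first-order Markov chain over
#' latent disease states (stable, prodrome, exacerbation). Symptoms are
#' emitted per state with fixed Bernoulli probabilities; pulse and SpO2 are a
#' patient-specific baseline plus a state-dependent shift plus Gaussian noise.
#' Admissions follow a per-day logistic hazard on latent severity, SpO2 drop
#' and pulse rise; corticosteroid and antibiotic courses start from a logistic
#' hazard on the day's total symptom count and then run for a fixed course
#' length. Daily weather (48-h mean/max temperature, three cold indicators, a
#' population alert level) follows a seasonal sinusoid and is by default
#' independent of the patients; `couple_weather = TRUE` adds a cold-driven
#' shift to the symptom emission logits, giving the population-level signal
#' used in the symptom-peak analysis.
#'
#' @param n_patients number of patients.
#' @param n_days days of follow-up per patient (day index 0-based).
#' @param seed integer root seed; all module streams derive from it.
#' @param transition named per-day transition probabilities
#'   `stable_to_prodrome`, `prodrome_to_exacerbation`, `exacerbation_to_stable`.
#' @param emission 3 x 8 matrix of symptom emission probabilities with rows
#'   `stable`, `prodrome`, `exacerbation` and columns the 8 symptoms (3 major:
#'   breathlessness, sputum colour, sputum amount; 5 minor: cold, wheeze,
#'   sore throat, cough, fever).
#' @param physiology list: population mean/SD of patient baselines and daily
#'   noise SD for pulse (bpm) and SpO2 (%), and per-state additive shifts.
#' @param admission list of logistic hazard coefficients: `intercept`,
#'   `severity` (0/1/2 for stable/prodrome/exacerbation), `spo2_drop` (per %
#'   below the patient's baseline), `pulse_rise` (per bpm above baseline).
#' @param corticosteroid,antibiotic lists: onset hazard `intercept` and
#'   `symptom_count` coefficient (per present symptom), and `course_length`
#'   days of continued use after an onset.
#' @param missingness list: `base_rate` daily probability that a patient
#'   submits nothing; `dispersion` SD of the patient-level logit random
#'   effect; `pre_admission_multiplier` applied to the daily rate on the
#'   `pre_admission_window` days before each admission; `field_rate` small
#'   independent per-field dropout.
#' @param weather list: seasonal curve `temp_mean`, `temp_amplitude`,
#'   `temp_noise_sd`, `peak_day`; `couple_weather` flag and
#'   `coupling_strength` (logit shift per degree C below 5 added to symptom
#'   emissions when coupled).
#' @param baseline list of moments for the static covariates
#'   (age, BMI, FEV1 percent predicted, MRC grade, anxiety/depression,
#'   respiratory quality of life, prior admissions, sex/smoking rates) and a
#'   `missing_rate` applied to each covariate.
#' @param reset_after_admission logical; an admission resets the latent state
#'   to stable on the next day.
#' @return an object of class `telecopd_cohort_config`.
#' @export
cohort_config <- function(n_patients = 135,
                          n_days = 363,
                          seed = 1L,
                          transition = c(stable_to_prodrome = 0.015,
                                         prodrome_to_exacerbation = 0.20,
                                         exacerbation_to_stable = 0.12),
                          emission = default_emission(),
                          physiology = list(
                            pulse_mean = 80, pulse_sd = 8, pulse_noise_sd = 5,
                            pulse_shift = c(stable = 0, prodrome = 4, exacerbation = 10),
                            spo2_mean = 93, spo2_sd = 2, spo2_noise_sd = 1.2,
                            spo2_shift = c(stable = 0, prodrome = -1.5, exacerbation = -4)),
                          admission = list(intercept = -8.6, severity = 1.6,
                                           spo2_drop = 0.15, pulse_rise = 0.02),
                          corticosteroid = list(intercept = -5.5, symptom_count = 0.45,
                                                course_length = 7L),
                          antibiotic = list(intercept = -4.8, symptom_count = 0.40,
                                            course_length = 7L),
                          missingness = list(base_rate = 0.30, dispersion = 0.7,
                                             pre_admission_multiplier = 3,
                                             pre_admission_window = 3L,
                                             field_rate = 0.02),
                          weather = list(temp_mean = 9, temp_amplitude = 7,
                                         temp_noise_sd = 2.5, peak_day = 200,
                                         couple_weather = FALSE,
                                         coupling_strength = 0.25),
                          baseline = list(age_mean = 70, age_sd = 8,
                                          bmi_mean = 27, bmi_sd = 5,
                                          fev1pp_mean = 45, fev1pp_sd = 12,
                                          anxiety_mean = 8, anxiety_sd = 4,
                                          depression_mean = 7, depression_sd = 4,
                                          qol_mean = 60, qol_sd = 15,
                                          prior_admissions_rate = 1.2,
                                          male_rate = 0.55, smoking_rate = 0.3,
                                          missing_rate = 0.05),
                          reset_after_admission = TRUE) {
  cfg <- list(n_patients = n_patients, n_days = n_days, seed = seed,
              transition = transition, emission = emission,
              physiology = physiology, admission = admission,
              corticosteroid = corticosteroid, antibiotic = antibiotic,
              missingness = missingness, weather = weather,
              baseline = baseline,
              reset_after_admission = isTRUE(reset_after_admission))
  class(cfg) <- "telecopd_cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Default per-state symptom emission probabilities
#'
#' @return a 3 x 8 matrix (states x symptoms).
#' @export
default_emission <- function() {
  m <- rbind(
    stable       = c(0.15, 0.05, 0.08, 0.05, 0.15, 0.04, 0.20, 0.02),
    prodrome     = c(0.40, 0.20, 0.30, 0.15, 0.35, 0.10, 0.45, 0.08),
    exacerbation = c(0.80, 0.60, 0.70, 0.30, 0.60, 0.20, 0.80, 0.25))
  colnames(m) <- SYMPTOM_VARS
  m
}

#' @export
validate_cohort_config <- function(cfg) {
  e <- character()
  e <- check_that(e, is_count(cfg$n_patients), "n_patients must be a non-negative integer")
  e <- check_that(e, is_count(cfg$n_days), "n_days must be a non-negative integer")
  e <- check_that(e, is.numeric(cfg$seed) && length(cfg$seed) == 1L, "seed must be a scalar")
  e <- check_that(e, is_prob(cfg$transition) && length(cfg$transition) == 3L,
                  "transition probabilities must be 3 values in [0,1]")
  e <- check_that(e, is.matrix(cfg$emission) && all(dim(cfg$emission) == c(3L, 8L)) &&
                    is_prob(cfg$emission),
                  "emission must be a 3x8 matrix of probabilities in [0,1]")
  e <- check_that(e, is_prob(cfg$missingness$base_rate),
                  "missingness base_rate must be in [0,1]")
  e <- check_that(e, is.numeric(cfg$missingness$pre_admission_multiplier) &&
                    cfg$missingness$pre_admission_multiplier >= 0,
                  "pre_admission_multiplier must be >= 0")
  e <- check_that(e, is_prob(cfg$missingness$field_rate),
                  "missingness field_rate must be in [0,1]")
  e <- check_that(e, cfg$missingness$dispersion >= 0, "dispersion must be >= 0")
  stop_if_errors(e, "invalid cohort configuration")
}

#' Generate static baseline covariates for a cohort
#'
#' One row per patient: demographics, spirometry, symptom-burden scales and
#' admission history, with missing values injected completely at random at
#' the configured rate. Deterministic given the config seed.
#'
#' @param config a [cohort_config()].
#' @return a data.frame of one `BaselineRecord` per patient.
#' @export
generate_baseline <- function(config) {
  validate_cohort_config(config)
  n <- config$n_patients
  b <- config$baseline
  if (n == 0L) {
    out <- data.frame(patient_id = character(), age = numeric(), sex = character(),
                      bmi = numeric(), fev1pp = numeric(), mrc = numeric(),
                      anxiety = numeric(), depression = numeric(), qol = numeric(),
                      prior_admissions = numeric(), smoker = character(),
                      stringsAsFactors = FALSE)
    return(out)
  }
  with_seed(child_seed(config$seed, "baseline"), {
    out <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      age = round(clamp(stats::rnorm(n, b$age_mean, b$age_sd), 40, 95)),
      sex = ifelse(stats::runif(n) < b$male_rate, "male", "female"),
      bmi = round(clamp(stats::rnorm(n, b$bmi_mean, b$bmi_sd), 14, 50), 1),
      fev1pp = round(clamp(stats::rnorm(n, b$fev1pp_mean, b$fev1pp_sd), 15, 69), 1),
      mrc = sample(1:5, n, replace = TRUE, prob = c(0.05, 0.15, 0.30, 0.35, 0.15)),
      anxiety = round(clamp(stats::rnorm(n, b$anxiety_mean, b$anxiety_sd), 0, 21)),
      depression = round(clamp(stats::rnorm(n, b$depression_mean, b$depression_sd), 0, 21)),
      qol = round(clamp(stats::rnorm(n, b$qol_mean, b$qol_sd), 0, 100), 1),
      prior_admissions = 1 + stats::rpois(n, b$prior_admissions_rate),
      smoker = ifelse(stats::runif(n) < b$smoking_rate, "yes", "no"),
      stringsAsFactors = FALSE)
    # MCAR missingness on every covariate except the identifier
    for (col in setdiff(names(out), "patient_id")) {
      miss <- stats::runif(n) < b$missing_rate
      out[[col]][miss] <- NA
    }
    out
  })
}

# Simulate the shared daily weather series for the cohort.
simulate_weather <- function(config) {
  w <- config$weather
  nd <- config$n_days
  if (nd == 0L) {
    return(data.frame(day = integer(), mean_temp = numeric(), max_temp = numeric(),
                      temp_mean_lt2 = integer(), temp_max_lt4 = integer(),
                      temp_max_lt7 = integer(), alert_level = integer()))
  }
  with_seed(child_seed(config$seed, "weather"), {
    day <- seq_len(nd) - 1L
    seasonal <- w$temp_mean + w$temp_amplitude * cos(2 * pi * (day - w$peak_day) / 365.25)
    # AR(1) weather noise gives multi-day cold snaps rather than white noise
    eps <- stats::rnorm(nd, 0, w$temp_noise_sd)
    noise <- as.numeric(stats::filter(eps, 0.7, method = "recursive"))
    mean_temp <- seasonal + noise
    max_temp <- mean_temp + 2.5 + abs(stats::rnorm(nd, 0, 1.5))
    cold_index <- pmax(0, 7 - max_temp) + pmax(0, 2 - mean_temp)
    alert_level <- pmin(3L, as.integer(round(cold_index / 3 + stats::rnorm(nd, 0, 0.3))))
    alert_level <- pmax(0L, alert_level)
    data.frame(day = day,
               mean_temp = round(mean_temp, 1),
               max_temp = round(max_temp, 1),
               temp_mean_lt2 = as.integer(mean_temp < 2),
               temp_max_lt4 = as.integer(max_temp < 4),
               temp_max_lt7 = as.integer(max_temp < 7),
               alert_level = alert_level)
  })
}

#' Simulate daily telemonitoring records with ground truth
#'
#' Runs the latent Markov chain for every patient and emits one `DailyRecord`
#' per patient-day (symptoms, pulse, SpO2, medication flags, admission flag,
#' weather covariates) together with a `LatentTruth` table holding the latent
#' state and the exact generative admission and corticosteroid-onset
#' probabilities for every patient-day. No missingness is applied here; see
#' [apply_missingness()].
#'
#' @param config a [cohort_config()].
#' @param baseline baseline table from [generate_baseline()]; must cover all
#'   patient ids (it seeds the patient-specific physiology baselines).
#' @return list with elements `records` and `truth` (both data.frames).
#' @export
generate_daily <- function(config, baseline = generate_baseline(config)) {
  validate_cohort_config(config)
  n <- config$n_patients
  nd <- config$n_days
  if (n > 0L && nrow(baseline) < n)
    stop("baseline must cover all patients", call. = FALSE)

  weather <- simulate_weather(config)
  ph <- config$physiology
  tr <- config$transition
  adm <- config$admission
  em_logit <- stats::qlogis(clamp(config$emission, 1e-12, 1 - 1e-12))

  # day-specific emission logit shift when weather is coupled to symptoms
  shift_t <- if (isTRUE(config$weather$couple_weather) && nd > 0L)
    config$weather$coupling_strength * pmax(0, 5 - weather$mean_temp)
  else rep(0, max(nd, 1L))

  rec_list <- vector("list", n)
  truth_list <- vector("list", n)

  seed0 <- child_seed(config$seed, "daily")
  for (i in seq_len(n)) {
    pid <- baseline$patient_id[i]
    res <- with_seed(child_seed(seed0, paste0("patient:", i)),
                     simulate_patient_days(config, pid, nd, em_logit, shift_t, ph, tr, adm))
    rec_list[[i]] <- res$records
    truth_list[[i]] <- res$truth
  }
  records <- if (n > 0L) do.call(rbind, rec_list) else empty_records()
  truth <- if (n > 0L) do.call(rbind, truth_list) else
    data.frame(patient_id = character(), day = integer(), state = character(),
               admission_probability = numeric(), corticosteroid_probability = numeric())
  if (nrow(records)) {
    records <- merge(records, weather, by = "day", sort = FALSE)
    records <- records[order(records$patient_id, records$day),
                       c("patient_id", "day", SYMPTOM_VARS, PHYSIOLOGY_VARS,
                         MEDICATION_VARS, "admission", WEATHER_VARS)]
    rownames(records) <- NULL
  } else {
    records <- empty_records()
  }
  rownames(truth) <- NULL
  list(records = records, truth = truth)
}

empty_records <- function() {
  cols <- c("patient_id", "day", SYMPTOM_VARS, PHYSIOLOGY_VARS, MEDICATION_VARS,
            "admission", WEATHER_VARS)
  out <- as.data.frame(stats::setNames(rep(list(numeric(0)), length(cols)), cols))
  out$patient_id <- character(0)
  out
}

# One patient's day-by-day simulation (state machine; RNG already seeded).
simulate_patient_days <- function(config, pid, nd, em_logit, shift_t, ph, tr, adm) {
  if (nd == 0L) {
    return(list(records = NULL, truth = NULL))
  }
  pulse_base <- stats::rnorm(1, ph$pulse_mean, ph$pulse_sd)
  spo2_base <- stats::rnorm(1, ph$spo2_mean, ph$spo2_sd)
  states <- c("stable", "prodrome", "exacerbation")

  state <- 1L
  cort_left <- 0L
  abx_left <- 0L
  symp <- matrix(0L, nd, 8L, dimnames = list(NULL, SYMPTOM_VARS))
  pulse <- numeric(nd); spo2 <- numeric(nd)
  abx <- integer(nd); cort <- integer(nd); admission <- integer(nd)
  st_out <- integer(nd); p_adm <- numeric(nd); p_cort <- numeric(nd)

  for (t in seq_len(nd)) {
    if (t > 1L) {
      if (admission[t - 1L] == 1L && config$reset_after_admission) {
        state <- 1L
      } else {
        u <- stats::runif(1)
        state <- switch(state,
          `1` = if (u < tr[["stable_to_prodrome"]]) 2L else 1L,
          `2` = if (u < tr[["prodrome_to_exacerbation"]]) 3L else 2L,
          `3` = if (u < tr[["exacerbation_to_stable"]]) 1L else 3L)
      }
    }
    st_out[t] <- state
    p_sym <- stats::plogis(em_logit[state, ] + shift_t[t])
    symp[t, ] <- as.integer(stats::runif(8) < p_sym)
    pulse[t] <- clamp(pulse_base + ph$pulse_shift[state] + stats::rnorm(1, 0, ph$pulse_noise_sd),
                      30, 220)
    spo2[t] <- clamp(spo2_base + ph$spo2_shift[state] + stats::rnorm(1, 0, ph$spo2_noise_sd),
                     50, 100)

    sev <- state - 1L
    lp <- adm$intercept + adm$severity * sev +
      adm$spo2_drop * max(0, spo2_base - spo2[t]) +
      adm$pulse_rise * max(0, pulse[t] - pulse_base)
    p_adm[t] <- stats::plogis(lp)
    admission[t] <- as.integer(stats::runif(1) < p_adm[t])

    n_all <- sum(symp[t, ])
    # corticosteroid: onset hazard only when not already on a course
    if (cort_left > 0L) {
      cort[t] <- 1L
      cort_left <- cort_left - 1L
      p_cort[t] <- 0
    } else {
      p_cort[t] <- stats::plogis(config$corticosteroid$intercept +
                                   config$corticosteroid$symptom_count * n_all)
      if (stats::runif(1) < p_cort[t]) {
        cort[t] <- 1L
        cort_left <- config$corticosteroid$course_length - 1L
      }
    }
    if (abx_left > 0L) {
      abx[t] <- 1L
      abx_left <- abx_left - 1L
    } else {
      p_abx <- stats::plogis(config$antibiotic$intercept +
                               config$antibiotic$symptom_count * n_all)
      if (stats::runif(1) < p_abx) {
        abx[t] <- 1L
        abx_left <- config$antibiotic$course_length - 1L
      }
    }
  }
  records <- data.frame(patient_id = pid, day = seq_len(nd) - 1L,
                        as.data.frame(symp),
                        pulse = round(pulse, 1), spo2 = round(spo2, 1),
                        antibiotic = abx, corticosteroid = cort,
                        admission = admission, stringsAsFactors = FALSE)
  truth <- data.frame(patient_id = pid, day = seq_len(nd) - 1L,
                      state = states[st_out],
                      admission_probability = p_adm,
                      corticosteroid_probability = p_cort,
                      stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

#' Mask telemonitoring fields to emulate non-reporting
#'
#' Applies the missingness model to a fully observed record table: each
#' patient-day is unsubmitted with probability `plogis(qlogis(base_rate) +
#' patient_effect)`, multiplied by `pre_admission_multiplier` (capped at 1) on
#' the `pre_admission_window` days before each admission, masking all
#' patient-reported fields for that day. Each field is additionally dropped
#' independently with probability `field_rate`. Admission outcome flags and
#' weather covariates are never masked.
#'
#' @param records record table from [generate_daily()].
#' @param config a [cohort_config()].
#' @return the records with masked entries set to `NA`.
#' @export
apply_missingness <- function(records, config) {
  validate_cohort_config(config)
  m <- config$missingness
  if (m$pre_admission_multiplier < 0)
    stop("invalid cohort configuration:\n  - pre_admission_multiplier must be >= 0",
         call. = FALSE)
  if (!nrow(records)) return(records)
  records <- records[order(records$patient_id, records$day), ]
  rownames(records) <- NULL
  with_seed(child_seed(config$seed, "missingness"), {
    pts <- unique(records$patient_id)
    eff <- stats::rnorm(length(pts), 0, m$dispersion)
    names(eff) <- pts
    p_day <- stats::plogis(stats::qlogis(clamp(m$base_rate, 1e-12, 1 - 1e-12)) +
                             eff[records$patient_id])
    if (m$base_rate == 0) p_day[] <- 0
    if (m$base_rate == 1) p_day[] <- 1
    # elevate the rate on the days immediately before each admission
    pre <- rep(FALSE, nrow(records))
    w <- m$pre_admission_window
    if (w > 0) {
      adm_idx <- which(records$admission == 1)
      for (a in adm_idx) {
        j <- a - seq_len(w)
        j <- j[j >= 1 & records$patient_id[j] == records$patient_id[a]]
        pre[j] <- TRUE
      }
    }
    p_day[pre] <- pmin(1, p_day[pre] * m$pre_admission_multiplier)
    day_mask <- stats::runif(nrow(records)) < p_day
    for (v in MASKABLE_VARS) {
      field_mask <- if (m$field_rate > 0)
        stats::runif(nrow(records)) < m$field_rate else FALSE
      records[[v]][day_mask | field_mask] <- NA
    }
    records
  })
}

#' Ground-truth event probabilities (Bayes-optimal risk scores)
#'
#' Returns the exact generative per-day event probability from the latent
#' truth table. Used as the oracle score against which fitted models are
#' benchmarked: no classifier can systematically beat it on data simulated
#' from the same process.
#'
#' @param truth truth table from [generate_daily()].
#' @param outcome `"admission"` or `"corticosteroid"`.
#' @return data.frame `patient_id`, `day`, `score`.
#' @export
oracle_scores <- function(truth, outcome = c("admission", "corticosteroid")) {
  outcome <- match.arg(outcome)
  col <- switch(outcome, admission = "admission_probability",
                corticosteroid = "corticosteroid_probability")
  data.frame(patient_id = truth$patient_id, day = truth$day,
             score = truth[[col]], stringsAsFactors = FALSE)
}

#' Simulate a complete cohort (baseline + daily records + missingness)
#'
#' Convenience wrapper chaining [generate_baseline()], [generate_daily()] and
#' [apply_missingness()].
#'
#' @param config a [cohort_config()].
#' @param mask apply the missingness model (default TRUE).
#' @return list with `baseline`, `records` (masked), `records_full`
#'   (pre-masking) and `truth`.
#' @export
simulate_cohort <- function(config, mask = TRUE) {
  baseline <- generate_baseline(config)
  sim <- generate_daily(config, baseline)
  records <- if (mask) apply_missingness(sim$records, config) else sim$records
  list(baseline = baseline, records = records, records_full = sim$records,
       truth = sim$truth)
}
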