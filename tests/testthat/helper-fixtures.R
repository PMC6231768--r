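# Shared fixture builders: everything is generated in code at test time.

# A daily-record table built by hand: `symptoms` is a list of per-day 8-vectors
# (or a single vector recycled), vitals and medication flags default to benign
# constants. One patient.
manual_records <- function(symptoms, patient_id = "P001",
                           pulse = 80, spo2 = 95,
                           antibiotic = 0, corticosteroid = 0,
                           admission = 0) {
  if (!is.list(symptoms)) symptoms <- list(symptoms)
  n <- length(symptoms)
  sm <- do.call(rbind, symptoms)
  colnames(sm) <- telecopd:::SYMPTOM_VARS
  data.frame(patient_id = patient_id, day = seq_len(n) - 1L,
             as.data.frame(sm),
             pulse = rep_len(pulse, n), spo2 = rep_len(spo2, n),
             antibiotic = rep_len(antibiotic, n),
             corticosteroid = rep_len(corticosteroid, n),
             admission = rep_len(admission, n),
             stringsAsFactors = FALSE)
}

# Counts data.frame straight from (nMajor, nMinor) pairs.
counts_df <- function(nMajor, nMinor) {
  data.frame(nMajor = nMajor, nMinor = nMinor, nAll = nMajor + nMinor)
}

# Small cohort config for fast simulation tests.
tiny_config <- function(n_patients = 12, n_days = 60, seed = 1, ...) {
  cohort_config(n_patients = n_patients, n_days = n_days, seed = seed, ...)
}

# Independent literal transcription of the two-consecutive-bad-day rules,
# written as an explicit loop so it shares nothing with detect_onsets().
oracle_onsets_two_bad_days <- function(bad) {
  n <- length(bad)
  onset <- rep(FALSE, n)
  for (t in seq_len(n)) {
    if (t < 3 || t > n - 1) next    # context t-2, t-1, t+1 must exist
    onset[t] <- isTRUE(bad[t] && bad[t + 1] && !bad[t - 1] && !bad[t - 2])
  }
  onset
}

# Literal transcription of definition 5 over an nAll series.
oracle_onsets_def5 <- function(nAll) {
  n <- length(nAll)
  onset <- rep(FALSE, n)
  for (t in seq_len(n)) {
    b1 <- isTRUE(nAll[t] >= 5)
    b2 <- t < n && isTRUE(nAll[t] == 4) && isTRUE(nAll[t + 1] >= 4)
    onset[t] <- b1 || b2
  }
  onset
}

# Brute-force AUC over all positive-negative pairs (ties count half).
brute_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# Brute-force concordant/discordant rank correlations for short vectors.
brute_kendall <- function(x, y) {
  n <- length(x); num <- 0; dx <- 0; dy <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sx <- sign(x[j] - x[i]); sy <- sign(y[j] - y[i])
    num <- num + sx * sy
    dx <- dx + (sx != 0); dy <- dy + (sy != 0)
  }
  num / sqrt(dx * dy)
}

brute_spearman <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# Match an oracle score to each episode's outcome day (t + 1).
oracle_for_episodes <- function(episodes, truth, outcome) {
  osc <- oracle_scores(truth, outcome)
  idx <- match(paste(episodes$meta$patient_id, episodes$meta$t + 1L),
               paste(osc$patient_id, osc$day))
  osc$score[idx]
}
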