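test_that("cohort generation is deterministic and respects sizes", {
  cfg <- tiny_config(n_patients = 5, n_days = 20, seed = 42)
  b1 <- generate_baseline(cfg)
  b2 <- generate_baseline(cfg)
  expect_identical(b1, b2)
  expect_equal(nrow(b1), 5)

  s1 <- simulate_cohort(cfg)
  s2 <- simulate_cohort(cfg)
  expect_identical(s1, s2)
  expect_equal(nrow(s1$records_full), 5 * 20)
  expect_equal(nrow(s1$truth), 5 * 20)

  # a different seed changes the draw
  s3 <- simulate_cohort(tiny_config(n_patients = 5, n_days = 20, seed = 43))
  expect_false(identical(s1$records, s3$records))

  empty <- generate_baseline(tiny_config(n_patients = 0))
  expect_equal(nrow(empty), 0)
})

test_that("invalid configurations are rejected with aggregated messages", {
  expect_error(cohort_config(n_patients = -3), "n_patients")
  expect_error(cohort_config(transition = c(stable_to_prodrome = 1.2,
                                            prodrome_to_exacerbation = 0.1,
                                            exacerbation_to_stable = 0.1)),
               "transition")
  em <- default_emission(); em[1, 1] <- 2
  expect_error(cohort_config(emission = em), "emission")
  cfg <- tiny_config()
  cfg$missingness$pre_admission_multiplier <- -1
  expect_error(apply_missingness(empty_records_for_test(), cfg), "multiplier")
})

empty_records_for_test <- function() {
  sim <- generate_daily(tiny_config(n_patients = 1, n_days = 2))
  sim$records
}

test_that("baseline moments match the configured distribution", {
  cfg <- cohort_config(n_patients = 2000, n_days = 0, seed = 5,
                       baseline = utils::modifyList(
                         eval(formals(cohort_config)$baseline),
                         list(missing_rate = 0)))
  b <- generate_baseline(cfg)
  se <- cfg$baseline$fev1pp_sd / sqrt(2000)
  # truncation to the enrolment range shifts the mean slightly; 3 SE of the
  # configured spread still brackets it
  expect_lt(abs(mean(b$fev1pp) - cfg$baseline$fev1pp_mean), 3 * se + 0.6)
  expect_lt(abs(mean(b$age) - cfg$baseline$age_mean), 3 * cfg$baseline$age_sd / sqrt(2000) + 0.2)
})

test_that("degenerate emission and row-count contracts hold", {
  em0 <- default_emission(); em0[] <- 0
  cfg <- tiny_config(n_patients = 2, n_days = 10, emission = em0)
  sim <- generate_daily(cfg)
  expect_equal(nrow(sim$records), 20)
  expect_true(all(as.matrix(sim$records[, telecopd:::SYMPTOM_VARS]) == 0))
})

test_that("intercept-only admission hazard matches its analytic rate", {
  p <- stats::plogis(-4)
  n_tot <- 0L; n_adm <- 0L
  for (s in 1:50) {
    cfg <- tiny_config(n_patients = 20, n_days = 50, seed = 1000 + s,
                       admission = list(intercept = -4, severity = 0,
                                        spo2_drop = 0, pulse_rise = 0))
    sim <- generate_daily(cfg)
    n_tot <- n_tot + nrow(sim$records)
    n_adm <- n_adm + sum(sim$records$admission)
  }
  half <- 2.576 * sqrt(n_tot * p * (1 - p))
  expect_lt(abs(n_adm - n_tot * p), half)
  # and the recorded generative probability agrees exactly
  expect_equal(unique(sim$truth$admission_probability), p)
})

test_that("latent transition frequencies calibrate to the configuration", {
  cfg <- cohort_config(n_patients = 60, n_days = 250, seed = 8,
                       admission = list(intercept = -30, severity = 0,
                                        spo2_drop = 0, pulse_rise = 0))
  truth <- generate_daily(cfg)$truth
  truth <- truth[order(truth$patient_id, truth$day), ]
  prev <- truth$state[-nrow(truth)]
  nxt <- truth$state[-1]
  same_pt <- truth$patient_id[-nrow(truth)] == truth$patient_id[-1]
  for (pair in list(c("stable", "prodrome", "stable_to_prodrome"),
                    c("prodrome", "exacerbation", "prodrome_to_exacerbation"),
                    c("exacerbation", "stable", "exacerbation_to_stable"))) {
    at_risk <- same_pt & prev == pair[1]
    phat <- mean(nxt[at_risk] == pair[2])
    p0 <- cfg$transition[[pair[3]]]
    se <- sqrt(p0 * (1 - p0) / sum(at_risk))
    expect_lt(abs(phat - p0), 3 * se)
  }
})

test_that("missingness masking honours its configured rates", {
  cfg <- tiny_config(n_patients = 4, n_days = 30, seed = 2)
  sim <- generate_daily(cfg)

  # base rate 0, multiplier 1: identity
  cfg0 <- cfg; cfg0$missingness$base_rate <- 0
  cfg0$missingness$field_rate <- 0
  cfg0$missingness$pre_admission_multiplier <- 1
  expect_identical(apply_missingness(sim$records, cfg0),
                   sim$records[order(sim$records$patient_id, sim$records$day), ])

  # base rate 1: everything maskable missing, outcomes untouched
  cfg1 <- cfg; cfg1$missingness$base_rate <- 1
  masked <- apply_missingness(sim$records, cfg1)
  expect_true(all(is.na(as.matrix(masked[, telecopd:::MASKABLE_VARS]))))
  expect_false(anyNA(masked$admission))

  # Monte-Carlo rate: base 0.3 with no dispersion/field dropout, away from
  # admissions
  cfg3 <- cohort_config(n_patients = 300, n_days = 340, seed = 3,
                        missingness = list(base_rate = 0.3, dispersion = 0,
                                           pre_admission_multiplier = 1,
                                           pre_admission_window = 0L,
                                           field_rate = 0),
                        admission = list(intercept = -30, severity = 0,
                                         spo2_drop = 0, pulse_rise = 0))
  simbig <- generate_daily(cfg3)
  m <- apply_missingness(simbig$records, cfg3)
  frac <- mean(is.na(as.matrix(m[, telecopd:::MASKABLE_VARS])))
  expect_gte(frac, 0.29); expect_lte(frac, 0.31)
})

test_that("pre-admission days are masked more often", {
  cfg <- cohort_config(n_patients = 80, n_days = 200, seed = 4)
  sim <- generate_daily(cfg)
  masked <- apply_missingness(sim$records, cfg)
  masked <- masked[order(masked$patient_id, masked$day), ]
  pre <- rep(FALSE, nrow(masked))
  for (a in which(masked$admission == 1)) {
    j <- a - 1:3
    j <- j[j >= 1 & masked$patient_id[j] == masked$patient_id[a]]
    pre[j] <- TRUE
  }
  skip_if(sum(pre) < 30)  # needs enough admissions to compare rates
  miss_day <- is.na(masked$breathlessness)
  expect_gt(mean(miss_day[pre]), mean(miss_day[!pre]) + 0.2)
})

test_that("oracle scores are the generative probabilities and discriminate", {
  # constant hazard: all scores equal, AUC undefined signal ~ 0.5 by ties
  cfg <- tiny_config(n_patients = 30, n_days = 80, seed = 6,
                     admission = list(intercept = -5, severity = 0,
                                      spo2_drop = 0, pulse_rise = 0))
  sim <- generate_daily(cfg)
  osc <- oracle_scores(sim$truth, "admission")
  expect_equal(length(unique(osc$score)), 1L)
  lab <- sim$records$admission
  skip_if(sum(lab) == 0)
  expect_equal(auc(osc$score, lab), 0.5)

  # severity-dependent hazard: oracle clearly above chance
  cfg2 <- cohort_config(n_patients = 80, n_days = 200, seed = 7)
  sim2 <- generate_daily(cfg2)
  osc2 <- oracle_scores(sim2$truth, "admission")
  a <- auc(osc2$score, sim2$records$admission)
  ci <- auc_ci(osc2$score, sim2$records$admission, "delong")
  expect_gt(a, 0.5)
  expect_gt(ci[1], 0.5)
  expect_error(oracle_scores(sim2$truth, "relapse"))
})

test_that("default configuration yields realistic event rates", {
  sim <- simulate_cohort(cohort_config(seed = 123))
  rf <- sim$records_full
  adm_rate <- mean(rf$admission)
  expect_gt(adm_rate, 1e-4); expect_lt(adm_rate, 1e-2)   # order 10^-3
  onsets <- sum(unlist(tapply(rf$corticosteroid, rf$patient_id,
                              function(x) sum(diff(x) == 1) + (x[1] == 1))))
  onset_rate <- onsets / nrow(rf)
  expect_gt(onset_rate, 1e-3); expect_lt(onset_rate, 1e-1) # order 10^-2
  expect_true(all(rf$spo2 >= 50 & rf$spo2 <= 100))
  expect_true(all(rf$pulse >= 30 & rf$pulse <= 220))
})
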