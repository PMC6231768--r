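test_that("sparse-patient exclusion is strict at the threshold", {
  base <- manual_records(rep(0, 8))
  make_patient <- function(id, missing_frac) {
    r <- manual_records(replicate(20, rep(0, 8), simplify = FALSE), patient_id = id)
    nm <- length(telecopd:::MASKABLE_VARS)
    cells <- expand.grid(row = seq_len(20), var = telecopd:::MASKABLE_VARS,
                         stringsAsFactors = FALSE)
    k <- round(missing_frac * nrow(cells))
    if (k > 0) for (i in seq_len(k))
      r[cells$row[i], cells$var[i]] <- NA
    r
  }
  recs <- rbind(make_patient("A", 1), make_patient("B", 0.5),
                make_patient("C", 0.95))
  kept <- exclude_sparse_patients(recs, 0.95)
  expect_setequal(unique(kept$patient_id), c("B", "C"))  # exactly 95% retained
})

test_that("forward fill copies the last observation for up to the horizon", {
  got <- forward_fill(c(5, NA, NA, 7))
  expect_equal(got$values, c(5, 5, 5, 7))
  expect_equal(got$flags, c(0, 1, 1, 0))

  # 16 missing days after one observation: only the first 15 are filled
  x <- c(3, rep(NA, 16))
  got <- forward_fill(x, horizon = 15)
  expect_equal(got$values, c(3, rep(3, 15), NA))
  expect_equal(got$flags, c(0, rep(1, 15), 0))

  # leading missingness has no donor
  got <- forward_fill(c(NA, NA, 4))
  expect_equal(got$values, c(NA, NA, 4))
  expect_equal(got$flags, c(0, 0, 0))

  expect_equal(forward_fill(numeric(0))$values, numeric(0))
  # horizon 0 fills nothing
  expect_equal(forward_fill(c(1, NA), horizon = 0)$values, c(1, NA))
})

two_patient_records <- function() {
  rbind(manual_records(replicate(10, rep(0, 8), simplify = FALSE), "A"),
        manual_records(replicate(10, rep(0, 8), simplify = FALSE), "B"))
}

test_that("episode enumeration matches direct counting of valid end-days", {
  recs <- two_patient_records()
  ep <- build_episodes(recs, episode_config(window = 3, scenario = "complete"))
  # per patient: t in 2..8 (0-based; needs 3-day history and a next day) = 7
  expect_equal(nrow(ep$meta), 14)
  expect_equal(sort(unique(ep$meta$t)), 2:8)
  expect_equal(colnames(ep$values)[1:3],
               c("breathlessness_d0", "breathlessness_d1", "breathlessness_d2"))
  # window larger than any record: empty with a warning
  expect_warning(
    empty <- build_episodes(recs, episode_config(window = 11, scenario = "complete")),
    "exceeds")
  expect_equal(nrow(empty$meta), 0)
})

test_that("complete scenario drops windows with missing symptoms; imputed fills them", {
  recs <- two_patient_records()
  recs$sputum_colour[recs$patient_id == "A" & recs$day == 4] <- NA
  epc <- build_episodes(recs, episode_config(window = 3, scenario = "complete"))
  # day 4 sits in windows ending at t = 4, 5, 6 for patient A
  a_t <- epc$meta$t[epc$meta$patient_id == "A"]
  expect_setequal(a_t, c(2, 3, 7, 8))
  expect_equal(sum(epc$meta$patient_id == "B"), 7)

  epi <- build_episodes(recs, episode_config(window = 3, scenario = "imputed"))
  expect_equal(sum(epi$meta$patient_id == "A"), 7)
  filled <- epi$values[epi$meta$patient_id == "A" & epi$meta$t == 4, "sputum_colour_d0"]
  expect_equal(unname(filled), 0)   # copied from day 3
  flag <- epi$flags[epi$meta$patient_id == "A" & epi$meta$t == 4, "sputum_colour_d0_imputed"]
  expect_equal(unname(flag), 1)
})

test_that("imputation flags are sound and scenarios nest", {
  cfg <- tiny_config(n_patients = 8, n_days = 40, seed = 9)
  sim <- simulate_cohort(cfg)
  recs <- sim$records
  epi <- build_episodes(recs, episode_config(window = 5, scenario = "imputed"))
  epc <- build_episodes(recs, episode_config(window = 5, scenario = "complete"))

  # flag soundness: spot-check that flagged day-t entries were missing in the
  # raw records and unflagged ones were observed
  for (i in seq_len(min(nrow(epi$meta), 200))) {
    raw <- recs[recs$patient_id == epi$meta$patient_id[i] &
                  recs$day == epi$meta$t[i], ]
    for (v in c("breathlessness", "pulse")) {
      flagged <- unname(epi$flags[i, paste0(v, "_d0_imputed")] == 1)
      expect_equal(flagged, is.na(raw[[v]]))
    }
  }

  # every complete episode reappears in the imputed set with clean symptom flags
  key_c <- paste(epc$meta$patient_id, epc$meta$t)
  key_i <- paste(epi$meta$patient_id, epi$meta$t)
  expect_true(all(key_c %in% key_i))
  sym_flag_cols <- paste0(rep(telecopd:::SYMPTOM_VARS, each = 5), "_d", 0:4, "_imputed")
  matched <- epi$flags[match(key_c, key_i), sym_flag_cols, drop = FALSE]
  expect_true(all(matched == 0))

  # count direction: imputed sets are at least as large, events included
  expect_gte(nrow(epi$meta), nrow(epc$meta))
  expect_gte(sum(epi$meta$label), sum(epc$meta$label))
})

test_that("episodes never use information after their end day", {
  cfg <- tiny_config(n_patients = 4, n_days = 30, seed = 10)
  sim <- simulate_cohort(cfg)
  recs <- sim$records
  ec <- episode_config(window = 5, scenario = "imputed")
  full <- build_episodes(recs, ec)
  t_star <- 15L
  pick <- which(full$meta$t == t_star)
  expect_gt(length(pick), 0)
  truncated <- build_episodes(recs[recs$day <= t_star + 1L, ], ec)
  tpick <- which(truncated$meta$t == t_star)
  key_f <- paste(full$meta$patient_id[pick])
  key_t <- paste(truncated$meta$patient_id[tpick])
  expect_setequal(key_f, key_t)
  expect_equal(full$values[pick[order(key_f)], ],
               truncated$values[tpick[order(key_t)], ])
  expect_equal(full$flags[pick[order(key_f)], ],
               truncated$flags[tpick[order(key_t)], ])
})

test_that("calendar gaps are materialized as missing days", {
  recs <- manual_records(replicate(6, rep(0, 8), simplify = FALSE), "A")
  recs <- recs[recs$day != 3, ]    # physically absent day
  ep <- build_episodes(recs, episode_config(window = 2, scenario = "complete"))
  expect_false(3 %in% ep$meta$t)   # missing day cannot end an episode
  expect_false(4 %in% ep$meta$t)   # ... nor sit inside one in complete data
  epi <- build_episodes(recs, episode_config(window = 2, scenario = "imputed"))
  expect_true(4 %in% epi$meta$t)   # fillable in the imputed scenario
})

test_that("corticosteroid episodes keep only new-onset days", {
  recs <- manual_records(replicate(8, rep(0, 8), simplify = FALSE), "A",
                         corticosteroid = c(0, 0, 1, 1, 0, 0, 0, 1))
  ep <- build_episodes(recs, episode_config(window = 2, scenario = "complete",
                                            outcome = "corticosteroid"))
  filt <- corticosteroid_filter(ep)
  # day t=2 (taking) and t=3 (taking) are dropped as end days
  expect_false(any(filt$meta$t %in% c(2, 3)))
  # t=1: not taking on day 1, starts day 2 -> positive label
  expect_equal(filt$meta$label[filt$meta$t == 1], 1)
  # t=6: not taking on 6, starts day 7 -> positive; t=4: negative
  expect_equal(filt$meta$label[filt$meta$t == 6], 1)
  expect_equal(filt$meta$label[filt$meta$t == 4], 0)
  expect_error(corticosteroid_filter(build_episodes(recs,
    episode_config(window = 2, scenario = "complete"))), "corticosteroid")
})
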