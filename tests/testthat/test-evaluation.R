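test_that("AUC equals the pairwise probability with ties counting half", {
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1.0)
  expect_equal(auc(rep(0.3, 10), rep(0:1, 5)), 0.5)
  expect_error(auc(1:4, rep(1, 4)), "absent")

  set.seed(41)
  for (i in 1:1000) {
    n <- sample(4:20, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    expect_identical(auc(scores, labels), brute_auc(scores, labels))
  }
})

clamp_unit <- function(x) pmin(pmax(x, 0), 1)

test_that("DeLong intervals agree with an independent implementation", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(30:120, 1)
    scores <- round(rnorm(n), 1)
    labels <- rbinom(n, 1, 0.4)
    if (sum(labels) < 2 || sum(1 - labels) < 2) next
    r <- suppressMessages(pROC::roc(labels, scores, direction = "<"))
    expect_equal(auc(scores, labels), as.numeric(r$auc))
    ours <- auc_ci(scores, labels, "delong")
    ref <- as.numeric(suppressWarnings(pROC::ci.auc(r, method = "delong")))[c(1, 3)]
    expect_equal(ours, clamp_unit(ref), tolerance = 1e-10)
  }
})

clamp_unit <- function(x) pmin(pmax(x, 0), 1)

test_that("interval constructions are ordered and the consensus is their hull", {
  set.seed(43)
  scores <- rnorm(300); labels <- rbinom(300, 1, 0.2)
  dl <- auc_ci(scores, labels, "delong")
  ch <- auc_ci(scores, labels, "chebyshev")
  expect_lte(ch[1], dl[1]); expect_gte(ch[2], dl[2])   # Chebyshev is wider

  rs <- auc_ci(scores, labels, "resample", B = 400, seed = 1)
  point <- auc(scores, labels)
  for (iv in list(dl, ch, rs)) {
    expect_lte(iv[1], point); expect_gte(iv[2], point)
  }
  expect_equal(consensus_ci(list(dl, dl)), dl)
  expect_equal(consensus_ci(list(c(0.4, 0.6), c(0.45, 0.55))), c(0.4, 0.6))
  expect_equal(consensus_ci(list(c(0.1, 0.2), c(0.7, 0.8))), c(0.1, 0.8))

  # all-tie scores: interval centred on one half
  tie <- auc_ci(rep(1, 40), rep(0:1, 20), "delong")
  expect_equal(mean(tie), 0.5)

  # a single positive: DeLong variance undefined, warned bootstrap fallback
  expect_warning(auc_ci(1:12, c(rep(0, 11), 1), "delong", B = 200),
                 "falling back")
})

test_that("DeLong coverage is nominal under null and signal", {
  for (scenario in c("null", "signal")) {
    set.seed(44)
    hits <- 0L; N <- 1000L
    for (i in seq_len(N)) {
      neg <- rnorm(100)
      pos <- rnorm(100, mean = if (scenario == "null") 0 else 1)
      truth <- if (scenario == "null") 0.5 else pnorm(1 / sqrt(2))
      ci <- auc_ci(c(neg, pos), rep(0:1, each = 100), "delong")
      if (ci[1] <= truth && truth <= ci[2]) hits <- hits + 1L
    }
    expect_gte(hits / N, 0.93)
    expect_lte(hits / N, 0.97)
  }
})

test_that("operating points fall where the ROC geometry dictates", {
  # perfect classifier: zero false positives at any achievable sensitivity
  op <- fpr_at_tpr(c(1, 2, 3, 4), c(0, 0, 1, 1), 0.8)
  expect_equal(op$fpr, 0)
  # labels equal to binary scores
  op2 <- fpr_at_tpr(c(0, 1, 0, 1), c(0, 1, 0, 1), 0.8)
  expect_equal(op2$fpr, 0)
  # chance-level scores: FPR tracks the target TPR on the diagonal
  set.seed(45)
  sc <- runif(10000); lb <- rbinom(10000, 1, 0.1)
  op3 <- fpr_at_tpr(sc, lb, 0.8)
  expect_lt(abs(op3$fpr - 0.8), 0.03)
  # a binary rule with TPR 0.5: the step overshoots, the interpolation
  # blends the vertex with (1,1)
  sc4 <- c(1, 0, 0, 0, 1, 0); lb4 <- c(1, 1, 0, 0, 0, 0)
  op4 <- fpr_at_tpr(sc4, lb4, 0.75)
  expect_equal(op4$fpr, 1)            # only the (1,1) corner reaches TPR 0.75
  expect_equal(op4$fpr_interpolated, 0.25 + (1 - 0.25) * (0.75 - 0.5) / (1 - 0.5))
})

test_that("fold assignments partition patients and balance episode counts", {
  set.seed(46)
  pid <- rep(sprintf("P%03d", 1:30), times = sample(5:40, 30, replace = TRUE))
  folds <- make_folds(pid, k_outer = 5, k_inner = 4, n_runs = 3, seed = 2)
  expect_silent(audit_folds(folds))

  counts <- table(pid)
  for (run in folds$runs) {
    expect_setequal(names(run$outer), names(counts))
    load <- tapply(as.numeric(counts[names(run$outer)]), run$outer, sum)
    expect_lt(max(load) / min(load), 1.5)
  }
  # distinct runs give distinct partitions; same seed reproduces
  expect_false(identical(folds$runs[[1]]$outer, folds$runs[[2]]$outer))
  folds2 <- make_folds(pid, k_outer = 5, k_inner = 4, n_runs = 3, seed = 2)
  expect_identical(folds, folds2)
  # equal counts, k dividing n: perfectly equal folds
  pid_eq <- rep(sprintf("Q%02d", 1:10), each = 4)
  f_eq <- make_folds(pid_eq, k_outer = 5, k_inner = 2, n_runs = 1, seed = 3)
  expect_true(all(table(f_eq$runs[[1]]$outer) == 2))
  expect_error(make_folds(pid_eq, k_outer = 11), "fewer patients")
})

test_that("nested CV passes oracle scores through and respects fold structure", {
  cfg <- tiny_config(n_patients = 20, n_days = 60, seed = 13,
                     admission = list(intercept = -5, severity = 1.6,
                                      spo2_drop = 0.15, pulse_rise = 0.02))
  sim <- simulate_cohort(cfg)
  ep <- build_episodes(sim$records, episode_config(window = 3, scenario = "imputed"))
  osc <- oracle_for_episodes(ep, sim$truth, "admission")
  feat <- list(x = matrix(0, nrow(ep$meta), 0), label = ep$meta$label,
               patient_id = ep$meta$patient_id)
  folds <- make_folds(ep$meta$patient_id, k_outer = 4, k_inner = 3, n_runs = 2,
                      seed = 4)
  rep <- run_nested_cv(feat, model = NULL, folds = folds, fixed_scores = osc,
                       ci_B = 200)
  expect_equal(rep$aggregated_auc, auc(osc, ep$meta$label))
  expect_equal(rep$per_run_auc[1], rep$per_run_auc[2])
  expect_true(rep$ci$delong[1] <= rep$aggregated_auc &&
                rep$aggregated_auc <= rep$ci$delong[2])
  expect_equal(rep$n_pos, sum(ep$meta$label))
})

test_that("rank correlations match brute-force concordance counting", {
  set.seed(47)
  for (i in 1:200) {
    n <- sample(4:8, 1)
    x <- sample(1:20, n); y <- sample(1:20, n)
    expect_equal(stats::cor(x, y, method = "kendall"), brute_kendall(x, y))
    expect_equal(stats::cor(x, y, method = "spearman"), brute_spearman(x, y))
  }
})

test_that("population-level block prediction honours its degenerate cases", {
  cfg <- tiny_config(n_patients = 10, n_days = 120, seed = 14)
  sim <- simulate_cohort(cfg)
  res <- population_score_prediction(sim$records, window = 14)
  expect_equal(length(res$target), 120 %/% 14 + 1)
  held <- !is.na(res$pred_lagged)
  # the lagged heuristic is exactly the shifted target
  expect_equal(res$pred_lagged[held], res$target[which(held) - 1])
  expect_error(population_score_prediction(sim$records, window = 60), "blocks")
})
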