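#' Patient-grouped nested fold assignment
#'
#' Assigns patients (never episodes) to `k_outer` disjoint outer folds per
#' run, balancing fold episode counts greedily: patients are taken in
#' decreasing episode-count order (ties shuffled per run) and each goes to
#' the currently lightest fold. Within each outer-training set the same
#' scheme yields `k_inner` inner folds. Distinct runs use distinct shuffles,
#' all derived from one seed.
#'
#' @param patient_id patient identifier per episode.
#' @param k_outer,k_inner numbers of outer and inner folds (defaults 10/10).
#' @param n_runs repetitions of the whole partition (default 10).
#' @param seed integer seed.
#' @return object of class `telecopd_folds`: list of runs, each with `outer`
#'   (named vector patient -> outer fold) and `inner` (list per outer fold:
#'   named vector patient -> inner fold over the outer-training patients).
#' @export
make_folds <- function(patient_id, k_outer = 10L, k_inner = 10L,
                       n_runs = 10L, seed = 1L) {
  counts <- table(patient_id)
  pts <- names(counts)
  if (length(pts) < k_outer)
    stop("fewer patients (", length(pts), ") than outer folds (", k_outer, ")",
         call. = FALSE)
  runs <- lapply(seq_len(n_runs), function(r) {
    with_seed(child_seed(seed, paste0("folds:run", r)), {
      outer <- greedy_assign(counts, k_outer)
      inner <- lapply(seq_len(k_outer), function(f) {
        train_pts <- names(outer)[outer != f]
        ki <- min(k_inner, length(train_pts))
        greedy_assign(counts[train_pts], ki)
      })
      list(outer = outer, inner = inner)
    })
  })
  structure(list(runs = runs, k_outer = as.integer(k_outer),
                 k_inner = as.integer(k_inner), n_runs = as.integer(n_runs),
                 seed = seed),
            class = "telecopd_folds")
}

# Greedy balanced assignment of patients to k folds by episode count.
greedy_assign <- function(counts, k) {
  pts <- names(counts)
  ord <- order(-as.numeric(counts), stats::runif(length(counts)))
  fold_of <- integer(length(pts))
  load <- numeric(k)
  npat <- integer(k)
  for (i in ord) {
    f <- order(load, npat)[1]
    fold_of[i] <- f
    load[f] <- load[f] + counts[i]
    npat[f] <- npat[f] + 1L
  }
  stats::setNames(fold_of, pts)
}

#' Audit a fold assignment for patient leakage
#'
#' Checks, for every run, that the outer folds partition the patients
#' disjointly and that every inner fold lies within its outer-training
#' patients and is itself disjoint. Returns the number of (run, outer,
#' inner) splits audited; errors on any violation.
#'
#' @param folds a `telecopd_folds` object.
#' @return invisibly, the number of splits audited.
#' @export
audit_folds <- function(folds) {
  n_audited <- 0L
  for (r in seq_along(folds$runs)) {
    run <- folds$runs[[r]]
    pts <- names(run$outer)
    if (anyDuplicated(pts)) stop("run ", r, ": duplicated patient in outer folds")
    for (f in seq_len(folds$k_outer)) {
      test_pts <- pts[run$outer == f]
      train_pts <- names(run$inner[[f]])
      if (length(intersect(test_pts, train_pts)))
        stop("run ", r, " outer fold ", f, ": test patient present in inner folds")
      if (!setequal(train_pts, setdiff(pts, test_pts)))
        stop("run ", r, " outer fold ", f, ": inner folds do not cover the training set")
      inner <- run$inner[[f]]
      for (g in unique(inner)) {
        val_pts <- names(inner)[inner == g]
        if (length(intersect(val_pts, setdiff(train_pts, val_pts))) ||
            length(intersect(val_pts, test_pts)))
          stop("run ", r, " outer ", f, " inner ", g, ": patient leakage")
        n_audited <- n_audited + 1L
      }
    }
  }
  invisible(n_audited)
}

#' Area under the ROC curve (Mann-Whitney, ties count half)
#'
#' `P(score+ > score-) + 0.5 P(tie)`, computed from midranks, so binary
#' predictors get the AUC of their single operating point.
#'
#' @param scores numeric risk scores.
#' @param labels 0/1 outcome labels; both classes must be present.
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("AUC undefined: one outcome class is absent", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong structural-component variance of the AUC estimator.
delong_variance <- function(scores, labels) {
  labels <- as.integer(labels)
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  if (m < 2L || n < 2L) return(NA_real_)
  all_r <- rank(c(x, y), ties.method = "average")
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  v10 <- (all_r[seq_len(m)] - rx) / n            # per-positive components
  v01 <- 1 - (all_r[m + seq_len(n)] - ry) / m    # per-negative components
  stats::var(v10) / m + stats::var(v01) / n
}

#' Confidence interval for the AUC
#'
#' Three constructions:
#' \describe{
#'   \item{delong}{normal interval `point +/- z * sqrt(V)` with the DeLong
#'     structural-components variance `V`.}
#'   \item{resample}{percentile interval over patient-level (cluster)
#'     bootstrap replicates; episodes within a patient are resampled
#'     together because they are dependent. Falls back to row resampling
#'     when no patient ids are given.}
#'   \item{chebyshev}{distribution-free `point +/- sqrt(V / alpha)` using
#'     the DeLong variance; always at least as wide as the DeLong interval.}
#' }
#' All intervals are truncated to [0, 1]. With fewer than 2 cases per class
#' the DeLong variance is undefined and delong/chebyshev fall back to the
#' resampling interval with a warning.
#'
#' @param scores,labels as in [auc()].
#' @param method one of `"delong"`, `"resample"`, `"chebyshev"`.
#' @param alpha two-sided miscoverage level (default 0.05).
#' @param patient_id optional cluster id per observation for the bootstrap.
#' @param B bootstrap replicates (default 1000).
#' @param seed seed for the bootstrap.
#' @return numeric `c(lower, upper)`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "resample", "chebyshev"),
                   alpha = 0.05, patient_id = NULL, B = 1000L, seed = 1L) {
  method <- match.arg(method)
  point <- auc(scores, labels)
  if (method %in% c("delong", "chebyshev")) {
    v <- delong_variance(scores, labels)
    if (is.na(v)) {
      warning("DeLong variance undefined (fewer than 2 cases in a class); ",
              "falling back to the resampling interval")
      return(auc_ci(scores, labels, "resample", alpha, patient_id, B, seed))
    }
    half <- if (method == "delong") stats::qnorm(1 - alpha / 2) * sqrt(v)
            else sqrt(v / alpha)
    return(clamp(c(point - half, point + half), 0, 1))
  }
  # patient-level bootstrap
  with_seed(child_seed(seed, "auc-bootstrap"), {
    if (is.null(patient_id)) patient_id <- seq_along(scores)
    idx_by <- split(seq_along(scores), patient_id)
    reps <- numeric(0)
    for (b in seq_len(B)) {
      take <- sample(length(idx_by), replace = TRUE)
      ii <- unlist(idx_by[take], use.names = FALSE)
      if (length(unique(labels[ii])) < 2L) next
      reps <- c(reps, auc(scores[ii], labels[ii]))
    }
    if (length(reps) < 10L)
      stop("bootstrap failed: almost all replicates single-class", call. = FALSE)
    clamp(as.numeric(stats::quantile(reps, c(alpha / 2, 1 - alpha / 2),
                                     names = FALSE, type = 7)), 0, 1)
  })
}

#' Consensus interval across CI methods
#'
#' The conservative hull: minimum lower bound and maximum upper bound over
#' the member intervals (each of which should also be reported).
#'
#' @param intervals list of >= 2 numeric `c(lower, upper)` intervals.
#' @return numeric `c(lower, upper)`.
#' @export
consensus_ci <- function(intervals) {
  stopifnot(is.list(intervals), length(intervals) >= 2L)
  lo <- min(vapply(intervals, `[`, numeric(1), 1))
  hi <- max(vapply(intervals, `[`, numeric(1), 2))
  c(lo, hi)
}

#' False-positive rate at a target sensitivity
#'
#' The smallest empirical FPR among thresholds whose TPR is at least the
#' target. For coarse (e.g. binary) scores the step value can overshoot, so
#' the linearly interpolated FPR at exactly the target TPR along the
#' empirical ROC polyline (for a binary predictor: the segment from its
#' single ROC vertex to (1,1)) is reported alongside.
#'
#' @param scores,labels as in [auc()].
#' @param target_tpr target sensitivity (default 0.80).
#' @return list: `fpr` (step value), `fpr_interpolated`, `tpr` achieved at
#'   the step threshold.
#' @export
fpr_at_tpr <- function(scores, labels, target_tpr = 0.80) {
  labels <- as.integer(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L)
    stop("ROC undefined: one outcome class is absent", call. = FALSE)
  o <- order(scores, decreasing = TRUE)
  ss <- scores[o]; ls <- labels[o]
  block_ends <- cumsum(rle(ss)$lengths)   # last index of each tied block
  tpr <- cumsum(ls == 1)[block_ends] / n1
  fpr <- cumsum(ls == 0)[block_ends] / n0
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  if (tpr[length(tpr)] < 1) { tpr <- c(tpr, 1); fpr <- c(fpr, 1) }
  feas <- which(tpr >= target_tpr)
  i <- feas[which.min(fpr[feas])]
  # linear interpolation at exactly the target along the ROC polyline
  j <- which(tpr >= target_tpr)[1]
  interp <- if (j == 1L || tpr[j] == target_tpr) fpr[j] else {
    w <- (target_tpr - tpr[j - 1]) / (tpr[j] - tpr[j - 1])
    fpr[j - 1] + w * (fpr[j] - fpr[j - 1])
  }
  list(fpr = fpr[i], fpr_interpolated = interp, tpr = tpr[i])
}

#' Patient-grouped nested cross-validation with aggregated AUC
#'
#' For every run and outer fold: hyperparameters are tuned on the inner
#' folds (patients of the test fold appear nowhere), the model is refitted
#' on the full outer-training set and scored on the test fold; test-fold
#' scores are merged across outer folds into one per-run score vector whose
#' AUC is the run's merged AUC. The aggregated AUC is the mean over runs.
#' Confidence intervals (DeLong, patient-bootstrap resampling, Chebyshev,
#' and their consensus hull) are computed on the pooled all-runs merged
#' predictions.
#'
#' Rule-based predictors bypass fitting entirely: supply `fixed_scores`
#' (one score per episode, e.g. a 0/1 onset flag) and the identical episodes
#' are evaluated under the same fold structure. Episodes with `NA` fixed
#' scores (rule context unavailable) are excluded, mirroring the smaller
#' per-definition sample sizes.
#'
#' @param features a `telecopd_features` object, or a list with elements
#'   `x`, `label`, `patient_id`.
#' @param model a [model_spec()], or `NULL` when `fixed_scores` is given.
#' @param folds a [make_folds()] assignment on the same patients.
#' @param fixed_scores optional per-episode score vector replacing model
#'   fitting.
#' @param ci_B bootstrap replicates for the resampling CI.
#' @return object of class `telecopd_report`: per-run AUCs, aggregated AUC,
#'   CIs per method and consensus, sample/event counts, the pooled merged
#'   predictions, and the operating point at 80% sensitivity.
#' @export
run_nested_cv <- function(features, model = NULL, folds, fixed_scores = NULL,
                          ci_B = 1000L) {
  x <- features$x; labels <- as.integer(features$label)
  patient_id <- features$patient_id
  keep <- rep(TRUE, length(labels))
  if (!is.null(fixed_scores)) keep <- !is.na(fixed_scores)
  x <- x[keep, , drop = FALSE]; labels <- labels[keep]
  patient_id <- patient_id[keep]
  if (!is.null(fixed_scores)) fixed_scores <- fixed_scores[keep]

  merged <- list()
  per_run_auc <- numeric(length(folds$runs))
  for (r in seq_along(folds$runs)) {
    run <- folds$runs[[r]]
    sc <- rep(NA_real_, length(labels))
    if (!is.null(fixed_scores)) {
      sc <- fixed_scores
    } else {
      for (f in seq_len(folds$k_outer)) {
        test_pts <- names(run$outer)[run$outer == f]
        te <- patient_id %in% test_pts
        tr <- !te
        if (!any(te)) next
        inner <- run$inner[[f]]
        inner_id <- unname(inner[match(patient_id[tr], names(inner))])
        tuned <- tune_model(x[tr, , drop = FALSE], labels[tr],
                            patient_id[tr], inner_id, model)
        fit <- fit_model(x[tr, , drop = FALSE], labels[tr], model,
                         hyper = tuned$hyper)
        sc[te] <- predict_scores(fit, x[te, , drop = FALSE])
      }
    }
    ok <- !is.na(sc)
    if (length(unique(labels[ok])) < 2L)
      stop("merged test predictions are single-class; cannot compute AUC",
           call. = FALSE)
    per_run_auc[r] <- auc(sc[ok], labels[ok])
    merged[[r]] <- data.frame(run = r, patient_id = patient_id[ok],
                              score = sc[ok], label = labels[ok],
                              stringsAsFactors = FALSE)
  }
  merged <- do.call(rbind, merged)
  # fixed-score predictors yield identical runs; pooling their duplicates
  # would fake a larger sample, so the CI uses one copy
  pool <- if (!is.null(fixed_scores)) merged[merged$run == 1L, ] else merged
  cis <- list(
    delong = auc_ci(pool$score, pool$label, "delong"),
    resample = auc_ci(pool$score, pool$label, "resample",
                      patient_id = pool$patient_id, B = ci_B,
                      seed = folds$seed),
    chebyshev = auc_ci(pool$score, pool$label, "chebyshev"))
  op <- fpr_at_tpr(pool$score, pool$label, 0.80)
  structure(list(per_run_auc = per_run_auc,
                 aggregated_auc = mean(per_run_auc),
                 ci = cis, consensus = consensus_ci(cis),
                 n = sum(!is.na(labels)), n_pos = sum(labels == 1),
                 merged = merged, fpr_at_80tpr = op),
            class = "telecopd_report")
}

#' @export
print.telecopd_report <- function(x, digits = 3, ...) {
  cat("<telecopd_report>\n")
  cat(sprintf("  aggregated AUC %.*f over %d run(s); N=%d, N+=%d\n",
              digits, x$aggregated_auc, length(x$per_run_auc), x$n, x$n_pos))
  for (m in names(x$ci))
    cat(sprintf("  %-9s 95%% CI (%.*f, %.*f)\n", m, digits, x$ci[[m]][1],
                digits, x$ci[[m]][2]))
  cat(sprintf("  consensus 95%% CI (%.*f, %.*f)\n", digits, x$consensus[1],
              digits, x$consensus[2]))
  cat(sprintf("  FPR at 80%% TPR: %.*f\n", digits, x$fpr_at_80tpr$fpr))
  invisible(x)
}
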