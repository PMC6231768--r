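#' Model specification for the classifier bench
#'
#' Uniform train/predict/tune contract over the three model families used
#' for next-day event prediction:
#' \describe{
#'   \item{elastic_net}{regularized logistic regression (glmnet) with an
#'     adaptive penalty: per-feature penalty factors are set from a
#'     univariate association filter computed on the training fold, so
#'     features with stronger marginal association are penalized less.}
#'   \item{svm}{sparse maximum-margin classifier (RBF-kernel support vector
#'     machine, kernlab).}
#'   \item{xgboost}{gradient-boosted tree ensemble.}
#' }
#' Hyperparameters are searched over inner folds: exhaustive `grid` search
#' for the linear and max-margin families, `random` search (budget draws
#' from the declared ranges) for the boosted ensemble. Class imbalance is
#' handled by inverse-prevalence instance weighting, on by default.
#'
#' @param family model family.
#' @param search `"grid"` or `"random"` (default per family).
#' @param budget number of candidates evaluated in random search.
#' @param space hyperparameter space; a data.frame of candidates (grid) or a
#'   named list of ranges/sets (random). `NULL` uses the family default.
#' @param balance_classes inverse-prevalence instance weighting.
#' @param standardize center/scale features using training-fold statistics.
#' @param adaptive_filter elastic net only: penalty factors from the
#'   training-fold univariate filter.
#' @param seed integer seed controlling fitting and the random-search
#'   candidate stream (each family draws an independent stream).
#' @return an object of class `telecopd_model_spec`.
#' @export
model_spec <- function(family = c("elastic_net", "svm", "xgboost"),
                       search = NULL, budget = 10L, space = NULL,
                       balance_classes = TRUE, standardize = TRUE,
                       adaptive_filter = TRUE, seed = 1L) {
  family <- match.arg(family)
  search <- search %||% switch(family, xgboost = "random", "grid")
  stopifnot(search %in% c("grid", "random"), is_count(budget), budget >= 1)
  space <- space %||% default_space(family)
  structure(list(family = family, search = search, budget = as.integer(budget),
                 space = space, balance_classes = isTRUE(balance_classes),
                 standardize = isTRUE(standardize),
                 adaptive_filter = isTRUE(adaptive_filter),
                 seed = as.integer(seed)),
            class = "telecopd_model_spec")
}

default_space <- function(family) {
  switch(family,
    elastic_net = expand.grid(alpha = c(0.2, 0.5, 0.8),
                              lambda = c(0.1, 0.03, 0.01, 0.003, 0.001)),
    svm = expand.grid(C = c(0.1, 1, 10), sigma = c(0.001, 0.01, 0.1)),
    xgboost = list(eta = c(0.03, 0.3), max_depth = c(2L, 6L),
                   nrounds = c(50L, 250L), subsample = c(0.6, 1),
                   colsample_bytree = c(0.5, 1), min_child_weight = c(1L, 10L)))
}

# Candidate hyperparameter sets for a spec: a list of named lists.
candidate_points <- function(spec) {
  if (spec$search == "grid") {
    if (!is.data.frame(spec$space) || !nrow(spec$space))
      stop("empty hyperparameter search space", call. = FALSE)
    lapply(seq_len(nrow(spec$space)), function(i) as.list(spec$space[i, , drop = FALSE]))
  } else {
    rng <- spec$space
    if (!is.list(rng) || !length(rng))
      stop("empty hyperparameter search space", call. = FALSE)
    with_seed(child_seed(spec$seed, paste0("search:", spec$family)), {
      lapply(seq_len(spec$budget), function(i) {
        p <- lapply(rng, function(r) {
          if (is.integer(r)) sample(seq(r[1], r[2]), 1L)
          else if (length(r) == 2L) stats::runif(1, r[1], r[2])
          else sample(r, 1L)
        })
        p
      })
    })
  }
}

instance_weights <- function(labels, balance) {
  n <- length(labels)
  if (!balance) return(rep(1, n))
  n1 <- sum(labels == 1); n0 <- n - n1
  ifelse(labels == 1, n / (2 * n1), n / (2 * n0))
}

#' Fit a classifier under the bench contract
#'
#' Standardization statistics, the adaptive penalty filter and all learned
#' parameters come from the supplied (training) data only. Deterministic
#' given the spec seed.
#'
#' @param x numeric feature matrix with column names.
#' @param labels 0/1 vector; both classes must be present.
#' @param spec a [model_spec()].
#' @param hyper named list of hyperparameters; `NULL` uses the first grid
#'   point / midpoint of ranges.
#' @return an object of class `telecopd_model`.
#' @export
fit_model <- function(x, labels, spec, hyper = NULL) {
  stopifnot(inherits(spec, "telecopd_model_spec"))
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("degenerate fit: labels contain a single class", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  hyper <- hyper %||% default_hyper(spec)

  center <- scale_ <- rep(0, ncol(x))
  if (spec$standardize) {
    center <- colMeans(x)
    scale_ <- apply(x, 2, stats::sd)
    scale_[scale_ == 0 | !is.finite(scale_)] <- 1
    x <- sweep(sweep(x, 2, center), 2, scale_, "/")
  } else {
    scale_ <- rep(1, ncol(x))
  }
  w <- instance_weights(labels, spec$balance_classes)

  fit <- with_seed(child_seed(spec$seed, paste0("fit:", spec$family)), {
    switch(spec$family,
      elastic_net = fit_elastic_net(x, labels, w, hyper, spec),
      svm = fit_svm(x, labels, w, hyper),
      xgboost = fit_xgboost(x, labels, hyper, spec))
  })
  structure(list(family = spec$family, fit = fit$object, extra = fit$extra,
                 hyper = hyper, center = center, scale = scale_,
                 standardize = spec$standardize,
                 manifest = colnames(x)),
            class = "telecopd_model")
}

default_hyper <- function(spec) {
  if (spec$search == "grid") as.list(spec$space[1, , drop = FALSE])
  else lapply(spec$space, function(r) {
    if (is.integer(r)) as.integer(round(mean(r[1:2]))) else mean(r[1:2])
  })
}

# Univariate association filter: |weighted correlation| of each feature with
# the outcome, turned into glmnet penalty factors (strong features penalized
# less). Computed on training data only.
adaptive_penalty_factors <- function(x, labels) {
  y <- labels - mean(labels)
  xs <- sweep(x, 2, colMeans(x))
  denom <- sqrt(colSums(xs^2) * sum(y^2))
  score <- abs(as.numeric(crossprod(xs, y))) / pmax(denom, 1e-12)
  pf <- 1 / (0.05 + score)
  pf * length(pf) / sum(pf)        # normalize to mean 1
}

fit_elastic_net <- function(x, labels, w, hyper, spec) {
  pf <- if (spec$adaptive_filter) adaptive_penalty_factors(x, labels)
        else rep(1, ncol(x))
  lam <- hyper$lambda
  lambda_path <- sort(unique(c(lam * c(20, 8, 3, 1))), decreasing = TRUE)
  # rare events leave few positives in small inner folds; glmnet warns about
  # this routine condition on every such fit
  obj <- withCallingHandlers(
    glmnet::glmnet(x, factor(labels, levels = c(0, 1)), family = "binomial",
                   alpha = hyper$alpha, lambda = lambda_path,
                   weights = w, penalty.factor = pf, standardize = FALSE),
    warning = function(w_) {
      if (grepl("fewer than 8", conditionMessage(w_)))
        invokeRestart("muffleWarning")
    })
  list(object = obj, extra = list(s = lam))
}

fit_svm <- function(x, labels, w, hyper) {
  y <- factor(labels, levels = c(0, 1))
  cw <- c(`0` = sum(w[labels == 0]) / sum(labels == 0),
          `1` = sum(w[labels == 1]) / sum(labels == 1))
  obj <- kernlab::ksvm(x, y, type = "C-svc", kernel = "rbfdot",
                       kpar = list(sigma = hyper$sigma), C = hyper$C,
                       class.weights = cw, prob.model = FALSE, scaled = FALSE)
  # orient the decision values so higher = higher risk, using training data
  dec <- kernlab::predict(obj, x, type = "decision")[, 1L]
  flip <- auc(dec, labels) < 0.5
  list(object = obj, extra = list(flip = flip))
}

fit_xgboost <- function(x, labels, hyper, spec) {
  n1 <- sum(labels == 1)
  spw <- if (spec$balance_classes) (length(labels) - n1) / n1 else 1
  dtrain <- xgboost::xgb.DMatrix(x, label = labels)
  params <- list(objective = "binary:logistic", eval_metric = "auc",
                 eta = hyper$eta, max_depth = hyper$max_depth,
                 subsample = hyper$subsample,
                 colsample_bytree = hyper$colsample_bytree,
                 min_child_weight = hyper$min_child_weight,
                 scale_pos_weight = spw, nthread = 1)
  obj <- xgboost::xgb.train(params = params, data = dtrain,
                            nrounds = hyper$nrounds, verbose = 0)
  list(object = obj, extra = NULL)
}

#' Predict risk scores from a fitted bench model
#'
#' Higher score means higher predicted risk. Scores are only rank-meaningful
#' (AUC is calibration-invariant); any strictly monotone rescaling leaves
#' downstream evaluation unchanged.
#'
#' @param model a `telecopd_model` from [fit_model()].
#' @param x feature matrix; columns must match the model's manifest (any
#'   order).
#' @return numeric score vector.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "telecopd_model"))
  if (is.null(colnames(x)) || !all(model$manifest %in% colnames(x)))
    stop("feature matrix does not match the model manifest", call. = FALSE)
  x <- x[, model$manifest, drop = FALSE]
  if (model$standardize)
    x <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  switch(model$family,
    elastic_net = as.numeric(predict(
      model$fit, newx = x, s = model$extra$s, type = "link")),
    svm = {
      dec <- kernlab::predict(model$fit, x, type = "decision")[, 1L]
      if (model$extra$flip) -dec else dec
    },
    xgboost = as.numeric(predict(model$fit, xgboost::xgb.DMatrix(x))))
}

#' Tune hyperparameters on inner folds
#'
#' Evaluates every candidate point by the AUC of the predictions merged
#' across the inner validation folds and returns the argmax (first on ties).
#' Raises if any patient appears on both sides of an inner split.
#'
#' @param x,labels training-fold features and labels.
#' @param patient_id patient identifier per row.
#' @param inner_folds integer inner-fold id per row (patient-disjoint).
#' @param spec a [model_spec()].
#' @return list: `hyper` (best candidate), `auc` (its merged inner AUC),
#'   `trace` (candidate AUCs).
#' @export
tune_model <- function(x, labels, patient_id, inner_folds, spec) {
  cands <- candidate_points(spec)
  folds <- sort(unique(inner_folds))
  for (f in folds) {
    shared <- intersect(patient_id[inner_folds == f], patient_id[inner_folds != f])
    if (length(shared))
      stop("patient leakage across inner folds: ", paste(utils::head(shared, 3),
           collapse = ", "), call. = FALSE)
  }
  aucs <- vapply(cands, function(h) {
    sc <- rep(NA_real_, length(labels))
    for (f in folds) {
      tr <- inner_folds != f
      if (length(unique(labels[tr])) < 2L) next
      m <- fit_model(x[tr, , drop = FALSE], labels[tr], spec, hyper = h)
      sc[!tr] <- predict_scores(m, x[!tr, , drop = FALSE])
    }
    ok <- !is.na(sc)
    if (!any(ok) || length(unique(labels[ok])) < 2L) return(NA_real_)
    auc(sc[ok], labels[ok])
  }, numeric(1))
  if (all(is.na(aucs)))
    stop("no candidate could be evaluated on the inner folds", call. = FALSE)
  best <- which.max(aucs)
  list(hyper = cands[[best]], auc = aucs[best], trace = aucs)
}
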