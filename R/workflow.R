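#' Validate and normalize an experiment configuration
#'
#' Reads a YAML experiment configuration (or takes an equivalent list),
#' fills defaults and checks every field, reporting all problems together.
#' Recognized sections: `cohort` (passed to [cohort_config()]), `episodes`
#' (`window`, `max_fill_horizon`, `sparse_patient_threshold`), `evaluation`
#' (`k_outer`, `k_inner`, `n_runs`, `ci_B`), `definitions` (subset of 1-5),
#' `scenarios`, `outcomes`, `models` (list of [model_spec()] arguments),
#' `covariate_sets`, `seed`, and `output` (`dir`, `overwrite`).
#'
#' @param config path to a YAML file, or a list.
#' @return normalized configuration list of class `telecopd_experiment_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  e <- character()
  known <- c("cohort", "episodes", "evaluation", "definitions", "scenarios",
             "outcomes", "models", "covariate_sets", "seed", "output")
  unknown <- setdiff(names(config), known)
  e <- check_that(e, length(unknown) == 0L,
                  paste("unknown config keys:", paste(unknown, collapse = ", ")))

  seed <- config$seed %||% 1L
  e <- check_that(e, is.numeric(seed) && length(seed) == 1L, "seed must be a scalar")

  cohort_args <- config$cohort %||% list()
  cohort_args$seed <- cohort_args$seed %||% seed
  cohort <- tryCatch(do.call(cohort_config, normalize_cohort_args(cohort_args)),
                     error = function(err) {
                       e <<- c(e, conditionMessage(err)); NULL
                     })

  ep <- config$episodes %||% list()
  episodes <- list(window = ep$window %||% 7L,
                   definition_window = ep$definition_window %||% 1L,
                   max_fill_horizon = ep$max_fill_horizon %||% 15L,
                   sparse_patient_threshold = ep$sparse_patient_threshold %||% 0.95)
  e <- check_that(e, is_count(episodes$window) && episodes$window >= 1,
                  "episodes$window must be an integer >= 1")
  e <- check_that(e, is_count(episodes$definition_window) &&
                    episodes$definition_window >= 1,
                  "episodes$definition_window must be an integer >= 1")
  e <- check_that(e, is_count(episodes$max_fill_horizon),
                  "episodes$max_fill_horizon must be a non-negative integer")

  ev <- config$evaluation %||% list()
  evaluation <- list(k_outer = ev$k_outer %||% 10L, k_inner = ev$k_inner %||% 10L,
                     n_runs = ev$n_runs %||% 10L, ci_B = ev$ci_B %||% 1000L)
  for (f in names(evaluation))
    e <- check_that(e, is_count(evaluation[[f]]) && evaluation[[f]] >= 1,
                    paste0("evaluation$", f, " must be a positive integer"))

  definitions <- config$definitions %||% 1:5
  e <- check_that(e, all(definitions %in% 1:5), "definitions must be in 1..5")
  scenarios <- config$scenarios %||% c("complete", "imputed")
  e <- check_that(e, all(scenarios %in% c("complete", "imputed")),
                  "scenarios must be 'complete' and/or 'imputed'")
  outcomes <- config$outcomes %||% "admission"
  e <- check_that(e, all(outcomes %in% c("admission", "corticosteroid")),
                  "outcomes must be 'admission' and/or 'corticosteroid'")
  covariate_sets <- config$covariate_sets %||% "telemonitoring"
  e <- check_that(e, all(covariate_sets %in% c("telemonitoring", "weather", "joint")),
                  "covariate_sets must be telemonitoring/weather/joint")

  models <- lapply(config$models %||% list(), function(m) {
    m$seed <- m$seed %||% seed
    tryCatch(do.call(model_spec, m),
             error = function(err) { e <<- c(e, conditionMessage(err)); NULL })
  })
  output <- list(dir = config$output$dir %||% NULL,
                 overwrite = isTRUE(config$output$overwrite))
  stop_if_errors(e, "invalid experiment configuration")
  structure(list(cohort = cohort, episodes = episodes, evaluation = evaluation,
                 definitions = as.integer(definitions), scenarios = scenarios,
                 outcomes = outcomes, models = models,
                 covariate_sets = covariate_sets, seed = seed, output = output),
            class = "telecopd_experiment_config")
}

# YAML gives plain lists; rebuild the nested cohort_config arguments,
# letting scalar shortcuts (e.g. couple_weather) land in the right slot.
normalize_cohort_args <- function(args) {
  defaults <- formals(cohort_config)
  top <- intersect(names(args), names(defaults))
  out <- args[top]
  for (slot in c("transition", "physiology", "admission", "corticosteroid",
                 "antibiotic", "missingness", "weather", "baseline")) {
    if (!is.null(out[[slot]])) {
      dflt <- eval(defaults[[slot]])
      merged <- utils::modifyList(as.list(dflt), as.list(out[[slot]]))
      out[[slot]] <- if (slot == "transition") unlist(merged) else merged
    }
  }
  extra <- setdiff(names(args), names(defaults))
  # allow flat keys that belong to the weather/missingness sub-lists
  for (k in extra) {
    hit <- FALSE
    for (slot in c("weather", "missingness")) {
      dflt <- eval(defaults[[slot]])
      if (k %in% names(dflt)) {
        cur <- out[[slot]] %||% dflt
        cur[[k]] <- args[[k]]
        out[[slot]] <- cur
        hit <- TRUE
        break
      }
    }
    if (!hit) stop("unknown cohort config key: ", k, call. = FALSE)
  }
  out
}

#' Run a full simulated experiment grid
#'
#' Simulates one cohort, builds one shared episode realization per
#' (scenario, outcome) cell, and evaluates (a) every requested
#' symptom-count definition as a next-day predictor and (b) every requested
#' model family on every covariate set (imputed scenario, as longer feature
#' histories require imputation), all on identical episodes and identical
#' patient-grouped folds. Returns a Table-1-shaped summary plus the full
#' per-cell reports and a provenance block (config hash, seed, package
#' version) sufficient to reproduce any row.
#'
#' @param config a [validate_config()] result, a list, or a YAML path.
#' @param quiet suppress per-stage progress messages.
#' @return list of class `telecopd_experiment`: `summary` data.frame,
#'   `reports`, `population` (when weather is coupled), `provenance`.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  if (!inherits(config, "telecopd_experiment_config"))
    config <- validate_config(config)
  say <- function(...) if (!quiet) message(...)
  stage <- "simulate"
  res <- tryCatch({
    say("simulating cohort (", config$cohort$n_patients, " patients x ",
        config$cohort$n_days, " days)")
    sim <- simulate_cohort(config$cohort)
    records <- exclude_sparse_patients(sim$records,
                                       config$episodes$sparse_patient_threshold)
    rows <- list()
    reports <- list()
    for (outcome in config$outcomes) {
      eps <- list()
      folds <- list()
      for (scen in config$scenarios) {
        stage <- paste0("episodes:", outcome, ":", scen)
        # score-counting rules need no history: the complete scenario uses
        # 1-day windows; the imputed scenario shares the model window so
        # rules and models are compared on identical episodes
        w_scen <- if (scen == "complete") config$episodes$definition_window
                  else config$episodes$window
        ec <- episode_config(window = w_scen,
                             max_fill_horizon = config$episodes$max_fill_horizon,
                             scenario = scen, outcome = outcome)
        ep <- build_episodes(records, ec)
        if (outcome == "corticosteroid") ep <- corticosteroid_filter(ep)
        eps[[scen]] <- ep
        folds[[scen]] <- make_folds(ep$meta$patient_id,
                                    k_outer = config$evaluation$k_outer,
                                    k_inner = config$evaluation$k_inner,
                                    n_runs = config$evaluation$n_runs,
                                    seed = child_seed(config$seed,
                                                      paste0("folds:", outcome, ":", scen)))
        for (d in config$definitions) {
          stage <- sprintf("definition %d (%s, %s)", d, scen, outcome)
          say("evaluating ", stage)
          sc <- definition_scores(ep, d)
          feat <- list(x = matrix(0, nrow(ep$meta), 0), label = ep$meta$label,
                       patient_id = ep$meta$patient_id)
          rep_d <- run_nested_cv(feat, model = NULL, folds = folds[[scen]],
                                 fixed_scores = sc,
                                 ci_B = config$evaluation$ci_B)
          key <- sprintf("%s_def%d_%s", outcome, d, scen)
          reports[[key]] <- rep_d
          rows[[key]] <- summary_row(
            description = sprintf("Definition %d", d),
            practical = definition_is_practical(d), scenario = scen,
            outcome = outcome, report = rep_d)
        }
      }
      if (length(config$models) && "imputed" %in% config$scenarios) {
        ep <- eps[["imputed"]]
        for (cs in config$covariate_sets) {
          stage <- paste0("features:", cs)
          catalogue <- default_catalogue(cs, W = config$episodes$window,
                                         include_indicators = TRUE)
          feat <- extract_features(ep, catalogue, sim$baseline)
          for (m in config$models) {
            stage <- sprintf("model %s (%s, %s)", m$family, cs, outcome)
            say("fitting ", stage)
            rep_m <- run_nested_cv(feat, model = m, folds = folds[["imputed"]],
                                   ci_B = config$evaluation$ci_B)
            key <- sprintf("%s_%s_%s", outcome, m$family, cs)
            reports[[key]] <- rep_m
            rows[[key]] <- summary_row(
              description = sprintf("%s (%s)", m$family, cs),
              practical = TRUE, scenario = "imputed", outcome = outcome,
              report = rep_m)
          }
        }
      }
    }
    list(rows = rows, reports = reports, baseline = sim$baseline,
         records = records, truth = sim$truth)
  }, error = function(err) {
    stop("experiment failed at stage [", stage, "]: ", conditionMessage(err),
         call. = FALSE)
  })
  summary <- do.call(rbind, res$rows)
  rownames(summary) <- NULL
  provenance <- list(
    config_hash = content_hash(yaml::as.yaml(unclass_config(config))),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("telecopd")))
  out <- structure(list(summary = summary, reports = res$reports,
                        provenance = provenance),
                   class = "telecopd_experiment")
  if (!is.null(config$output$dir))
    write_experiment(out, config$output$dir, overwrite = config$output$overwrite)
  out
}

unclass_config <- function(config) {
  rapply(unclass(config), unclass, how = "replace")
}

summary_row <- function(description, practical, scenario, outcome, report) {
  data.frame(outcome = outcome, description = description,
             practical = ifelse(practical, "Yes", "No"), scenario = scenario,
             auc = round(report$aggregated_auc, 3),
             ci_low = round(report$consensus[1], 3),
             ci_high = round(report$consensus[2], 3),
             n_pos = report$n_pos, n = report$n,
             stringsAsFactors = FALSE)
}

#' @export
print.telecopd_experiment <- function(x, ...) {
  cat("<telecopd_experiment> provenance hash ", x$provenance$config_hash,
      ", seed ", x$provenance$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Write an experiment bundle to a directory
#'
#' Writes `summary.csv` and `report.json` (summary, per-cell AUCs and CIs,
#' provenance). Refuses to overwrite existing files unless `overwrite`.
#'
#' @param experiment a `telecopd_experiment`.
#' @param dir output directory (created if needed).
#' @param overwrite allow replacing existing files.
#' @export
write_experiment <- function(experiment, dir, overwrite = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("summary.csv", "report.json"))
  exists <- file.exists(paths)
  if (any(exists) && !overwrite)
    stop("output files exist (use overwrite = TRUE): ",
         paste(paths[exists], collapse = ", "), call. = FALSE)
  utils::write.csv(experiment$summary, paths[1], row.names = FALSE, na = "")
  payload <- list(
    summary = experiment$summary,
    reports = lapply(experiment$reports, function(r)
      list(aggregated_auc = r$aggregated_auc, per_run_auc = r$per_run_auc,
           ci = r$ci, consensus = r$consensus, n = r$n, n_pos = r$n_pos,
           fpr_at_80tpr = r$fpr_at_80tpr)),
    provenance = experiment$provenance)
  jsonlite::write_json(payload, paths[2], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}
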