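#' @keywords internal
"_PACKAGE"

# Symptom variable names, in canonical order: 3 major then 5 minor.
MAJOR_SYMPTOMS <- c("breathlessness", "sputum_colour", "sputum_amount")
MINOR_SYMPTOMS <- c("cold", "wheeze", "sore_throat", "cough", "fever")
SYMPTOM_VARS   <- c(MAJOR_SYMPTOMS, MINOR_SYMPTOMS)
PHYSIOLOGY_VARS <- c("pulse", "spo2")
MEDICATION_VARS <- c("antibiotic", "corticosteroid")
MASKABLE_VARS   <- c(SYMPTOM_VARS, PHYSIOLOGY_VARS, MEDICATION_VARS)
WEATHER_VARS    <- c("mean_temp", "max_temp",
                     "temp_mean_lt2", "temp_max_lt4", "temp_max_lt7",
                     "alert_level")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child seed from a root seed and a stream label
#'
#' All randomness in the package flows from one root seed. Each module draws
#' from its own stream, obtained by hashing a string label together with the
#' root seed, so that e.g. regenerating baseline covariates never perturbs the
#' daily-record stream. The result is always a valid 32-bit seed.
#'
#' @param seed integer root seed.
#' @param key character stream label.
#' @return an integer seed in [0, 2^31 - 1).
#' @export
child_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- 5381
  for (b in utf8ToInt(paste0(key, collapse = ""))) {
    h <- (h * 131 + b) %% 2147483647
  }
  as.integer((abs(seed) * 48271 + h) %% 2147483647)
}

# Run expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Collect validation failures; used by config constructors so that all
# problems are reported together rather than one at a time.
check_that <- function(errors, ok, msg) {
  if (!isTRUE(ok)) c(errors, msg) else errors
}

stop_if_errors <- function(errors, context) {
  if (length(errors))
    stop(context, ":\n  - ", paste(errors, collapse = "\n  - "), call. = FALSE)
  invisible(TRUE)
}

is_prob <- function(x) is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x <= 1)

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 0 && x == floor(x)

# Rolling polynomial hash of a character scalar, hex string; used for config
# provenance (content fingerprinting, not cryptographic).
content_hash <- function(x) {
  h <- 5381
  for (b in utf8ToInt(x)) h <- (h * 131 + b) %% 4294967296
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
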