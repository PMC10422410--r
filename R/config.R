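# Run configuration for the command-line entry points: documented
# defaults, strict (unknown-key-rejecting) loading, flag overrides, and a
# provenance hash.

#' Default run configuration
#'
#' @return Named list of every configurable setting with its default:
#'   file paths (`gaze`, `layouts`, `model`, `fis`, `out`), `seed`,
#'   fixation detection (`dispersion_px`, `min_duration_ms`),
#'   normalization (`time_scale_ms`, `ib_cap`), ANFIS hyperparameters
#'   (`epochs`, `train_frac`, `learn_rate`, `ridge`), defuzzification
#'   `resolution`, and `log_level`.
#' @export
etmt_defaults <- function() {
  list(gaze = NULL, layouts = NULL, model = NULL, fis = NULL, out = NULL,
       seed = 1L, dispersion_px = 50, min_duration_ms = 100,
       time_scale_ms = 180000, ib_cap = 3, epochs = 30L,
       train_frac = 0.75, learn_rate = 0.01, ridge = 1e-8,
       resolution = 1e-3, log_level = "info")
}

#' Load a run configuration
#'
#' Reads a JSON (or YAML, by extension) configuration file, validates it
#' against the documented schema — unknown keys are rejected, silent typos
#' must not corrupt scoring — applies flag overrides (which take
#' precedence over file values), and records a provenance hash of the
#' resolved configuration.
#'
#' @param path Optional configuration file; `NULL` means defaults only.
#' @param overrides Named list of values overriding the file (e.g. parsed
#'   command-line flags).
#' @return The resolved configuration (class `etmt_config`) with
#'   attribute `hash`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- etmt_defaults()
  apply_keys <- function(cfg, values, origin) {
    unknown <- setdiff(names(values), names(cfg))
    if (length(unknown)) {
      stop_param("unknown configuration key(s) in ", origin, ": ",
                 paste(unknown, collapse = ", "))
    }
    for (k in names(values)) cfg[[k]] <- values[[k]]
    cfg
  }
  if (!is.null(path)) {
    if (!file.exists(path)) stop_param("config file not found: ", path)
    values <- if (grepl("[.]ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::fromJSON(readLines(path, warn = FALSE),
                         simplifyVector = TRUE)
    }
    cfg <- apply_keys(cfg, as.list(values %||% list()), path)
  }
  cfg <- apply_keys(cfg, overrides, "overrides")
  numeric_keys <- c("seed", "dispersion_px", "min_duration_ms",
                    "time_scale_ms", "ib_cap", "epochs", "train_frac",
                    "learn_rate", "ridge", "resolution")
  bad <- numeric_keys[!vapply(cfg[numeric_keys], function(v) {
    is.numeric(v) && length(v) == 1L && is.finite(v)
  }, logical(1))]
  if (length(bad)) {
    stop_param("configuration key(s) must be single numbers: ",
               paste(bad, collapse = ", "))
  }
  structure(cfg, class = "etmt_config", hash = rlang::hash(cfg))
}

#' @export
print.etmt_config <- function(x, ...) {
  cat("<etmt_config> hash", attr(x, "hash"), "\n")
  for (k in names(x)) {
    cat(sprintf("  %-16s %s\n", k,
                if (is.null(x[[k]])) "<unset>" else format(x[[k]])))
  }
  invisible(x)
}
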