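# Gaze-recording data model and file I/O: raw gaze logs, fixation tables,
# and score reports.

#' Gaze-log dialect
#'
#' Describes how a delimited gaze log maps onto the columns the package
#' needs. Vendor exports differ in delimiters and header names; the default
#' dialect matches the package's own CSV layout
#' `participant,stimulus,timestamp_ms,x_px,y_px,pupil_mm,valid`.
#'
#' @param sep Field delimiter.
#' @param participant,stimulus,timestamp,x,y,pupil,valid Header names of the
#'   corresponding columns. `participant`, `pupil` and `valid` are optional
#'   in the file: a missing participant column yields a single participant
#'   `"P1"`, a missing pupil column yields `NA` diameters, and a missing
#'   valid column marks every sample valid.
#' @return A named list of class `etmt_dialect`.
#' @export
gaze_dialect <- function(sep = ",", participant = "participant",
                         stimulus = "stimulus", timestamp = "timestamp_ms",
                         x = "x_px", y = "y_px", pupil = "pupil_mm",
                         valid = "valid") {
  structure(list(sep = sep, participant = participant, stimulus = stimulus,
                 timestamp = timestamp, x = x, y = y, pupil = pupil,
                 valid = valid),
            class = "etmt_dialect")
}

#' Construct a trial record
#'
#' One trial is one participant viewing one TMT stimulus: an ordered stream
#' of gaze samples, optionally with pre-detected fixations. Timestamps are
#' milliseconds; coordinates are screen pixels (origin top-left, y down).
#'
#' @param participant_id,stimulus_id Identifying tokens.
#' @param samples Data frame with columns `timestamp_ms`, `x_px`, `y_px`,
#'   `pupil_mm`, `valid`, ordered by timestamp.
#' @param fixations Optional fixation data frame (see [detect_fixations()]).
#' @param trial_start,trial_end Trial bounds in ms; default to the sample
#'   timestamp range.
#' @return An object of class `etmt_trial`.
#' @export
trial_record <- function(participant_id, stimulus_id, samples,
                         fixations = NULL, trial_start = NULL,
                         trial_end = NULL) {
  stopifnot(is.data.frame(samples))
  req <- c("timestamp_ms", "x_px", "y_px")
  miss <- setdiff(req, names(samples))
  if (length(miss)) stop_param("samples lack column(s): ",
                               paste(miss, collapse = ", "))
  if (is.null(samples$valid)) samples$valid <- TRUE
  if (is.null(samples$pupil_mm)) samples$pupil_mm <- NA_real_
  if (is.unsorted(samples$timestamp_ms)) {
    samples <- samples[order(samples$timestamp_ms), , drop = FALSE]
  }
  trial_start <- trial_start %||%
    (if (nrow(samples)) min(samples$timestamp_ms) else 0)
  trial_end <- trial_end %||%
    (if (nrow(samples)) max(samples$timestamp_ms) else 0)
  if (trial_end < trial_start) stop_param("trial_end must be >= trial_start")
  structure(list(participant_id = as.character(participant_id),
                 stimulus_id = as.character(stimulus_id),
                 samples = samples, fixations = fixations,
                 trial_start = as.numeric(trial_start),
                 trial_end = as.numeric(trial_end)),
            class = "etmt_trial")
}

#' @export
print.etmt_trial <- function(x, ...) {
  cat(sprintf("<etmt_trial> %s / %s: %d samples, %s fixations, %.0f ms\n",
              x$participant_id, x$stimulus_id, nrow(x$samples),
              if (is.null(x$fixations)) "?" else nrow(x$fixations),
              x$trial_end - x$trial_start))
  invisible(x)
}

#' Read a delimited gaze log
#'
#' Parses a delimited gaze log into one [trial_record()] per
#' (participant, stimulus) pair. Invalid samples are retained with
#' `valid = FALSE`; they later break fixation runs rather than being
#' interpolated.
#'
#' @param path Path of the delimited text file (with header).
#' @param dialect A [gaze_dialect()].
#' @return A list of `etmt_trial` objects.
#' @export
read_gaze_log <- function(path, dialect = gaze_dialect()) {
  if (!file.exists(path)) stop_param("gaze log not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = dialect$sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE)
  for (col in c("timestamp", "stimulus", "x", "y")) {
    if (!(dialect[[col]] %in% names(raw))) {
      stop_param("gaze log is missing required column '", dialect[[col]], "'")
    }
  }
  n <- nrow(raw)
  part <- if (dialect$participant %in% names(raw)) {
    raw[[dialect$participant]]
  } else rep("P1", n)
  valid <- if (dialect$valid %in% names(raw)) {
    tolower(raw[[dialect$valid]]) %in% c("true", "t", "1", "yes")
  } else rep(TRUE, n)
  num_col <- function(name, what, required_when_valid) {
    v <- suppressWarnings(as.numeric(raw[[name]]))
    bad <- which(is.na(v) & required_when_valid)
    if (length(bad)) {
      stop_param("non-numeric ", what, " in gaze log at line ",
                 bad[1] + 1L, " (column '", name, "')")
    }
    v
  }
  ts <- num_col(dialect$timestamp, "timestamp", rep(TRUE, n))
  x <- num_col(dialect$x, "x coordinate", valid)
  y <- num_col(dialect$y, "y coordinate", valid)
  pupil <- if (dialect$pupil %in% names(raw)) {
    suppressWarnings(as.numeric(raw[[dialect$pupil]]))
  } else rep(NA_real_, n)
  df <- data.frame(participant = part, stimulus = raw[[dialect$stimulus]],
                   timestamp_ms = ts, x_px = x, y_px = y, pupil_mm = pupil,
                   valid = valid, stringsAsFactors = FALSE)
  keys <- unique(df[, c("participant", "stimulus")])
  trials <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- df[df$participant == keys$participant[i] &
                df$stimulus == keys$stimulus[i], , drop = FALSE]
    sub <- sub[order(sub$timestamp_ms), , drop = FALSE]
    rownames(sub) <- NULL
    trials[[i]] <- trial_record(keys$participant[i], keys$stimulus[i],
                                sub[, c("timestamp_ms", "x_px", "y_px",
                                        "pupil_mm", "valid")])
  }
  trials
}

#' Write trials back to the gaze-log CSV dialect
#'
#' @param trials A list of `etmt_trial` objects (or a single one).
#' @param path Output path.
#' @param dialect A [gaze_dialect()].
#' @return `path`, invisibly.
#' @export
write_gaze_log <- function(trials, path, dialect = gaze_dialect()) {
  if (inherits(trials, "etmt_trial")) trials <- list(trials)
  rows <- lapply(trials, function(tr) {
    s <- tr$samples
    data.frame(participant = tr$participant_id, stimulus = tr$stimulus_id,
               timestamp_ms = s$timestamp_ms, x_px = s$x_px, y_px = s$y_px,
               pupil_mm = s$pupil_mm, valid = s$valid,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  names(out) <- vapply(c("participant", "stimulus", "timestamp", "x", "y",
                         "pupil", "valid"),
                       function(k) dialect[[k]], character(1))
  utils::write.table(out, path, sep = dialect$sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Detect fixations with the dispersion-threshold (I-DT) algorithm
#'
#' A fixation is a maximal run of consecutive *valid* samples whose bounding
#' box satisfies width + height <= `dispersion_px` and whose time span is at
#' least `min_duration_ms`. Invalid samples break runs. The detector is
#' deterministic and idempotent.
#'
#' @param samples Data frame with `timestamp_ms`, `x_px`, `y_px` and
#'   optionally `valid` (default all valid), ordered by timestamp.
#' @param dispersion_px Maximum bounding-box dispersion (width + height), px.
#' @param min_duration_ms Minimum fixation span, ms.
#' @return Data frame with columns `onset_ms`, `duration_ms`, `cx_px`,
#'   `cy_px`, ordered by onset and non-overlapping.
#' @export
detect_fixations <- function(samples, dispersion_px = 50,
                             min_duration_ms = 100) {
  if (!is.numeric(dispersion_px) || dispersion_px <= 0) {
    stop_param("dispersion_px must be > 0")
  }
  if (!is.numeric(min_duration_ms) || min_duration_ms <= 0) {
    stop_param("min_duration_ms must be > 0")
  }
  empty <- data.frame(onset_ms = numeric(0), duration_ms = numeric(0),
                      cx_px = numeric(0), cy_px = numeric(0))
  if (is.null(samples) || nrow(samples) == 0) return(empty)
  valid <- if (is.null(samples$valid)) rep(TRUE, nrow(samples)) else
    samples$valid
  valid <- valid & is.finite(samples$x_px) & is.finite(samples$y_px)
  runs <- rle(valid)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    idx <- starts[k]:ends[k]
    out[[length(out) + 1L]] <- idt_scan(samples$timestamp_ms[idx],
                                        samples$x_px[idx],
                                        samples$y_px[idx],
                                        dispersion_px, min_duration_ms)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  if (is.null(res) || !nrow(res)) empty else res
}

# Core I-DT scan over one run of consecutive valid samples.
idt_scan <- function(t, x, y, dispersion_px, min_duration_ms) {
  n <- length(t)
  res <- list()
  i <- 1L
  while (i <= n) {
    # grow the window until it spans at least min_duration_ms
    j <- i
    while (j < n && (t[j] - t[i]) < min_duration_ms) j <- j + 1L
    if ((t[j] - t[i]) < min_duration_ms) break
    win_x <- range(x[i:j]); win_y <- range(y[i:j])
    disp <- (win_x[2] - win_x[1]) + (win_y[2] - win_y[1])
    if (disp <= dispersion_px) {
      # extend while dispersion stays below threshold
      while (j < n) {
        nx <- range(win_x[1], win_x[2], x[j + 1L])
        ny <- range(win_y[1], win_y[2], y[j + 1L])
        if ((nx[2] - nx[1]) + (ny[2] - ny[1]) > dispersion_px) break
        j <- j + 1L
        win_x <- nx; win_y <- ny
      }
      res[[length(res) + 1L]] <- data.frame(
        onset_ms = t[i], duration_ms = t[j] - t[i],
        cx_px = mean(x[i:j]), cy_px = mean(y[i:j]))
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(res)) do.call(rbind, res) else NULL
}

#' Read or write a fixation table
#'
#' CSV with columns `participant,stimulus,onset_ms,duration_ms,cx_px,cy_px`.
#'
#' @param fixations Data frame of fixations plus `participant` and
#'   `stimulus` columns.
#' @param path File path.
#' @return `read_fixation_table` returns the data frame;
#'   `write_fixation_table` returns `path` invisibly.
#' @export
write_fixation_table <- function(fixations, path) {
  utils::write.csv(fixations, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_fixation_table
#' @export
read_fixation_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Construct a score report
#'
#' The per-participant output of the scoring pipeline: the 13-entry feature
#' vector, the three scores with bands, deficit flags, and provenance.
#'
#' @param participant_id Token.
#' @param features Named numeric vector of the 13 features (FL1..FH4).
#' @param vss_score,fa_score,ci_score Scores in \[0, 1\].
#' @param bands Named character vector (`vss`, `fa`, `ci`), each
#'   low/medium/high.
#' @param flags Named character vector of deficit grades (see
#'   [deficit_flags()]).
#' @param provenance List of scalar provenance entries (seeds, config hash,
#'   trial coverage).
#' @return An object of class `etmt_report`.
#' @export
score_report <- function(participant_id, features, vss_score, fa_score,
                         ci_score, bands, flags, provenance = list()) {
  structure(list(participant_id = as.character(participant_id),
                 features = features, vss_score = as.numeric(vss_score),
                 fa_score = as.numeric(fa_score),
                 ci_score = as.numeric(ci_score),
                 bands = bands, flags = flags, provenance = provenance),
            class = "etmt_report")
}

#' @export
print.etmt_report <- function(x, ...) {
  cat(sprintf(paste0("<etmt_report> %s: visual search speed %.3f (%s), ",
                     "focused attention %.3f (%s), cognitive impairment ",
                     "%.3f (%s)\n"),
              x$participant_id, x$vss_score, x$bands[["vss"]],
              x$fa_score, x$bands[["fa"]], x$ci_score, x$bands[["ci"]]))
  invisible(x)
}

report_to_list <- function(r) {
  list(participant_id = r$participant_id,
       features = as.list(r$features),
       vss_score = r$vss_score, fa_score = r$fa_score,
       ci_score = r$ci_score,
       bands = as.list(r$bands), flags = as.list(r$flags),
       provenance = r$provenance)
}

list_to_report <- function(l) {
  score_report(l$participant_id,
               features = unlist(l$features),
               vss_score = l$vss_score, fa_score = l$fa_score,
               ci_score = l$ci_score,
               bands = unlist(l$bands), flags = unlist(l$flags),
               provenance = l$provenance)
}

#' Write or read score reports
#'
#' Reports are stored as a JSON array with full numeric precision so a
#' write/read round trip reproduces the reports exactly.
#' [write_scores_csv()] writes a flat one-row-per-participant CSV instead.
#'
#' @param reports A list of [score_report()] objects (or one report).
#' @param path File path.
#' @return `read_scores` returns a list of reports; the writers return
#'   `path` invisibly.
#' @export
write_scores <- function(reports, path) {
  if (inherits(reports, "etmt_report")) reports <- list(reports)
  payload <- lapply(reports, report_to_list)
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  payload <- jsonlite::fromJSON(readLines(path, warn = FALSE),
                                simplifyVector = FALSE)
  lapply(payload, list_to_report)
}

#' @rdname write_scores
#' @export
write_scores_csv <- function(reports, path) {
  if (inherits(reports, "etmt_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    cbind(data.frame(participant_id = r$participant_id,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(r$features)),
          data.frame(vss_score = r$vss_score, fa_score = r$fa_score,
                     ci_score = r$ci_score,
                     vss_band = r$bands[["vss"]], fa_band = r$bands[["fa"]],
                     ci_band = r$bands[["ci"]], stringsAsFactors = FALSE))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
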