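# The thirteen fixation-based features: low-level fixation statistics
# (FL1-FL4), per-AOI middle-level metrics (FM1-FM5), and high-level
# scanpath-derived features (FH1-FH4).

FEATURE_NAMES <- c("FL1", "FL2", "FL3", "FL4",
                   "FM1", "FM2", "FM3", "FM4", "FM5",
                   "FH1", "FH2", "FH3", "FH4")

#' Low-level fixation features
#'
#' FL1 = fixation count, FL2 = total fixation time (ms), FL3 = fixation
#' time as a percentage of the trial duration, FL4 = mean fixation
#' duration (ms, 0 when there are no fixations).
#'
#' @param fixations Fixation data frame (see [detect_fixations()]).
#' @param trial_duration Trial duration in ms (> 0).
#' @return Named numeric vector `FL1..FL4`.
#' @export
low_level <- function(fixations, trial_duration) {
  if (!is.numeric(trial_duration) || trial_duration <= 0) {
    stop_param("trial_duration must be > 0")
  }
  n <- if (is.null(fixations)) 0L else nrow(fixations)
  total <- if (n) sum(fixations$duration_ms) else 0
  c(FL1 = n, FL2 = total, FL3 = 100 * total / trial_duration,
    FL4 = if (n) total / n else 0)
}

# Map each fixation centroid to an AOI label (NA when outside every AOI).
fixation_hits <- function(fixations, layout) {
  if (is.null(fixations) || nrow(fixations) == 0) return(character(0))
  vapply(seq_len(nrow(fixations)), function(i) {
    aoi_hit(layout, fixations$cx_px[i], fixations$cy_px[i])
  }, character(1))
}

#' Per-AOI middle-level features
#'
#' For each AOI: FM1 = dwell time (ms), FM2 = dwell percentage of the
#' trial, FM3 = glances (count of fixations inside), FM4 = revisits
#' (distinct visit runs minus one; a visit run is a maximal streak of
#' consecutive fixations in the same AOI), FM5 = duration of the first
#' fixation inside. AOIs never fixated get all-zero rows.
#'
#' @inheritParams low_level
#' @param layout An [make_layout()] layout.
#' @return Data frame with one row per AOI: `label`, `FM1..FM5`.
#' @export
aoi_level <- function(fixations, layout, trial_duration) {
  if (!is.numeric(trial_duration) || trial_duration <= 0) {
    stop_param("trial_duration must be > 0")
  }
  hits <- fixation_hits(fixations, layout)
  labels <- layout$aois$label
  runs <- if (length(hits)) {
    rle(ifelse(is.na(hits), "<out>", hits))$values
  } else character(0)
  out <- lapply(labels, function(lab) {
    in_aoi <- which(!is.na(hits) & hits == lab)
    n_runs <- sum(runs == lab)
    data.frame(label = lab,
               FM1 = if (length(in_aoi)) sum(fixations$duration_ms[in_aoi])
                     else 0,
               FM2 = 0, # filled below
               FM3 = length(in_aoi),
               FM4 = max(0L, n_runs - 1L),
               FM5 = if (length(in_aoi))
                       fixations$duration_ms[in_aoi[1]] else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$FM2 <- 100 * res$FM1 / trial_duration
  res
}

#' Scanpath string of a trial
#'
#' Maps each fixation, in onset order, to the label of the AOI containing
#' its centroid; fixations outside every AOI contribute nothing. By default
#' consecutive duplicate labels are collapsed to one token, so the string
#' records the order of AOI visits rather than individual fixations (dwell
#' is already captured by the middle-level features); set
#' `collapse = FALSE` for one token per in-AOI fixation.
#'
#' @inheritParams aoi_level
#' @param collapse Collapse consecutive duplicate tokens?
#' @return Character vector of AOI labels.
#' @export
scanpath_string <- function(fixations, layout, collapse = TRUE) {
  hits <- fixation_hits(fixations, layout)
  tokens <- hits[!is.na(hits)]
  if (collapse && length(tokens)) tokens <- rle(tokens)$values
  tokens
}

#' Token-level Levenshtein distance
#'
#' Minimum number of token insertions, deletions and substitutions (unit
#' costs) transforming `a` into `b`. Tokens are atomic, so multi-character
#' target labels such as "12" cost a single edit.
#'
#' @param a,b Character vectors of tokens.
#' @return Integer edit distance.
#' @export
levenshtein <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  n <- length(a); m <- length(b)
  if (n == 0L) return(m)
  if (m == 0L) return(n)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- integer(m + 1L)
    cur[1L] <- i
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j + 1L] + 1L, cur[j] + 1L,
                         prev[j] + (a[i] != b[j]))
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Scanpath score (FH1)
#'
#' The Levenshtein distance between the observed scanpath string and the
#' layout's expected visiting sequence.
#'
#' @param observed Character vector of observed AOI tokens.
#' @param layout An [make_layout()] layout.
#' @return Integer scanpath score.
#' @export
scanpath_score <- function(observed, layout) {
  levenshtein(observed, layout$expected_sequence)
}

#' Total completion time (FH2)
#'
#' Duration of one trial, or the summed duration of a list of trials
#' (a whole session).
#'
#' @param trial An `etmt_trial`, or a list of them.
#' @return Duration in ms.
#' @export
total_time <- function(trial) {
  if (inherits(trial, "etmt_trial")) {
    if (nrow(trial$samples) == 0 && is.null(trial$fixations)) {
      stop_param("empty trial: no samples or fixations")
    }
    return(trial$trial_end - trial$trial_start)
  }
  sum(vapply(trial, total_time, numeric(1)))
}

#' Error rate (FH3)
#'
#' Counts two kinds of mistakes: fixations that fall outside every AOI, and
#' wrong visits on the collapsed scanpath. Wrong visits are counted with a
#' pointer walk along the expected sequence: a token equal to the next
#' expected label advances the pointer, any other token counts one error.
#'
#' @inheritParams aoi_level
#' @return Integer error count.
#' @export
error_rate <- function(fixations, layout) {
  hits <- fixation_hits(fixations, layout)
  out_of_aoi <- sum(is.na(hits))
  tokens <- scanpath_string(fixations, layout, collapse = TRUE)
  out_of_aoi + wrong_token_count(tokens, layout$expected_sequence)
}

# Pointer walk over the collapsed scanpath against the expected sequence.
wrong_token_count <- function(tokens, expected) {
  ptr <- 1L
  wrong <- 0L
  for (tok in tokens) {
    if (ptr <= length(expected) && tok == expected[ptr]) {
      ptr <- ptr + 1L
    } else {
      wrong <- wrong + 1L
    }
  }
  wrong
}

#' Inattentional blindness (FH4)
#'
#' Counts repeated contiguous patterns in the scanpath: scanning left to
#' right, at position i the longest run of at least `min_pattern_len`
#' tokens starting at i that also occurs earlier in the sequence (ending
#' before i) counts one event, and the scan jumps past it; otherwise the
#' scan advances one token. Re-viewing a run of already-visited targets
#' without registering them is the behavioural signature this captures;
#' single-token revisits are below the default minimum pattern length and
#' do not count.
#'
#' @param scanpath Character vector of AOI tokens.
#' @param min_pattern_len Minimum repeated-run length (>= 1).
#' @return Integer count of repeated-pattern events.
#' @export
inattentional_blindness <- function(scanpath, min_pattern_len = 2L) {
  if (!is_count(min_pattern_len) || min_pattern_len < 1) {
    stop_param("min_pattern_len must be a positive integer")
  }
  scanpath <- as.character(scanpath)
  n <- length(scanpath)
  count <- 0L
  i <- 1L
  while (i <= n) {
    best <- 0L
    len <- min_pattern_len
    # if a pattern of length L has no earlier occurrence, no longer pattern
    # starting at i can have one (its prefix would), so stop at first miss
    while (i + len - 1L <= n) {
      if (occurs_before(scanpath, i, len)) best <- len else break
      len <- len + 1L
    }
    if (best >= min_pattern_len) {
      count <- count + 1L
      i <- i + best
    } else {
      i <- i + 1L
    }
  }
  count
}

# Does scanpath[i:(i+len-1)] occur as a contiguous run ending before i?
occurs_before <- function(scanpath, i, len) {
  pat <- scanpath[i:(i + len - 1L)]
  last_start <- i - len # occurrence must end at i-1 or earlier
  if (last_start < 1L) return(FALSE)
  for (j in seq_len(last_start)) {
    if (all(scanpath[j:(j + len - 1L)] == pat)) return(TRUE)
  }
  FALSE
}

# Per-trial feature row: FL, aggregated FM, FH.
trial_features <- function(trial, layout, dispersion_px = 50,
                           min_duration_ms = 100) {
  fix <- trial$fixations %||%
    detect_fixations(trial$samples, dispersion_px, min_duration_ms)
  dur <- max(trial$trial_end - trial$trial_start, 1e-9)
  fl <- low_level(fix, dur)
  fm <- aoi_level(fix, layout, dur)
  tokens <- scanpath_string(fix, layout)
  c(fl,
    FM1 = sum(fm$FM1), FM2 = mean(fm$FM2), FM3 = sum(fm$FM3),
    FM4 = sum(fm$FM4), FM5 = mean(fm$FM5),
    FH1 = scanpath_score(tokens, layout),
    FH2 = trial$trial_end - trial$trial_start,
    FH3 = error_rate(fix, layout),
    FH4 = inattentional_blindness(tokens))
}

#' Assemble the 13-entry feature vector for one participant
#'
#' Computes the per-trial features for each of the participant's trials
#' and aggregates them into one vector: counts and times (FL1, FL2, FM1,
#' FM3, FM4, FH1-FH4) are summed across trials, percentages and averages
#' (FL3, FL4, FM2, FM5) are averaged. FM features are first aggregated
#' across AOIs within a trial (sums for FM1/FM3/FM4, means over all AOIs
#' for FM2/FM5). A participant missing trials is aggregated over the
#' available ones with a warning, and the coverage is recorded in the
#' provenance attribute.
#'
#' @param trials List of `etmt_trial` objects for one participant.
#' @param layouts Named list of layouts keyed by stimulus id.
#' @param expected_stimuli Stimulus ids the session should contain.
#' @param dispersion_px,min_duration_ms Fixation-detection parameters used
#'   when a trial carries no pre-detected fixations.
#' @return One-row data frame `participant_id`, `FL1..FH4`, with a
#'   `provenance` attribute recording trial coverage and the aggregation
#'   rule.
#' @export
assemble_features <- function(trials, layouts,
                              expected_stimuli = names(layouts),
                              dispersion_px = 50, min_duration_ms = 100) {
  if (!length(trials)) stop_param("no trials supplied")
  stim <- vapply(trials, function(tr) tr$stimulus_id, character(1))
  missing <- setdiff(expected_stimuli, stim)
  if (length(missing)) {
    warning("participant ", trials[[1]]$participant_id,
            " is missing trial(s): ", paste(missing, collapse = ", "),
            "; aggregating over available trials", call. = FALSE)
  }
  rows <- do.call(rbind, lapply(trials, function(tr) {
    if (!tr$stimulus_id %in% names(layouts)) {
      stop_param("no layout for stimulus ", tr$stimulus_id)
    }
    trial_features(tr, layouts[[tr$stimulus_id]], dispersion_px,
                   min_duration_ms)
  }))
  summed <- c("FL1", "FL2", "FM1", "FM3", "FM4", "FH1", "FH2", "FH3", "FH4")
  averaged <- c("FL3", "FL4", "FM2", "FM5")
  vec <- numeric(length(FEATURE_NAMES))
  names(vec) <- FEATURE_NAMES
  vec[summed] <- colSums(rows[, summed, drop = FALSE])
  vec[averaged] <- colMeans(rows[, averaged, drop = FALSE])
  out <- cbind(data.frame(participant_id = trials[[1]]$participant_id,
                          stringsAsFactors = FALSE),
               as.data.frame(as.list(vec)))
  attr(out, "provenance") <- list(
    n_trials = length(trials), stimuli = stim,
    complete = length(missing) == 0,
    aggregation = "sums: FL1,FL2,FM1,FM3,FM4,FH1-FH4; means: FL3,FL4,FM2,FM5")
  out
}

#' Feature table for a cohort
#'
#' @param participants List of participants, each a list with
#'   `participant_id` and `trials`.
#' @inheritParams assemble_features
#' @return Data frame with one row per participant (13 features + id).
#' @export
feature_table <- function(participants, layouts,
                          expected_stimuli = names(layouts),
                          dispersion_px = 50, min_duration_ms = 100) {
  rows <- lapply(participants, function(p) {
    assemble_features(p$trials, layouts, expected_stimuli,
                      dispersion_px, min_duration_ms)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
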