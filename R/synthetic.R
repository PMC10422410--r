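# Synthetic TMT-session simulator: 60 Hz gaze streams over generated
# layouts with parameterized impairment behaviour (stray fixations,
# revisit runs, slowed search), so every pipeline stage is testable
# without participant data.

#' Impairment behaviour profile
#'
#' Parameterizes how a simulated participant walks a TMT trail.
#'
#' @param dwell_mean_ms,dwell_sd_ms Per-target fixation dwell distribution
#'   (normal, truncated above 120 ms so every emitted dwell survives the
#'   default fixation-detection minimum duration of 100 ms with margin).
#' @param transit_ms Inter-target travel time; travel samples are emitted
#'   as invalid (tracking loss during saccades), so they break fixation
#'   runs.
#' @param stray_prob Per-transition probability of a stray fixation —
#'   either on a wrong target or outside every target.
#' @param revisit_prob Per-transition probability of replaying the run of
#'   the previous two visited targets (an inattentional-blindness event).
#' @param slow_factor Multiplicative time dilation >= 1 applied to dwells
#'   and transits.
#' @param noise_px Gaussian gaze jitter (sd, pixels) around fixation
#'   points.
#' @return Object of class `etmt_profile`.
#' @export
impairment_profile <- function(dwell_mean_ms = 250, dwell_sd_ms = 50,
                               transit_ms = 150, stray_prob = 0.02,
                               revisit_prob = 0.01, slow_factor = 1,
                               noise_px = 5) {
  if (dwell_mean_ms <= 0) stop_param("dwell_mean_ms must be > 0")
  if (stray_prob < 0 || stray_prob > 1) {
    stop_param("stray_prob must be in [0, 1]")
  }
  if (revisit_prob < 0 || revisit_prob > 1) {
    stop_param("revisit_prob must be in [0, 1]")
  }
  if (slow_factor < 1) stop_param("slow_factor must be >= 1")
  structure(list(dwell_mean_ms = dwell_mean_ms, dwell_sd_ms = dwell_sd_ms,
                 transit_ms = transit_ms, stray_prob = stray_prob,
                 revisit_prob = revisit_prob, slow_factor = slow_factor,
                 noise_px = noise_px),
            class = "etmt_profile")
}

#' Default low / medium / high impairment profiles
#'
#' Group separation mirrors the qualitative contrast between an unimpaired
#' performer (clean ascending trail, fast) and an impaired one (stray
#' visits, repeated revisiting of already-seen targets, slowed search).
#'
#' @return Named list of three [impairment_profile()] objects.
#' @export
default_profiles <- function() {
  list(low = impairment_profile(),
       medium = impairment_profile(stray_prob = 0.15, revisit_prob = 0.15,
                                   slow_factor = 1.5),
       high = impairment_profile(stray_prob = 0.35, revisit_prob = 0.35,
                                 slow_factor = 2.5))
}

# Normal draw truncated below at `lower` (rejection with a bounded loop).
rtruncnorm1 <- function(mean, sd, lower = 120) {
  for (i in 1:100) {
    v <- stats::rnorm(1, mean, sd)
    if (v > lower) return(v)
  }
  lower + 1
}

# Random point outside every AOI by a wide margin, so it can neither hit a
# target nor merge with an adjacent target fixation under I-DT.
stray_point <- function(layout, margin) {
  a <- layout$aois
  for (i in 1:1000) {
    px <- stats::runif(1, 0, layout$width)
    py <- stats::runif(1, 0, layout$height)
    if (all(sqrt((a$cx - px)^2 + (a$cy - py)^2) > a$radius + margin)) {
      return(c(px, py))
    }
  }
  c(0, 0) # canvas corner is clear of AOIs by construction margins
}

#' Simulate one TMT trial
#'
#' Walks the layout's expected sequence emitting a fixation per target; at
#' each transition a stray fixation is inserted with probability
#' `stray_prob` (60% a wrong target — never the previous or next expected
#' one, so each stray yields exactly one countable error — and 40% an
#' out-of-AOI point) and the previous two visited targets are replayed
#' with probability `revisit_prob`. Gaze samples are emitted at `rate_hz`
#' with Gaussian jitter; inter-target transit samples are emitted as
#' invalid. Fully reproducible from `seed`.
#'
#' @param profile An [impairment_profile()].
#' @param layout An [make_layout()] layout.
#' @param participant_id Token recorded on the trial.
#' @param rate_hz Sampling rate (the simulated tracker runs at 60 Hz).
#' @param seed Integer seed.
#' @return An `etmt_trial` (fixations not pre-detected).
#' @export
simulate_trial <- function(profile, layout, participant_id = "sim",
                           rate_hz = 60, seed = 1L) {
  stopifnot(inherits(profile, "etmt_profile"),
            inherits(layout, "etmt_layout"))
  exp_seq <- layout$expected_sequence
  centers <- layout$aois
  aoi_xy <- function(label) {
    i <- match(label, centers$label)
    c(centers$cx[i], centers$cy[i])
  }
  with_seed(seed, {
    # plan the fixation itinerary
    plan <- list()
    visited <- character(0)
    for (k in seq_along(exp_seq)) {
      if (k > 1L) {
        if (stats::runif(1) < profile$stray_prob) {
          if (stats::runif(1) < 0.6) {
            pool <- setdiff(centers$label,
                            c(exp_seq[k], visited[length(visited)]))
            lab <- pool[sample.int(length(pool), 1L)]
            plan[[length(plan) + 1L]] <- list(xy = aoi_xy(lab))
          } else {
            plan[[length(plan) + 1L]] <- list(
              xy = stray_point(layout, margin = 50 + 20))
          }
        }
        if (stats::runif(1) < profile$revisit_prob &&
              length(visited) >= 2L) {
          nb <- length(visited)
          plan[[length(plan) + 1L]] <- list(xy = aoi_xy(visited[nb - 1L]))
          plan[[length(plan) + 1L]] <- list(xy = aoi_xy(visited[nb]))
        }
      }
      plan[[length(plan) + 1L]] <- list(xy = aoi_xy(exp_seq[k]))
      visited <- c(visited, exp_seq[k])
    }
    # realize the gaze stream
    dt <- 1000 / rate_hz
    t <- 0
    rows <- vector("list", length(plan))
    prev_xy <- NULL
    for (j in seq_along(plan)) {
      xy <- plan[[j]]$xy
      if (!is.null(prev_xy)) {
        transit <- profile$transit_ms * profile$slow_factor
        n_t <- floor(transit / dt)
        if (n_t > 0) {
          frac <- seq_len(n_t) / (n_t + 1)
          rows[[length(rows) + 1L]] <- data.frame(
            timestamp_ms = t + (seq_len(n_t) - 1L) * dt,
            x_px = prev_xy[1] + frac * (xy[1] - prev_xy[1]),
            y_px = prev_xy[2] + frac * (xy[2] - prev_xy[2]),
            pupil_mm = NA_real_, valid = FALSE)
        }
        t <- t + transit
      }
      dwell <- rtruncnorm1(profile$dwell_mean_ms, profile$dwell_sd_ms) *
        profile$slow_factor
      n_s <- max(2L, floor(dwell / dt) + 1L)
      rows[[j]] <- data.frame(
        timestamp_ms = t + (seq_len(n_s) - 1L) * dt,
        x_px = xy[1] + stats::rnorm(n_s, 0, profile$noise_px),
        y_px = xy[2] + stats::rnorm(n_s, 0, profile$noise_px),
        pupil_mm = 3.5 + stats::rnorm(n_s, 0, 0.05),
        valid = TRUE)
      t <- t + dwell
      prev_xy <- xy
    }
    samples <- do.call(rbind, rows)
    samples <- samples[order(samples$timestamp_ms), , drop = FALSE]
    rownames(samples) <- NULL
    trial_record(participant_id, layout$stimulus_id, samples,
                 trial_start = 0, trial_end = t)
  })
}

#' Cohort specification
#'
#' @param n_per_group Participants per impairment group (>= 1).
#' @param profiles Named list of [impairment_profile()]s, keys `low`,
#'   `medium`, `high`.
#' @param seed Integer master seed.
#' @return Object of class `etmt_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 10L, profiles = default_profiles(),
                        seed = 1L) {
  stopifnot(n_per_group >= 1,
            setequal(names(profiles), c("low", "medium", "high")))
  structure(list(n_per_group = as.integer(n_per_group), profiles = profiles,
                 seed = as.integer(seed)),
            class = "etmt_cohort_spec")
}

#' Simulate a cohort of ETMT sessions
#'
#' Simulates `n_per_group` participants per impairment group, each viewing
#' all four stimuli; the generating group is retained as ground truth for
#' recovery experiments.
#'
#' @param spec A [cohort_spec()].
#' @param layouts Named list of the four layouts ([make_layout_set()]).
#' @param rate_hz Sampling rate.
#' @return List with `participants` (each a list `participant_id`,
#'   `group`, `trials`) and the named character vector `groups`.
#' @export
simulate_cohort <- function(spec, layouts, rate_hz = 60) {
  stopifnot(inherits(spec, "etmt_cohort_spec"))
  groups <- rep(c("low", "medium", "high"), each = spec$n_per_group)
  n <- length(groups)
  ids <- sprintf("S%03d", seq_len(n))
  seeds <- matrix(derive_seeds(spec$seed, n * length(layouts)), n)
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    trials <- vector("list", length(layouts))
    for (j in seq_along(layouts)) {
      trials[[j]] <- simulate_trial(spec$profiles[[groups[i]]],
                                    layouts[[j]], participant_id = ids[i],
                                    rate_hz = rate_hz, seed = seeds[i, j])
    }
    participants[[i]] <- list(participant_id = ids[i], group = groups[i],
                              trials = trials)
  }
  names(groups) <- ids
  list(participants = participants, groups = groups)
}
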