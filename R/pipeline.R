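# Orchestration of the full flow: gaze -> fixations -> features -> two
# fuzzy scores -> ANFIS cognitive-impairment score -> report.

#' Score one ETMT session
#'
#' Runs the deterministic composition of the pipeline stages for one
#' participant: fixation detection (when trials carry none), feature
#' assembly, the two Mamdani scores, the ANFIS cognitive-impairment score,
#' bands, and deficit flags.
#'
#' @param trials List of the participant's `etmt_trial` objects.
#' @param layouts Named list of layouts keyed by stimulus id.
#' @param anfis_model A trained `etmt_anfis`.
#' @param vss_fis,fa_fis Optional scoring systems; defaults are built from
#'   the session's layouts (normalization scale = summed expected-sequence
#'   length).
#' @param dispersion_px,min_duration_ms Fixation-detection parameters.
#' @param time_scale_ms,ib_cap Normalization scales for the default
#'   scoring systems.
#' @param resolution Defuzzification grid step.
#' @return A [score_report()].
#' @export
run_session <- function(trials, layouts, anfis_model, vss_fis = NULL,
                        fa_fis = NULL, dispersion_px = 50,
                        min_duration_ms = 100, time_scale_ms = 180000,
                        ib_cap = 3, resolution = 1e-3) {
  if (!length(trials)) stop_param("run_session: no trials supplied")
  seq_scale <- session_sequence_length(layouts)
  vss_fis <- vss_fis %||% build_vss_fis(seq_scale, time_scale_ms)
  fa_fis <- fa_fis %||% build_fa_fis(seq_scale, ib_cap)
  fv_row <- assemble_features(trials, layouts,
                              dispersion_px = dispersion_px,
                              min_duration_ms = min_duration_ms)
  fv <- unlist(fv_row[1, FEATURE_NAMES])
  vss <- fis_score(vss_fis, fv[["FH1"]], fv[["FH2"]], resolution)
  fa <- fis_score(fa_fis, fv[["FH3"]], fv[["FH4"]], resolution)
  ci <- score_participant(anfis_model, fv)
  prov <- attr(fv_row, "provenance")
  config <- list(dispersion_px = dispersion_px,
                 min_duration_ms = min_duration_ms,
                 time_scale_ms = time_scale_ms, ib_cap = ib_cap,
                 resolution = resolution, scan_scale = seq_scale)
  score_report(fv_row$participant_id[1], fv,
               vss_score = vss, fa_score = fa, ci_score = ci$score,
               bands = c(vss = score_band(vss), fa = score_band(fa),
                         ci = ci$band),
               flags = deficit_flags(vss, fa),
               provenance = c(prov[c("n_trials", "complete")],
                              list(config_hash = rlang::hash(config))))
}

# Total expected-sequence length across a session's stimuli.
session_sequence_length <- function(layouts) {
  sum(vapply(layouts, function(l) length(l$expected_sequence), numeric(1)))
}

#' Fit the scoring model on a cohort and score every participant
#'
#' Assembles the cohort feature table, labels it with k-means
#' ([kmeans_label()]), initializes and trains the ANFIS
#' ([anfis_train()]), then produces a per-participant report with the
#' trained model.
#'
#' @param participants List of participants (each a list `participant_id`,
#'   `trials`), e.g. from [simulate_cohort()].
#' @param layouts Named list of layouts.
#' @param seed Seed driving clustering and the train/test split.
#' @param epochs Training epochs.
#' @param train_frac Training fraction.
#' @param ... Passed to [run_session()] for the per-participant reports.
#' @return List with `model`, `dataset`, `features` (the cohort table),
#'   `reports`, `train_stats`, `test_stats`, `history`.
#' @export
fit_cohort <- function(participants, layouts, seed = 1L, epochs = 30L,
                       train_frac = 0.75, ...) {
  if (length(participants) < 8) {
    stop_param("need at least 8 participants to fit a cohort")
  }
  feats <- feature_table(participants, layouts)
  dataset <- kmeans_label(feats, k = 3L, seed = seed)
  fit <- anfis_train(anfis_init(dataset), dataset, epochs = epochs,
                     train_frac = train_frac, seed = seed)
  reports <- lapply(participants, function(p) {
    run_session(p$trials, layouts, anfis_model = fit$model, ...)
  })
  names(reports) <- vapply(participants, `[[`, character(1),
                           "participant_id")
  list(model = fit$model, dataset = dataset, features = feats,
       reports = reports, train_stats = fit$train_stats,
       test_stats = fit$test_stats, history = fit$history)
}
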