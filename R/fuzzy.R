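# Mamdani fuzzy-inference engine and the two configured scoring systems:
# visual search speed (inputs FH1, FH2) and focused attention (FH3, FH4).
# Each system has 2 inputs with 3 trapezoidal sets each, 1 output, and a
# complete 9-rule base; min AND, min implication, max aggregation, centroid
# defuzzification on a uniform grid.

#' Trapezoidal membership function
#'
#' @param a,b,c,d Breakpoints with a <= b <= c <= d: membership is 0
#'   outside \[a, d\], 1 on \[b, c\], and linear on the edges. Degenerate
#'   edges (a == b or c == d) are vertical steps.
#' @return Object of class `etmt_trapmf`.
#' @export
trapezoid_mf <- function(a, b, c, d) {
  v <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(v)) || is.unsorted(v)) {
    stop_param("trapezoid breakpoints must be finite and ordered a<=b<=c<=d")
  }
  structure(v, class = "etmt_trapmf")
}

#' Membership degree of a trapezoid
#'
#' @param mf A [trapezoid_mf()].
#' @param x Numeric vector of evaluation points.
#' @return Degrees in \[0, 1\], vectorized over `x`.
#' @export
trapezoid_membership <- function(mf, x) {
  a <- mf[["a"]]; b <- mf[["b"]]; cc <- mf[["c"]]; d <- mf[["d"]]
  out <- numeric(length(x))
  plateau <- x >= b & x <= cc
  out[plateau] <- 1
  rise <- x > a & x < b
  out[rise] <- (x[rise] - a) / (b - a)
  fall <- x > cc & x < d
  out[fall] <- (d - x[fall]) / (d - cc)
  out
}

#' Fuzzy variable with three linguistic sets
#'
#' @param name Variable name.
#' @param universe Numeric `c(lo, hi)` range.
#' @param sets Named list of three [trapezoid_mf()] (low, medium, high);
#'   together the sets must cover the universe (every point has positive
#'   membership in at least one set).
#' @return Object of class `etmt_fuzzyvar`.
#' @export
fuzzy_variable <- function(name, universe = c(0, 1),
                           sets = default_partition()) {
  stopifnot(length(universe) == 2, universe[1] < universe[2],
            length(sets) == 3, !is.null(names(sets)))
  grid <- seq(universe[1], universe[2], length.out = 201)
  cover <- Reduce(`+`, lapply(sets, trapezoid_membership, x = grid))
  if (any(cover <= 0)) stop_param("sets do not cover the universe")
  structure(list(name = name, universe = universe, sets = sets),
            class = "etmt_fuzzyvar")
}

#' Default three-set partition of the unit interval
#'
#' A plateau-covering partition: adjacent plateaus touch, so at every point
#' of \[0, 1\] at least one set has membership 1. This keeps the
#' defuzzified output monotone across set crossovers (with a partition
#' whose plateaus do not touch, the aggregated mass dips at crossovers and
#' the centroid moves non-monotonically).
#'
#' @return Named list `low`, `medium`, `high` of [trapezoid_mf()].
#' @export
default_partition <- function() {
  list(low = trapezoid_mf(0, 0, 0.3, 0.5),
       medium = trapezoid_mf(0.1, 0.3, 0.7, 0.9),
       high = trapezoid_mf(0.5, 0.7, 1, 1))
}

#' Default 9-rule base
#'
#' The complete rule matrix over two inputs with sets low/medium/high.
#' Both inputs are "badness" quantities (more edits / more time / more
#' errors / more blindness events), so low inputs map to a high score:
#' (L,L)->H, (L,M)->H, (M,L)->H, (M,M)->M, (L,H)->M, (H,L)->M, (M,H)->L,
#' (H,M)->L, (H,H)->L. The matrix is symmetric in the two inputs.
#'
#' @return Data frame with columns `in1`, `in2`, `out` (9 rows).
#' @export
default_rules <- function() {
  data.frame(
    in1 = c("low", "low", "medium", "medium", "low", "high", "medium",
            "high", "high"),
    in2 = c("low", "medium", "low", "medium", "high", "low", "high",
            "medium", "high"),
    out = c("high", "high", "high", "medium", "medium", "medium", "low",
            "low", "low"),
    stringsAsFactors = FALSE)
}

#' Construct a two-input Mamdani system
#'
#' @param input1,input2 [fuzzy_variable()] inputs.
#' @param output [fuzzy_variable()] output.
#' @param rules Data frame `in1,in2,out` naming sets; must contain every
#'   (set1, set2) combination exactly once (9 rules).
#' @return Object of class `etmt_mamdani`.
#' @export
mamdani_fis <- function(input1, input2, output, rules = default_rules()) {
  if (is.null(rules) || nrow(rules) == 0) stop_param("empty rule base")
  combos <- paste(rules$in1, rules$in2)
  expected <- as.vector(outer(names(input1$sets), names(input2$sets),
                              paste))
  if (nrow(rules) != 9 || !setequal(combos, expected) ||
      anyDuplicated(combos)) {
    stop_param("rule base must contain each of the 9 set combinations ",
               "exactly once")
  }
  if (!all(rules$out %in% names(output$sets))) {
    stop_param("rule consequents must name output sets")
  }
  structure(list(input1 = input1, input2 = input2, output = output,
                 rules = rules),
            class = "etmt_mamdani")
}

#' Evaluate a Mamdani system
#'
#' Inputs are clipped to their universes; AND is the minimum over
#' antecedent memberships, implication clips each rule's consequent at the
#' firing strength (min), rules aggregate by maximum, and the output is the
#' centroid of the aggregated shape on a uniform grid. If the aggregate is
#' identically zero, the universe midpoint is returned with attribute
#' `degenerate = TRUE`.
#'
#' @param fis An [mamdani_fis()] system.
#' @param x1,x2 Crisp input values.
#' @param resolution Output grid step.
#' @return Crisp score in the output universe.
#' @export
mamdani_evaluate <- function(fis, x1, x2, resolution = 1e-3) {
  if (!is.numeric(resolution) || resolution <= 0) {
    stop_param("resolution must be > 0")
  }
  u1 <- fis$input1$universe; u2 <- fis$input2$universe
  x1 <- min(max(x1, u1[1]), u1[2])
  x2 <- min(max(x2, u2[1]), u2[2])
  uo <- fis$output$universe
  grid <- seq(uo[1], uo[2], by = resolution)
  # strongest firing per consequent set (max aggregation commutes with the
  # per-set clip, so clip each output set once at its best strength)
  strength <- vapply(seq_len(nrow(fis$rules)), function(r) {
    min(trapezoid_membership(fis$input1$sets[[fis$rules$in1[r]]], x1),
        trapezoid_membership(fis$input2$sets[[fis$rules$in2[r]]], x2))
  }, numeric(1))
  agg <- numeric(length(grid))
  for (set_name in unique(fis$rules$out)) {
    w <- max(strength[fis$rules$out == set_name])
    if (w <= 0) next
    mu <- trapezoid_membership(fis$output$sets[[set_name]], grid)
    agg <- pmax(agg, pmin(w, mu))
  }
  total <- sum(agg)
  if (total == 0) {
    return(structure(mean(uo), degenerate = TRUE))
  }
  sum(grid * agg) / total
}

# Wrap a Mamdani core with input normalization for the ETMT scores.
new_scoring_fis <- function(fis, name, input_names, norm) {
  structure(list(fis = fis, name = name, input_names = input_names,
                 norm = norm),
            class = "etmt_fis")
}

#' @export
print.etmt_fis <- function(x, ...) {
  cat(sprintf("<etmt_fis> %s: inputs %s (scales %s)\n", x$name,
              paste(x$input_names, collapse = ", "),
              paste(signif(unlist(x$norm), 4), collapse = ", ")))
  invisible(x)
}

#' Build the visual-search-speed scoring system
#'
#' A Mamdani system on normalized scanpath score and completion time.
#' FH1 is normalized by the expected-sequence length (session total when
#' scoring a whole session) and capped at 1; FH2 by a reference maximum
#' completion time. Low scanpath score and low time give a high
#' visual-search-speed score.
#'
#' @param scan_scale Reference scale for FH1: the expected-sequence length
#'   (sum over the session's stimuli when scoring sessions).
#' @param time_scale_ms Reference maximum completion time in ms.
#' @param rules Optional 9-rule override.
#' @return An `etmt_fis` scoring object.
#' @export
build_vss_fis <- function(scan_scale, time_scale_ms = 180000,
                          rules = default_rules()) {
  if (missing(scan_scale) || !is.numeric(scan_scale) || scan_scale <= 0) {
    stop_param("scan_scale (expected-sequence length) must be supplied > 0")
  }
  if (!is.numeric(time_scale_ms) || time_scale_ms <= 0) {
    stop_param("time_scale_ms must be > 0")
  }
  core <- mamdani_fis(fuzzy_variable("FH1_norm"), fuzzy_variable("FH2_norm"),
                      fuzzy_variable("visual_search_speed"), rules)
  new_scoring_fis(core, "visual_search_speed", c("FH1", "FH2"),
                  list(scale1 = scan_scale, scale2 = time_scale_ms))
}

#' Build the focused-attention scoring system
#'
#' A Mamdani system on normalized error rate and inattentional blindness.
#' FH3 is normalized by the expected-sequence length (capped at 1); FH4 by
#' `ib_cap` events. Low errors and no blindness events give a high
#' focused-attention score.
#'
#' @param error_scale Reference scale for FH3 (expected-sequence length).
#' @param ib_cap FH4 value treated as saturating (default 3 events).
#' @param rules Optional 9-rule override.
#' @return An `etmt_fis` scoring object.
#' @export
build_fa_fis <- function(error_scale, ib_cap = 3, rules = default_rules()) {
  if (missing(error_scale) || !is.numeric(error_scale) || error_scale <= 0) {
    stop_param("error_scale (expected-sequence length) must be supplied > 0")
  }
  if (!is.numeric(ib_cap) || ib_cap <= 0) stop_param("ib_cap must be > 0")
  core <- mamdani_fis(fuzzy_variable("FH3_norm"), fuzzy_variable("FH4_norm"),
                      fuzzy_variable("focused_attention"), rules)
  new_scoring_fis(core, "focused_attention", c("FH3", "FH4"),
                  list(scale1 = error_scale, scale2 = ib_cap))
}

#' Score raw feature values with a scoring system
#'
#' Normalizes the two raw inputs by the system's reference scales (capped
#' at 1) and evaluates the Mamdani core.
#'
#' @param scorer An `etmt_fis` from [build_vss_fis()] or [build_fa_fis()].
#' @param v1,v2 Raw feature values (FH1 and FH2, or FH3 and FH4).
#' @param resolution Defuzzification grid step.
#' @return Crisp score in \[0, 1\].
#' @export
fis_score <- function(scorer, v1, v2, resolution = 1e-3) {
  stopifnot(inherits(scorer, "etmt_fis"))
  mamdani_evaluate(scorer$fis,
                   min(v1 / scorer$norm$scale1, 1),
                   min(v2 / scorer$norm$scale2, 1),
                   resolution)
}

#' Band a score into low / medium / high
#'
#' Thirds of the unit interval: low on \[0, 1/3), medium on \[1/3, 2/3\],
#' high on (2/3, 1\].
#'
#' @param score Score in \[0, 1\].
#' @return `"low"`, `"medium"` or `"high"`.
#' @export
score_band <- function(score) {
  if (score < 1 / 3) "low" else if (score <= 2 / 3) "medium" else "high"
}

#' Deficit indication flags
#'
#' Maps the two fuzzy scores to graded deficit indications: the
#' visual-search-speed score indicates processing-speed and
#' visual-attention deficits; the focused-attention score indicates motor
#' impairment, attentional disengagement, memory deficits,
#' neuropsychological impairment, and executive functioning. A high score
#' grades its linked deficits "low", a medium score "medium", a low score
#' "high".
#'
#' @param vss,fa Scores in \[0, 1\].
#' @return Named character vector of deficit grades.
#' @export
deficit_flags <- function(vss, fa) {
  grade <- function(score) {
    switch(score_band(score), high = "low", medium = "medium", low = "high")
  }
  g_vss <- grade(vss); g_fa <- grade(fa)
  c(processing_speed = g_vss, visual_attention = g_vss,
    motor_impairment = g_fa, attentional_disengagement = g_fa,
    memory = g_fa, neuropsychological = g_fa, executive_functioning = g_fa)
}

#' Write or read a scoring-system configuration as JSON
#'
#' Stores universes, trapezoid breakpoints, the rule matrix and the
#' normalization scales with full precision, so a write/read round trip is
#' exact.
#'
#' @param scorer An `etmt_fis`.
#' @param path File path.
#' @return `read_fis_config` returns the scoring object; the writer
#'   returns `path` invisibly.
#' @export
write_fis_config <- function(scorer, path) {
  var_payload <- function(v) {
    list(name = v$name, universe = v$universe,
         sets = lapply(v$sets, function(mf) as.numeric(mf)))
  }
  payload <- list(name = scorer$name, input_names = scorer$input_names,
                  norm = scorer$norm,
                  input1 = var_payload(scorer$fis$input1),
                  input2 = var_payload(scorer$fis$input2),
                  output = var_payload(scorer$fis$output),
                  rules = scorer$fis$rules)
  writeLines(jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                              dataframe = "columns", pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_fis_config
#' @export
read_fis_config <- function(path) {
  p <- jsonlite::fromJSON(readLines(path, warn = FALSE))
  var_from <- function(v) {
    sets <- lapply(v$sets, function(bp) do.call(trapezoid_mf, as.list(bp)))
    fuzzy_variable(v$name, v$universe, sets)
  }
  core <- mamdani_fis(var_from(p$input1), var_from(p$input2),
                      var_from(p$output), as.data.frame(p$rules))
  new_scoring_fis(core, p$name, p$input_names, p$norm)
}
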