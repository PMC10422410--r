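# The thirteen features: low-level arithmetic, per-AOI visit accounting,
# scanpath construction, Levenshtein scoring, error counting, and
# inattentional-blindness pattern detection.

test_that("low-level features follow their definitions", {
  fix <- make_fix(c(0, 300, 600), rep(200, 3), 1:3, 1:3)
  fl <- low_level(fix, trial_duration = 800)
  expect_equal(unname(fl), c(3, 600, 75.0, 200))

  expect_equal(unname(low_level(make_fix(numeric(0), numeric(0),
                                         numeric(0), numeric(0)), 1000)),
               c(0, 0, 0, 0))
  # one fixation spanning the whole trial
  expect_equal(low_level(make_fix(0, 500, 1, 1), 500)[["FL3"]], 100)
  expect_error(low_level(fix, 0), "trial_duration")
})

test_that("per-AOI features count dwells, glances, revisits and first looks", {
  lay <- make_layout("tmt_a_simple", seed = 4)
  # AOI "3" gets a 250 ms fixation, then others, then a 150 ms return
  fix <- fixations_visiting(lay, c("3", "1", "2", "3"))
  fix$duration_ms <- c(250, 200, 200, 150)
  fm <- aoi_level(fix, lay, trial_duration = 2000)
  row3 <- fm[fm$label == "3", ]
  expect_equal(row3$FM1, 400)
  expect_equal(row3$FM3, 2)
  expect_equal(row3$FM4, 1)
  expect_equal(row3$FM5, 250)
  expect_equal(row3$FM2, 100 * 400 / 2000)
  # never-fixated AOI is all zero
  row8 <- fm[fm$label == "8", ]
  expect_equal(unlist(row8[, c("FM1", "FM2", "FM3", "FM4", "FM5")],
                      use.names = FALSE), rep(0, 5))
  # two consecutive fixations in one AOI are a single visit run
  fix2 <- fixations_visiting(lay, c("5", "5"))
  fm2 <- aoi_level(fix2, lay, 1000)
  expect_equal(fm2[fm2$label == "5", ]$FM3, 2)
  expect_equal(fm2[fm2$label == "5", ]$FM4, 0)
})

test_that("dwell never exceeds total fixation time", {
  lay <- make_layout("tmt_a_simple", seed = 4)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(5:25, 1)
    fix <- make_fix((seq_len(n) - 1) * 300, runif(n, 80, 280),
                    runif(n, 0, lay$width), runif(n, 0, lay$height))
    dur <- n * 300 + 1000
    fm <- aoi_level(fix, lay, dur)
    fl <- low_level(fix, dur)
    expect_lte(sum(fm$FM1), fl[["FL2"]])
  }
})

test_that("scanpath strings map fixations to AOI visits", {
  lay <- make_layout("tmt_a_simple", seed = 4)
  fix <- fixations_visiting(lay, c("6", "1", "2", "3", "4", "5", "6", "7",
                                   "8"))
  expect_equal(scanpath_string(fix, lay),
               c("6", "1", "2", "3", "4", "5", "6", "7", "8"))
  # out-of-AOI fixations contribute nothing
  none <- make_fix(c(0, 300), c(200, 200), c(-500, -500), c(-500, -600))
  expect_length(scanpath_string(none, lay), 0)
  # consecutive duplicates collapse unless asked not to
  dup <- fixations_visiting(lay, c("3", "3", "4"))
  expect_equal(scanpath_string(dup, lay), c("3", "4"))
  expect_equal(scanpath_string(dup, lay, collapse = FALSE),
               c("3", "3", "4"))
})

test_that("levenshtein matches the recursive oracle and its axioms", {
  expect_equal(levenshtein(c("a", "b"), c("a", "b")), 0)
  expect_equal(levenshtein(strsplit("kitten", "")[[1]],
                           strsplit("sitting", "")[[1]]), 3)
  expect_equal(levenshtein(character(0), as.character(1:8)), 8)
  alphabet <- c("1", "2", "3", "A", "12")
  set.seed(5)
  for (i in 1:300) {
    a <- sample(alphabet, sample(0:6, 1), replace = TRUE)
    b <- sample(alphabet, sample(0:6, 1), replace = TRUE)
    d <- levenshtein(a, b)
    expect_identical(d, lev_oracle(a, b))
    expect_identical(d, levenshtein(b, a))
    expect_identical(d == 0L, identical(a, b))
  }
  # triangle inequality on random triples
  for (i in 1:100) {
    a <- sample(alphabet, sample(0:5, 1), replace = TRUE)
    b <- sample(alphabet, sample(0:5, 1), replace = TRUE)
    cc <- sample(alphabet, sample(0:5, 1), replace = TRUE)
    expect_lte(levenshtein(a, cc), levenshtein(a, b) + levenshtein(b, cc))
  }
})

test_that("multi-character labels cost a single edit", {
  expect_equal(levenshtein(c("12", "13"), c("12", "14")), 1)
})

test_that("the scanpath score reproduces the worked example", {
  lay <- make_layout("tmt_a_simple", seed = 4)
  obs <- c("6", "1", "2", "3", "4", "5", "6", "7", "8")
  expect_equal(scanpath_score(obs, lay), 1)
  expect_equal(scanpath_score(lay$expected_sequence, lay), 0)
  expect_equal(scanpath_score(character(0), lay), 8)
})

test_that("total time sums trial durations across a session", {
  s <- make_samples(rep(1, 5), rep(1, 5))
  tr <- trial_record("P1", "tmt_a_simple", s, trial_start = 0,
                     trial_end = 4042)
  expect_equal(total_time(tr), 4042)
  trials <- lapply(1:4, function(i) {
    trial_record("P1", "tmt_a_simple", s, trial_start = 0,
                 trial_end = 1000)
  })
  expect_equal(total_time(trials), 4000)
  one <- trial_record("P1", "tmt_a_simple", s[1, , drop = FALSE])
  expect_equal(total_time(one), 0)
  empty <- trial_record("P1", "tmt_a_simple", s[0, , drop = FALSE])
  expect_error(total_time(empty), "empty")
})

test_that("error rate counts out-of-AOI fixations plus wrong visits", {
  lay <- make_layout("tmt_a_simple", seed = 4)
  perfect <- fixations_visiting(lay, lay$expected_sequence)
  expect_equal(error_rate(perfect, lay), 0)
  # the worked example: one premature visit to 6 is a single error
  stray6 <- fixations_visiting(lay, c("6", as.character(1:8)))
  expect_equal(error_rate(stray6, lay), 1)
  # pointer walk on "1 3 2" against "1 2 3": token 3 mismatches (1 error),
  # 2 then matches; plus 2 out-of-AOI fixations
  lay3 <- lay
  mixed <- rbind(fixations_visiting(lay, c("1", "3", "2")),
                 make_fix(c(2000, 2300), c(200, 200), c(-50, -60),
                          c(-50, -60)))
  # restrict the expectation walk: expected sequence is 1..8; tokens
  # "1","3","2": 1 matches, 3 wrong, 2 matches -> 1 wrong + 2 out = 3
  expect_equal(error_rate(mixed, lay3), 3)
})

test_that("inattentional blindness counts repeated runs, not single tokens", {
  expect_equal(inattentional_blindness(
    c("6", "1", "2", "3", "4", "5", "6", "7", "8")), 0)
  expect_equal(inattentional_blindness(
    c("1", "2", "3", "6", "7", "6", "7", "8")), 1)
  expect_equal(inattentional_blindness(character(0)), 0)
  expect_error(inattentional_blindness(c("1", "2"), min_pattern_len = 0),
               "min_pattern_len")
  # min length 1 counts single-token repeats too
  expect_equal(inattentional_blindness(c("6", "1", "6"),
                                       min_pattern_len = 1), 1)
})

test_that("inattentional blindness agrees with the exhaustive oracle", {
  set.seed(6)
  alphabet <- as.character(1:4)
  for (i in 1:400) {
    sp <- sample(alphabet, sample(0:8, 1), replace = TRUE)
    expect_identical(inattentional_blindness(sp), ib_oracle(sp),
                     label = paste(sp, collapse = " "))
  }
})

test_that("a perfect trail yields zero high-level error features", {
  layouts <- test_layouts()
  for (id in names(layouts)) {
    lay <- layouts[[id]]
    fix <- fixations_visiting(lay, lay$expected_sequence)
    sp <- scanpath_string(fix, lay)
    expect_equal(scanpath_score(sp, lay), 0, info = id)
    expect_equal(error_rate(fix, lay), 0, info = id)
    expect_equal(inattentional_blindness(sp), 0, info = id)
  }
})

test_that("feature assembly aggregates across trials as documented", {
  layouts <- test_layouts()
  p0 <- impairment_profile(stray_prob = 0, revisit_prob = 0, noise_px = 0)
  one <- simulate_trial(p0, layouts$tmt_a_simple, participant_id = "P1",
                        seed = 2)
  # four identical trials: summed counts x4, averaged percentages unchanged
  four <- assemble_features(list(one, one, one, one),
                            layouts["tmt_a_simple"])
  single <- assemble_features(list(one), layouts["tmt_a_simple"])
  for (f in c("FL1", "FL2", "FM1", "FM3", "FM4", "FH1", "FH2", "FH3",
              "FH4")) {
    expect_equal(four[[f]], 4 * single[[f]], info = f)
  }
  for (f in c("FL3", "FL4", "FM2", "FM5")) {
    expect_equal(four[[f]], single[[f]], info = f)
  }
  # zero-impairment simulation has clean high-level features
  expect_equal(single$FH1, 0)
  expect_equal(single$FH3, 0)
  expect_equal(single$FH4, 0)
  # missing trials warn and are flagged in provenance
  expect_warning(partial <- assemble_features(list(one), layouts),
                 "missing")
  expect_false(attr(partial, "provenance")$complete)
  expect_true(attr(single, "provenance")$complete)
})
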