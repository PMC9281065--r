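make_events <- function(time, category = "fluid_crystalloid", volume_cc = 800,
                        agent = NA_character_, dose = NA_real_) {
  tibble::tibble(patient_id = "X", time = time, category = category,
                 agent = agent, volume_cc = volume_cc, dose = dose)
}

test_that("agent names normalize case-insensitively with brand synonyms", {
  expect_equal(normalize_agent("Levophed"), "norepinephrine")
  expect_equal(normalize_agent("Neosynephrine"), "phenylephrine")
  expect_equal(normalize_agent("DOBUTamine"), "dobutamine")
  expect_equal(normalize_agent("midodrine"), "unrecognized")
  expect_equal(normalize_agent(c(" levophed ", "Vasopressin")),
               c("norepinephrine", "vasopressin"))
})

test_that("any-administration onsets fire at every eligible positive dose", {
  spec <- criterion_any_administration("vaso", c("norepinephrine", "dopamine"))
  ev <- make_events(c(10, 10.5, 30), category = "vasoactive", volume_cc = 0,
                    agent = c("Levophed", "norepinephrine", "dopamine"),
                    dose = c(4, 2, 8))
  expect_equal(detect_any_administration_onsets(ev, spec), c(10, 10.5, 30))
  expect_equal(detect_any_administration_onsets(ev[0, ], spec), numeric(0))
  # unrecognized agents and zero doses never trigger
  ev2 <- make_events(c(1, 2), category = "vasoactive", volume_cc = 0,
                     agent = c("midodrine", "norepinephrine"), dose = c(5, 0))
  expect_equal(detect_any_administration_onsets(ev2, spec), numeric(0))
})

test_that("volume-window onsets match the worked examples", {
  spec <- criterion_volume_window("f8", "fluid_crystalloid", 2400, 8, ">=")
  expect_equal(detect_volume_window_onsets(make_events(c(10, 12, 14.5)), spec), 14.5)
  expect_equal(detect_volume_window_onsets(make_events(c(0, 9, 18)), spec), numeric(0))
  alb <- criterion_volume_window("alb", "albumin25", 200, 2, ">=")
  expect_equal(detect_volume_window_onsets(
    make_events(3, category = "albumin25", volume_cc = 200), alb), 3)
})

test_that("comparator fidelity: 2400 cc reaching qualifies, PRBC 1500 cc must exceed", {
  fluid <- criterion_volume_window("f8", "fluid_crystalloid", 2400, 8, ">=")
  expect_equal(detect_volume_window_onsets(make_events(c(1, 3, 5)), fluid), 5)
  prbc <- criterion_volume_window("prbc", "prbc", 1500, 24, ">")
  exactly_1500 <- make_events(c(2, 10), category = "prbc", volume_cc = 750)
  expect_equal(detect_volume_window_onsets(exactly_1500, prbc), numeric(0))
  over_1500 <- make_events(c(2, 10, 11), category = "prbc", volume_cc = c(750, 750, 10))
  expect_equal(detect_volume_window_onsets(over_1500, prbc), 11)
})

test_that("combination-window onsets require all components inside one window", {
  spec <- criterion_combo_window("combo", c(prbc = 500, ffp = 500,
                                            platelet_pheresis = 500), 6)
  ok <- make_events(c(1, 3, 5), category = c("prbc", "ffp", "platelet_pheresis"),
                    volume_cc = 500)
  expect_equal(detect_combo_window_onsets(ok, spec), 5)
  missing_comp <- make_events(c(1, 8), category = c("prbc", "ffp"), volume_cc = 500)
  expect_equal(detect_combo_window_onsets(missing_comp, spec), numeric(0))
  too_spread <- make_events(c(1, 3, 9.5),
                            category = c("prbc", "ffp", "platelet_pheresis"),
                            volume_cc = 500)
  expect_equal(detect_combo_window_onsets(too_spread, spec), numeric(0))
})

test_that("PRBC-then-fluid sequence rule anchors at the PRBC crossing", {
  us <- ruleset("US")
  seq_spec <- us$criteria[[5]]
  expect_equal(seq_spec$kind, "sequence")
  ev <- dplyr::bind_rows(
    make_events(2, category = "prbc", volume_cc = 500),
    make_events(c(6, 8, 10), category = "fluid_crystalloid", volume_cc = 800))
  # fluid 2400cc/8h crossing at t=10, within (2, 14] after the PRBC crossing
  expect_equal(detect_sequence_onsets(ev, seq_spec), 2)
  # follow-up fluid too late
  ev_late <- dplyr::bind_rows(
    make_events(2, category = "prbc", volume_cc = 500),
    make_events(c(20, 22, 24), category = "fluid_crystalloid", volume_cc = 800))
  expect_equal(detect_sequence_onsets(ev_late, seq_spec), numeric(0))
  # no follow-up at all
  ev_none <- make_events(2, category = "prbc", volume_cc = 500)
  expect_equal(detect_sequence_onsets(ev_none, seq_spec), numeric(0))
})

test_that("volume detection is permutation-invariant and volume-monotone", {
  spec <- criterion_volume_window("f8", c("fluid_crystalloid", "fluid_colloid"),
                                  2400, 8, ">=")
  withr::with_seed(99, {
    for (i in 1:50) {
      ev <- random_fluid_log(sample(2:15, 1))
      base <- detect_volume_window_onsets(ev, spec)
      shuffled <- ev[sample(nrow(ev)), ]
      expect_equal(detect_volume_window_onsets(shuffled, spec), base)
      # adding volume to an eligible record never delays the earliest onset
      el <- which(ev$category %in% spec$categories)
      if (length(el) > 0 && length(base) > 0) {
        ev2 <- ev
        ev2$volume_cc[el[1]] <- ev2$volume_cc[el[1]] + 500
        more <- detect_volume_window_onsets(ev2, spec)
        expect_true(length(more) > 0)
        expect_lte(min(more), min(base))
      }
      # adding a non-eligible record changes nothing
      ev3 <- dplyr::bind_rows(ev, make_events(5, category = "vasoactive",
                                              volume_cc = 0, agent = "dopamine",
                                              dose = 4))
      expect_equal(detect_volume_window_onsets(ev3, spec), base)
    }
  })
})

test_that("segments group onsets by the merge gap", {
  seg <- build_segments(c(10, 10.5, 11.2), merge_gap_h = 1)
  expect_equal(nrow(seg), 1)
  expect_equal(seg$onset_time, 10)
  expect_equal(seg$end_time, 12.2)
  expect_equal(nrow(build_segments(c(10, 20), 1)), 2)
  expect_equal(nrow(build_segments(numeric(0), 1)), 0)
  expect_error(build_segments(c(1, 2), merge_gap_h = 0), "merge_gap_h")
})

test_that("cohort labelling follows the first-segment-after-6h rule", {
  patients <- tibble::tibble(patient_id = c("A", "B", "C"))
  segments <- tibble::tibble(
    patient_id = c("A", "A", "B"),
    onset_time = c(4, 30, 4),
    end_time = c(5, 31, 5),
    criteria = "vasoactive_any")
  lab <- label_cohort(patients, segments, min_onset_h = 6)
  expect_equal(lab$group[lab$patient_id == "A"], "unstable")
  expect_equal(lab$onset_time[lab$patient_id == "A"], 30)
  expect_equal(lab$group[lab$patient_id == "B"], "excluded")
  expect_equal(lab$exclusion_reason[lab$patient_id == "B"], "only_early_segments")
  expect_equal(lab$group[lab$patient_id == "C"], "stable")
  # partition: each patient in exactly one group
  expect_equal(sort(lab$patient_id), c("A", "B", "C"))
  expect_true(all(lab$group %in% c("stable", "unstable", "excluded")))
})

test_that("inclusion filters drop young, short-stay and empty-profile patients", {
  patients <- tibble::tibble(
    patient_id = c("A", "B", "C", "D"),
    age = c(20.0, 45, 21, 70),
    los_h = c(100, 5.9, 48, 72))
  obs <- tibble::tibble(patient_id = c("A", "B", "C"), time = 1,
                        variable = "heart_rate", value = 80, source = "t")
  flt <- apply_inclusion_filters(patients, obs)
  expect_equal(flt$patients$patient_id, "C")
  expect_equal(flt$report$n[flt$report$reason == "age_at_or_below_20y"], 1)
  expect_equal(flt$report$n[flt$report$reason == "los_below_6h"], 1)
  expect_equal(flt$report$n[flt$report$reason == "incomplete_profile"], 1)
  bad <- tibble::tibble(patient_id = "Z", age = 50, los_h = -1)
  expect_error(apply_inclusion_filters(bad, obs), "discharge")
})
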