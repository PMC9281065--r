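#' Normalize a vasoactive agent name
#'
#' Case-insensitive mapping of brand and generic inotrope/vasopressor names
#' to canonical agent ids (e.g. `"Levophed"` to `norepinephrine`,
#' `"Neosynephrine"` to `phenylephrine`). Names absent from the dictionary
#' map to the sentinel `"unrecognized"` and never trigger a criterion.
#'
#' @param raw_name Character vector of agent names.
#' @param dictionary Dictionary tibble, see [agent_dictionary()].
#' @return Character vector of canonical ids.
#' @examples
#' normalize_agent(c("Levophed", "DOBUTamine", "midodrine"))
#' @export
normalize_agent <- function(raw_name, dictionary = agent_dictionary()) {
  idx <- match(tolower(trimws(raw_name)), dictionary$raw_name)
  out <- dictionary$canonical[idx]
  out[is.na(idx)] <- "unrecognized"
  out
}

#' Annotation criterion constructors
#'
#' A criterion describes one way an intervention log marks hemodynamic
#' instability: any administration of an eligible vasoactive agent
#' (`criterion_any_administration`); a cumulative volume of eligible
#' categories reaching a threshold within a look-back window
#' (`criterion_volume_window`, comparator `">="` or `">"`); every component
#' category reaching its minimum volume within one window
#' (`criterion_combo_window`); or a PRBC volume crossing followed by a
#' fluid-therapy onset within a follow-up window
#' (`criterion_sequence`).
#'
#' @param id Short criterion id used in segment annotations.
#' @param agents Eligible canonical agent ids.
#' @param categories Eligible intervention categories.
#' @param threshold_cc Volume threshold in cc (must be positive).
#' @param window_h Look-back window in hours (must be positive).
#' @param comparator `">="` (reaching the stated dosage qualifies) or `">"`
#'   (strictly exceeding it).
#' @param components For combos: named numeric vector, minimum volume (cc)
#'   per category.
#' @param trigger_spec,followup_specs,followup_window_h For sequences: the
#'   initial volume-window criterion, the list of criteria whose onsets
#'   count as follow-up therapy, and the follow-up window in hours.
#' @return A list of class `hd_criterion`.
#' @name criteria
NULL

#' @rdname criteria
#' @export
criterion_any_administration <- function(id, agents) {
  check_field(length(agents) > 0, "agents", "must name at least one agent")
  structure(list(id = id, kind = "any_administration", agents = agents),
            class = "hd_criterion")
}

#' @rdname criteria
#' @export
criterion_volume_window <- function(id, categories, threshold_cc, window_h,
                                    comparator = ">=") {
  check_field(threshold_cc > 0, "threshold_cc", "must be positive")
  check_field(window_h > 0, "window_h", "must be positive")
  check_field(comparator %in% c(">=", ">"), "comparator", "must be \">=\" or \">\"")
  structure(list(id = id, kind = "volume_window", categories = categories,
                 threshold_cc = threshold_cc, window_h = window_h,
                 comparator = comparator),
            class = "hd_criterion")
}

#' @rdname criteria
#' @export
criterion_combo_window <- function(id, components, window_h) {
  check_field(window_h > 0, "window_h", "must be positive")
  check_field(length(components) > 0 && !is.null(names(components)),
              "components", "must be a named vector of minimum volumes")
  check_field(all(components > 0), "components", "minimum volumes must be positive")
  structure(list(id = id, kind = "combo_window", components = components,
                 window_h = window_h),
            class = "hd_criterion")
}

#' @rdname criteria
#' @export
criterion_sequence <- function(id, trigger_spec, followup_specs, followup_window_h) {
  check_field(inherits(trigger_spec, "hd_criterion") &&
                trigger_spec$kind == "volume_window",
              "trigger_spec", "must be a volume-window criterion")
  check_field(followup_window_h > 0, "followup_window_h", "must be positive")
  structure(list(id = id, kind = "sequence", trigger_spec = trigger_spec,
                 followup_specs = followup_specs,
                 followup_window_h = followup_window_h),
            class = "hd_criterion")
}

.vaso_agents <- c("dobutamine", "dopamine", "epinephrine", "norepinephrine",
                  "phenylephrine", "vasopressin")
.fluid_categories <- c("fluid_crystalloid", "fluid_colloid")

#' Annotation rulesets
#'
#' The two published rule columns. Both cohorts share the vasoactive
#' any-administration rule (dobutamine, dopamine, epinephrine,
#' norepinephrine/Levophed, phenylephrine/Neosynephrine, vasopressin) and
#' the fluid-therapy dosages (2400 cc in 8 h or 3000 cc in 12 h, read as
#' reaching the stated dosage). They differ on blood products:
#' * `TPEVGH`: 25% albumin 200 cc within 2 h counts as fluid therapy;
#'   PRBC strictly more than 1500 cc within 24 h; or the combination
#'   PRBC 500 cc + FFP 500 cc + platelet pheresis 500 cc within 6 h.
#' * `US`: PRBC 800 cc over the course of 24 h; or PRBC 500 cc in 2 h
#'   followed by fluid therapy (per the fluid criteria) within 12 h.
#'
#' @param name `"TPEVGH"` or `"US"`.
#' @return A list of class `hd_ruleset` with elements `name` and `criteria`.
#' @export
ruleset <- function(name = c("TPEVGH", "US")) {
  name <- match.arg(name)
  fluid_8h <- criterion_volume_window("fluid_2400cc_8h", .fluid_categories, 2400, 8, ">=")
  fluid_12h <- criterion_volume_window("fluid_3000cc_12h", .fluid_categories, 3000, 12, ">=")
  vaso <- criterion_any_administration("vasoactive_any", .vaso_agents)
  criteria <- if (name == "TPEVGH") {
    list(
      vaso, fluid_8h, fluid_12h,
      criterion_volume_window("albumin25_200cc_2h", "albumin25", 200, 2, ">="),
      criterion_volume_window("prbc_1500cc_24h", "prbc", 1500, 24, ">"),
      criterion_combo_window("combo_prbc_ffp_plt_6h",
                             c(prbc = 500, ffp = 500, platelet_pheresis = 500), 6)
    )
  } else {
    list(
      vaso, fluid_8h, fluid_12h,
      criterion_volume_window("prbc_800cc_24h", "prbc", 800, 24, ">="),
      criterion_sequence("prbc_500cc_2h_then_fluid",
                         criterion_volume_window("prbc_500cc_2h", "prbc", 500, 2, ">="),
                         list(fluid_8h, fluid_12h), 12)
    )
  }
  structure(list(name = name, criteria = criteria), class = "hd_ruleset")
}

validate_events <- function(events) {
  needed <- c("time", "category")
  miss <- setdiff(needed, names(events))
  check_field(length(miss) == 0, "events",
              paste("missing columns:", paste(miss, collapse = ", ")))
  check_field(all(events$time >= 0), "time", "must be non-negative")
  if ("volume_cc" %in% names(events)) {
    check_field(all(is.na(events$volume_cc) | events$volume_cc >= 0),
                "volume_cc", "must be non-negative")
  }
  invisible(events)
}

#' Detect instability onsets for one patient's intervention log
#'
#' `detect_any_administration_onsets()` returns the time of every
#' administration of an eligible agent with positive dose.
#' `detect_volume_window_onsets()` returns each earliest time at which the
#' cumulative eligible volume over the half-open look-back window
#' `(t - window_h, t]` first satisfies the comparator against the
#' threshold, evaluated at event times; after a crossing, detection re-arms
#' only once the running window total falls back below the threshold, so
#' one sustained episode yields one onset. Record volumes count wholly at
#' their charted time. `detect_combo_window_onsets()` does the same with
#' every component category required to reach its minimum within one
#' window. `detect_sequence_onsets()` reports the initial crossing time of
#' the trigger criterion when any follow-up criterion has an onset within
#' the follow-up window after it. `detect_onsets()` dispatches on the
#' criterion kind; `detect_ruleset_onsets()` pools onsets over a whole
#' ruleset, returning a tibble of `(time, criterion)`.
#'
#' @param events Intervention records for a single patient (tibble with
#'   `time`, `category` and, where relevant, `agent`, `volume_cc`, `dose`).
#'   Order does not matter; records are sorted defensively.
#' @param spec An `hd_criterion`.
#' @param dictionary Agent dictionary for normalization.
#' @return Numeric vector of onset times (sorted), or for
#'   `detect_ruleset_onsets()` a tibble.
#' @name detect_onsets
NULL

#' @rdname detect_onsets
#' @export
detect_any_administration_onsets <- function(events, spec,
                                             dictionary = agent_dictionary()) {
  validate_events(events)
  if (nrow(events) == 0) return(numeric(0))
  vaso <- events[events$category == "vasoactive", , drop = FALSE]
  if (nrow(vaso) == 0) return(numeric(0))
  agent <- normalize_agent(vaso$agent, dictionary)
  dose <- if ("dose" %in% names(vaso)) vaso$dose else rep(1, nrow(vaso))
  sort(vaso$time[agent %in% spec$agents & !is.na(dose) & dose > 0])
}

# running window total of a point-mass volume series over (t - W, t],
# evaluated at the critical times where it can change: event times
# (increase) and event times + W (decrease). Returns crossing times with
# the re-arming rule applied.
window_crossings <- function(time, volume, window_h, threshold, comparator) {
  o <- order(time)
  time <- time[o]; volume <- volume[o]
  crit <- sort(unique(c(time, time + window_h)))
  # total over (tc - W, tc] via cumulative sums at event times
  csum <- cumsum(volume)
  upto <- function(x) {  # sum of volumes with time <= x
    c(0, csum)[findInterval(x, time) + 1]
  }
  total <- upto(crit) - upto(crit - window_h)
  meets <- if (comparator == ">=") total >= threshold else total > threshold
  is_event <- crit %in% time
  onsets <- numeric(0)
  armed <- TRUE
  for (i in seq_along(crit)) {
    if (armed && meets[i] && is_event[i]) {
      onsets <- c(onsets, crit[i])
      armed <- FALSE
    } else if (!armed && !meets[i]) {
      armed <- TRUE
    }
  }
  onsets
}

#' @rdname detect_onsets
#' @export
detect_volume_window_onsets <- function(events, spec) {
  validate_events(events)
  el <- events[events$category %in% spec$categories & !is.na(events$volume_cc), , drop = FALSE]
  if (nrow(el) == 0) return(numeric(0))
  check_field(all(el$volume_cc >= 0), "volume_cc", "must be non-negative")
  window_crossings(el$time, el$volume_cc, spec$window_h,
                   spec$threshold_cc, spec$comparator)
}

#' @rdname detect_onsets
#' @export
detect_combo_window_onsets <- function(events, spec) {
  if (spec$kind == "sequence") return(detect_sequence_onsets(events, spec))
  validate_events(events)
  cats <- names(spec$components)
  el <- events[events$category %in% cats & !is.na(events$volume_cc), , drop = FALSE]
  if (nrow(el) == 0) return(numeric(0))
  o <- order(el$time)
  el <- el[o, , drop = FALSE]
  crit <- sort(unique(c(el$time, el$time + spec$window_h)))
  meets_all <- rep(TRUE, length(crit))
  for (cat in cats) {
    sub <- el[el$category == cat, , drop = FALSE]
    if (nrow(sub) == 0) return(numeric(0))
    csum <- cumsum(sub$volume_cc)
    upto <- function(x) {
      c(0, csum)[findInterval(x, sub$time) + 1]
    }
    total <- upto(crit) - upto(crit - spec$window_h)
    meets_all <- meets_all & (total >= spec$components[[cat]])
  }
  is_event <- crit %in% el$time
  onsets <- numeric(0)
  armed <- TRUE
  for (i in seq_along(crit)) {
    if (armed && meets_all[i] && is_event[i]) {
      onsets <- c(onsets, crit[i])
      armed <- FALSE
    } else if (!armed && !meets_all[i]) {
      armed <- TRUE
    }
  }
  onsets
}

#' @rdname detect_onsets
#' @export
detect_sequence_onsets <- function(events, spec) {
  t0 <- detect_volume_window_onsets(events, spec$trigger_spec)
  if (length(t0) == 0) return(numeric(0))
  followup <- sort(unique(unlist(lapply(spec$followup_specs, function(fs) {
    detect_volume_window_onsets(events, fs)
  }))))
  keep <- vapply(t0, function(t) {
    any(followup > t & followup <= t + spec$followup_window_h)
  }, logical(1))
  t0[keep]
}

#' @rdname detect_onsets
#' @export
detect_onsets <- function(events, spec, dictionary = agent_dictionary()) {
  switch(spec$kind,
         any_administration = detect_any_administration_onsets(events, spec, dictionary),
         volume_window = detect_volume_window_onsets(events, spec),
         combo_window = detect_combo_window_onsets(events, spec),
         sequence = detect_sequence_onsets(events, spec),
         abort(paste("unknown criterion kind:", spec$kind)))
}

#' @rdname detect_onsets
#' @export
detect_ruleset_onsets <- function(events, rules = ruleset("TPEVGH"),
                                  dictionary = agent_dictionary()) {
  out <- purrr::map_dfr(rules$criteria, function(cr) {
    tibble(time = detect_onsets(events, cr, dictionary), criterion = cr$id)
  })
  if (nrow(out) == 0) return(tibble(time = numeric(0), criterion = character(0)))
  arrange(out, .data$time)
}

#' Group onset times into unstable segments
#'
#' Consecutive onsets separated by at most `merge_gap_h` form one segment;
#' the segment onset is the first onset of the run and the end is the last
#' onset plus the merge gap. Segments are disjoint and ordered.
#'
#' @param onsets Tibble `(time, criterion)` from [detect_ruleset_onsets()],
#'   or a numeric vector of onset times.
#' @param merge_gap_h Merge gap in hours (default 1, the scoring interval).
#' @return Tibble with `onset_time`, `end_time`, `criteria`
#'   (comma-separated ids of the triggering criteria).
#' @export
build_segments <- function(onsets, merge_gap_h = 1) {
  check_field(merge_gap_h > 0, "merge_gap_h", "must be positive")
  if (is.numeric(onsets)) onsets <- tibble(time = onsets, criterion = NA_character_)
  if (nrow(onsets) == 0) {
    return(tibble(onset_time = numeric(0), end_time = numeric(0), criteria = character(0)))
  }
  onsets <- arrange(onsets, .data$time)
  run <- cumsum(c(1, diff(onsets$time) > merge_gap_h))
  onsets |>
    mutate(run = run) |>
    group_by(run) |>
    summarise(onset_time = min(.data$time),
              end_time = max(.data$time) + merge_gap_h,
              criteria = paste(sort(unique(stats::na.omit(.data$criterion))), collapse = ","),
              .groups = "drop") |>
    select("onset_time", "end_time", "criteria")
}

#' Partition a cohort into stable / unstable / excluded
#'
#' Segments whose onset falls at or before `min_onset_h` (default 6 h, the
#' first-segment rule) are discarded. A patient with a surviving segment is
#' `unstable`, with the first surviving segment as the validation segment.
#' A patient whose only segments began too early is `excluded`
#' (`only_early_segments`): interventions did occur, so counting them as
#' stable would contaminate the negative class. Patients with no segments
#' are `stable`.
#'
#' @param patients Patients table (must have `patient_id`).
#' @param segments Tibble of segments with `patient_id`, `onset_time`,
#'   `end_time`, `criteria` for all patients.
#' @param min_onset_h Earliest admissible onset (hours after admission).
#' @return Tibble of class `hd_labels`: `patient_id`, `group`,
#'   `onset_time`, `end_time`, `criteria`, `exclusion_reason`.
#' @export
label_cohort <- function(patients, segments, min_onset_h = 6) {
  if (nrow(segments) == 0) {
    segments <- tibble(patient_id = character(0), onset_time = numeric(0),
                       end_time = numeric(0), criteria = character(0))
  }
  counts <- dplyr::count(segments, .data$patient_id, name = "n_segments")
  late <- segments |>
    filter(.data$onset_time > min_onset_h) |>
    group_by(.data$patient_id) |>
    slice_min(.data$onset_time, n = 1, with_ties = FALSE) |>
    ungroup() |>
    mutate(n_late = 1L) |>
    select("patient_id", "n_late", "onset_time", "end_time", "criteria")
  labels <- patients |>
    select("patient_id") |>
    left_join(counts, by = "patient_id") |>
    left_join(late, by = "patient_id") |>
    mutate(
      n_segments = tidyr::replace_na(.data$n_segments, 0L),
      n_late = tidyr::replace_na(.data$n_late, 0L),
      group = case_when(
        .data$n_late > 0 ~ "unstable",
        .data$n_segments > 0 ~ "excluded",
        TRUE ~ "stable"),
      exclusion_reason = if_else(.data$group == "excluded",
                                 "only_early_segments", NA_character_)) |>
    select("patient_id", "group", "onset_time", "end_time", "criteria",
           "exclusion_reason")
  class(labels) <- c("hd_labels", class(labels))
  labels
}

#' Apply the cohort inclusion filters
#'
#' Drops patients aged 20 years or less (inclusion requires strictly more
#' than 20 years), patients who stayed in the ICU less than 6 hours, and
#' patients with an incomplete data profile (no observation records at
#' all). Returns the included patients and an exclusion report with counts
#' per reason (the flow-diagram ledger).
#'
#' @param patients Patients table with `age` and `los_h` (or `admit_time`/
#'   `discharge_time` ISO instants from which `los_h` is derived).
#' @param observations Long observation table.
#' @param min_age_y,min_los_h Inclusion cut-offs.
#' @return A list with `patients` (included rows) and `report` (tibble of
#'   `reason`, `n`).
#' @export
apply_inclusion_filters <- function(patients, observations,
                                    min_age_y = 20, min_los_h = 6) {
  if (!"los_h" %in% names(patients)) {
    adm <- as.POSIXct(patients$admit_time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    dis <- as.POSIXct(patients$discharge_time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    patients$los_h <- as.numeric(difftime(dis, adm, units = "hours"))
  }
  check_field(all(patients$los_h >= 0), "discharge_time", "discharge before admission")
  has_obs <- patients$patient_id %in% unique(observations$patient_id)
  excl_age <- patients$age <= min_age_y
  excl_los <- !excl_age & patients$los_h < min_los_h
  excl_obs <- !excl_age & !excl_los & !has_obs
  keep <- !(excl_age | excl_los | excl_obs)
  report <- tibble(
    reason = c("age_at_or_below_20y", "los_below_6h", "incomplete_profile", "included"),
    n = c(sum(excl_age), sum(excl_los), sum(excl_obs), sum(keep)))
  list(patients = patients[keep, , drop = FALSE], report = report)
}

#' Annotate a whole cohort
#'
#' Runs the inclusion filters, detects onsets per patient under the chosen
#' ruleset, builds segments and labels the cohort.
#'
#' @param interventions Intervention table for all patients.
#' @param patients Patients table.
#' @param observations Observations table (for the incomplete-profile
#'   filter); if `NULL` the profile filter is skipped.
#' @param rules An [ruleset()] or its name.
#' @param merge_gap_h Segment merge gap in hours.
#' @param min_onset_h First-segment rule cut-off.
#' @return A list with `labels` (see [label_cohort()]), `segments`,
#'   `inclusion_report`, and the included `patients`.
#' @export
annotate_cohort <- function(interventions, patients, observations = NULL,
                            rules = ruleset("TPEVGH"), merge_gap_h = 1,
                            min_onset_h = 6) {
  if (is.character(rules)) rules <- ruleset(rules)
  if (!is.null(observations)) {
    flt <- apply_inclusion_filters(patients, observations)
  } else {
    flt <- list(patients = patients,
                report = tibble(reason = "included", n = nrow(patients)))
  }
  patients <- flt$patients
  dict <- agent_dictionary()
  interventions <- semi_join(interventions, patients, by = "patient_id")
  segments <- interventions |>
    group_by(.data$patient_id) |>
    group_modify(function(ev, key) {
      build_segments(detect_ruleset_onsets(ev, rules, dict), merge_gap_h)
    }) |>
    ungroup()
  labels <- label_cohort(patients, segments, min_onset_h)
  list(labels = labels, segments = segments, inclusion_report = flt$report,
       patients = patients)
}
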