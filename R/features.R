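#' Replace physiologically implausible values with missing
#'
#' Values outside the registry plausibility range `[lo, hi]` are replaced
#' by `NA`; in-range values are untouched. Idempotent. Variables not in the
#' registry pass through unchanged (with an informational message).
#'
#' @param observations Long observation table (`patient_id`, `time`,
#'   `variable`, `value`, ...).
#' @param registry Feature registry.
#' @return The filtered observation table.
#' @export
apply_plausibility_filter <- function(observations, registry = default_registry()) {
  unknown <- setdiff(unique(observations$variable), registry$variable)
  if (length(unknown) > 0) {
    inform(paste("variables not in registry passed through unfiltered:",
                 paste(unknown, collapse = ", ")))
  }
  i <- match(observations$variable, registry$variable)
  lo <- registry$lo[i]
  hi <- registry$hi[i]
  out <- !is.na(i) & !is.na(observations$value) &
    (observations$value < lo | observations$value > hi)
  observations$value[out] <- NA_real_
  observations
}

# Vectorized staleness-limited LOCF: for each (patient_id, reference_time)
# query and each registry variable, take the latest observation at or
# before the reference time whose age does not exceed the variable's
# staleness limit. Queries must carry a unique `.row_id`.
locf_sample <- function(observations, queries, registry) {
  obs <- observations |>
    filter(.data$variable %in% registry$variable, !is.na(.data$value)) |>
    select("patient_id", "variable", "time", "value")
  dup <- duplicated(obs[, c("patient_id", "variable", "time")])
  if (any(dup)) {
    inform(sprintf("%d same-timestamp duplicate observations; last written wins", sum(dup)))
  }
  q <- tidyr::crossing(queries, variable = registry$variable) |>
    mutate(time = .data$reference_time, value = NA_real_, is_query = TRUE)
  all_rows <- bind_rows(mutate(obs, is_query = FALSE, .row_id = NA_integer_,
                               reference_time = NA_real_),
                        q) |>
    arrange(.data$patient_id, .data$variable, .data$time, .data$is_query)
  # carry forward the last observation index without crossing group bounds
  grp <- paste(all_rows$patient_id, all_rows$variable, sep = "\r")
  new_grp <- c(TRUE, grp[-1] != grp[-length(grp)])
  gstart <- cummax(seq_along(grp) * new_grp)
  pos <- ifelse(!all_rows$is_query, seq_len(nrow(all_rows)), 0L)
  filled <- cummax(pos)
  valid <- filled >= gstart & filled > 0
  obs_time <- ifelse(valid, all_rows$time[pmax(filled, 1L)], NA_real_)
  obs_value <- ifelse(valid, all_rows$value[pmax(filled, 1L)], NA_real_)
  res <- all_rows |>
    mutate(obs_time = obs_time, obs_value = obs_value) |>
    filter(.data$is_query)
  staleness <- setNames(registry$staleness_h, registry$variable)
  age <- res$time - res$obs_time
  res$sampled <- unname(ifelse(!is.na(age) & age <= unname(staleness[res$variable]),
                               res$obs_value, NA_real_))
  res |>
    select(".row_id", "patient_id", "reference_time", "variable", "sampled") |>
    tidyr::pivot_wider(names_from = "variable", values_from = "sampled") |>
    arrange(.data$.row_id)
}

#' Sample all registry variables at a reference time
#'
#' Last-observation-carried-forward with expiry: for each variable, the
#' latest observation at or before `reference_time` whose age is within the
#' variable's staleness limit; otherwise missing. Observations should be
#' plausibility-filtered first.
#'
#' @param observations Observations for one patient.
#' @param reference_time Hours from admission (non-negative).
#' @param registry Feature registry.
#' @return One-row tibble with a column per registry variable.
#' @export
sample_at <- function(observations, reference_time, registry = default_registry()) {
  check_field(all(reference_time >= 0), "reference_time", "must be non-negative")
  pid <- if (nrow(observations) > 0) observations$patient_id[1] else "p"
  if (!"patient_id" %in% names(observations)) observations$patient_id <- pid
  q <- tibble(.row_id = seq_along(reference_time), patient_id = pid,
              reference_time = reference_time)
  locf_sample(observations, q, registry) |>
    select(dplyr::all_of(registry$variable))
}

#' Apply clinical fallback imputation
#'
#' Fills missing invasive systolic/diastolic/mean pressures from the
#' same-row noninvasive counterpart when present (`nibp_to_ibp` rule), and
#' sets missing FiO2 to the room-air fraction 0.21 (`fio2_room_air` rule).
#' Every other missing value stays missing, and observed values are never
#' overwritten.
#'
#' @param samples Tibble with one column per registry variable (one or
#'   more rows).
#' @param registry Feature registry (its `fallback`/`fallback_source`
#'   columns drive the rules).
#' @return `samples` with fallbacks applied.
#' @export
impute_features <- function(samples, registry = default_registry()) {
  for (i in seq_len(nrow(registry))) {
    var <- registry$variable[i]
    if (!var %in% names(samples)) next
    rule <- registry$fallback[i]
    if (rule == "nibp_to_ibp") {
      src <- registry$fallback_source[i]
      if (!is.na(src) && src %in% names(samples)) {
        samples[[var]] <- coalesce(samples[[var]], samples[[src]])
      }
    } else if (rule == "fio2_room_air") {
      samples[[var]] <- coalesce(samples[[var]], 0.21)
    }
  }
  samples
}

#' Shock index
#'
#' Heart rate divided by systolic blood pressure (invasive, after
#' noninvasive fallback imputation); missing when either input is missing.
#'
#' @param samples Tibble with `heart_rate` and `sbp_inv` columns.
#' @return Numeric vector.
#' @export
compute_shock_index <- function(samples) {
  samples$heart_rate / samples$sbp_inv
}

#' Build the lead-time-indexed sample matrix
#'
#' For each unstable patient, one row per integer lead `t = 1..horizon_h`
#' hours before the validation onset (reference time `onset - t`, kept
#' while non-negative), labelled 1. For each stable patient, by default one
#' row at `admission + stable_window_h` using only observations inside that
#' window, labelled 0 with lead 0; with `stable_hourly = TRUE` stable
#' patients instead contribute one row per hour of stay up to `horizon_h`
#' (needed for the false-alarm-rate analysis). Rows are plausibility
#' filtered, LOCF-sampled with staleness expiry, then fallback-imputed.
#' Missingness is encoded as `NA` in the value columns (the missingness
#' mask is exactly `is.na()` of those columns).
#'
#' @param labels Cohort labels from [label_cohort()] / [annotate_cohort()].
#' @param observations Long observation table.
#' @param registry Feature registry.
#' @param horizon_h Pre-onset horizon in hours.
#' @param stable_window_h Stable-group observation window in hours.
#' @param stable_hourly Sample stable patients hourly instead of once.
#' @param patients Required when `stable_hourly = TRUE` (for `los_h`).
#' @return Tibble of class `hd_samples`: `patient_id`, `reference_time`,
#'   `lead_hours`, `label`, plus one column per registry variable.
#' @export
build_sample_matrix <- function(labels, observations, registry = default_registry(),
                                horizon_h = 24, stable_window_h = 5,
                                stable_hourly = FALSE, patients = NULL) {
  unstable <- labels[labels$group == "unstable", , drop = FALSE]
  if (any(is.na(unstable$onset_time))) {
    abort("unstable patient lacks an onset time", class = "hemodyn_validation_error")
  }
  stable <- labels[labels$group == "stable", , drop = FALSE]
  q_unstable <- tidyr::crossing(unstable[, c("patient_id", "onset_time")],
                                lead_hours = seq_len(horizon_h)) |>
    mutate(reference_time = .data$onset_time - .data$lead_hours, label = 1L) |>
    filter(.data$reference_time >= 0) |>
    select("patient_id", "reference_time", "lead_hours", "label")
  if (stable_hourly) {
    check_field(!is.null(patients), "patients",
                "required when stable_hourly = TRUE")
    los <- setNames(patients$los_h, patients$patient_id)
    q_stable <- stable |>
      mutate(max_h = pmin(floor(los[.data$patient_id]), horizon_h)) |>
      filter(.data$max_h >= 1) |>
      tidyr::uncount(.data$max_h, .id = "hour") |>
      mutate(reference_time = as.numeric(.data$hour), lead_hours = 0L, label = 0L) |>
      select("patient_id", "reference_time", "lead_hours", "label")
  } else {
    q_stable <- stable |>
      mutate(reference_time = stable_window_h, lead_hours = 0L, label = 0L) |>
      select("patient_id", "reference_time", "lead_hours", "label")
  }
  queries <- bind_rows(q_unstable, q_stable) |>
    mutate(.row_id = dplyr::row_number())
  obs <- apply_plausibility_filter(observations, registry)
  wide <- locf_sample(obs, queries, registry)
  out <- queries |>
    left_join(wide, by = c(".row_id", "patient_id", "reference_time")) |>
    select(-".row_id") |>
    impute_features(registry)
  class(out) <- c("hd_samples", class(out))
  attr(out, "registry_hash") <- hash(as.data.frame(registry))
  attr(out, "features") <- registry$variable
  out
}
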