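#' Configure the synthetic ICU cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The generator
#' emulates a mixed adult ICU in which a fraction of patients (default 19%,
#' the instability prevalence reported for real mixed-ICU cohorts) go on to
#' receive a qualifying hemodynamic intervention. Each destined-unstable
#' patient carries a latent severity drawn `N(latent_separation_d, 1)`
#' against `N(0, 1)` for stable patients; the latent value is expressed as a
#' signed drift (in SDs, direction per variable: blood pressures, hemoglobin
#' and hematocrit fall; heart rate, CVP, BUN, lactate, AST, creatinine,
#' airway pressures and FiO2 rise) that ramps linearly over the
#' deterioration horizon and reaches full magnitude one hour before onset.
#' Stable patients express their latent severity at a constant level, so the
#' best achievable discrimination one hour before onset is the closed form
#' `theoretical_auroc(d)`.
#'
#' @param n_patients Number of patients.
#' @param prevalence Fraction of patients destined to receive a qualifying
#'   intervention, in (0, 1) (0 allowed for degenerate test cohorts).
#' @param seed Integer seed; one global seed fans out to per-patient
#'   substreams keyed by patient id, so generating a smaller cohort leaves
#'   the shared patients' draws unchanged.
#' @param latent_separation_d Standardized mean difference of the latent
#'   severity between destined groups.
#' @param deterioration_horizon_h Hours before onset over which drift ramps.
#' @param drift Named numeric vector: signed per-variable drift magnitude in
#'   SDs at full expression. Defaults cover the variables with a documented
#'   direction of difference between groups.
#' @param missingness Named numeric vector of per-scheduled-sample drop
#'   probabilities (default includes 22.1% for lactate).
#' @param sampling_period_h Named numeric vector of hours between scheduled
#'   samples per variable category.
#' @param baseline_sd Per-patient baseline offset SD (in units of the
#'   variable's `ref_sd`); models stable between-patient differences.
#' @param noise_sd Per-observation measurement noise SD (same units).
#' @param los_meanlog,los_sdlog Log-normal length-of-stay parameters (hours).
#' @param los_min_h Minimum length of stay (hours).
#' @param onset_meanlog,onset_sdlog Log-normal onset-time parameters (hours
#'   after admission) for destined-unstable patients.
#' @param onset_min_h Minimum onset time; kept above 6 h so generated onsets
#'   survive the first-segment rule.
#' @param distractor_rate Probability that a stable patient receives one or
#'   two sub-threshold (500 cc) fluid boluses that must not trigger any
#'   annotation criterion.
#' @param registry Feature registry, see [default_registry()].
#' @return A list of class `hd_cohort_config`.
#' @seealso [generate_cohort()], [theoretical_auroc()]
#' @export
cohort_config <- function(n_patients = 500,
                          prevalence = 0.19,
                          seed = 1L,
                          latent_separation_d = 1.5,
                          deterioration_horizon_h = 24,
                          drift = default_drift(),
                          missingness = default_missingness(),
                          sampling_period_h = c(vital = 1, lab = 24,
                                                blood_gas = 8, ventilation = 4),
                          baseline_sd = 0.5,
                          noise_sd = 0.8,
                          los_meanlog = log(48),
                          los_sdlog = 0.6,
                          los_min_h = 8,
                          onset_meanlog = log(24),
                          onset_sdlog = 0.6,
                          onset_min_h = 7,
                          distractor_rate = 0.3,
                          registry = default_registry()) {
  check_field(is.numeric(n_patients) && n_patients >= 1, "n_patients", "must be >= 1")
  check_field(prevalence >= 0 && prevalence < 1, "prevalence", "must be in [0, 1)")
  check_field(is.numeric(seed) && length(seed) == 1, "seed", "must be a single integer")
  check_field(latent_separation_d >= 0, "latent_separation_d", "must be >= 0")
  check_field(deterioration_horizon_h >= 1, "deterioration_horizon_h", "must be >= 1")
  check_field(all(missingness >= 0 & missingness <= 1), "missingness", "rates must be in [0, 1]")
  check_field(all(names(missingness) %in% registry$variable), "missingness",
              "rates keyed by unknown variable id")
  check_field(all(names(drift) %in% registry$variable), "drift",
              "drift keyed by unknown variable id")
  check_field(all(sampling_period_h > 0), "sampling_period_h", "must be positive")
  check_field(los_min_h > 0 && los_meanlog > 0, "los", "length-of-stay must be positive")
  check_field(onset_min_h > 6, "onset_min_h", "must exceed the 6 h first-segment rule")
  check_field(distractor_rate >= 0 && distractor_rate <= 1, "distractor_rate", "must be in [0, 1]")
  validate_registry(registry)
  structure(list(
    n_patients = as.integer(n_patients), prevalence = prevalence,
    seed = as.integer(seed), latent_separation_d = latent_separation_d,
    deterioration_horizon_h = deterioration_horizon_h, drift = drift,
    missingness = missingness, sampling_period_h = sampling_period_h,
    baseline_sd = baseline_sd, noise_sd = noise_sd,
    los_meanlog = los_meanlog, los_sdlog = los_sdlog, los_min_h = los_min_h,
    onset_meanlog = onset_meanlog, onset_sdlog = onset_sdlog,
    onset_min_h = onset_min_h, distractor_rate = distractor_rate,
    registry = registry
  ), class = "hd_cohort_config")
}

#' @rdname cohort_config
#' @export
default_drift <- function() {
  c(heart_rate = 1.1,
    sbp_inv = -1.2, dbp_inv = -0.8, map_inv = -1.2,
    sbp_ninv = -1.2, dbp_ninv = -0.8, map_ninv = -1.2,
    cvp = 1.0,
    hemoglobin = -0.8, hematocrit = -0.8,
    bun = 0.8, lactate = 1.1, ast = 0.7, creatinine = 0.7,
    peak_airway_pressure = 0.6, mean_airway_pressure = 0.6,
    fio2 = 0.6)
}

#' @rdname cohort_config
#' @export
default_missingness <- function() {
  c(sbp_inv = 0.35, dbp_inv = 0.35, map_inv = 0.35,
    heart_rate = 0.03, sbp_ninv = 0.05, dbp_ninv = 0.05, map_ninv = 0.05,
    resp_rate = 0.03, spo2 = 0.03, temperature = 0.05, cvp = 0.4,
    glucose = 0.1, bun = 0.08, creatinine = 0.08, ast = 0.15,
    bilirubin = 0.15, hemoglobin = 0.05, hematocrit = 0.05,
    platelets = 0.08, wbc = 0.08, sodium = 0.08, potassium = 0.08,
    bicarbonate = 0.15, lactate = 0.221, ph = 0.15, pao2 = 0.15,
    paco2 = 0.15, fio2 = 0.3, peak_airway_pressure = 0.25,
    mean_airway_pressure = 0.25, peep = 0.25, tidal_volume = 0.25,
    minute_ventilation = 0.25)
}

#' Generate a synthetic ICU cohort
#'
#' Emits four tidy tables: `patients` (demographics, admission descriptors,
#' APACHE II, ISO-8601 admission/discharge instants plus `los_h` in hours,
#' ICU mortality), `observations` (long: `patient_id`, `time` in hours from
#' admission, `variable`, `value`, `source`), `interventions` (`patient_id`,
#' `time`, `category`, `agent`, `volume_cc`, `dose`) and `ground_truth`
#' (destined `group`, true `onset_time`, latent severity, trigger type).
#'
#' Every destined-unstable patient receives an intervention bundle whose
#' records satisfy exactly one annotation criterion at the true onset,
#' rotating among a vasoactive dose, three 800 cc crystalloid boluses over
#' 4 h (fluid-volume rule), two 800 cc PRBC units over 6 h (PRBC-volume
#' rule), and a 500 + 500 + 500 cc PRBC/FFP/platelet combination within
#' 6 h; most also receive post-onset vasoactive continuation doses that
#' merge into the same unstable segment. Stable patients receive no
#' qualifying interventions (optionally sub-threshold fluid distractors).
#' All observation values are clamped inside the registry plausibility
#' range, so the plausibility filter is a no-op on clean synthetic data.
#'
#' @param config A [cohort_config()] object.
#' @return A list of class `hd_cohort` with elements `patients`,
#'   `observations`, `interventions`, `ground_truth` and the `config`.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 20, seed = 1))
#' table(cohort$ground_truth$group)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "hd_cohort_config")) {
    abort("`config` must be created by cohort_config()", class = "hemodyn_validation_error")
  }
  ids <- sprintf("P%05d", seq_len(config$n_patients))
  per <- lapply(ids, function(pid) {
    withr::with_seed(substream_seed(config$seed, pid), generate_patient(pid, config))
  })
  cohort <- list(
    patients = bind_rows(lapply(per, `[[`, "patient")),
    observations = bind_rows(lapply(per, `[[`, "observations")),
    interventions = bind_rows(lapply(per, `[[`, "interventions")),
    ground_truth = bind_rows(lapply(per, `[[`, "ground_truth")),
    config = config
  )
  if (nrow(cohort$interventions) == 0) {
    cohort$interventions <- empty_interventions()
  }
  class(cohort) <- "hd_cohort"
  cohort
}

empty_interventions <- function() {
  tibble(patient_id = character(), time = numeric(), category = character(),
         agent = character(), volume_cc = numeric(), dose = numeric())
}

# epoch for exported ISO-8601 instants; admissions spread over 2010-2020Q1
.hd_epoch <- as.POSIXct("2010-01-01 00:00:00", tz = "UTC")

generate_patient <- function(pid, config) {
  reg <- config$registry
  unstable <- runif(1) < config$prevalence
  latent <- rnorm(1, mean = if (unstable) config$latent_separation_d else 0, sd = 1)

  onset <- NA_real_
  trigger <- NA_character_
  los <- max(config$los_min_h, rlnorm(1, config$los_meanlog, config$los_sdlog))
  if (unstable) {
    onset <- max(config$onset_min_h, rlnorm(1, config$onset_meanlog, config$onset_sdlog))
    los <- max(los, onset + 6)
    trigger <- sample(c("vasoactive", "fluid_volume", "prbc_volume", "combo_transfusion"), 1)
  }

  admit_offset_h <- runif(1, 0, 10.25 * 365.25 * 24)
  admit <- .hd_epoch + admit_offset_h * 3600
  patient <- tibble(
    patient_id = pid,
    age = round(pmin(95, pmax(21, rnorm(1, 68, 14))), 1),
    gender = sample(c("male", "female"), 1, prob = c(0.65, 0.35)),
    admission_type = sample(c("emergency", "not_emergency", "other"), 1,
                            prob = c(0.44, 0.46, 0.10)),
    icu_type = sample(c("medical", "surgical"), 1, prob = c(0.61, 0.39)),
    admission_source = sample(c("cardiovascular", "gastrointestinal",
                                "metabolic_endocrine", "neurologic",
                                "respiratory", "trauma", "other"), 1,
                              prob = c(0.10, 0.30, 0.05, 0.02, 0.02, 0.04, 0.47)),
    apache2 = round(pmin(50, pmax(2, rnorm(1, 22, 8)))),
    admit_time = format(admit, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    discharge_time = format(admit + los * 3600, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    admit_year = as.integer(format(admit, "%Y", tz = "UTC")),
    los_h = los,
    mortality = as.integer(runif(1) < if (unstable) 0.41 else 0.11)
  )

  observations <- generate_observations(pid, config, los, latent, unstable, onset)
  interventions <- generate_interventions(pid, config, los, unstable, onset, trigger)

  list(patient = patient, observations = observations,
       interventions = interventions,
       ground_truth = tibble(patient_id = pid,
                             group = if (unstable) "unstable" else "stable",
                             onset_time = onset, latent = latent,
                             trigger_type = trigger))
}

# drift expression weight at time t: stable severity is constant; unstable
# severity ramps linearly over the horizon, reaching 1 one hour before onset
drift_weight <- function(t, unstable, onset, horizon) {
  if (!unstable) return(rep(1, length(t)))
  ramp_start <- onset - horizon
  w <- (t - ramp_start) / max(horizon - 1, 1)
  pmin(1, pmax(0, w))
}

generate_observations <- function(pid, config, los, latent, unstable, onset) {
  reg <- config$registry
  periods <- config$sampling_period_h[reg$category]
  n_times <- floor(los / periods) + 1
  variable <- rep(reg$variable, n_times)
  category <- rep(reg$category, n_times)
  period <- rep(unname(periods), n_times)
  k <- sequence(n_times) - 1
  time <- k * period
  ref <- rep(reg$ref_value, n_times)
  sdv <- rep(reg$ref_sd, n_times)
  lo <- rep(reg$lo, n_times)
  hi <- rep(reg$hi, n_times)
  delta <- unname(config$drift[reg$variable])
  delta[is.na(delta)] <- 0
  delta <- rep(delta, n_times)

  baseline <- rep(rnorm(nrow(reg), 0, config$baseline_sd), n_times)
  w <- drift_weight(time, unstable, onset, config$deterioration_horizon_h)
  value <- ref + sdv * (baseline + delta * latent * w +
                          rnorm(length(time), 0, config$noise_sd))
  value <- round(pmin(hi, pmax(lo, value)), 3)

  obs <- tibble(patient_id = pid, time = time, variable = variable,
                value = value, source = category)
  # per-sample missingness from the same patient substream
  rates <- config$missingness[obs$variable]
  rates[is.na(rates)] <- 0
  obs[runif(nrow(obs)) >= rates, ]
}

generate_interventions <- function(pid, config, los, unstable, onset, trigger) {
  if (!unstable) {
    if (runif(1) < config$distractor_rate) {
      n <- sample(1:2, 1)
      t <- sort(runif(n, 0, max(los - 0.5, 0.5)))
      return(tibble(patient_id = pid, time = t, category = "fluid_crystalloid",
                    agent = NA_character_, volume_cc = 500, dose = NA_real_))
    }
    return(empty_interventions())
  }
  bundle <- switch(trigger,
    vasoactive = tibble(
      patient_id = pid, time = onset, category = "vasoactive",
      agent = sample(c("norepinephrine", "Levophed", "dopamine", "epinephrine",
                       "vasopressin", "Neosynephrine", "dobutamine"), 1),
      volume_cc = 0, dose = round(runif(1, 2, 16), 2)),
    fluid_volume = tibble(
      patient_id = pid, time = onset - c(4, 2, 0),
      category = "fluid_crystalloid", agent = NA_character_,
      volume_cc = 800, dose = NA_real_),
    prbc_volume = tibble(
      patient_id = pid, time = onset - c(6, 0), category = "prbc",
      agent = NA_character_, volume_cc = 800, dose = NA_real_),
    combo_transfusion = tibble(
      patient_id = pid, time = onset - c(4, 2, 0),
      category = c("prbc", "ffp", "platelet_pheresis"),
      agent = NA_character_, volume_cc = 500, dose = NA_real_)
  )
  # vasoactive continuation after onset (most unstable patients get pressors);
  # crossings land within the merge gap so the segment onset is unchanged
  if (runif(1) < 0.97) {
    cont <- tibble(patient_id = pid, time = onset + c(0.5, 1.2),
                   category = "vasoactive", agent = "norepinephrine",
                   volume_cc = 0, dose = round(runif(2, 2, 16), 2))
    bundle <- bind_rows(bundle, cont)
  }
  arrange(bundle, .data$time)
}

#' Drop scheduled observations at per-variable missingness rates
#'
#' Each row is dropped independently with its variable's rate; retained
#' values are unchanged. Used by the generator internally (with per-patient
#' substreams); exposed for building custom missingness scenarios.
#'
#' @param observations Long observation table.
#' @param rates Named numeric vector of drop probabilities keyed by
#'   variable id; variables absent from `rates` are kept. Unknown names
#'   (not present in `registry`) raise an error.
#' @param seed Integer seed.
#' @param registry Feature registry used to validate rate names.
#' @return The thinned observation table.
#' @export
apply_missingness <- function(observations, rates, seed,
                              registry = default_registry()) {
  unknown <- setdiff(names(rates), registry$variable)
  check_field(length(unknown) == 0, "rates",
              paste("unknown variable id:", paste(unknown, collapse = ", ")))
  check_field(all(rates >= 0 & rates <= 1), "rates", "must be in [0, 1]")
  r <- rates[observations$variable]
  r[is.na(r)] <- 0
  keep <- withr::with_seed(seed, runif(nrow(observations)) >= r)
  observations[keep, ]
}

#' Closed-form AUROC of the latent severity signal
#'
#' For a score equal to a latent Gaussian signal with standardized mean
#' difference `d` between classes (unit variance in each), the AUROC is
#' `pnorm(d / sqrt(2))`. Used as the closed-form reference against which
#' the end-to-end pipeline's discrimination is checked.
#'
#' @param latent_separation_d Standardized mean difference, `d >= 0`.
#' @return The AUROC as a probability.
#' @examples
#' theoretical_auroc(0)    # 0.5
#' theoretical_auroc(1.5)  # ~0.856
#' @export
theoretical_auroc <- function(latent_separation_d) {
  check_field(is.numeric(latent_separation_d) && all(latent_separation_d >= 0),
              "latent_separation_d", "must be >= 0")
  pnorm(latent_separation_d / sqrt(2))
}

#' @export
print.hd_cohort <- function(x, ...) {
  cat(sprintf("<hd_cohort> %d patients (%d unstable), %d observations, %d intervention records\n",
              nrow(x$patients), sum(x$ground_truth$group == "unstable"),
              nrow(x$observations), nrow(x$interventions)))
  invisible(x)
}
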