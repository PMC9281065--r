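#' Published table schemas
#'
#' Column contracts for the interchange CSVs. Missing values are written
#' as empty fields; times are numeric hours from admission except the
#' patient admission/discharge instants, which are ISO-8601.
#'
#' @param id Schema id: one of `"patients"`, `"observations"`,
#'   `"interventions"`, `"ground_truth"`, `"labels"`, `"segments"`,
#'   `"samples"`.
#' @param registry Feature registry (for the `samples` schema).
#' @return Character vector of required column names.
#' @export
table_schema <- function(id, registry = default_registry()) {
  schemas <- list(
    patients = c("patient_id", "age", "gender", "admission_type", "icu_type",
                 "admission_source", "apache2", "admit_time", "discharge_time",
                 "admit_year", "los_h", "mortality"),
    observations = c("patient_id", "time", "variable", "value", "source"),
    interventions = c("patient_id", "time", "category", "agent", "volume_cc", "dose"),
    ground_truth = c("patient_id", "group", "onset_time", "latent", "trigger_type"),
    labels = c("patient_id", "group", "onset_time", "end_time", "criteria",
               "exclusion_reason"),
    segments = c("patient_id", "onset_time", "end_time", "criteria"),
    samples = c("patient_id", "reference_time", "lead_hours", "label",
                registry$variable))
  check_field(id %in% names(schemas), "id", "unknown schema id")
  schemas[[id]]
}

#' Read / write an interchange table with schema checking
#'
#' `write_table()` writes a CSV with missing values as empty fields;
#' `read_table()` reads one back and fails, listing the offending
#' columns, when the header does not match the schema. The pair is
#' round-trip stable on canonical tables. An empty file with a valid
#' header reads as an empty table.
#'
#' @param x Table to write.
#' @param path File path.
#' @param id Schema id, see [table_schema()].
#' @param registry Feature registry (for the `samples` schema).
#' @return `read_table()` returns a tibble; `write_table()` the path,
#'   invisibly.
#' @export
write_table <- function(x, path, id, registry = default_registry()) {
  schema <- table_schema(id, registry)
  miss <- setdiff(schema, names(x))
  check_field(length(miss) == 0, "x",
              paste("missing columns:", paste(miss, collapse = ", ")))
  readr::write_csv(as_tibble(x)[, schema], path, na = "", progress = FALSE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path, id, registry = default_registry()) {
  schema <- table_schema(id, registry)
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       na = c("", "NA"))
  miss <- setdiff(schema, names(x))
  extra <- setdiff(names(x), schema)
  check_field(length(miss) == 0 && length(extra) == 0, "path",
              sprintf("schema mismatch for '%s' (missing: %s; extra: %s)", id,
                      paste(miss, collapse = ", "), paste(extra, collapse = ", ")))
  x[, schema]
}

#' Write / read a whole synthetic cohort directory
#'
#' @param cohort An `hd_cohort`.
#' @param dir Output directory (created if needed).
#' @return `write_cohort()` the directory path invisibly; `read_cohort()`
#'   a list of tables.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(cohort$patients, file.path(dir, "patients.csv"), "patients")
  write_table(cohort$observations, file.path(dir, "observations.csv"), "observations")
  write_table(cohort$interventions, file.path(dir, "interventions.csv"), "interventions")
  write_table(cohort$ground_truth, file.path(dir, "ground_truth.csv"), "ground_truth")
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(patients = read_table(file.path(dir, "patients.csv"), "patients"),
       observations = read_table(file.path(dir, "observations.csv"), "observations"),
       interventions = read_table(file.path(dir, "interventions.csv"), "interventions"),
       ground_truth = read_table(file.path(dir, "ground_truth.csv"), "ground_truth"))
}

#' Patient-level train/test split
#'
#' Assigns whole patients to partitions so no patient contributes rows to
#' both; stratified by label group so both partitions carry both classes.
#'
#' @param labels Cohort labels.
#' @param test_fraction Fraction of patients held out, in (0, 1).
#' @param seed Integer seed.
#' @return Tibble `patient_id`, `partition` (`"train"`/`"test"`).
#' @export
split_patients <- function(labels, test_fraction = 0.5, seed = 1L) {
  check_field(test_fraction > 0 && test_fraction < 1, "test_fraction",
              "must be in (0, 1)")
  withr::with_seed(seed, {
    labels |>
      select("patient_id", "group") |>
      group_by(.data$group) |>
      mutate(partition = ifelse(seq_len(dplyr::n()) %in%
                                  sample.int(dplyr::n(), round(dplyr::n() * test_fraction)),
                                "test", "train")) |>
      ungroup() |>
      select("patient_id", "partition")
  })
}

#' Configure an end-to-end validation run
#'
#' @param n_patients,prevalence,latent_separation_d,seed Generator
#'   settings, see [cohort_config()].
#' @param rules Annotation ruleset name (`"TPEVGH"` or `"US"`).
#' @param merge_gap_h,min_onset_h Annotation settings.
#' @param horizon_h,stable_window_h Feature-extraction settings.
#' @param threshold Alarm threshold (the fixed default is 0.7).
#' @param test_fraction Held-out patient fraction.
#' @param n_trees,max_depth,eta Model hyperparameters.
#' @param registry Feature registry.
#' @param out_dir Optional directory for report artifacts.
#' @return A list of class `hd_run_config`.
#' @export
pipeline_config <- function(n_patients = 2000, prevalence = 0.19,
                            latent_separation_d = 1.5, seed = 1L,
                            rules = "TPEVGH", merge_gap_h = 1, min_onset_h = 6,
                            horizon_h = 24, stable_window_h = 5,
                            threshold = 0.7, test_fraction = 0.5,
                            n_trees = 200, max_depth = 4, eta = 0.1,
                            registry = default_registry(), out_dir = NULL) {
  check_field(test_fraction > 0 && test_fraction < 1, "test_fraction",
              "must be in (0, 1)")
  structure(list(n_patients = n_patients, prevalence = prevalence,
                 latent_separation_d = latent_separation_d, seed = as.integer(seed),
                 rules = rules, merge_gap_h = merge_gap_h, min_onset_h = min_onset_h,
                 horizon_h = horizon_h, stable_window_h = stable_window_h,
                 threshold = threshold, test_fraction = test_fraction,
                 n_trees = n_trees, max_depth = max_depth, eta = eta,
                 registry = registry, out_dir = out_dir),
            class = "hd_run_config")
}

#' Run the full validation pipeline
#'
#' Generate (or accept) a cohort, apply the inclusion filters, annotate
#' instability from the intervention logs, extract the lead-time-indexed
#' sample matrix, split by patient, train the tree-ensemble score on the
#' training partition, score the held-out partition, and evaluate:
#' discrimination at one hour before onset (model vs shock index vs SBP,
#' with paired DeLong tests), time-varying AUROC over the horizon, a
#' threshold sweep, lead-time and false-alarm analysis, calibration,
#' admission-source/gender/type/mortality/year subgroups, and a manifest
#' of per-stage row counts. All randomness derives from the configured
#' seed; the same config and seed give identical results.
#'
#' @param config An [pipeline_config()] object.
#' @param cohort Optionally a pre-built `hd_cohort` (otherwise generated
#'   from the config).
#' @return A list of class `hd_pipeline` with elements `cohort`, `labels`,
#'   `samples`, `split`, `model`, `evaluation` (a list of result objects)
#'   and `manifest`.
#' @export
run_pipeline <- function(config, cohort = NULL) {
  if (!inherits(config, "hd_run_config")) {
    abort("`config` must come from pipeline_config()", class = "hemodyn_validation_error")
  }
  reg <- config$registry
  if (is.null(cohort)) {
    cohort <- generate_cohort(cohort_config(
      n_patients = config$n_patients, prevalence = config$prevalence,
      seed = config$seed, latent_separation_d = config$latent_separation_d,
      deterioration_horizon_h = config$horizon_h, registry = reg))
  }

  ann <- annotate_cohort(cohort$interventions, cohort$patients,
                         cohort$observations, rules = config$rules,
                         merge_gap_h = config$merge_gap_h,
                         min_onset_h = config$min_onset_h)
  labels <- ann$labels
  usable <- filter(labels, .data$group != "excluded")

  samples <- build_sample_matrix(usable, cohort$observations, reg,
                                 horizon_h = config$horizon_h,
                                 stable_window_h = config$stable_window_h)
  split <- split_patients(usable, config$test_fraction,
                          seed = substream_seed(config$seed, "split"))
  samples <- left_join(samples, split, by = "patient_id")
  train_samples <- filter(samples, .data$partition == "train")
  test_samples <- filter(samples, .data$partition == "test")
  attr(train_samples, "features") <- attr(samples, "features") <- reg$variable
  attr(train_samples, "registry_hash") <- hash(as.data.frame(reg))

  model <- train_risk_model(train_samples, n_trees = config$n_trees,
                            max_depth = config$max_depth, eta = config$eta,
                            seed = substream_seed(config$seed, "train"))

  test_scores <- predict_risk(model, test_samples)
  shock <- baseline_score(test_samples, "shock_index")
  sbp <- baseline_score(test_samples, "sbp")

  lead1_idx <- test_samples$label == 0 | test_samples$lead_hours == 1
  l1 <- test_samples$label[lead1_idx]
  disc <- list(
    model = delong_ci(test_scores[lead1_idx], l1),
    shock_index = delong_ci(shock[lead1_idx], l1),
    sbp = delong_ci(sbp[lead1_idx], l1),
    model_vs_shock_index = delong_paired_test(test_scores[lead1_idx],
                                              shock[lead1_idx], l1),
    model_vs_sbp = delong_paired_test(test_scores[lead1_idx], sbp[lead1_idx], l1))

  tv <- time_varying_auroc(test_samples,
                           list(model = test_scores, shock_index = shock, sbp = sbp),
                           leads = seq_len(config$horizon_h))
  sweep <- threshold_sweep(test_scores[lead1_idx], l1)
  thr <- config$threshold

  # hourly stable sampling for the alarm analyses on the held-out patients
  test_labels <- semi_join(usable, filter(split, .data$partition == "test"),
                           by = "patient_id")
  alarm_samples <- build_sample_matrix(test_labels, cohort$observations, reg,
                                       horizon_h = config$horizon_h,
                                       stable_window_h = config$stable_window_h,
                                       stable_hourly = TRUE,
                                       patients = cohort$patients)
  alarm_samples$score <- predict_risk(model, alarm_samples)
  lead_time <- lead_time_analysis(alarm_samples, threshold = thr,
                                  window_h = config$horizon_h,
                                  labels = test_labels)

  calibration <- calibration_table(test_scores[lead1_idx], l1)

  sub_tab <- test_samples[lead1_idx, c("patient_id", "label")]
  sub_tab$score <- test_scores[lead1_idx]
  sub_tab <- left_join(sub_tab,
                       cohort$patients[, c("patient_id", "admission_source",
                                           "gender", "admission_type",
                                           "icu_type", "mortality", "admit_year")],
                       by = "patient_id")
  subgroups <- list(
    admission_source = subgroup_metrics(sub_tab$score, sub_tab$label,
                                        sub_tab$admission_source, thr),
    gender = subgroup_metrics(sub_tab$score, sub_tab$label, sub_tab$gender, thr),
    admission_type = subgroup_metrics(sub_tab$score, sub_tab$label,
                                      sub_tab$admission_type, thr),
    icu_type = subgroup_metrics(sub_tab$score, sub_tab$label, sub_tab$icu_type, thr),
    mortality = subgroup_metrics(sub_tab$score, sub_tab$label,
                                 as.character(sub_tab$mortality), thr),
    year = subgroup_metrics(sub_tab$score, sub_tab$label,
                            year_groups(sub_tab$admit_year), thr))

  manifest <- build_manifest(config, cohort, ann, labels, samples, split)

  out <- list(cohort = cohort, labels = labels, segments = ann$segments,
              samples = samples, split = split, model = model,
              evaluation = list(discrimination = disc, time_varying = tv,
                                sweep = sweep, threshold = thr,
                                lead_time = lead_time,
                                calibration = calibration,
                                subgroups = subgroups),
              manifest = manifest, config = config)
  class(out) <- "hd_pipeline"
  if (!is.null(config$out_dir)) write_pipeline_artifacts(out, config$out_dir)
  out
}

build_manifest <- function(config, cohort, ann, labels, samples, split) {
  incl <- ann$inclusion_report
  n_total <- nrow(cohort$patients)
  n_included <- incl$n[incl$reason == "included"]
  counts <- tibble(
    stage = c("patients_total",
              paste0("excluded_", incl$reason[incl$reason != "included"]),
              "patients_included", "stable", "unstable", "excluded_only_early_segments",
              "sample_rows", "train_patients", "test_patients"),
    n = c(n_total, incl$n[incl$reason != "included"], n_included,
          sum(labels$group == "stable"), sum(labels$group == "unstable"),
          sum(labels$group == "excluded"), nrow(samples),
          sum(split$partition == "train"), sum(split$partition == "test")))
  structure(list(counts = counts,
                 config_hash = hash(config[setdiff(names(config), "registry")]),
                 seed = config$seed,
                 version = as.character(utils::packageVersion("hemodyn")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")),
            class = "hd_manifest")
}

#' @export
print.hd_manifest <- function(x, ...) {
  cat("<hd_manifest> seed", x$seed, "config", substr(x$config_hash, 1, 8), "\n")
  print(x$counts, n = Inf)
  invisible(x)
}

write_pipeline_artifacts <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- run$evaluation
  readr::write_csv(ev$time_varying, file.path(dir, "fig2a_table.csv"), progress = FALSE)
  readr::write_csv(ev$sweep, file.path(dir, "threshold_sweep.csv"), progress = FALSE)
  readr::write_csv(ev$lead_time$lead_curve, file.path(dir, "leadtime.csv"), progress = FALSE)
  readr::write_csv(ev$calibration, file.path(dir, "calibration.csv"), progress = FALSE)
  readr::write_csv(bind_rows(ev$subgroups, .id = "grouping"),
                   file.path(dir, "subgroups.csv"), progress = FALSE)
  write_table(run$labels, file.path(dir, "labels.csv"), "labels")
  metrics <- list(
    discrimination = lapply(ev$discrimination, as.list),
    threshold = ev$threshold,
    false_alarm_rate = ev$lead_time$false_alarm$overall,
    manifest = list(counts = as.list(run$manifest$counts),
                    config_hash = run$manifest$config_hash,
                    seed = run$manifest$seed))
  jsonlite::write_json(metrics, file.path(dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Summarise a pipeline run
#'
#' `glance()` returns the headline numbers of a run: lead-1 AUROCs for the
#' model and both baselines, the operating point at the configured
#' threshold, lead-time fractions and the false-alarm rate.
#'
#' @param x An `hd_pipeline`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.hd_pipeline <- function(x, ...) {
  ev <- x$evaluation
  at_thr <- ev$sweep[which.min(abs(ev$sweep$threshold - ev$threshold)), ]
  tibble(
    n_patients = nrow(x$cohort$patients),
    n_unstable = sum(x$labels$group == "unstable"),
    auroc_model = ev$discrimination$model$auroc,
    auroc_shock_index = ev$discrimination$shock_index$auroc,
    auroc_sbp = ev$discrimination$sbp$auroc,
    threshold = ev$threshold,
    recall = at_thr$recall,
    specificity = at_thr$specificity,
    precision = at_thr$precision,
    false_alarm_rate = ev$lead_time$false_alarm$overall,
    frac_alarmed_over_5h = mean(
      !is.na(ev$lead_time$first_alarm$first_alarm_lead_h) &
        ev$lead_time$first_alarm$first_alarm_lead_h > 5))
}

#' @export
print.hd_pipeline <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<hd_pipeline> %d patients (%d unstable)\n", g$n_patients, g$n_unstable))
  cat(sprintf("  lead-1 AUROC: model %.3f | shock index %.3f | SBP %.3f\n",
              g$auroc_model, g$auroc_shock_index, g$auroc_sbp))
  cat(sprintf("  at threshold %.2f: recall %.3f, specificity %.3f; false-alarm rate %.3f\n",
              g$threshold, g$recall, g$specificity, g$false_alarm_rate))
  invisible(x)
}
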