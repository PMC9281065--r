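#' Confusion-matrix metrics over a threshold grid
#'
#' Alarms fire when `score > threshold` (strict). For each grid threshold
#' the confusion matrix and derived recall (sensitivity), precision and
#' specificity are reported; the four cells sum to the sample size at
#' every threshold.
#'
#' @param scores Scores in `[0, 1]` (missing dropped pairwise with labels).
#' @param labels 0/1 outcomes.
#' @param step Grid step (default 0.01 over `[0, 1]`).
#' @return Tibble of class `hd_sweep`: `threshold`, `tp`, `fp`, `tn`,
#'   `fn`, `recall`, `precision`, `specificity`.
#' @export
threshold_sweep <- function(scores, labels, step = 0.01) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  check_field(length(scores) > 0, "scores", "no scored samples")
  grid <- seq(0, 1, by = step)
  pos <- sort(scores[labels == 1])
  neg <- sort(scores[labels == 0])
  n_pos <- length(pos)
  n_neg <- length(neg)
  tp <- n_pos - findInterval(grid, pos)   # scores strictly above threshold
  fp <- n_neg - findInterval(grid, neg)
  out <- tibble(
    threshold = grid, tp = tp, fp = fp,
    tn = n_neg - fp, fn = n_pos - tp,
    recall = if (n_pos > 0) tp / n_pos else NA_real_,
    precision = ifelse(tp + fp > 0, tp / (tp + fp), NA_real_),
    specificity = if (n_neg > 0) (n_neg - fp) / n_neg else NA_real_)
  class(out) <- c("hd_sweep", class(out))
  out
}

#' Select an alarm threshold from a sweep
#'
#' Policies: `"fixed"` returns `value` (default 0.7, the operating point
#' chosen to keep recall high at acceptable specificity);
#' `"break_even"` the grid threshold minimizing `|recall - specificity|`;
#' `"min_recall"` the threshold with maximum specificity among those with
#' recall at least `min_recall`.
#'
#' @param sweep Output of [threshold_sweep()].
#' @param policy Selection policy.
#' @param value Fixed threshold for `policy = "fixed"`.
#' @param min_recall Constraint for `policy = "min_recall"`.
#' @return A single threshold.
#' @export
select_threshold <- function(sweep, policy = c("fixed", "break_even", "min_recall"),
                             value = 0.7, min_recall = 0.7) {
  policy <- rlang::arg_match(policy)
  check_field(nrow(sweep) > 0, "sweep", "empty sweep")
  switch(policy,
    fixed = value,
    break_even = sweep$threshold[which.min(abs(sweep$recall - sweep$specificity))],
    min_recall = {
      ok <- sweep[!is.na(sweep$recall) & sweep$recall >= min_recall, , drop = FALSE]
      check_field(nrow(ok) > 0, "min_recall", "no threshold attains the recall floor")
      ok$threshold[which.max(ok$specificity)]
    })
}

#' Alarm lead-time and false-alarm analysis
#'
#' Works on hourly scored samples: unstable rows indexed by `lead_hours`
#' (hours before onset, 1..window) and stable rows sampled hourly
#' (`lead_hours = 0`, `reference_time` = hour of stay). An alarm is
#' `score > threshold` (strict). Reports, per lead hour, the fraction of
#' unstable patients alarmed at exactly that lead (per-hour true-alarm
#' fraction); the first-alarm lead per patient (the earliest crossing in
#' clock time, i.e. the largest alarmed lead within the window) with its
#' distribution quantiles and the non-increasing curve
#' `fraction(first-alarm lead >= k)`; and the stable-cohort false-alarm
#' rate, overall and per hour of stay.
#'
#' @param scored_samples Tibble with `patient_id`, `lead_hours`, `label`,
#'   `reference_time`, `score`.
#' @param threshold Alarm threshold.
#' @param window_h Lead window in hours.
#' @param labels Optional cohort labels; unstable patients absent from the
#'   scored samples are then counted and warned about.
#' @return A list of class `hd_lead_time`: `per_hour` (lead, n, true-alarm
#'   fraction), `first_alarm` (per patient), `lead_curve` (k, fraction of
#'   unstable patients with first-alarm lead >= k), `quantiles`,
#'   `false_alarm` (overall rate and per-hour tibble), `n_missed`,
#'   `n_excluded`.
#' @export
lead_time_analysis <- function(scored_samples, threshold = 0.7, window_h = 24,
                               labels = NULL) {
  s <- as_tibble(scored_samples)
  uns <- filter(s, .data$label == 1, .data$lead_hours >= 1,
                .data$lead_hours <= window_h)
  stab <- filter(s, .data$label == 0)
  n_excluded <- 0L
  if (!is.null(labels)) {
    expected <- labels$patient_id[labels$group == "unstable"]
    missing_pts <- setdiff(expected, unique(uns$patient_id))
    n_excluded <- length(missing_pts)
    if (n_excluded > 0) {
      warn(sprintf("%d unstable patients lack score series and were excluded", n_excluded))
    }
  }
  per_hour <- uns |>
    group_by(lead_hours = .data$lead_hours) |>
    summarise(n = dplyr::n(), true_alarm_fraction = mean(.data$score > threshold),
              .groups = "drop") |>
    arrange(.data$lead_hours)
  first_alarm <- uns |>
    group_by(.data$patient_id) |>
    summarise(first_alarm_lead_h = if (any(.data$score > threshold))
      max(.data$lead_hours[.data$score > threshold]) else NA_real_,
      .groups = "drop")
  n_pat <- nrow(first_alarm)
  lead_curve <- tibble(k = seq_len(window_h)) |>
    mutate(fraction = vapply(.data$k, function(kk) {
      if (n_pat == 0) return(NA_real_)
      mean(!is.na(first_alarm$first_alarm_lead_h) &
             first_alarm$first_alarm_lead_h >= kk)
    }, numeric(1)))
  alarmed <- first_alarm$first_alarm_lead_h[!is.na(first_alarm$first_alarm_lead_h)]
  quantiles <- if (length(alarmed) > 0) {
    tibble(prob = c(0.05, 0.25, 0.5, 0.75, 0.95),
           first_alarm_lead_h = unname(quantile(alarmed, c(0.05, 0.25, 0.5, 0.75, 0.95))))
  } else tibble(prob = numeric(0), first_alarm_lead_h = numeric(0))
  false_alarm_per_hour <- stab |>
    group_by(hour = floor(.data$reference_time)) |>
    summarise(n = dplyr::n(), false_alarm_rate = mean(.data$score > threshold),
              .groups = "drop")
  out <- list(
    per_hour = per_hour, first_alarm = first_alarm, lead_curve = lead_curve,
    quantiles = quantiles,
    false_alarm = list(
      overall = if (nrow(stab) > 0) mean(stab$score > threshold) else NA_real_,
      per_hour = false_alarm_per_hour),
    n_missed = sum(is.na(first_alarm$first_alarm_lead_h)),
    n_patients = n_pat, n_excluded = n_excluded, threshold = threshold)
  class(out) <- "hd_lead_time"
  out
}

#' @export
print.hd_lead_time <- function(x, ...) {
  cat(sprintf("<hd_lead_time> threshold %.2f: %d unstable patients, %d never alarmed; false-alarm rate %.3f\n",
              x$threshold, x$n_patients, x$n_missed, x$false_alarm$overall))
  invisible(x)
}

#' Calibration table
#'
#' Bins predictions into `n_bins` equal-width probability bins and reports
#' the mean prediction, observed event fraction and count per bin; empty
#' bins appear with zero count. Counts sum to the number of samples.
#'
#' @param scores Predicted probabilities in `[0, 1]`.
#' @param labels 0/1 outcomes.
#' @param n_bins Number of bins.
#' @return Tibble of class `hd_calibration`: `bin`, `bin_low`, `bin_high`,
#'   `mean_predicted`, `observed_fraction`, `count`.
#' @export
calibration_table <- function(scores, labels, n_bins = 10) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  check_field(length(scores) >= n_bins, "scores", "need at least n_bins samples")
  breaks <- seq(0, 1, length.out = n_bins + 1)
  bin <- cut(scores, breaks, include.lowest = TRUE, labels = FALSE)
  out <- tibble(bin = bin, score = scores, label = labels) |>
    group_by(.data$bin) |>
    summarise(mean_predicted = mean(.data$score),
              observed_fraction = mean(.data$label),
              count = dplyr::n(), .groups = "drop") |>
    tidyr::complete(bin = seq_len(n_bins),
                    fill = list(mean_predicted = NA_real_,
                                observed_fraction = NA_real_, count = 0L)) |>
    mutate(bin_low = breaks[.data$bin], bin_high = breaks[.data$bin + 1]) |>
    select("bin", "bin_low", "bin_high", "mean_predicted",
           "observed_fraction", "count")
  class(out) <- c("hd_calibration", class(out))
  out
}

#' Discrimination and operating-point metrics by subgroup
#'
#' For each group: AUROC with DeLong CI plus recall, precision and
#' specificity at the chosen threshold. Groups lacking either class are
#' skipped with a warning and flagged in the output.
#'
#' @param scores,labels Aligned score and outcome vectors.
#' @param groups Group membership vector aligned with `scores`.
#' @param threshold Alarm threshold for the operating point.
#' @param alpha CI error rate.
#' @return Tibble: `group`, `n`, `n_pos`, `auroc`, `ci_low`, `ci_high`,
#'   `recall`, `precision`, `specificity`, `skipped`.
#' @export
subgroup_metrics <- function(scores, labels, groups, threshold = 0.7,
                             alpha = 0.05) {
  keep <- !is.na(scores) & !is.na(labels) & !is.na(groups)
  scores <- scores[keep]; labels <- as.integer(labels[keep]); groups <- groups[keep]
  purrr::map_dfr(sort(unique(groups)), function(g) {
    idx <- groups == g
    s <- scores[idx]; l <- labels[idx]
    base <- tibble(group = as.character(g), n = sum(idx), n_pos = sum(l == 1))
    if (sum(l == 1) < 2 || sum(l == 0) < 2) {
      warn(sprintf("subgroup '%s' lacks both classes (or has < 2 per class); skipped", g))
      return(mutate(base, auroc = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    recall = NA_real_, precision = NA_real_,
                    specificity = NA_real_, skipped = TRUE))
    }
    ci <- delong_ci(s, l, alpha)
    tp <- sum(s > threshold & l == 1); fn <- sum(s <= threshold & l == 1)
    fp <- sum(s > threshold & l == 0); tn <- sum(s <= threshold & l == 0)
    mutate(base, auroc = ci$auroc, ci_low = ci$ci_low, ci_high = ci$ci_high,
           recall = tp / (tp + fn),
           precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
           specificity = tn / (tn + fp), skipped = FALSE)
  })
}

#' Calendar-year grouping with sparse-final-year merge
#'
#' Maps admission years to grouping labels, merging the final year into
#' the previous one when it has fewer than `min_n` patients (e.g. a year
#' with only a few months of enrolment).
#'
#' @param years Integer admission years.
#' @param min_n Minimum size for the final year to stand alone.
#' @return Character vector of year labels (merged years as `"2019-2020"`).
#' @export
year_groups <- function(years, min_n = 30) {
  tab <- table(years)
  labels <- as.character(years)
  if (length(tab) >= 2) {
    last <- as.integer(names(tab)[length(tab)])
    if (tab[length(tab)] < min_n) {
      prev <- as.integer(names(tab)[length(tab) - 1])
      merged <- paste0(prev, "-", last)
      labels[years %in% c(prev, last)] <- merged
    }
  }
  labels
}

#' Case-mix comparison between two cohorts
#'
#' Per registry variable: the median in each cohort's sample matrix and
#' the percent difference `(B - A) / A`. Optionally compares baseline
#' characteristic tables: Kruskal-Wallis p-values for continuous
#' variables and Fisher-exact p-values for categorical ones (reported
#' raw, uncorrected). Variables absent from a cohort are reported as not
#' comparable (`NA` medians).
#'
#' @param samples_a,samples_b Sample matrices (or any tibbles with
#'   registry-variable columns) for cohorts A and B.
#' @param registry Feature registry shared by both cohorts.
#' @param baseline_a,baseline_b Optional baseline-characteristics tables.
#' @param continuous,categorical Column names in the baseline tables to
#'   test.
#' @return A list of class `hd_case_mix`: `features` (variable, median_a,
#'   median_b, pct_diff) and `baseline` (variable, test, p_value).
#' @export
case_mix_report <- function(samples_a, samples_b, registry = default_registry(),
                            baseline_a = NULL, baseline_b = NULL,
                            continuous = character(0), categorical = character(0)) {
  med <- function(tab, v) {
    if (!v %in% names(tab)) return(NA_real_)
    median(tab[[v]], na.rm = TRUE)
  }
  features <- purrr::map_dfr(registry$variable, function(v) {
    ma <- med(samples_a, v)
    mb <- med(samples_b, v)
    tibble(variable = v, median_a = ma, median_b = mb,
           pct_diff = if (!is.na(ma) && !is.na(mb) && ma != 0)
             (mb - ma) / ma * 100 else NA_real_)
  })
  baseline <- tibble(variable = character(0), test = character(0),
                     p_value = numeric(0))
  if (!is.null(baseline_a) && !is.null(baseline_b)) {
    cohort <- rep(c("A", "B"), c(nrow(baseline_a), nrow(baseline_b)))
    baseline <- bind_rows(
      purrr::map_dfr(continuous, function(v) {
        vals <- c(baseline_a[[v]], baseline_b[[v]])
        tibble(variable = v, test = "kruskal_wallis",
               p_value = stats::kruskal.test(vals, factor(cohort))$p.value)
      }),
      purrr::map_dfr(categorical, function(v) {
        vals <- c(as.character(baseline_a[[v]]), as.character(baseline_b[[v]]))
        tbl <- table(vals, cohort)
        p <- tryCatch(stats::fisher.test(tbl, workspace = 2e6)$p.value,
                      error = function(e) withr::with_seed(
                        0L, stats::fisher.test(tbl, simulate.p.value = TRUE,
                                               B = 2000)$p.value))
        tibble(variable = v, test = "fisher_exact", p_value = p)
      }))
  }
  structure(list(features = features, baseline = baseline),
            class = "hd_case_mix")
}
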