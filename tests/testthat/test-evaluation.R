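test_that("auroc matches exhaustive pair counting, including ties", {
  expect_equal(auroc(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auroc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_error(auroc(c(1, 2), c(1, 1)), "both classes")
  withr::with_seed(31, {
    for (i in 1:100) {
      n <- sample(4:30, 1)
      labels <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
      expect_equal(auroc(scores, labels), pair_count_auroc(scores, labels))
    }
  })
})

test_that("reversing score orientation complements the AUROC", {
  withr::with_seed(5, {
    scores <- rnorm(50)  # tie-free
    labels <- rbinom(50, 1, 0.4)
    labels[1:2] <- c(0, 1)
    expect_equal(auroc(scores, labels) + auroc(-scores, labels), 1.0)
  })
})

test_that("DeLong interval contains the estimate and agrees with pROC", {
  withr::with_seed(17, {
    scores <- c(rnorm(80, 1), rnorm(120))
    labels <- rep(c(1, 0), c(80, 120))
  })
  ci <- delong_ci(scores, labels)
  expect_true(ci$ci_low <= ci$auroc && ci$auroc <= ci$ci_high)
  expect_gte(ci$se, 0)
  ref <- pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE), method = "delong")
  expect_equal(ci$ci_low, as.numeric(ref[1]), tolerance = 1e-8)
  expect_equal(ci$auroc, as.numeric(ref[2]), tolerance = 1e-10)
  expect_equal(ci$ci_high, as.numeric(ref[3]), tolerance = 1e-8)
  # perfect separation collapses the interval and is flagged
  perf <- delong_ci(c(1, 0.9, 0.1, 0.2), c(1, 1, 0, 0))
  expect_equal(perf$auroc, 1.0)
  expect_true(perf$degenerate)
  expect_equal(perf$ci_low, perf$ci_high)
})

test_that("paired DeLong test is antisymmetric and agrees with pROC", {
  withr::with_seed(23, {
    labels <- rep(c(1, 0), c(60, 90))
    a <- rnorm(150) + labels
    b <- 0.5 * a + rnorm(150, sd = 0.8)
  })
  t1 <- delong_paired_test(a, b, labels)
  t2 <- delong_paired_test(b, a, labels)
  expect_equal(t1$z, -t2$z)
  expect_equal(t1$p_value, t2$p_value)
  ref <- pROC::roc.test(pROC::roc(labels, a, quiet = TRUE),
                        pROC::roc(labels, b, quiet = TRUE), method = "delong")
  expect_equal(t1$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
  # identical scorers: z = 0, p = 1
  same <- delong_paired_test(a, a, labels)
  expect_equal(same$z, 0)
  expect_equal(same$p_value, 1)
  # a strong model beats noise decisively at n = 200/200
  withr::with_seed(29, {
    l2 <- rep(c(1, 0), each = 200)
    strong <- l2 + rnorm(400, sd = 0.1)
    noise <- rnorm(400)
  })
  expect_lt(delong_paired_test(strong, noise, l2)$p_value, 0.001)
})

test_that("time-varying AUROC handles degenerate scorers and missing leads", {
  samples <- tibble::tibble(
    label = rep(c(1, 0), c(6, 10)),
    lead_hours = c(rep(1L, 3), rep(2L, 3), rep(0L, 10)))
  const <- rep(0.5, 16)
  tv <- time_varying_auroc(samples, list(flat = const), leads = 1:2)
  expect_true(all(tv$auroc == 0.5))
  expect_warning(time_varying_auroc(samples, list(flat = const), leads = 3),
                 "lead 3")
  one <- time_varying_auroc(samples, list(m = seq(0, 1, length.out = 16)),
                            leads = 1)
  expect_equal(nrow(one), 1)
})

test_that("threshold sweep cells always sum to n with monotone recall/specificity", {
  withr::with_seed(41, {
    for (i in 1:20) {
      n <- sample(10:200, 1)
      scores <- round(runif(n), sample(c(1, 2, 3), 1))
      labels <- rbinom(n, 1, 0.3)
      if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
      sw <- threshold_sweep(scores, labels)
      expect_true(all(sw$tp + sw$fp + sw$tn + sw$fn == n))
      expect_true(all(diff(sw$recall) <= 1e-12))
      expect_true(all(diff(sw$specificity) >= -1e-12))
      expect_equal(sw$recall, sw$tp / (sw$tp + sw$fn))
      expect_equal(sw$specificity, sw$tn / (sw$tn + sw$fp))
    }
  })
  sw <- threshold_sweep(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
  expect_equal(sw$recall[sw$threshold == 0], 1)      # every positive above 0
  expect_equal(sw$recall[sw$threshold == 1], 0)      # nothing above 1
  expect_equal(sw$specificity[sw$threshold == 1], 1)
})

test_that("threshold policies behave as documented", {
  sw <- threshold_sweep(seq(0.01, 1, length.out = 100),
                        rep(c(0, 1), each = 50))
  expect_equal(select_threshold(sw, "fixed", value = 0.7), 0.7)
  be <- select_threshold(sw, "break_even")
  row <- sw[sw$threshold == be, ]
  expect_lt(abs(row$recall - row$specificity), 0.1)
  mr <- select_threshold(sw, "min_recall", min_recall = 0.8)
  expect_gte(sw$recall[sw$threshold == mr], 0.8)
  expect_error(select_threshold(sw[0, ], "fixed"), "sweep")
})

test_that("lead-time analysis finds the earliest crossing and monotone curves", {
  # one patient alarmed from lead 7 onward, one never alarmed
  scored <- dplyr::bind_rows(
    tibble::tibble(patient_id = "U1", lead_hours = 1:24, label = 1L,
                   reference_time = 30 - (1:24),
                   score = ifelse(1:24 <= 7, 0.9, 0.1)),
    tibble::tibble(patient_id = "U2", lead_hours = 1:24, label = 1L,
                   reference_time = 40 - (1:24), score = 0.2),
    tibble::tibble(patient_id = "S1", lead_hours = 0L, label = 0L,
                   reference_time = 1:30,
                   score = rep(c(0.8, 0.1, 0.1), 10)))
  lt <- lead_time_analysis(scored, threshold = 0.7)
  fa <- lt$first_alarm
  expect_equal(fa$first_alarm_lead_h[fa$patient_id == "U1"], 7)
  expect_true(is.na(fa$first_alarm_lead_h[fa$patient_id == "U2"]))
  expect_equal(lt$n_missed, 1)
  expect_true(all(diff(lt$lead_curve$fraction) <= 1e-12))
  expect_true(all(lt$lead_curve$fraction >= 0 & lt$lead_curve$fraction <= 1))
  expect_equal(lt$per_hour$true_alarm_fraction[lt$per_hour$lead_hours == 1], 0.5)
  expect_equal(lt$false_alarm$overall, 1 / 3)
  # a labelled unstable patient without series is counted and warned about
  labels <- tibble::tibble(patient_id = c("U1", "U2", "U3", "S1"),
                           group = c("unstable", "unstable", "unstable", "stable"))
  expect_warning(lt2 <- lead_time_analysis(scored, 0.7, labels = labels),
                 "1 unstable")
  expect_equal(lt2$n_excluded, 1)
})

test_that("calibration bins are self-consistent for Bernoulli(score) labels", {
  withr::with_seed(53, {
    scores <- runif(5000)
    labels <- rbinom(5000, 1, scores)
  })
  cal <- calibration_table(scores, labels, n_bins = 10)
  expect_equal(sum(cal$count), 5000)
  filled <- cal[cal$count > 20, ]
  se <- sqrt(filled$mean_predicted * (1 - filled$mean_predicted) / filled$count)
  expect_true(all(abs(filled$observed_fraction - filled$mean_predicted) <= 3 * se))
  # all-zero labels give zero observed rates
  cal0 <- calibration_table(runif(100), rep(0, 100))
  expect_true(all(cal0$observed_fraction[cal0$count > 0] == 0))
  expect_equal(sum(cal0$count), 100)
})

test_that("subgroup metrics reduce to global metrics for a single group", {
  withr::with_seed(61, {
    labels <- rbinom(300, 1, 0.3)
    scores <- runif(300) + 0.3 * labels
  })
  g1 <- subgroup_metrics(scores, labels, rep("all", 300), threshold = 0.5)
  global <- delong_ci(scores, labels)
  expect_equal(g1$auroc, global$auroc)
  expect_equal(g1$ci_low, global$ci_low)
  two <- subgroup_metrics(c(scores, scores), c(labels, labels),
                          rep(c("a", "b"), each = 300), threshold = 0.5)
  expect_equal(two$auroc[1], two$auroc[2])
  one_class_grp <- ifelse(seq_along(labels) %in% head(which(labels == 1), 10),
                          "posonly", "mixed")
  expect_warning(skipped <- subgroup_metrics(scores, labels, one_class_grp),
                 "posonly")
  expect_true(skipped$skipped[skipped$group == "posonly"])
})

test_that("year grouping merges a sparse final year", {
  years <- c(rep(2018, 40), rep(2019, 40), rep(2020, 5))
  g <- year_groups(years, min_n = 30)
  expect_true(all(g[years >= 2019] == "2019-2020"))
  expect_true(all(g[years == 2018] == "2018"))
  full <- year_groups(c(rep(2018, 40), rep(2019, 40)), min_n = 30)
  expect_setequal(unique(full), c("2018", "2019"))
})

test_that("case-mix medians and percent differences match direct arithmetic", {
  reg <- default_registry()
  a <- tibble::tibble(glucose = c(100, 123, 150), bun = c(10, 18, 40),
                      ast = c(20, 27, 33))
  b <- tibble::tibble(glucose = c(160, 168, 200), bun = c(25, 31, 60),
                      ast = c(40, 47, 90))
  rep_ab <- case_mix_report(a, b, reg)
  f <- rep_ab$features
  expect_equal(f$pct_diff[f$variable == "glucose"], (168 - 123) / 123 * 100)
  expect_equal(f$pct_diff[f$variable == "bun"], (31 - 18) / 18 * 100)
  expect_equal(f$pct_diff[f$variable == "ast"], (47 - 27) / 27 * 100)
  expect_true(is.na(f$median_a[f$variable == "lactate"]))  # not comparable
  same <- case_mix_report(a, a, reg)
  expect_true(all(same$features$pct_diff[!is.na(same$features$pct_diff)] == 0))
  # baseline tests: Kruskal-Wallis for continuous, Fisher for categorical
  base_a <- tibble::tibble(apache2 = c(10, 20, 30, 15, 25),
                           gender = c("m", "m", "f", "f", "m"))
  base_b <- tibble::tibble(apache2 = c(40, 45, 50, 42, 48),
                           gender = c("m", "f", "f", "f", "f"))
  rb <- case_mix_report(a, b, reg, base_a, base_b,
                        continuous = "apache2", categorical = "gender")
  kw <- rb$baseline[rb$baseline$variable == "apache2", ]
  expect_equal(kw$p_value,
               kruskal.test(c(base_a$apache2, base_b$apache2),
                            factor(rep(c("A", "B"), each = 5)))$p.value)
  expect_equal(rb$baseline$test[rb$baseline$variable == "gender"], "fisher_exact")
})
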