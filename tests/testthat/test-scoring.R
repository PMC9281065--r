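# small cohorts shared across scoring tests
scoring_fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cohort <- generate_cohort(cohort_config(n_patients = 300, seed = 21,
                                              latent_separation_d = 1.5))
      ann <- annotate_cohort(cohort$interventions, cohort$patients,
                             cohort$observations)
      samples <- build_sample_matrix(ann$labels, cohort$observations)
      cache <<- list(cohort = cohort, labels = ann$labels, samples = samples)
    }
    cache
  }
})

test_that("training is deterministic and invariant to row permutation", {
  fx <- scoring_fixture()
  m1 <- train_risk_model(fx$samples, n_trees = 30, seed = 4)
  m2 <- train_risk_model(fx$samples, n_trees = 30, seed = 4)
  shuffled <- withr::with_seed(1, fx$samples[sample(nrow(fx$samples)), ])
  attr(shuffled, "features") <- attr(fx$samples, "features")
  m3 <- train_risk_model(shuffled, n_trees = 30, seed = 4)
  p <- predict_risk(m1, fx$samples)
  expect_identical(p, predict_risk(m2, fx$samples))
  expect_identical(p, predict_risk(m3, fx$samples))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("single-class training fails and schema mismatch is named", {
  fx <- scoring_fixture()
  stable_only <- fx$samples[fx$samples$label == 0, ]
  expect_error(train_risk_model(stable_only), "both classes")
  m <- train_risk_model(fx$samples, n_trees = 20, seed = 1)
  expect_error(predict_risk(m, fx$samples[, 1:5]), "heart_rate")
})

test_that("missing values are tolerated, including an all-missing row", {
  fx <- scoring_fixture()
  m <- train_risk_model(fx$samples, n_trees = 30, seed = 2)
  empty <- fx$samples[1, ]
  empty[, m$features] <- NA_real_
  s <- predict_risk(m, empty)
  expect_true(is.finite(s) && s >= 0 && s <= 1)
  # duplicated rows score identically (pure function)
  two <- dplyr::bind_rows(fx$samples[3, ], fx$samples[3, ])
  expect_equal(predict_risk(m, two)[1], predict_risk(m, two)[2])
})

test_that("a separable training set is fit perfectly, permuted labels are not", {
  reg <- default_registry()
  n <- 200
  sep <- tibble::tibble(
    patient_id = sprintf("Q%03d", 1:n),
    reference_time = 5, lead_hours = rep(c(1L, 0L), each = n / 2),
    label = rep(c(1L, 0L), each = n / 2))
  for (v in reg$variable) sep[[v]] <- NA_real_
  sep$heart_rate <- ifelse(sep$label == 1, 130, 70) + rep_len(c(-1, 0, 1), n)
  attr(sep, "features") <- reg$variable
  m <- train_risk_model(sep, n_trees = 50, seed = 1)
  expect_equal(auroc(predict_risk(m, sep), sep$label), 1.0)
  # permuted labels: held-out AUROC compatible with 0.5
  fx <- scoring_fixture()
  perm <- fx$samples
  perm$label <- withr::with_seed(7, sample(perm$label))
  perm <- perm[perm$lead_hours <= 1, ]   # one row per patient
  attr(perm, "features") <- attr(fx$samples, "features")
  half <- withr::with_seed(8, sample(nrow(perm)) <= nrow(perm) / 2)
  train <- perm[half, ]; test <- perm[!half, ]
  attr(train, "features") <- attr(fx$samples, "features")
  m0 <- train_risk_model(train, n_trees = 30, seed = 1,
                         one_row_per_patient = FALSE)
  a <- auroc(predict_risk(m0, test), test$label)
  m_pos <- sum(test$label == 1); m_neg <- sum(test$label == 0)
  se <- sqrt((m_pos + m_neg + 1) / (12 * m_pos * m_neg))
  expect_lt(abs(a - 0.5), 3 * se)
})

test_that("baseline scores are oriented so higher means riskier", {
  s <- tibble::tibble(heart_rate = c(110, 70, 80), sbp_inv = c(88, 120, NA))
  sbp <- baseline_score(s, "sbp")
  expect_gt(sbp[1], sbp[2])          # SBP 88 riskier than 120
  si <- baseline_score(s, "shock_index")
  expect_gt(si[1], si[2])
  expect_true(is.na(si[3]))
  expect_error(baseline_score(s, "bogus"))
})

test_that("score timelines cover every hour and track deterioration", {
  fx <- scoring_fixture()
  m <- train_risk_model(fx$samples, n_trees = 50, seed = 3)
  gt <- fx$cohort$ground_truth
  unstable_ids <- gt$patient_id[gt$group == "unstable" & gt$onset_time >= 12]
  pts <- fx$cohort$patients[fx$cohort$patients$patient_id %in% unstable_ids, ]
  obs <- fx$cohort$observations[fx$cohort$observations$patient_id %in% unstable_ids, ]
  tl <- score_timeline(m, obs, pts)
  for (pid in head(unstable_ids, 3)) {
    series <- tl[tl$patient_id == pid, ]
    expect_equal(nrow(series), floor(pts$los_h[pts$patient_id == pid]))
    expect_true(all(diff(series$reference_time) > 0))
  }
  # deteriorating patients drift upward toward onset: positive score-vs-time
  # trend over the pre-onset ramp for the typical patient
  rho <- vapply(unstable_ids, function(pid) {
    onset <- gt$onset_time[gt$patient_id == pid]
    pre <- tl[tl$patient_id == pid &
                tl$reference_time >= onset - 24 & tl$reference_time <= onset, ]
    suppressWarnings(cor(pre$reference_time, pre$score, method = "spearman"))
  }, numeric(1))
  expect_gt(median(rho, na.rm = TRUE), 0)
  expect_gt(mean(rho > 0, na.rm = TRUE), 0.7)
  # empty stay gives an empty series
  empty <- score_timeline(m, obs[0, ], pts[0, ])
  expect_equal(nrow(empty), 0)
})
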