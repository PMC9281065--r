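#' Train the tree-ensemble risk score
#'
#' Fits a gradient-boosted ensemble of depth-limited decision trees
#' (via xgboost) mapping the registry variables to an instability
#' probability. Missing inputs are handled natively: every split learns a
#' default branch, so a row with any subset of missing variables — even
#' all-missing — still receives a finite score in `[0, 1]`.
#'
#' By default training uses one randomly chosen lead-time row per unstable
#' patient (seeded) plus the stable rows, mimicking onset-anchored training
#' without leaking a patient's whole trajectory; rows are canonically
#' sorted before fitting so the result is invariant to input row order.
#'
#' @param samples An `hd_samples` tibble from [build_sample_matrix()] with
#'   both labels present.
#' @param n_trees,max_depth,eta Ensemble size, tree depth and learning
#'   rate (defaults 200, 4, 0.1).
#' @param seed Integer seed (governs the per-patient row draw and the
#'   fitting).
#' @param one_row_per_patient Sample a single lead row per unstable
#'   patient for training.
#' @return An object of class `hd_risk_model`.
#' @export
train_risk_model <- function(samples, n_trees = 200, max_depth = 4, eta = 0.1,
                             seed = 1L, one_row_per_patient = TRUE) {
  features <- attr(samples, "features") %||% intersect(default_registry()$variable, names(samples))
  check_field(length(unique(samples$label)) == 2, "samples",
              "training set must contain both classes")
  train <- arrange(as_tibble(samples), .data$patient_id, .data$lead_hours,
                   .data$reference_time)
  if (one_row_per_patient) {
    pos <- train |>
      filter(.data$label == 1) |>
      group_by(.data$patient_id) |>
      group_modify(function(rows, key) {
        k <- withr::with_seed(substream_seed(seed, key$patient_id),
                              sample.int(nrow(rows), 1))
        rows[k, , drop = FALSE]
      }) |>
      ungroup()
    train <- bind_rows(pos, filter(train, .data$label == 0))
  }
  train <- arrange(train, .data$patient_id, .data$lead_hours, .data$reference_time)
  x <- as.matrix(train[, features])
  y <- train$label
  dtrain <- xgboost::xgb.DMatrix(x, label = y, missing = NA)
  booster <- withr::with_seed(seed, xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, nthread = 1, seed = seed),
    data = dtrain, nrounds = n_trees, verbose = 0))
  structure(list(
    booster = booster, features = features, n_trees = n_trees,
    max_depth = max_depth, eta = eta, seed = seed,
    class_prior = mean(y), n_train = nrow(train),
    registry_hash = attr(samples, "registry_hash")
  ), class = "hd_risk_model")
}

#' Score samples with a risk model
#'
#' A pure function of the model and the feature values: returns one
#' probability per row, including rows with all features missing.
#'
#' @param model An `hd_risk_model`.
#' @param samples Tibble carrying the model's feature columns.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_risk <- function(model, samples) {
  miss <- setdiff(model$features, names(samples))
  check_field(length(miss) == 0, "samples",
              paste("missing feature columns:", paste(miss, collapse = ", ")))
  x <- as.matrix(as_tibble(samples)[, model$features])
  as.numeric(stats::predict(model$booster, xgboost::xgb.DMatrix(x, missing = NA)))
}

#' Single-parameter baseline scores
#'
#' Returns the baseline oriented so that higher means riskier: the shock
#' index (heart rate / SBP) as-is, SBP negated. Missing inputs give a
#' missing score (excluded pairwise from AUROC downstream).
#'
#' @param samples Tibble with `heart_rate` and `sbp_inv` (post-imputation).
#' @param which `"shock_index"` or `"sbp"`.
#' @return Numeric vector.
#' @export
baseline_score <- function(samples, which = c("shock_index", "sbp")) {
  which <- rlang::arg_match(which)
  switch(which,
         shock_index = compute_shock_index(samples),
         sbp = -samples$sbp_inv)
}

#' Hourly risk-score timeline over each patient's stay
#'
#' Builds a sample at every whole hour of the stay (staleness-limited LOCF
#' plus fallback imputation) and scores it, producing the series used by
#' the lead-time and false-alarm analyses.
#'
#' @param model An `hd_risk_model`.
#' @param observations Plausibility-filtered observation table.
#' @param patients Patients table with `los_h`.
#' @param registry Feature registry.
#' @param grid_step_h Grid step in hours.
#' @return Tibble `patient_id`, `reference_time`, `score`.
#' @export
score_timeline <- function(model, observations, patients,
                           registry = default_registry(), grid_step_h = 1) {
  grid <- patients |>
    select("patient_id", "los_h") |>
    mutate(n = floor(.data$los_h / grid_step_h)) |>
    filter(.data$n >= 1) |>
    tidyr::uncount(.data$n, .id = "k") |>
    mutate(reference_time = .data$k * grid_step_h) |>
    select("patient_id", "reference_time")
  if (nrow(grid) == 0) {
    return(tibble(patient_id = character(), reference_time = numeric(),
                  score = numeric()))
  }
  queries <- mutate(grid, .row_id = dplyr::row_number())
  wide <- locf_sample(observations, queries, registry) |>
    impute_features(registry)
  tibble(patient_id = wide$patient_id,
         reference_time = wide$reference_time,
         score = predict_risk(model, wide))
}

#' @export
print.hd_risk_model <- function(x, ...) {
  cat(sprintf("<hd_risk_model> %d trees, depth %d, eta %.2f, %d training rows (prior %.3f)\n",
              x$n_trees, x$max_depth, x$eta, x$n_train, x$class_prior))
  invisible(x)
}

#' Tidy a fitted risk model
#'
#' `tidy()` returns per-feature split gain and frequency; `glance()` a
#' one-row model summary.
#'
#' @param x An `hd_risk_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hd_risk_model <- function(x, ...) {
  imp <- xgboost::xgb.importance(model = x$booster)
  as_tibble(imp) |>
    rename(feature = "Feature", gain = "Gain", cover = "Cover",
           frequency = "Frequency")
}

#' @rdname tidy.hd_risk_model
#' @export
glance.hd_risk_model <- function(x, ...) {
  tibble(n_trees = x$n_trees, max_depth = x$max_depth, eta = x$eta,
         n_train = x$n_train, class_prior = x$class_prior, seed = x$seed)
}
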