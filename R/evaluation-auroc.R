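#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, with ties counted one half (midranks).
#' Missing scores are dropped pairwise with their labels.
#'
#' @param scores Numeric score vector (higher = riskier).
#' @param labels 0/1 (or logical) outcome vector.
#' @return The AUROC.
#' @examples
#' auroc(c(0.8, 0.4, 0.6, 0.2), c(1, 1, 0, 0))  # 0.75
#' @export
auroc <- function(scores, labels) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  m <- sum(labels == 1)
  n <- sum(labels == 0)
  check_field(m > 0 && n > 0, "labels", "both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - m * (m + 1) / 2) / (m * n)
}

# DeLong structural components via midranks (Sun & Xu fast formulation).
# scores: matrix with one column per scorer; returns list(theta, S10, S01, m, n)
delong_components <- function(scores, labels) {
  labels <- as.integer(labels)
  x_idx <- which(labels == 1)
  y_idx <- which(labels == 0)
  m <- length(x_idx)
  n <- length(y_idx)
  k <- ncol(scores)
  theta <- numeric(k)
  V10 <- matrix(0, m, k)
  V01 <- matrix(0, n, k)
  for (j in seq_len(k)) {
    x <- scores[x_idx, j]
    y <- scores[y_idx, j]
    tx <- rank(c(x, y), ties.method = "average")[seq_len(m)]
    ty <- rank(c(x, y), ties.method = "average")[m + seq_len(n)]
    txx <- rank(x, ties.method = "average")
    tyy <- rank(y, ties.method = "average")
    V10[, j] <- (tx - txx) / n
    V01[, j] <- 1 - (ty - tyy) / m
    theta[j] <- (sum(tx) - m * (m + 1) / 2) / (m * n)
  }
  list(theta = theta,
       S10 = stats::cov(V10), S01 = stats::cov(V01),
       m = m, n = n)
}

#' AUROC with a DeLong confidence interval
#'
#' Variance from the DeLong structural components (midranks for ties),
#' normal-approximation interval truncated to `[0, 1]`. With perfect
#' separation the variance degenerates to zero and the interval collapses
#' to the point estimate (`degenerate` flag set).
#'
#' @param scores,labels As in [auroc()] (missing scores dropped pairwise).
#' @param alpha Two-sided error rate (default 0.05 for a 95% CI).
#' @return One-row tibble of class `hd_discrimination`: `auroc`, `ci_low`,
#'   `ci_high`, `se`, `n_pos`, `n_neg`, `alpha`, `degenerate`.
#' @export
delong_ci <- function(scores, labels, alpha = 0.05) {
  keep <- !is.na(scores) & !is.na(labels)
  scores <- scores[keep]
  labels <- as.integer(labels[keep])
  check_field(sum(labels == 1) >= 2 && sum(labels == 0) >= 2, "labels",
              "need at least two samples in each class")
  cmp <- delong_components(matrix(scores, ncol = 1), labels)
  v <- cmp$S10[1, 1] / cmp$m + cmp$S01[1, 1] / cmp$n
  se <- sqrt(max(v, 0))
  z <- stats::qnorm(1 - alpha / 2)
  out <- tibble(
    auroc = cmp$theta[1],
    ci_low = max(0, cmp$theta[1] - z * se),
    ci_high = min(1, cmp$theta[1] + z * se),
    se = se, n_pos = cmp$m, n_neg = cmp$n, alpha = alpha,
    degenerate = se == 0)
  class(out) <- c("hd_discrimination", class(out))
  out
}

#' Paired DeLong test for two correlated AUROCs
#'
#' Compares two scorers evaluated on the same samples using the paired
#' DeLong covariance of their structural components. Identical score
#' vectors give `z = 0`, `p = 1`; swapping the scorers negates `z`.
#'
#' @param scores_a,scores_b Score vectors for the two models on the same
#'   samples. Rows where either score or the label is missing are dropped.
#' @param labels 0/1 outcome vector.
#' @return One-row tibble: `auroc_a`, `auroc_b`, `delta`, `z`, `p_value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels) {
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  s <- cbind(scores_a[keep], scores_b[keep])
  labels <- as.integer(labels[keep])
  check_field(sum(labels == 1) >= 2 && sum(labels == 0) >= 2, "labels",
              "need at least two samples in each class")
  cmp <- delong_components(s, labels)
  contrast <- c(1, -1)
  v <- drop(t(contrast) %*% cmp$S10 %*% contrast) / cmp$m +
    drop(t(contrast) %*% cmp$S01 %*% contrast) / cmp$n
  delta <- cmp$theta[1] - cmp$theta[2]
  z <- if (v <= 0) {
    if (abs(delta) < .Machine$double.eps^0.5) 0 else sign(delta) * Inf
  } else delta / sqrt(v)
  tibble(auroc_a = cmp$theta[1], auroc_b = cmp$theta[2], delta = delta,
         z = z, p_value = if (is.infinite(z)) 0 else 2 * stats::pnorm(-abs(z)))
}

#' Time-varying discrimination by hours before onset
#'
#' For each lead `t`, the AUROC (with DeLong CI) of unstable rows sampled
#' `t` hours before onset against the stable rows, for any number of
#' scorers. The stable-group sample is reused at every lead. Leads with no
#' positive rows are omitted with a warning.
#'
#' @param samples An `hd_samples` tibble (needs `lead_hours`, `label`).
#' @param scores Named list of score vectors aligned with `samples` rows
#'   (or a single numeric vector, named `"model"`).
#' @param leads Integer leads to evaluate.
#' @param alpha CI error rate.
#' @return Tibble of class `hd_tv_auroc`: `lead_hours`, `scorer`, `auroc`,
#'   `ci_low`, `ci_high`, `n_pos`, `n_neg`.
#' @export
time_varying_auroc <- function(samples, scores, leads = 1:24, alpha = 0.05) {
  if (is.numeric(scores)) scores <- list(model = scores)
  stable_idx <- which(samples$label == 0)
  out <- purrr::map_dfr(leads, function(t) {
    pos_idx <- which(samples$label == 1 & samples$lead_hours == t)
    if (length(pos_idx) == 0) {
      warn(sprintf("no positive rows at lead %d h; omitted", t))
      return(tibble())
    }
    purrr::map_dfr(names(scores), function(nm) {
      s <- scores[[nm]][c(pos_idx, stable_idx)]
      l <- rep(c(1L, 0L), c(length(pos_idx), length(stable_idx)))
      ci <- delong_ci(s, l, alpha)
      tibble(lead_hours = t, scorer = nm, auroc = ci$auroc,
             ci_low = ci$ci_low, ci_high = ci$ci_high,
             n_pos = ci$n_pos, n_neg = ci$n_neg)
    })
  })
  class(out) <- c("hd_tv_auroc", class(out))
  out
}
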