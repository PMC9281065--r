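# Independent brute-force oracles used to cross-check the package's
# vectorized implementations on small random instances.

# AUROC by exhaustive pair counting (ties count one half).
pair_count_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Volume-window onsets by brute force: recompute the window total from
# scratch at every critical time (event times and event expiries), walking
# forward with the re-arming rule. O(n^2); independent of the package's
# cumulative-sum implementation.
brute_volume_onsets <- function(time, volume, window_h, threshold, comparator = ">=") {
  crit <- sort(unique(c(time, time + window_h)))
  onsets <- numeric(0)
  armed <- TRUE
  for (tc in crit) {
    total <- sum(volume[time > tc - window_h & time <= tc])
    meets <- if (comparator == ">=") total >= threshold else total > threshold
    if (armed && meets && any(abs(time - tc) < 1e-12)) {
      onsets <- c(onsets, tc)
      armed <- FALSE
    } else if (!armed && !meets) {
      armed <- TRUE
    }
  }
  onsets
}

# Combination-window onsets by brute force over critical times.
brute_combo_onsets <- function(events, components, window_h) {
  ev <- events[events$category %in% names(components), , drop = FALSE]
  if (nrow(ev) == 0) return(numeric(0))
  crit <- sort(unique(c(ev$time, ev$time + window_h)))
  onsets <- numeric(0)
  armed <- TRUE
  for (tc in crit) {
    meets <- all(vapply(names(components), function(cat) {
      sub <- ev[ev$category == cat & ev$time > tc - window_h & ev$time <= tc, ]
      sum(sub$volume_cc) >= components[[cat]]
    }, logical(1)))
    if (armed && meets && any(abs(ev$time - tc) < 1e-12)) {
      onsets <- c(onsets, tc)
      armed <- FALSE
    } else if (!armed && !meets) {
      armed <- TRUE
    }
  }
  onsets
}

# Random intervention log for oracle-equivalence tests.
random_fluid_log <- function(n_events, max_t = 48) {
  tibble::tibble(
    patient_id = "X",
    time = round(runif(n_events, 0, max_t), 2),
    category = sample(c("fluid_crystalloid", "fluid_colloid", "prbc", "ffp",
                        "platelet_pheresis", "albumin25"),
                      n_events, replace = TRUE),
    agent = NA_character_,
    volume_cc = sample(c(100, 200, 250, 500, 800, 1000, 1500), n_events,
                       replace = TRUE),
    dose = NA_real_)
}

# A tiny deterministic observation stream for feature tests.
tiny_observations <- function() {
  tibble::tibble(
    patient_id = "P1",
    time = c(0, 2, 2, 4, 9, 9.5),
    variable = c("heart_rate", "lactate", "sbp_ninv", "heart_rate",
                 "heart_rate", "sbp_ninv"),
    value = c(80, 2.5, 112, 95, 110, 88),
    source = "test")
}
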