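# Builders shared across test files. All fixtures are constructed in code.

# Homogeneous Poisson spike train on [t0, t1) at `rate` Hz.
poisson_train <- function(rate, t0, t1) {
  n <- rpois(1, rate * (t1 - t0))
  sort(runif(n, t0, t1))
}

# A bare session of `n` tones with fixed onset spacing and optional shocks.
make_session <- function(onsets, tone_s = 30, shock = TRUE,
                         platform = NULL, presses = NULL, freezing = NULL,
                         headturn = NULL) {
  trials <- lapply(seq_along(onsets), function(k) {
    on <- onsets[k]
    trial_events(
      trial_id = k, tone_onset_s = on, tone_duration_s = tone_s,
      shock_interval_s = if (shock) c(on + tone_s - 2, on + tone_s) else NULL,
      platform_intervals_s = if (!is.null(platform)) platform[[k]] else NULL,
      headturn_s = if (!is.null(headturn)) headturn[k] else NA_real_,
      freezing_intervals_s = if (!is.null(freezing)) freezing[[k]] else NULL,
      press_times_s = if (!is.null(presses)) presses[[k]] else numeric(0))
  })
  session_events(trials, session_id = "fixture")
}

make_unit <- function(spikes, unit_id = "u1", region = "rPL",
                      group = "avoidance", width = 300) {
  unit_recording(unit_id = unit_id, region = region,
                 spike_width_us = width, group = group,
                 spike_times_s = spikes)
}

# A forged zscore_row for direct classification tests: z0/z1 are the first
# two post-event bins, baseline bins are zero.
forge_zrow <- function(z0, z1, cfg = classifier_config(),
                       unclassifiable = FALSE) {
  nb <- cfg$baseline_bins + cfg$response_bins
  z <- rep(0, nb)
  z[cfg$baseline_bins + 1L] <- z0
  z[cfg$baseline_bins + 2L] <- z1
  structure(list(unit_id = "forged", z = z,
                 bin_edges_s = seq(-cfg$baseline_bins * cfg$bin_width_s,
                                   cfg$response_bins * cfg$bin_width_s,
                                   by = cfg$bin_width_s),
                 unclassifiable = unclassifiable,
                 alignment = "tone_onset"),
            class = "zscore_row")
}

# Random non-overlapping sorted half-open intervals inside [lo, hi).
random_intervals <- function(n, lo, hi) {
  if (n == 0) return(NULL)
  pts <- sort(runif(2 * n, lo, hi))
  matrix(pts, ncol = 2, byrow = TRUE)
}
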