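#' Percent time on platform during the tone
#'
#' 100 x (platform occupancy intersected with the tone window) / tone
#' length. Intervals are half-open, so occupancy is invariant to splitting
#' an interval at an interior point.
#'
#' @param trial a \code{trial_events}.
#' @return Percentage between 0 and 100.
#' @export
platform_percent <- function(trial) {
  on <- trial$tone_onset_s
  100 * interval_occupancy(trial$platform_intervals_s, on,
                           on + trial$tone_duration_s) /
    trial$tone_duration_s
}

#' Platform occupancy timecourse in 3-s bins
#'
#' Percent of each successive 3-s bin of the tone spent on the platform.
#' The mean of the ten bin values equals [platform_percent()] exactly.
#'
#' @param trial a \code{trial_events}.
#' @param bin_s bin width, seconds.
#' @return Numeric vector of per-bin percentages.
#' @export
platform_timecourse <- function(trial, bin_s = 3) {
  on <- trial$tone_onset_s
  edges <- seq(0, trial$tone_duration_s, by = bin_s)
  vapply(seq_len(length(edges) - 1L), function(b) {
    100 * interval_occupancy(trial$platform_intervals_s,
                             on + edges[b], on + edges[b + 1L]) / bin_s
  }, numeric(1))
}

#' Avoidance latency of a trial
#'
#' Time from tone onset to the first platform entry within the tone.
#' Trials with no entry during the tone (including rats already on the
#' platform at onset with no re-entry) are capped at the tone length and
#' flagged never-avoided; capped latencies enter rank tests at ceiling,
#' matching how non-avoiders are plotted.
#'
#' @param trial a \code{trial_events}.
#' @return List: \code{latency_s}, \code{never_avoided}.
#' @export
avoidance_latency <- function(trial) {
  on <- trial$tone_onset_s
  entries <- trial$platform_intervals_s[, 1L]
  entries <- entries[entries >= on & entries < on + trial$tone_duration_s]
  if (length(entries))
    list(latency_s = entries[1L] - on, never_avoided = FALSE)
  else
    list(latency_s = trial$tone_duration_s, never_avoided = TRUE)
}

#' Conditioned suppression ratio of bar pressing
#'
#' (pretone rate - tone rate) / (pretone rate + tone rate): 0 means no
#' suppression, 1 complete suppression (no pressing during the tone), and
#' negative values indicate facilitation. Both rates zero yields 0 by
#' convention. \code{percent = TRUE} returns the x100 display scale.
#'
#' @param pretone_rate,tone_rate press rates (Hz or presses/min, any common
#'   unit), non-negative.
#' @param percent return percentage rather than the unit-scaled ratio.
#' @return Suppression ratio between -1 and 1 (or -100 and 100).
#' @export
suppression_ratio <- function(pretone_rate, tone_rate, percent = FALSE) {
  stopifnot(all(pretone_rate >= 0), all(tone_rate >= 0))
  denom <- pretone_rate + tone_rate
  r <- ifelse(denom == 0, 0, (pretone_rate - tone_rate) / denom)
  if (percent) 100 * r else r
}

#' Pretone and tone bar-press rates for a trial
#'
#' Pretone rate uses the 60 s before tone onset; tone rate the 30-s tone.
#' Presses are pooled across the whole session before windowing, so trial
#' bookkeeping of inter-trial presses does not affect the rates.
#'
#' @param trial a \code{trial_events}.
#' @param session the containing \code{session_events} (for pooled
#'   presses); if NULL, the trial's own press list is used.
#' @param config a [classifier_config()].
#' @return List: \code{pretone_rate_hz}, \code{tone_rate_hz}.
#' @export
press_rates <- function(trial, session = NULL,
                        config = classifier_config()) {
  presses <- if (is.null(session)) trial$press_times_s
             else session_press_times(session)
  on <- trial$tone_onset_s
  w <- config$pretone_rate_window_s
  pre <- sum(presses >= on - w & presses < on) / w
  tone <- sum(presses >= on & presses < on + trial$tone_duration_s) /
    trial$tone_duration_s
  list(pretone_rate_hz = pre, tone_rate_hz = tone)
}

#' Percent time freezing during the tone
#'
#' @param trial a \code{trial_events} (freezing enters as pre-scored
#'   intervals).
#' @return Percentage between 0 and 100.
#' @export
freezing_percent <- function(trial) {
  on <- trial$tone_onset_s
  100 * interval_occupancy(trial$freezing_intervals_s, on,
                           on + trial$tone_duration_s) /
    trial$tone_duration_s
}

#' Behavioral summary of a session
#'
#' One row per trial with every behavioral endpoint: percent time on
#' platform, avoidance latency (capped), percent freezing, press rates and
#' the suppression ratio. Trials are reported individually and never
#' averaged silently across tones.
#'
#' @param session a \code{session_events}.
#' @param config a [classifier_config()].
#' @return data.frame with columns \code{trial_id, pct_platform,
#'   avoid_latency_s, never_avoided, pct_freezing, pretone_rate_hz,
#'   tone_rate_hz, suppression}, plus the 3-s timecourse as columns
#'   \code{tc_1 ... tc_10}.
#' @export
behavior_summary <- function(session, config = classifier_config()) {
  rows <- lapply(session$trials, function(tr) {
    al <- avoidance_latency(tr)
    pr <- press_rates(tr, session, config)
    tc <- platform_timecourse(tr)
    out <- data.frame(trial_id = tr$trial_id,
                      pct_platform = platform_percent(tr),
                      avoid_latency_s = al$latency_s,
                      never_avoided = al$never_avoided,
                      pct_freezing = freezing_percent(tr),
                      pretone_rate_hz = pr$pretone_rate_hz,
                      tone_rate_hz = pr$tone_rate_hz,
                      suppression = suppression_ratio(pr$pretone_rate_hz,
                                                      pr$tone_rate_hz))
    for (b in seq_along(tc)) out[[paste0("tc_", b)]] <- tc[b]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
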