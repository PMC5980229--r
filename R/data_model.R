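#' Analysis configuration for response classification
#'
#' Bundles every window and threshold used by the peri-event and ISI
#' analyses. Defaults follow the recording methodology of the platform
#' avoidance task: firing is binned at 500 ms, normalized against 20 pretone
#' bins (10 s), and a unit counts as excited when the first tone bin exceeds
#' Z = 2.58 (p < 0.01, two-tailed) or inhibited when either of the first two
#' tone bins falls below Z = -1.96 (p < 0.05, two-tailed). The longer
#' latency allowed for inhibition reflects the multi-synaptic inhibitory
#' pathways in prefrontal circuits.
#'
#' @param bin_width_s width of a peri-event bin, seconds.
#' @param baseline_bins number of pretone bins forming the baseline.
#' @param response_bins number of post-event bins analysed (28 s; the 2-s
#'   shock at the end of the tone is masked from all spike counting).
#' @param z_excite Z threshold for an excitatory response in the first bin.
#' @param z_inhibit Z threshold (negative) for an inhibitory response in
#'   either of the first two bins.
#' @param n_trials_for_tone tone-onset classification uses the first
#'   \code{n_trials_for_tone} trials of the session.
#' @param isi_z Z threshold for the ISI-based inhibition-latency rule.
#' @param isi_baseline_s length of the pretone window supplying baseline
#'   interspike intervals.
#' @param pretone_rate_window_s window before tone onset used for pretone
#'   bar-press rates in the suppression ratio.
#' @param projection_width_us,projection_rate_hz putative projection neurons
#'   have spike width strictly greater than \code{projection_width_us}
#'   microseconds and baseline rate strictly below
#'   \code{projection_rate_hz} Hz.
#' @param min_platform_latency_s platform entries earlier than this after
#'   tone onset are excluded from platform-entry classification so that
#'   onset responses are not mistaken for entry responses.
#' @param sustained_window_s,sustained_fraction an inhibited unit is called
#'   "sustained" when at least \code{sustained_fraction} of the bins inside
#'   \code{sustained_window_s} (seconds after the event) are below the
#'   inhibitory threshold; "brief" otherwise.
#' @return A list of class \code{classifier_config}.
#' @export
classifier_config <- function(bin_width_s = 0.5,
                              baseline_bins = 20L,
                              response_bins = 56L,
                              z_excite = 2.58,
                              z_inhibit = -1.96,
                              n_trials_for_tone = 5L,
                              isi_z = 1.65,
                              isi_baseline_s = 30,
                              pretone_rate_window_s = 60,
                              projection_width_us = 225,
                              projection_rate_hz = 15,
                              min_platform_latency_s = 1,
                              sustained_window_s = c(10, 28),
                              sustained_fraction = 0.5) {
  cfg <- list(bin_width_s = bin_width_s,
              baseline_bins = as.integer(baseline_bins),
              response_bins = as.integer(response_bins),
              z_excite = z_excite,
              z_inhibit = z_inhibit,
              n_trials_for_tone = as.integer(n_trials_for_tone),
              isi_z = isi_z,
              isi_baseline_s = isi_baseline_s,
              pretone_rate_window_s = pretone_rate_window_s,
              projection_width_us = projection_width_us,
              projection_rate_hz = projection_rate_hz,
              min_platform_latency_s = min_platform_latency_s,
              sustained_window_s = sustained_window_s,
              sustained_fraction = sustained_fraction)
  stopifnot(cfg$bin_width_s > 0, cfg$baseline_bins > 0, cfg$response_bins > 0,
            cfg$z_excite > 0, cfg$z_inhibit < 0, cfg$n_trials_for_tone > 0,
            cfg$isi_z > 0, cfg$isi_baseline_s > 0,
            cfg$pretone_rate_window_s > 0)
  structure(cfg, class = "classifier_config")
}

#' One recorded unit: sorted spike timestamps plus metadata
#'
#' @param unit_id character scalar.
#' @param region \code{"rPL"} or \code{"cPL"} (rostral / caudal prelimbic).
#' @param spike_width_us trough-to-peak spike width in microseconds.
#' @param group experimental group: \code{"avoidance"}, \code{"naive"} or
#'   \code{"fear"}.
#' @param spike_times_s strictly increasing spike times, seconds from
#'   session start. A unit with no spikes is legal (it is flagged and later
#'   reported as unclassifiable, never dropped).
#' @param ap_mm optional anterior-posterior electrode position, mm.
#' @return Object of class \code{unit_recording}.
#' @export
unit_recording <- function(unit_id, region, spike_width_us, group,
                           spike_times_s = numeric(0), ap_mm = NA_real_) {
  u <- structure(list(unit_id = as.character(unit_id),
                      region = as.character(region),
                      ap_mm = as.numeric(ap_mm),
                      spike_width_us = as.numeric(spike_width_us),
                      group = as.character(group),
                      spike_times_s = as.numeric(spike_times_s)),
                 class = "unit_recording")
  validate_unit_recording(u)
  u
}

#' @export
print.unit_recording <- function(x, ...) {
  cat(sprintf("<unit_recording> %s  %s/%s  width %.0f us  %d spikes\n",
              x$unit_id, x$group, x$region, x$spike_width_us,
              length(x$spike_times_s)))
  invisible(x)
}

#' Validate a unit_recording against its invariants
#'
#' Checks strictly increasing non-negative spike times, positive spike
#' width, and legal region/group labels.
#'
#' @param u a \code{unit_recording}.
#' @return \code{u}, invisibly; errors name the offending unit.
#' @export
validate_unit_recording <- function(u) {
  if (!nzchar(u$unit_id)) stop("unit_id must be non-empty")
  if (!u$region %in% c("rPL", "cPL"))
    stop(sprintf("unit %s: unknown region '%s'", u$unit_id, u$region))
  if (!u$group %in% c("avoidance", "naive", "fear"))
    stop(sprintf("unit %s: unknown group '%s'", u$unit_id, u$group))
  if (!is.finite(u$spike_width_us) || u$spike_width_us <= 0)
    stop(sprintf("unit %s: spike_width_us must be > 0", u$unit_id))
  st <- u$spike_times_s
  if (length(st)) {
    if (anyNA(st) || any(st < 0))
      stop(sprintf("unit %s: spike times must be finite and >= 0", u$unit_id))
    if (any(diff(st) <= 0))
      stop(sprintf("unit %s: spike times are not strictly increasing",
                   u$unit_id))
  }
  invisible(u)
}

#' Events of one conditioning trial
#'
#' All times are seconds from session start; every interval is half-open
#' \code{[start, end)}, which removes double counting at shared boundaries.
#'
#' @param trial_id integer trial index (1-based within session).
#' @param tone_onset_s tone onset time.
#' @param tone_duration_s tone length, default 30 s.
#' @param shock_interval_s length-2 numeric \code{c(on, off)} or \code{NULL}
#'   for shock-free trials (naive group, expression tests). For conditioned
#'   trials the 2-s shock co-terminates with the tone.
#' @param platform_intervals_s platform occupancy intervals: 2-column matrix
#'   (entry, exit), non-overlapping and sorted.
#' @param headturn_s optional time of the first orienting head turn.
#' @param freezing_intervals_s pre-scored freezing intervals, 2-column
#'   matrix.
#' @param press_times_s bar-press timestamps.
#' @param laser_intervals_s optional laser illumination intervals.
#' @return Object of class \code{trial_events}.
#' @export
trial_events <- function(trial_id, tone_onset_s, tone_duration_s = 30,
                         shock_interval_s = NULL,
                         platform_intervals_s = NULL,
                         headturn_s = NA_real_,
                         freezing_intervals_s = NULL,
                         press_times_s = numeric(0),
                         laser_intervals_s = NULL) {
  tr <- structure(list(trial_id = as.integer(trial_id),
                       tone_onset_s = as.numeric(tone_onset_s),
                       tone_duration_s = as.numeric(tone_duration_s),
                       shock_interval_s = if (is.null(shock_interval_s)) NULL
                                          else as.numeric(shock_interval_s),
                       platform_intervals_s =
                         as_interval_matrix(platform_intervals_s),
                       headturn_s = as.numeric(headturn_s),
                       freezing_intervals_s =
                         as_interval_matrix(freezing_intervals_s),
                       press_times_s = as.numeric(press_times_s),
                       laser_intervals_s =
                         if (is.null(laser_intervals_s)) NULL
                         else as_interval_matrix(laser_intervals_s)),
                  class = "trial_events")
  validate_trial_events(tr)
  tr
}

validate_intervals <- function(m, what, trial_id) {
  if (nrow(m) == 0L) return(invisible(m))
  if (any(m[, 2L] <= m[, 1L]))
    stop(sprintf("trial %d: %s interval with end <= start", trial_id, what))
  if (nrow(m) > 1L) {
    if (is.unsorted(m[, 1L], strictly = TRUE))
      stop(sprintf("trial %d: %s intervals not sorted", trial_id, what))
    if (any(m[-nrow(m), 2L] > m[-1L, 1L]))
      stop(sprintf("trial %d: overlapping %s intervals", trial_id, what))
  }
  invisible(m)
}

#' @rdname trial_events
#' @param tr a \code{trial_events} object.
#' @export
validate_trial_events <- function(tr) {
  if (!is.finite(tr$tone_onset_s) || tr$tone_onset_s < 0)
    stop(sprintf("trial %d: tone_onset_s must be >= 0", tr$trial_id))
  if (tr$tone_duration_s <= 0)
    stop(sprintf("trial %d: tone_duration_s must be > 0", tr$trial_id))
  if (!is.null(tr$shock_interval_s)) {
    if (length(tr$shock_interval_s) != 2L ||
        tr$shock_interval_s[2L] <= tr$shock_interval_s[1L])
      stop(sprintf("trial %d: shock interval must be c(on, off), off > on",
                   tr$trial_id))
  }
  validate_intervals(tr$platform_intervals_s, "platform", tr$trial_id)
  validate_intervals(tr$freezing_intervals_s, "freezing", tr$trial_id)
  if (!is.null(tr$laser_intervals_s))
    validate_intervals(tr$laser_intervals_s, "laser", tr$trial_id)
  invisible(tr)
}

#' A behavioral session: ordered trials
#'
#' @param trials list of \code{trial_events}, ordered by tone onset.
#' @param session_id character scalar.
#' @return Object of class \code{session_events}.
#' @export
session_events <- function(trials, session_id = "session") {
  s <- structure(list(session_id = as.character(session_id), trials = trials),
                 class = "session_events")
  validate_session_events(s)
  s
}

#' @rdname session_events
#' @param s a \code{session_events} object.
#' @export
validate_session_events <- function(s) {
  if (!length(s$trials)) stop("session must contain at least one trial")
  lapply(s$trials, validate_trial_events)
  onsets <- vapply(s$trials, `[[`, numeric(1), "tone_onset_s")
  ends <- onsets + vapply(s$trials, `[[`, numeric(1), "tone_duration_s")
  if (is.unsorted(onsets, strictly = TRUE))
    stop("trials are not ordered by tone onset")
  if (length(onsets) > 1L && any(ends[-length(ends)] > onsets[-1L]))
    stop("tone windows overlap between consecutive trials")
  invisible(s)
}

#' @export
print.session_events <- function(x, ...) {
  cat(sprintf("<session_events> %s: %d trials, first tone at %.1f s\n",
              x$session_id, length(x$trials), x$trials[[1L]]$tone_onset_s))
  invisible(x)
}

n_trials <- function(s) length(s$trials)

# Pool per-trial event streams into session-level vectors/matrices.
session_platform_intervals <- function(s) {
  do.call(rbind, lapply(s$trials, `[[`, "platform_intervals_s"))
}
session_press_times <- function(s) {
  sort(unlist(lapply(s$trials, `[[`, "press_times_s"), use.names = FALSE))
}

## ---------------------------------------------------------------- readers

read_csv_checked <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop(sprintf("%s: missing column(s) %s", path,
                 paste(miss, collapse = ", ")))
  df
}

#' Read units and spikes from the tabular interchange format
#'
#' \code{units.csv} holds one row per unit (\code{unit_id, region, ap_mm,
#' spike_width_us, group}); \code{spikes.csv} is long-format
#' (\code{unit_id, spike_time_s}). Units with no spikes are retained.
#'
#' @param units_path path to \code{units.csv}.
#' @param spikes_path path to \code{spikes.csv}.
#' @return Named list of \code{unit_recording} objects, in file order.
#' @export
read_units <- function(units_path, spikes_path) {
  ud <- read_csv_checked(units_path,
                         c("unit_id", "region", "ap_mm", "spike_width_us",
                           "group"))
  sd <- read_csv_checked(spikes_path, c("unit_id", "spike_time_s"))
  if (anyNA(suppressWarnings(as.numeric(sd$spike_time_s)))) {
    bad <- which(is.na(suppressWarnings(as.numeric(sd$spike_time_s))))[1L]
    stop(sprintf("%s: malformed spike_time_s at data row %d",
                 spikes_path, bad))
  }
  sd$spike_time_s <- as.numeric(sd$spike_time_s)
  if (anyDuplicated(ud$unit_id))
    stop(sprintf("%s: duplicated unit_id", units_path))
  spk <- split(sd$spike_time_s, factor(sd$unit_id, levels = ud$unit_id))
  units <- lapply(seq_len(nrow(ud)), function(i) {
    unit_recording(unit_id = ud$unit_id[i], region = ud$region[i],
                   ap_mm = ud$ap_mm[i],
                   spike_width_us = ud$spike_width_us[i],
                   group = ud$group[i],
                   spike_times_s = spk[[ud$unit_id[i]]] %||% numeric(0))
  })
  names(units) <- ud$unit_id
  units
}

#' Write units and spikes in canonical form
#'
#' Canonical formatting (fixed column order, 9-decimal times, no quoting)
#' makes write-read-write a byte-identical round trip.
#'
#' @param units list of \code{unit_recording}.
#' @param units_path,spikes_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_units <- function(units, units_path, spikes_path) {
  ud <- data.frame(
    unit_id = vapply(units, `[[`, character(1), "unit_id"),
    region = vapply(units, `[[`, character(1), "region"),
    ap_mm = vapply(units, function(u) {
      if (is.na(u$ap_mm)) "" else sprintf("%.3f", u$ap_mm)
    }, character(1)),
    spike_width_us = vapply(units, function(u) sprintf("%.1f",
                                                       u$spike_width_us),
                            character(1)),
    group = vapply(units, `[[`, character(1), "group"))
  utils::write.csv(ud, units_path, row.names = FALSE, quote = FALSE)
  sdl <- lapply(units, function(u) {
    if (!length(u$spike_times_s)) return(NULL)
    data.frame(unit_id = u$unit_id, spike_time_s = fmt_time(u$spike_times_s))
  })
  sd <- do.call(rbind, sdl)
  if (is.null(sd)) sd <- data.frame(unit_id = character(0),
                                    spike_time_s = character(0))
  utils::write.csv(sd, spikes_path, row.names = FALSE, quote = FALSE)
  invisible(c(units_path, spikes_path))
}

event_levels <- c("tone_onset", "shock_on", "shock_off", "platform_entry",
                  "platform_exit", "headturn", "freeze_start", "freeze_end",
                  "press", "laser_on", "laser_off")

pair_intervals <- function(starts, ends, what, trial_id) {
  if (length(starts) != length(ends))
    stop(sprintf("trial %d: unmatched %s start/end events", trial_id, what))
  if (!length(starts)) return(NULL)
  if (any(ends <= starts))
    stop(sprintf("trial %d: %s end precedes its matching start",
                 trial_id, what))
  cbind(starts, ends, deparse.level = 0)
}

#' Read a behavioral session from events.csv
#'
#' The file is long-format with columns \code{trial_id, event_type, time_s};
#' \code{event_type} draws from tone_onset, shock_on/off,
#' platform_entry/exit, headturn, freeze_start/end, press, laser_on/off.
#' Each trial must contain exactly one tone_onset; entry/exit style pairs
#' are matched in time order.
#'
#' @param path path to events.csv.
#' @param session_id identifier for the assembled session.
#' @param tone_duration_s tone length, seconds.
#' @return A \code{session_events} object.
#' @export
read_events <- function(path, session_id = NULL, tone_duration_s = 30) {
  df <- read_csv_checked(path, c("trial_id", "event_type", "time_s"))
  bad <- which(!df$event_type %in% event_levels)
  if (length(bad))
    stop(sprintf("%s: unknown event_type '%s' at data row %d", path,
                 df$event_type[bad[1L]], bad[1L]))
  if (anyNA(suppressWarnings(as.numeric(df$time_s))))
    stop(sprintf("%s: malformed time_s at data row %d", path,
                 which(is.na(suppressWarnings(as.numeric(df$time_s))))[1L]))
  df$time_s <- as.numeric(df$time_s)
  df <- df[order(df$trial_id, df$time_s, match(df$event_type, event_levels)), ]
  trials <- lapply(split(df, df$trial_id), function(td) {
    id <- td$trial_id[1L]
    get_times <- function(type) td$time_s[td$event_type == type]
    onset <- get_times("tone_onset")
    if (length(onset) != 1L)
      stop(sprintf("trial %s: expected exactly one tone_onset, found %d",
                   id, length(onset)))
    sh_on <- get_times("shock_on"); sh_off <- get_times("shock_off")
    if (length(sh_on) > 1L || length(sh_on) != length(sh_off))
      stop(sprintf("trial %s: malformed shock events", id))
    ht <- get_times("headturn")
    trial_events(
      trial_id = id, tone_onset_s = onset,
      tone_duration_s = tone_duration_s,
      shock_interval_s = if (length(sh_on)) c(sh_on, sh_off) else NULL,
      platform_intervals_s = pair_intervals(get_times("platform_entry"),
                                            get_times("platform_exit"),
                                            "platform", id),
      headturn_s = if (length(ht)) ht[1L] else NA_real_,
      freezing_intervals_s = pair_intervals(get_times("freeze_start"),
                                            get_times("freeze_end"),
                                            "freezing", id),
      press_times_s = get_times("press"),
      laser_intervals_s = pair_intervals(get_times("laser_on"),
                                         get_times("laser_off"),
                                         "laser", id))
  })
  trials <- trials[order(vapply(trials, `[[`, numeric(1), "tone_onset_s"))]
  session_events(unname(trials),
                 session_id = session_id %||%
                   sub("\\.csv$", "", basename(path)))
}

trial_event_rows <- function(tr) {
  rows <- list(data.frame(event_type = "tone_onset",
                          time_s = tr$tone_onset_s))
  add <- function(type, times) {
    if (length(times) && !all(is.na(times)))
      rows[[length(rows) + 1L]] <<- data.frame(event_type = type,
                                               time_s = times[!is.na(times)])
  }
  if (!is.null(tr$shock_interval_s)) {
    add("shock_on", tr$shock_interval_s[1L])
    add("shock_off", tr$shock_interval_s[2L])
  }
  add("platform_entry", tr$platform_intervals_s[, 1L])
  add("platform_exit", tr$platform_intervals_s[, 2L])
  add("headturn", tr$headturn_s)
  add("freeze_start", tr$freezing_intervals_s[, 1L])
  add("freeze_end", tr$freezing_intervals_s[, 2L])
  add("press", tr$press_times_s)
  if (!is.null(tr$laser_intervals_s)) {
    add("laser_on", tr$laser_intervals_s[, 1L])
    add("laser_off", tr$laser_intervals_s[, 2L])
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$time_s, match(out$event_type, event_levels)), ]
  out$trial_id <- tr$trial_id
  out[, c("trial_id", "event_type", "time_s")]
}

#' Write a session to events.csv in canonical form
#'
#' @param session a \code{session_events} object.
#' @param path output path.
#' @return Invisibly, \code{path}.
#' @export
write_events <- function(session, path) {
  rows <- do.call(rbind, lapply(session$trials, trial_event_rows))
  rows$time_s <- fmt_time(rows$time_s)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
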