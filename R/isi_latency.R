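#' Pretone ISI baseline for one unit on one trial
#'
#' Interspike intervals between consecutive spikes falling in the 30 s
#' before tone onset. At least two ISIs (three spikes) are required for a
#' sample SD; otherwise the trial is unscorable for latency detection, as
#' is a trial whose baseline ISIs are all identical (zero SD).
#'
#' @param unit a \code{unit_recording}.
#' @param tone_onset_s tone onset of the trial, seconds.
#' @param config a [classifier_config()].
#' @return List: \code{mean_isi_s}, \code{sd_isi_s}, \code{n_isis},
#'   \code{scorable}.
#' @export
isi_baseline <- function(unit, tone_onset_s, config = classifier_config()) {
  st <- unit$spike_times_s
  pre <- st[st >= tone_onset_s - config$isi_baseline_s & st < tone_onset_s]
  isis <- diff(pre)
  n <- length(isis)
  if (n < 2L)
    return(list(mean_isi_s = NA_real_, sd_isi_s = NA_real_, n_isis = n,
                scorable = FALSE))
  m <- mean(isis); s <- stats::sd(isis)
  list(mean_isi_s = m, sd_isi_s = s, n_isis = n,
       scorable = is.finite(s) && s > 0)
}

#' ISI-based inhibition onset latency for one trial
#'
#' The inhibition latency is the start of the first interspike interval,
#' among ISIs whose starting spike falls within the 30-s tone, that is
#' significantly longer than the average pretone ISI:
#' (ISI - mean) / sd > 1.65 (p < 0.05, one-tailed), with mean and sample SD
#' taken over the 30 s of pretone activity of the same cell and trial. The
#' ISI straddling tone onset is excluded (its start is pretone), and the
#' gap from the last spike to the window end is not an ISI.
#'
#' @param unit a \code{unit_recording}.
#' @param tone_onset_s tone onset, seconds.
#' @param config a [classifier_config()].
#' @param tone_duration_s tone length, seconds.
#' @return List: \code{latency_s} (seconds after tone onset, or NA),
#'   \code{reason} (NA, \code{"unscorable_baseline"} or
#'   \code{"no_qualifying_isi"}).
#' @export
inhibition_latency <- function(unit, tone_onset_s,
                               config = classifier_config(),
                               tone_duration_s = 30) {
  base <- isi_baseline(unit, tone_onset_s, config)
  if (!base$scorable)
    return(list(latency_s = NA_real_, reason = "unscorable_baseline"))
  st <- unit$spike_times_s
  starts <- st[-length(st)]
  isis <- diff(st)
  sel <- starts >= tone_onset_s & starts < tone_onset_s + tone_duration_s
  if (any(sel)) {
    zz <- (isis[sel] - base$mean_isi_s) / base$sd_isi_s
    hit <- which(zz > config$isi_z)
    if (length(hit)) {
      return(list(latency_s = starts[sel][hit[1L]] - tone_onset_s,
                  reason = NA_character_))
    }
  }
  list(latency_s = NA_real_, reason = "no_qualifying_isi")
}

#' Per-trial latency records for a set of units
#'
#' One row per unit x trial pairing the detected inhibition latency with
#' the behavioral latencies of the same trial: platform-entry latency
#' (capped at the 30-s tone for never-avoided trials) and headturn latency
#' (missing when no head turn was scored).
#'
#' @param units list of \code{unit_recording}.
#' @param session the shared \code{session_events}.
#' @param config a [classifier_config()].
#' @return data.frame with columns \code{unit_id, trial_id,
#'   inhibition_latency_s, reason, platform_latency_s, headturn_latency_s,
#'   avoided}.
#' @export
latency_records <- function(units, session, config = classifier_config()) {
  beh <- lapply(session$trials, function(tr) {
    al <- avoidance_latency(tr)
    list(trial_id = tr$trial_id, platform = al$latency_s,
         avoided = !al$never_avoided,
         headturn = if (is.na(tr$headturn_s)) NA_real_
                    else tr$headturn_s - tr$tone_onset_s)
  })
  rows <- lapply(units, function(u) {
    per <- lapply(seq_along(session$trials), function(k) {
      tr <- session$trials[[k]]
      il <- inhibition_latency(u, tr$tone_onset_s, config,
                               tr$tone_duration_s)
      data.frame(unit_id = u$unit_id, trial_id = beh[[k]]$trial_id,
                 inhibition_latency_s = il$latency_s, reason = il$reason,
                 platform_latency_s = beh[[k]]$platform,
                 headturn_latency_s = beh[[k]]$headturn,
                 avoided = beh[[k]]$avoided)
    })
    do.call(rbind, per)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-cell latency summary over successful trials
#'
#' For each cell, the inhibition latency and the behavioral latencies are
#' averaged across the trials with successful avoidance on which a
#' qualifying ISI was detected. Cells with no qualifying avoided trial are
#' omitted from the summary but counted.
#'
#' @param records data.frame from [latency_records()].
#' @return List: \code{summary} (data.frame \code{unit_id,
#'   mean_inhibition_latency_s, mean_platform_latency_s,
#'   mean_headturn_latency_s, n_trials}) and \code{n_omitted} (cells with
#'   no qualifying trial).
#' @export
per_cell_latency_summary <- function(records) {
  ok <- records$avoided & !is.na(records$inhibition_latency_s)
  use <- records[ok, , drop = FALSE]
  all_units <- unique(records$unit_id)
  if (!nrow(use)) {
    return(list(summary = data.frame(unit_id = character(0),
                                     mean_inhibition_latency_s = numeric(0),
                                     mean_platform_latency_s = numeric(0),
                                     mean_headturn_latency_s = numeric(0),
                                     n_trials = integer(0)),
                n_omitted = length(all_units)))
  }
  agg <- lapply(split(use, use$unit_id), function(d) {
    data.frame(unit_id = d$unit_id[1L],
               mean_inhibition_latency_s = mean(d$inhibition_latency_s),
               mean_platform_latency_s = mean(d$platform_latency_s),
               mean_headturn_latency_s =
                 if (all(is.na(d$headturn_latency_s))) NA_real_
                 else mean(d$headturn_latency_s, na.rm = TRUE),
               n_trials = nrow(d))
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  list(summary = out, n_omitted = length(all_units) - nrow(out))
}

#' Pearson correlation between two latency vectors
#'
#' Product-moment correlation with a two-tailed p-value; pairs with a
#' missing value in either vector are dropped.
#'
#' @param xs,ys numeric vectors of equal length.
#' @return List: \code{r}, \code{p}, \code{n} (complete pairs).
#' @export
latency_correlation <- function(xs, ys) {
  stopifnot(length(xs) == length(ys))
  ok <- is.finite(xs) & is.finite(ys)
  if (sum(ok) < 3L || stats::sd(xs[ok]) == 0 || stats::sd(ys[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = sum(ok)))
  ct <- stats::cor.test(xs[ok], ys[ok], method = "pearson",
                        alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
}

#' @rdname latency_correlation
#' @export
pearson_r <- latency_correlation
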