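#' Configuration of the synthetic cohort generator
#'
#' The generator emulates the statistical structure of single-unit
#' recordings during platform-mediated avoidance: putative projection
#' neurons with ~6 Hz log-normal baseline rates; 9-trial sessions of 30-s
#' tones separated by variable ~3-min intervals, with a 2-s shock
#' co-terminating with the tone on conditioned trials; platform entries
#' whose latency distribution has median 3.55 s with 91% of entries later
#' than 1 s; and tone responses that are either absent, excitatory (a
#' transient gain on the first 500 ms), or inhibitory (rate dropping to a
#' ~2 Hz floor, briefly or for the whole tone).
#'
#' Default cohort composition mirrors the recorded populations: 205
#' avoidance units (30 excited / 22 inhibited, of which 18 brief and 4
#' sustained), 166 naive units (20 / 3) and 191 fear-conditioned units
#' (25 / 3); all inhibited units sit in rostral PL.
#'
#' @param response_mix named list (one entry per group) of named integer
#'   vectors giving unit counts per response class
#'   (\code{excited, inhibited_brief, inhibited_sustained, none}).
#' @param baseline_rate_median_hz,baseline_rate_sdlog log-normal baseline
#'   firing-rate distribution (median on the natural scale).
#' @param excite_gain,excite_duration_s multiplier applied to the baseline
#'   rate over the first \code{excite_duration_s} of each tone for excited
#'   units.
#' @param inhibit_floor_hz firing-rate floor during inhibition.
#' @param inhibit_onset_range_s inhibition onset lag after tone onset is
#'   drawn uniformly from this range (one draw per unit).
#' @param inhibit_duration_brief_s,inhibit_duration_sustained_s inhibition
#'   durations for the brief and sustained classes.
#' @param n_trials,tone_s,shock_s session structure. Shocks co-terminate
#'   with the tone and are delivered to avoidance and fear groups only.
#' @param iti_range_s inter-trial onset-to-onset gap minus tone length is
#'   drawn uniformly from this range (mean 180 s).
#' @param platform_latency_median_s,platform_latency_sdlog log-normal
#'   platform-entry latency. The default sdlog 0.945 places 91% of entries
#'   beyond 1 s when the median is 3.55 s.
#' @param p_avoid per-trial probability of a successful avoidance
#'   (platform entry during the tone). Applies to groups with a platform.
#' @param press_rate_hz baseline bar-press rate; presses are suppressed to
#'   zero while the rat occupies the platform.
#' @param p_freeze,freeze_mean_s per-trial probability and mean duration of
#'   a freezing episode during the tone.
#' @param spike_width_range_us spike widths drawn uniformly from this range
#'   (projection-like by default).
#' @param rostral_fraction fraction of non-inhibited units assigned to rPL;
#'   inhibited units are always rostral, as observed.
#' @param seed top-level seed; child seeds are derived deterministically.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(response_mix = list(
                         avoidance = c(excited = 30, inhibited_brief = 18,
                                       inhibited_sustained = 4, none = 153),
                         naive = c(excited = 20, inhibited_brief = 3,
                                   inhibited_sustained = 0, none = 143),
                         fear = c(excited = 25, inhibited_brief = 3,
                                  inhibited_sustained = 0, none = 163)),
                       baseline_rate_median_hz = 6,
                       baseline_rate_sdlog = 0.35,
                       excite_gain = 3,
                       excite_duration_s = 0.5,
                       inhibit_floor_hz = 2,
                       inhibit_onset_range_s = c(0, 1),
                       inhibit_duration_brief_s = 8,
                       inhibit_duration_sustained_s = 28,
                       n_trials = 9L,
                       tone_s = 30,
                       shock_s = 2,
                       iti_range_s = c(120, 240),
                       platform_latency_median_s = 3.55,
                       platform_latency_sdlog = 0.945,
                       p_avoid = 0.7,
                       press_rate_hz = 0.5,
                       p_freeze = 0.5,
                       freeze_mean_s = 8,
                       spike_width_range_us = c(240, 450),
                       rostral_fraction = 0.5,
                       seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$baseline_rate_median_hz > 0, cfg$excite_gain > 0,
            cfg$inhibit_floor_hz >= 0, cfg$p_avoid >= 0, cfg$p_avoid <= 1,
            cfg$p_freeze >= 0, cfg$p_freeze <= 1, cfg$press_rate_hz >= 0,
            cfg$n_trials >= 1, cfg$tone_s > 0, cfg$shock_s >= 0,
            diff(cfg$iti_range_s) >= 0, cfg$iti_range_s[1] > cfg$tone_s)
  cfg$n_trials <- as.integer(cfg$n_trials)
  structure(cfg, class = "sim_config")
}

#' Read a sim_config from a YAML file
#'
#' Keys map one-to-one onto the arguments of [sim_config()]; absent keys
#' keep their defaults.
#'
#' @param path YAML file.
#' @return A \code{sim_config}.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop(sprintf("unknown sim_config key(s): %s", paste(bad, collapse = ", ")))
  if (!is.null(vals$response_mix))
    vals$response_mix <- lapply(vals$response_mix, unlist)
  do.call(sim_config, vals)
}

draw_platform_latency <- function(cfg) {
  repeat {
    lat <- stats::rlnorm(1, meanlog = log(cfg$platform_latency_median_s),
                         sdlog = cfg$platform_latency_sdlog)
    if (lat < cfg$tone_s - cfg$shock_s) return(lat)
  }
}

#' Simulate one behavioral session
#'
#' Builds a \code{session_events} with \code{n_trials} tones at variable
#' inter-trial intervals. Conditioned groups (\code{avoidance},
#' \code{fear}) receive a shock co-terminating with each tone. Groups with
#' platform behavior (\code{avoidance}, \code{naive}) enter the platform on
#' a trial with probability \code{p_avoid}, at a log-normal latency after
#' tone onset, preceded by a head turn, and leave shortly after tone end.
#' Bar presses form a homogeneous Poisson stream thinned to zero during
#' platform occupancy, which is what produces conditioned suppression of
#' pressing during avoided tones.
#'
#' @param cfg a [sim_config()].
#' @param group \code{"avoidance"}, \code{"naive"} or \code{"fear"}.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @param session_id session identifier.
#' @return A \code{session_events} object.
#' @export
simulate_session <- function(cfg, group = "avoidance", seed = NULL,
                             session_id = paste0(group, "_session")) {
  stopifnot(inherits(cfg, "sim_config"),
            group %in% c("avoidance", "naive", "fear"))
  if (!is.null(seed)) set.seed(seed)
  gaps <- stats::runif(cfg$n_trials, cfg$iti_range_s[1], cfg$iti_range_s[2])
  onsets <- cumsum(gaps) + c(0, cumsum(rep(cfg$tone_s, cfg$n_trials - 1)))
  has_shock <- group %in% c("avoidance", "fear")
  has_platform <- group %in% c("avoidance", "naive")
  session_end <- onsets[cfg$n_trials] + cfg$tone_s + 60

  platform <- vector("list", cfg$n_trials)
  headturn <- rep(NA_real_, cfg$n_trials)
  freezing <- vector("list", cfg$n_trials)
  for (k in seq_len(cfg$n_trials)) {
    on <- onsets[k]; off <- on + cfg$tone_s
    if (has_platform && stats::runif(1) < cfg$p_avoid) {
      lat <- draw_platform_latency(cfg)
      entry <- on + lat
      exit <- off + stats::rexp(1, 1 / 10)
      headturn[k] <- min(entry - 0.01,
                         max(on + 0.01, entry - stats::runif(1, 0.2, 0.8)))
      platform[[k]] <- c(entry, exit)
    }
    if (stats::runif(1) < cfg$p_freeze) {
      fs <- on + stats::runif(1, 0, 5)
      fe <- min(off, fs + stats::rexp(1, 1 / cfg$freeze_mean_s))
      if (fe > fs) freezing[[k]] <- c(fs, fe)
    }
  }

  n_press <- stats::rpois(1, cfg$press_rate_hz * session_end)
  presses <- sort(stats::runif(n_press, 0, session_end))
  occ <- do.call(rbind, c(platform[!vapply(platform, is.null, logical(1))],
                          list(matrix(numeric(0), ncol = 2))))
  if (nrow(occ)) {
    on_platform <- vapply(presses, function(p)
      any(p >= occ[, 1] & p < occ[, 2]), logical(1))
    presses <- presses[!on_platform]
  }

  bounds <- c(0, (onsets[-1] + onsets[-cfg$n_trials] + cfg$tone_s) / 2,
              session_end)
  assign_trial <- function(t) findInterval(t, bounds,
                                           rightmost.closed = TRUE)
  trials <- lapply(seq_len(cfg$n_trials), function(k) {
    on <- onsets[k]; off <- on + cfg$tone_s
    trial_events(
      trial_id = k, tone_onset_s = on, tone_duration_s = cfg$tone_s,
      shock_interval_s = if (has_shock) c(off - cfg$shock_s, off) else NULL,
      platform_intervals_s = if (!is.null(platform[[k]]))
        matrix(platform[[k]], ncol = 2) else NULL,
      headturn_s = headturn[k],
      freezing_intervals_s = if (!is.null(freezing[[k]]))
        matrix(freezing[[k]], ncol = 2) else NULL,
      press_times_s = presses[assign_trial(presses) == k])
  })
  session_events(trials, session_id = session_id)
}

# Piecewise-constant firing rate for one unit on one session.
# Returns a function rate(t) vectorized over t, plus the maximum rate.
unit_rate_fun <- function(cfg, response_class, session, baseline_hz,
                          lag_s, duration_s) {
  onsets <- vapply(session$trials, `[[`, numeric(1), "tone_onset_s")
  shocks <- lapply(session$trials, `[[`, "shock_interval_s")
  tone_s <- session$trials[[1]]$tone_duration_s
  excited <- response_class == "excited"
  inhibited <- response_class %in% c("inhibited_brief", "inhibited_sustained")
  rmax <- if (excited) baseline_hz * cfg$excite_gain else baseline_hz
  rate <- function(t) {
    r <- rep(baseline_hz, length(t))
    for (k in seq_along(onsets)) {
      on <- onsets[k]
      if (excited)
        r[t >= on & t < on + cfg$excite_duration_s] <-
          baseline_hz * cfg$excite_gain
      if (inhibited) {
        i0 <- on + lag_s
        i1 <- min(on + lag_s + duration_s, on + tone_s)
        r[t >= i0 & t < i1] <- cfg$inhibit_floor_hz
      }
      if (!is.null(shocks[[k]]))
        r[t >= shocks[[k]][1] & t < shocks[[k]][2]] <- 0
    }
    r
  }
  list(rate = rate, rmax = rmax)
}

#' Simulate one unit's spike train
#'
#' Spikes are drawn from an inhomogeneous Poisson process with a
#' piecewise-constant rate: log-normal baseline everywhere; during each
#' tone the rate is modified according to the unit's response class
#' (excited: baseline x \code{excite_gain} over the first 500 ms;
#' inhibited: \code{inhibit_floor_hz} from a per-unit onset lag for the
#' class duration); zero during the 2-s shock, matching the acquisition
#' gap in the recordings. Sampling is by thinning of a homogeneous process
#' at the maximum rate, which is exact for piecewise-constant intensities.
#'
#' @param cfg a [sim_config()].
#' @param response_class one of \code{"none"}, \code{"excited"},
#'   \code{"inhibited_brief"}, \code{"inhibited_sustained"}.
#' @param session the \code{session_events} the unit was recorded on.
#' @param unit_id,region,group metadata for the returned unit.
#' @param seed integer seed; \code{NULL} uses the current RNG state.
#' @return A \code{unit_recording}; attributes \code{injected_class},
#'   \code{injected_lag_s} and \code{baseline_hz} record the ground truth
#'   for parameter-recovery studies.
#' @export
simulate_unit <- function(cfg, response_class, session,
                          unit_id = "u1", region = "rPL",
                          group = "avoidance", seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"),
            response_class %in% c("none", "excited", "inhibited_brief",
                                  "inhibited_sustained"))
  if (!is.null(seed)) set.seed(seed)
  baseline <- stats::rlnorm(1, log(cfg$baseline_rate_median_hz),
                            cfg$baseline_rate_sdlog)
  lag <- stats::runif(1, cfg$inhibit_onset_range_s[1],
                      cfg$inhibit_onset_range_s[2])
  duration <- switch(response_class,
                     inhibited_brief = cfg$inhibit_duration_brief_s,
                     inhibited_sustained = cfg$inhibit_duration_sustained_s,
                     0)
  if (cfg$inhibit_floor_hz < 0) stop("negative rate in configuration")
  last <- session$trials[[length(session$trials)]]
  t_end <- last$tone_onset_s + last$tone_duration_s + 60
  rf <- unit_rate_fun(cfg, response_class, session, baseline, lag, duration)
  n <- stats::rpois(1, rf$rmax * t_end)
  tt <- sort(stats::runif(n, 0, t_end))
  keep <- stats::runif(n) < rf$rate(tt) / rf$rmax
  spikes <- tt[keep]
  spikes <- spikes[c(TRUE, diff(spikes) > 0)]
  width <- stats::runif(1, cfg$spike_width_range_us[1],
                        cfg$spike_width_range_us[2])
  u <- unit_recording(unit_id = unit_id, region = region,
                      spike_width_us = width, group = group,
                      spike_times_s = spikes)
  attr(u, "injected_class") <- response_class
  attr(u, "injected_lag_s") <- if (duration > 0) lag else NA_real_
  attr(u, "baseline_hz") <- baseline
  u
}

#' Simulate a full multi-group cohort
#'
#' For each group in \code{cfg$response_mix}, simulates one behavioral
#' session and the configured numbers of units per response class, and
#' (optionally) writes the \code{units.csv}, \code{spikes.csv} and
#' \code{events.csv} triplet per group. Inhibited units are placed in
#' rostral PL; other units alternate deterministically between regions at
#' \code{rostral_fraction}. Anterior-posterior positions are drawn from
#' region-specific ranges (rPL anterior to cPL).
#'
#' @param cfg a [sim_config()]; \code{cfg$seed} drives all randomness via
#'   deterministic child seeds, so the cohort is reproducible.
#' @param out_dir if non-NULL, CSV triplets are written here as
#'   \code{<group>_units.csv}, \code{<group>_spikes.csv},
#'   \code{<group>_events.csv}.
#' @return Named list per group with elements \code{units} (list of
#'   \code{unit_recording}) and \code{session} (\code{session_events}),
#'   invisibly when \code{out_dir} is given.
#' @export
simulate_cohort <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  groups <- names(cfg$response_mix)
  out <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    session <- simulate_session(cfg, group = g,
                                seed = child_seed(cfg$seed, gi * 1000000L),
                                session_id = paste0(g, "_session"))
    mix <- cfg$response_mix[[g]]
    classes <- rep(names(mix), times = mix)
    n_rostral_target <- 0
    units <- vector("list", length(classes))
    for (i in seq_along(classes)) {
      cl <- classes[i]
      inhibited <- cl %in% c("inhibited_brief", "inhibited_sustained")
      # inhibited units are rostral; others track rostral_fraction exactly
      if (inhibited) {
        region <- "rPL"
      } else {
        n_rostral_target <- n_rostral_target + cfg$rostral_fraction
        region <- if (n_rostral_target >= 1) "rPL" else "cPL"
        if (region == "rPL") n_rostral_target <- n_rostral_target - 1
      }
      useed <- child_seed(cfg$seed, gi * 1000000L + i)
      u <- simulate_unit(cfg, cl, session,
                         unit_id = sprintf("%s_%03d", g, i),
                         region = region, group = g, seed = useed)
      set.seed(child_seed(cfg$seed, gi * 1000000L + 500000L + i))
      u$ap_mm <- if (region == "rPL") stats::runif(1, 3.2, 4.2)
                 else stats::runif(1, 2.2, 3.2)
      units[[i]] <- u
    }
    names(units) <- vapply(units, `[[`, character(1), "unit_id")
    out[[g]] <- list(units = units, session = session)
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      write_units(units, file.path(out_dir, paste0(g, "_units.csv")),
                  file.path(out_dir, paste0(g, "_spikes.csv")))
      write_events(session, file.path(out_dir, paste0(g, "_events.csv")))
    }
  }
  if (is.null(out_dir)) out else invisible(out)
}
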