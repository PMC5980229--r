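#' Peri-event spike counts for one unit
#'
#' Bins a unit's spikes into half-open 500-ms bins from 10 s before to 28 s
#' after an alignment event, one row per qualifying trial. For
#' \code{alignment = "tone_onset"} the first \code{n_trials_for_tone}
#' trials are used. For \code{alignment = "platform_entry"} all successful
#' avoidance trials are used, excluding entries earlier than
#' \code{min_platform_latency_s} after tone onset (so that tone-onset
#' activity is not attributed to platform entry); alongside the
#' entry-aligned counts, pretone baseline counts from the same trials'
#' tones are returned, because entry responses are normalized against the
#' same pretone baseline as tone responses.
#'
#' Shock epochs are masked: the per-bin exposure (seconds of usable time)
#' is reduced by any overlap with the trial's shock interval, and rates are
#' computed as counts over exposure. For tone alignment the 28-s analysis
#' window ends at shock onset, so masking only matters for entry alignment.
#'
#' @param unit a \code{unit_recording}.
#' @param session a \code{session_events}.
#' @param alignment \code{"tone_onset"} or \code{"platform_entry"}.
#' @param config a [classifier_config()].
#' @return List of class \code{peri_event_counts}: \code{counts} and
#'   \code{exposure} (trials x bins), \code{bin_edges_s} (relative to the
#'   event), \code{align_times_s}, \code{trial_ids}, \code{n_trials},
#'   \code{alignment}, and for entry alignment \code{baseline_counts} /
#'   \code{baseline_exposure} (trials x baseline_bins, tone-anchored).
#'   Zero qualifying trials yields \code{n_trials = 0}, not an error.
#' @export
peri_event_counts <- function(unit, session,
                              alignment = c("tone_onset", "platform_entry"),
                              config = classifier_config()) {
  alignment <- match.arg(alignment)
  bw <- config$bin_width_s
  edges <- seq(-config$baseline_bins * bw, config$response_bins * bw,
               by = bw)
  nb <- length(edges) - 1L

  if (alignment == "tone_onset") {
    idx <- seq_len(min(config$n_trials_for_tone, length(session$trials)))
    align <- vapply(session$trials[idx], `[[`, numeric(1), "tone_onset_s")
  } else {
    lat <- vapply(session$trials, function(tr) {
      entries <- tr$platform_intervals_s[, 1L]
      entries <- entries[entries >= tr$tone_onset_s &
                         entries < tr$tone_onset_s + tr$tone_duration_s]
      if (length(entries)) entries[1L] - tr$tone_onset_s else NA_real_
    }, numeric(1))
    idx <- which(!is.na(lat) & lat >= config$min_platform_latency_s)
    align <- vapply(session$trials[idx], `[[`, numeric(1), "tone_onset_s") +
      lat[idx]
  }

  bin_one <- function(a, shock, edges_rel) {
    abs_edges <- a + edges_rel
    k <- length(abs_edges) - 1L
    cnt <- tabulate(findInterval(unit$spike_times_s, abs_edges,
                                 left.open = FALSE), nbins = k + 1L)[seq_len(k)]
    expo <- rep(diff(edges_rel), length.out = k)
    if (!is.null(shock))
      expo <- expo - mask_overlap(abs_edges[-(k + 1L)], abs_edges[-1L],
                                  shock[1L], shock[2L])
    list(cnt = cnt, expo = expo)
  }

  counts <- matrix(0, nrow = length(idx), ncol = nb)
  exposure <- matrix(bw, nrow = length(idx), ncol = nb)
  base_counts <- base_expo <- NULL
  if (alignment == "platform_entry") {
    base_counts <- matrix(0, nrow = length(idx),
                          ncol = config$baseline_bins)
    base_expo <- matrix(bw, nrow = length(idx), ncol = config$baseline_bins)
  }
  for (j in seq_along(idx)) {
    tr <- session$trials[[idx[j]]]
    b <- bin_one(align[j], tr$shock_interval_s, edges)
    counts[j, ] <- b$cnt
    exposure[j, ] <- b$expo
    if (alignment == "platform_entry") {
      pb <- bin_one(tr$tone_onset_s, tr$shock_interval_s,
                    seq(-config$baseline_bins * bw, 0, by = bw))
      base_counts[j, ] <- pb$cnt
      base_expo[j, ] <- pb$expo
    }
  }
  structure(list(counts = counts, exposure = exposure,
                 bin_edges_s = edges, align_times_s = align,
                 trial_ids = vapply(session$trials[idx], `[[`, integer(1),
                                    "trial_id"),
                 n_trials = length(idx), alignment = alignment,
                 baseline_counts = base_counts,
                 baseline_exposure = base_expo,
                 unit_id = unit$unit_id),
            class = "peri_event_counts")
}

#' Z-score one unit's peri-event rates against its pretone baseline
#'
#' Bin rates are pooled across trials (total counts over total exposure).
#' The baseline mean and sample SD (n-1 denominator) are taken across the
#' 20 pretone bin rates — for tone alignment these are the first 20 bins of
#' the window, for platform-entry alignment the tone-anchored pretone bins
#' returned by [peri_event_counts()]. Each bin's Z is its rate minus the
#' baseline mean, over the baseline SD. A zero or undefined baseline SD
#' (near-silent unit, no qualifying trials) flags the unit unclassifiable
#' rather than erroring.
#'
#' @param pec a \code{peri_event_counts}.
#' @param config a [classifier_config()].
#' @return List of class \code{zscore_row}: \code{z} (length
#'   \code{baseline_bins + response_bins}), \code{baseline_mean_hz},
#'   \code{baseline_sd_hz}, \code{unclassifiable} flag with \code{reason},
#'   \code{n_trials}, \code{bin_edges_s}, \code{alignment}.
#' @export
zscore <- function(pec, config = classifier_config()) {
  nb <- length(pec$bin_edges_s) - 1L
  out <- list(unit_id = pec$unit_id, z = rep(NA_real_, nb),
              baseline_mean_hz = NA_real_, baseline_sd_hz = NA_real_,
              unclassifiable = TRUE, reason = NA_character_,
              n_trials = pec$n_trials, bin_edges_s = pec$bin_edges_s,
              alignment = pec$alignment)
  class(out) <- "zscore_row"
  if (pec$n_trials == 0L) {
    out$reason <- "no_qualifying_trials"
    return(out)
  }
  rate <- colSums(pec$counts) / colSums(pec$exposure)
  if (pec$alignment == "platform_entry") {
    base <- colSums(pec$baseline_counts) / colSums(pec$baseline_exposure)
  } else {
    base <- rate[seq_len(config$baseline_bins)]
  }
  mu <- mean(base)
  sdv <- stats::sd(base)
  out$baseline_mean_hz <- mu
  out$baseline_sd_hz <- sdv
  if (!is.finite(sdv) || sdv == 0) {
    out$reason <- "zero_baseline_sd"
    return(out)
  }
  out$z <- (rate - mu) / sdv
  out$unclassifiable <- FALSE
  out
}

response_bin_index <- function(config, k) config$baseline_bins + k

#' Classify a unit's response at an alignment event
#'
#' A unit is excited when the first post-event bin exceeds
#' \code{z_excite} (2.58, p < 0.01 two-tailed); otherwise inhibited when
#' either of the first two post-event bins falls below \code{z_inhibit}
#' (-1.96, p < 0.05 two-tailed); otherwise unresponsive. The excitatory
#' rule is evaluated first, so the two labels are mutually exclusive.
#' Unclassifiable rows pass through with label \code{"unclassifiable"}.
#'
#' @param zrow a \code{zscore_row}.
#' @param config a [classifier_config()].
#' @return List of class \code{response_label}: \code{unit_id},
#'   \code{alignment}, \code{label}, \code{trigger_bin} (0-based index of
#'   the post-event bin that fired the rule, NA for none).
#' @export
classify_response <- function(zrow, config = classifier_config()) {
  lab <- "none"; trig <- NA_integer_
  if (zrow$unclassifiable) {
    lab <- "unclassifiable"
  } else {
    z0 <- zrow$z[response_bin_index(config, 1L)]
    z1 <- zrow$z[response_bin_index(config, 2L)]
    if (is.finite(z0) && z0 > config$z_excite) {
      lab <- "excited"; trig <- 0L
    } else if (is.finite(z0) && z0 < config$z_inhibit) {
      lab <- "inhibited"; trig <- 0L
    } else if (is.finite(z1) && z1 < config$z_inhibit) {
      lab <- "inhibited"; trig <- 1L
    }
  }
  structure(list(unit_id = zrow$unit_id, alignment = zrow$alignment,
                 label = lab, trigger_bin = trig),
            class = "response_label")
}

#' Split inhibited units into brief and sustained
#'
#' A unit counts as "sustained" when the inhibitory threshold is crossed in
#' at least \code{sustained_fraction} of the bins inside
#' \code{sustained_window_s} after the event (default: half the bins in
#' [10, 28) s); "brief" otherwise. Most recorded inhibitory responses ended
#' by ~10 s into the tone, a smaller fraction lasting the whole tone.
#'
#' @param zrow a classified \code{zscore_row} (must not be unclassifiable).
#' @param config a [classifier_config()].
#' @return \code{"brief"} or \code{"sustained"}.
#' @export
inhibition_duration_class <- function(zrow, config = classifier_config()) {
  stopifnot(!zrow$unclassifiable)
  lo <- config$sustained_window_s[1]; hi <- config$sustained_window_s[2]
  mid <- (zrow$bin_edges_s[-1] + zrow$bin_edges_s[-length(zrow$bin_edges_s)]) / 2
  sel <- mid > lo & mid < hi
  zz <- zrow$z[sel]
  zz <- zz[is.finite(zz)]
  frac <- if (length(zz)) mean(zz < config$z_inhibit) else 0
  if (frac >= config$sustained_fraction) "sustained" else "brief"
}

#' Z-score matrix for a set of units
#'
#' @param units list of \code{unit_recording}.
#' @param session the shared \code{session_events}.
#' @param alignment \code{"tone_onset"} or \code{"platform_entry"}.
#' @param config a [classifier_config()].
#' @return List of class \code{zscore_matrix}: \code{z} (units x bins,
#'   rownames = unit ids), \code{bin_edges_s}, \code{unclassifiable}
#'   logical vector, \code{baseline_mean_hz}, \code{baseline_sd_hz},
#'   \code{n_trials}, \code{alignment}, and \code{rows} (the underlying
#'   \code{zscore_row}s).
#' @export
build_zscore_matrix <- function(units, session,
                                alignment = c("tone_onset",
                                              "platform_entry"),
                                config = classifier_config()) {
  alignment <- match.arg(alignment)
  rows <- lapply(units, function(u)
    zscore(peri_event_counts(u, session, alignment, config), config))
  z <- do.call(rbind, lapply(rows, `[[`, "z"))
  rownames(z) <- vapply(rows, `[[`, character(1), "unit_id")
  structure(list(z = z, bin_edges_s = rows[[1]]$bin_edges_s,
                 unclassifiable = vapply(rows, `[[`, logical(1),
                                         "unclassifiable"),
                 baseline_mean_hz = vapply(rows, `[[`, numeric(1),
                                           "baseline_mean_hz"),
                 baseline_sd_hz = vapply(rows, `[[`, numeric(1),
                                         "baseline_sd_hz"),
                 n_trials = vapply(rows, `[[`, numeric(1), "n_trials"),
                 alignment = alignment, rows = rows),
            class = "zscore_matrix")
}

#' Classify every unit at an alignment event
#'
#' Driver producing the per-unit response table (the \code{responses.csv}
#' surface): one row per unit with its label, trigger bin and baseline
#' statistics. Unclassifiable units are reported, never dropped.
#'
#' @inheritParams build_zscore_matrix
#' @return data.frame with columns \code{unit_id, alignment, label,
#'   trigger_bin, baseline_mean_hz, baseline_sd_hz, n_trials}, plus
#'   \code{duration_class} (\code{"brief"}/\code{"sustained"} for inhibited
#'   units, NA otherwise).
#' @export
classify_units <- function(units, session,
                           alignment = c("tone_onset", "platform_entry"),
                           config = classifier_config()) {
  alignment <- match.arg(alignment)
  zm <- build_zscore_matrix(units, session, alignment, config)
  labs <- lapply(zm$rows, classify_response, config = config)
  dur <- vapply(seq_along(labs), function(i) {
    if (labs[[i]]$label == "inhibited")
      inhibition_duration_class(zm$rows[[i]], config)
    else NA_character_
  }, character(1))
  data.frame(unit_id = vapply(labs, `[[`, character(1), "unit_id"),
             alignment = alignment,
             label = vapply(labs, `[[`, character(1), "label"),
             trigger_bin = vapply(labs, `[[`, integer(1), "trigger_bin"),
             baseline_mean_hz = zm$baseline_mean_hz,
             baseline_sd_hz = zm$baseline_sd_hz,
             n_trials = zm$n_trials,
             duration_class = dur,
             row.names = NULL)
}

#' Time-resolved population response proportions
#'
#' At each bin, the fraction of classifiable units whose Z exceeds the
#' excitatory threshold and the fraction below the inhibitory threshold —
#' the population timecourse shown over the tone.
#'
#' @param zmat a \code{zscore_matrix}.
#' @param config a [classifier_config()].
#' @return data.frame with \code{bin_start_s, bin_end_s, prop_excited,
#'   prop_inhibited, n_units} (classifiable units with a finite Z at that
#'   bin).
#' @export
time_resolved_proportions <- function(zmat, config = classifier_config()) {
  z <- zmat$z[!zmat$unclassifiable, , drop = FALSE]
  nb <- ncol(z)
  exc <- numeric(nb); inh <- numeric(nb); n <- numeric(nb)
  for (b in seq_len(nb)) {
    zz <- z[, b]; zz <- zz[is.finite(zz)]
    n[b] <- length(zz)
    exc[b] <- if (length(zz)) mean(zz > config$z_excite) else 0
    inh[b] <- if (length(zz)) mean(zz < config$z_inhibit) else 0
  }
  data.frame(bin_start_s = zmat$bin_edges_s[-(nb + 1L)],
             bin_end_s = zmat$bin_edges_s[-1L],
             prop_excited = exc, prop_inhibited = inh, n_units = n)
}

#' Heat-map ordering of a Z-score matrix
#'
#' Rows (units) sorted by the mean Z of the first two post-event bins,
#' descending, ties broken by unit id — the ordering used for population
#' heat maps. Pure reordering: the multiset of rows is preserved.
#'
#' @param zmat a \code{zscore_matrix}.
#' @param config a [classifier_config()].
#' @return List with \code{z} (ordered matrix) and \code{order} (row
#'   permutation applied).
#' @export
heatmap_matrix <- function(zmat, config = classifier_config()) {
  i0 <- response_bin_index(config, 1L)
  key <- rowMeans(zmat$z[, c(i0, i0 + 1L), drop = FALSE])
  key[is.na(key)] <- -Inf
  ord <- order(-key, rownames(zmat$z))
  list(z = zmat$z[ord, , drop = FALSE], order = ord)
}

#' Putative projection neuron criterion
#'
#' Prefrontal units are typed as putative projection neurons when the
#' spike width strictly exceeds 225 microseconds and the baseline firing
#' rate is strictly below 15 Hz; narrow/fast units are putative
#' interneurons.
#'
#' @param spike_width_us spike width, microseconds (vectorized).
#' @param baseline_rate_hz baseline firing rate, Hz (vectorized).
#' @param config a [classifier_config()].
#' @return Logical vector.
#' @export
is_putative_projection <- function(spike_width_us, baseline_rate_hz,
                                   config = classifier_config()) {
  spike_width_us > config$projection_width_us &
    baseline_rate_hz < config$projection_rate_hz
}

#' Overlap of tone-onset and platform-entry responders
#'
#' For each polarity, counts units responsive to the tone only, to
#' platform entry only, or to both (the Venn partition of responders).
#'
#' @param tone_labels,platform_labels data.frames from [classify_units()]
#'   at the two alignments.
#' @return data.frame with one row per polarity and columns
#'   \code{tone_only, platform_only, both, total}.
#' @export
overlap_venn <- function(tone_labels, platform_labels) {
  out <- lapply(c("excited", "inhibited"), function(pol) {
    tu <- tone_labels$unit_id[tone_labels$label == pol]
    pu <- platform_labels$unit_id[platform_labels$label == pol]
    both <- length(intersect(tu, pu))
    data.frame(polarity = pol,
               tone_only = length(setdiff(tu, pu)),
               platform_only = length(setdiff(pu, tu)),
               both = both,
               total = length(union(tu, pu)))
  })
  do.call(rbind, out)
}
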