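cfg <- classifier_config()

test_that("bins are half-open: spikes at the edge fall into the later bin", {
  on <- 100
  ses <- make_session(on)
  u <- make_unit(c(on + 0.0, on + 0.5))
  pec <- peri_event_counts(u, ses, "tone_onset", cfg)
  expect_equal(pec$n_trials, 1L)
  i0 <- cfg$baseline_bins + 1L
  expect_equal(pec$counts[1, i0], 1)       # [0.0, 0.5)
  expect_equal(pec$counts[1, i0 + 1L], 1)  # [0.5, 1.0)
  expect_equal(sum(pec$counts), 2)
})

test_that("binning matches a brute-force per-spike assignment", {
  set.seed(210)
  for (rep in 1:100) {
    onsets <- cumsum(runif(sample(2:6, 1), 150, 250))
    ses <- make_session(onsets)
    spikes <- sort(runif(sample(5:60, 1), 0, max(onsets) + 60))
    spikes <- spikes[c(TRUE, diff(spikes) > 0)]
    u <- make_unit(spikes)
    pec <- peri_event_counts(u, ses, "tone_onset", cfg)
    edges <- pec$bin_edges_s
    brute <- matrix(0, nrow = pec$n_trials, ncol = length(edges) - 1L)
    for (j in seq_len(pec$n_trials)) {
      a <- pec$align_times_s[j]
      for (s in spikes) for (b in seq_len(length(edges) - 1L)) {
        if (s >= a + edges[b] && s < a + edges[b + 1L])
          brute[j, b] <- brute[j, b] + 1
      }
    }
    expect_equal(pec$counts, brute)
  }
})

test_that("tone-onset counting uses only the first five trials", {
  onsets <- seq(200, by = 250, length.out = 9)
  ses <- make_session(onsets)
  u <- make_unit(onsets + 0.1)  # one spike in bin 0 of every trial
  pec <- peri_event_counts(u, ses, "tone_onset", cfg)
  expect_equal(pec$n_trials, 5L)
  expect_equal(sum(pec$counts), 5)
})

test_that("z-scoring reproduces hand-computed values and degenerate flags", {
  # one trial; pretone bin rates alternate 4 and 8 Hz (counts 2/4 per
  # 0.5-s bin), first tone bin 2 Hz (1 spike): mu = 6, sample sd 2.0519,
  # z0 = (2 - 6)/2.0519 = -1.9494
  on <- 100
  ses <- make_session(on, shock = FALSE)
  spikes <- c()
  for (b in 1:20) {
    nsp <- if (b %% 2 == 1) 2 else 4
    lo <- on - 10 + (b - 1) * 0.5
    spikes <- c(spikes, lo + (1:nsp) / (nsp + 1) * 0.5)
  }
  spikes <- c(spikes, on + 0.25)
  u <- make_unit(spikes)
  zr <- zscore(peri_event_counts(u, ses, "tone_onset", cfg), cfg)
  expect_false(zr$unclassifiable)
  expect_equal(zr$baseline_mean_hz, 6)
  expect_equal(zr$baseline_sd_hz, sqrt(20 * 4 / 19))
  expect_equal(zr$z[cfg$baseline_bins + 1L], -1.949359, tolerance = 1e-6)
  # pretone z's are centred: they average zero
  expect_equal(mean(zr$z[1:20]), 0, tolerance = 1e-12)

  # constant-rate unit: sd = 0 -> unclassifiable, not an error
  u2 <- make_unit(seq(on - 10 + 0.25, on + 28, by = 0.5))
  zr2 <- zscore(peri_event_counts(u2, ses, "tone_onset", cfg), cfg)
  expect_true(zr2$unclassifiable)
  expect_equal(zr2$reason, "zero_baseline_sd")
  expect_equal(classify_response(zr2, cfg)$label, "unclassifiable")
})

test_that("classification thresholds and precedence follow the Z rules", {
  expect_equal(classify_response(forge_zrow(3.0, 0), cfg)$label, "excited")
  expect_equal(classify_response(forge_zrow(3.0, 0), cfg)$trigger_bin, 0L)
  r <- classify_response(forge_zrow(-1.0, -2.5), cfg)
  expect_equal(r$label, "inhibited")
  expect_equal(r$trigger_bin, 1L)
  expect_equal(classify_response(forge_zrow(-2.5, 0), cfg)$trigger_bin, 0L)
  expect_equal(classify_response(forge_zrow(2.0, -1.5), cfg)$label, "none")
  expect_equal(classify_response(forge_zrow(2.58, 0), cfg)$label, "none")
  expect_equal(classify_response(forge_zrow(-1.96, -1.96), cfg)$label,
               "none")
  expect_equal(classify_response(forge_zrow(0, 0, unclassifiable = TRUE),
                                 cfg)$label, "unclassifiable")
})

test_that("classification is invariant to spikes outside analysis windows", {
  set.seed(211)
  onsets <- cumsum(runif(5, 150, 250))
  ses <- make_session(onsets)
  spikes <- sort(runif(400, 0, max(onsets) + 60))
  u <- make_unit(spikes)
  base <- classify_response(zscore(peri_event_counts(u, ses, "tone_onset",
                                                     cfg), cfg), cfg)
  # inject spikes strictly between analysis windows (ITI, > 28 s after
  # onset and > 10 s before the next onset)
  extra <- onsets[1:4] + runif(20, 40, 100)
  u2 <- make_unit(sort(c(spikes, extra)))
  mod <- classify_response(zscore(peri_event_counts(u2, ses, "tone_onset",
                                                    cfg), cfg), cfg)
  expect_identical(mod$label, base$label)
  expect_identical(mod$trigger_bin, base$trigger_bin)
})

test_that("platform-entry alignment excludes fast entries and reuses the pretone baseline", {
  on <- c(200, 500, 800)
  platform <- list(matrix(c(on[1] + 0.4, on[1] + 45), ncol = 2),  # < 1 s
                   matrix(c(on[2] + 5.0, on[2] + 45), ncol = 2),
                   NULL)                                           # no entry
  ses <- make_session(on, platform = platform)
  set.seed(212)
  u <- make_unit(poisson_train(6, 0, 900))
  pec <- peri_event_counts(u, ses, "platform_entry", cfg)
  expect_equal(pec$n_trials, 1L)
  expect_equal(pec$trial_ids, 2L)
  expect_equal(pec$align_times_s, on[2] + 5.0)
  expect_false(is.null(pec$baseline_counts))
  # the baseline is the tone-anchored pretone of the same trial
  zr <- zscore(pec, cfg)
  pre <- sum(u$spike_times_s >= on[2] - 10 & u$spike_times_s < on[2])
  expect_equal(zr$baseline_mean_hz, pre / 10, tolerance = 1e-10)
})

test_that("no qualifying trials yields an empty-result flag, not an error", {
  ses <- make_session(c(200, 500))  # no platform events at all
  u <- make_unit(poisson_train(6, 0, 600))
  pec <- peri_event_counts(u, ses, "platform_entry", cfg)
  expect_equal(pec$n_trials, 0L)
  zr <- zscore(pec, cfg)
  expect_true(zr$unclassifiable)
  expect_equal(zr$reason, "no_qualifying_trials")
})

test_that("time-resolved proportions count threshold crossings per bin", {
  nb <- cfg$baseline_bins + cfg$response_bins
  zm <- structure(list(
    z = matrix(0, nrow = 4, ncol = nb,
               dimnames = list(paste0("u", 1:4), NULL)),
    bin_edges_s = seq(-10, 28, by = 0.5),
    unclassifiable = rep(FALSE, 4)), class = "zscore_matrix")
  props <- time_resolved_proportions(zm, cfg)
  expect_true(all(props$prop_excited == 0 & props$prop_inhibited == 0))
  zm$z[1, 30] <- 3
  zm$z[2, 31] <- -2.5
  props <- time_resolved_proportions(zm, cfg)
  expect_equal(props$prop_excited[30], 0.25)
  expect_equal(props$prop_inhibited[31], 0.25)
  expect_true(all(props$prop_excited + props$prop_inhibited <= 1))
})

test_that("heat-map ordering is a pure reordering with deterministic ties", {
  set.seed(213)
  nb <- cfg$baseline_bins + cfg$response_bins
  z <- matrix(rnorm(10 * nb), nrow = 10,
              dimnames = list(sprintf("u%02d", 10:1), NULL))
  zm <- structure(list(z = z, bin_edges_s = seq(-10, 28, by = 0.5),
                       unclassifiable = rep(FALSE, 10)),
                  class = "zscore_matrix")
  hm <- heatmap_matrix(zm, cfg)
  i0 <- cfg$baseline_bins + 1L
  key <- rowMeans(hm$z[, c(i0, i0 + 1L)])
  expect_true(all(diff(key) <= 0))
  expect_setequal(rownames(hm$z), rownames(z))
  # explicit-sort oracle
  key0 <- rowMeans(z[, c(i0, i0 + 1L)])
  expect_identical(rownames(hm$z), rownames(z)[order(-key0, rownames(z))])
  # single row is identity; ties break by unit id
  zm1 <- structure(list(z = z[1, , drop = FALSE],
                        bin_edges_s = zm$bin_edges_s,
                        unclassifiable = FALSE), class = "zscore_matrix")
  expect_identical(heatmap_matrix(zm1, cfg)$order, 1L)
  ztie <- matrix(0, nrow = 3, ncol = nb,
                 dimnames = list(c("b", "a", "c"), NULL))
  zmt <- structure(list(z = ztie, bin_edges_s = zm$bin_edges_s,
                        unclassifiable = rep(FALSE, 3)),
                   class = "zscore_matrix")
  expect_identical(rownames(heatmap_matrix(zmt, cfg)$z), c("a", "b", "c"))
})

test_that("projection-neuron criterion is strict on both boundaries", {
  expect_true(is_putative_projection(300, 6))
  expect_false(is_putative_projection(225, 6))
  expect_false(is_putative_projection(300, 15))
  expect_equal(is_putative_projection(c(300, 200), c(6, 6)),
               c(TRUE, FALSE))
})

test_that("responder overlap matches brute-force set intersection", {
  mk <- function(ids, labels) data.frame(unit_id = ids, label = labels)
  # disjoint
  v <- overlap_venn(mk(c("a", "b"), c("excited", "excited")),
                    mk(c("c", "d"), c("excited", "excited")))
  expect_equal(v$both[v$polarity == "excited"], 0)
  expect_equal(v$total[v$polarity == "excited"], 4)
  # identical
  v <- overlap_venn(mk(c("a", "b"), c("inhibited", "inhibited")),
                    mk(c("a", "b"), c("inhibited", "inhibited")))
  expect_equal(v$both[v$polarity == "inhibited"], 2)
  expect_equal(v$tone_only[v$polarity == "inhibited"], 0)
  # random labels vs brute force
  set.seed(214)
  for (rep in 1:100) {
    ids <- sprintf("u%02d", 1:20)
    t_lab <- sample(c("excited", "inhibited", "none"), 20, replace = TRUE)
    p_lab <- sample(c("excited", "inhibited", "none"), 20, replace = TRUE)
    v <- overlap_venn(mk(ids, t_lab), mk(ids, p_lab))
    for (pol in c("excited", "inhibited")) {
      tu <- ids[t_lab == pol]; pu <- ids[p_lab == pol]
      row <- v[v$polarity == pol, ]
      expect_equal(row$both, sum(ids %in% tu & ids %in% pu))
      expect_equal(row$tone_only + row$platform_only + row$both, row$total)
      expect_equal(row$total, length(unique(c(tu, pu))))
    }
  }
})

test_that("brief/sustained split reflects inhibition persistence", {
  nb <- cfg$baseline_bins + cfg$response_bins
  edges <- seq(-10, 28, by = 0.5)
  mk <- function(zlate) {
    z <- rep(0, nb); z[21] <- -3
    mid <- (edges[-1] + edges[-length(edges)]) / 2
    z[mid > 10 & mid < 28] <- zlate
    structure(list(unit_id = "x", z = z, bin_edges_s = edges,
                   unclassifiable = FALSE, alignment = "tone_onset"),
              class = "zscore_row")
  }
  expect_equal(inhibition_duration_class(mk(-3), cfg), "sustained")
  expect_equal(inhibition_duration_class(mk(0), cfg), "brief")
})
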