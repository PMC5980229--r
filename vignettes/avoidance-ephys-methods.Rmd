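---
title: "Methods: peri-event classification and behavioral metrics for platform-mediated avoidance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: peri-event classification and behavioral metrics for platform-mediated avoidance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The task and the data model

In platform-mediated avoidance, a rat pressing a lever for food learns that
a 30-s tone predicts a 2-s footshock co-terminating with the tone, and that
stepping onto a platform protects it. Sessions contain nine tone-shock
pairings at variable inter-trial intervals averaging three minutes.
Avoidance competes with foraging, so the behavioral readout is rich: time
on the platform, latency of entry, freezing, and conditioned suppression of
bar pressing. Extracellular single units recorded in prelimbic cortex (PL)
during the task show both excitatory and inhibitory responses to tone
onset; the analyses here quantify those responses and their relation to the
behavior.

`avoidephys` starts from *sorted* spike timestamps and scored behavioral
events — spike sorting and video scoring are upstream. All times are
seconds from session start, as doubles; every interval is half-open
`[start, end)`, which makes occupancy additive under splitting and removes
double counting at shared boundaries. Units with too little baseline
activity for any given analysis are carried through and reported as
`unclassifiable`, never dropped: near-silent cells are a fact of real
recordings, and silent attrition would bias population proportions.

The shock is special: acquisition systems blank during the 2-s shock, so
no spikes exist there. All spike-count windows therefore mask shock
epochs. Rates are computed as counts over *exposure* (usable seconds per
bin); for tone-aligned analyses the 28-s response window simply ends at
shock onset, and masking only has teeth for platform-entry-aligned windows
that straddle the shock.

# Peri-event Z-score classification

For each unit, spikes are binned in 500-ms bins from 10 s before to 28 s
after the alignment event. Tone-onset classification uses the first five
trials of the session; platform-entry classification uses all successful
avoidance trials. Bin rates are pooled across trials (total counts over
total exposure; identical to the mean of per-trial rates whenever exposure
is equal, and better behaved when the shock truncates a bin on some
trials). With $r_b$ the pooled rate of bin $b$, and $\mu$, $\sigma$ the
mean and sample standard deviation (the $n-1$ estimator; the estimator is
a package choice, as is averaging trials before taking the across-bin SD)
of the twenty pretone bin rates,

$$ z_b = \frac{r_b - \mu}{\sigma}. $$

A unit is **excited** when $z > 2.58$ (p < 0.01, two-tailed) in the first
post-event bin, and otherwise **inhibited** when $z < -1.96$ (p < 0.05,
two-tailed) in either of the first two bins — the extra bin allowed for
inhibition reflects the longer latencies of multi-synaptic inhibitory
circuits. Evaluating the excitatory rule first makes the labels mutually
exclusive by construction. When $\sigma = 0$ (constant or silent
baseline), the unit is flagged unclassifiable.

Platform-entry responses are normalized against *the same pretone
baseline* as tone responses, anchored to each qualifying trial's tone.
Entries earlier than 1 s after tone onset are excluded from entry-aligned
analysis so that tone-onset activity is not mistaken for an entry
response; in the recorded behavior 91% of entries are later than 1 s.

Inhibited units are further split into **brief** and **sustained**: a unit
is sustained when at least half of the bins in [10, 28) s remain below the
inhibitory threshold. The recordings motivate only a qualitative split
("ending by ~10 s"), so both the window and the fraction are exposed as
configuration (`sustained_window_s`, `sustained_fraction`).

Two consequences of the estimated baseline are worth knowing. First, the
false-positive rate of the excitatory rule is *not* the nominal one-tailed
0.005: the SD is estimated from twenty skewed Poisson bin rates, so the
tail is heavier. Our Monte-Carlo reference (200,000 replicates of per-bin
Poisson counts at 6 Hz, five-trial averages) puts the null excited rate at
0.0148 and the null inhibited rate at 0.0522; the test suite holds the
full spike-train pipeline to binomial 99% confidence bands around those
values at 2,000 units. Second, detection of a given rate drop is easier in
high-rate units (the drop grows like the rate while the bin-rate SD grows
like its square root), so labeled-inhibited populations are slightly
biased toward higher baselines.

# ISI-based inhibition latency

Per cell and per trial, the inhibition latency is the start of the first
interspike interval, among ISIs whose starting spike lies within the
30-s tone, satisfying

$$ \frac{\mathrm{ISI} - \overline{\mathrm{ISI}}_{pre}}{s_{pre}} > 1.65 $$

with mean and sample SD taken over the ISIs of the 30-s pretone window of
the same cell and trial (the per-cell-per-trial reading of the baseline;
a pooled-across-cells baseline is the other reading of the source
procedure, and is not implemented). The ISI straddling tone onset is
excluded — its start is pretone, and including it would allow negative
latencies. The gap from the last in-window spike to the window end is not
an ISI. Trials with fewer than two pretone ISIs, or zero ISI variance,
are unscorable and reported with a reason code. Per-cell summaries
average the detected latency and the behavioral latencies over successful
(avoided) trials only.

This detector is deliberately liberal (one-tailed 0.05 per ISI against an
exponential-like null), as in the source procedure: at 6 Hz a null ISI
crosses the threshold roughly 7% of the time, so over many tone ISIs most
cells eventually show *some* qualifying interval. Recovery is therefore
validated at the population level: with inhibition onsets injected
uniformly on [0, 3] s at a 6 to 2 Hz drop, the correlation between
injected onset and per-cell mean detected latency exceeds 0.5 at 200
units (measured ~0.75 in the suite).

# Behavioral endpoints

All tone-referenced percentages are over the 30-s tone: platform
occupancy, freezing (pre-scored intervals), and a 10-bin, 3-s timecourse
whose mean equals the overall platform percentage exactly. Avoidance
latency is the first platform entry within the tone; trials with no entry
are capped at 30 s and flagged, and capped values enter rank tests at
ceiling. Conditioned suppression of pressing is

$$ \frac{p - t}{p + t} $$

with $p$ the press rate in the 60 s before tone onset and $t$ the rate
during the tone; 0 is no suppression and 1 complete suppression, and
$p = t = 0$ returns 0 by convention. The unit-scaled ratio is reported
because the source results print values on that scale (0.922, 0.984); a
`percent = TRUE` flag reproduces the x100 display scale of the defining
formula.

# Population statistics

Pearson chi-square (no continuity correction — the printed statistics
22.545 and 0.547 reproduce exactly only without it), Fisher's exact test
by hypergeometric enumeration, Mann-Whitney U and Wilcoxon signed-rank
with midrank ties. The rank tests are exact for small samples (both
groups at most 12, or at most 15 nonzero differences) via dynamic
programmes equivalent to full permutation/sign enumeration — ties
included, which is why they are implemented here rather than delegated to
`stats::wilcox.test` (which abandons exactness under ties); the `stats`
routines serve as independent cross-checks in the test suite. Larger
samples use normal approximations with tie corrections and no continuity
correction. Two-tailed p-values throughout; Bonferroni correction is
never applied silently.

Laser modulation (optrode validation protocols) compares mean firing per
1-s bin across trials between equal-length OFF and ON epochs (10 s for
the constant-light silencing protocol, 30 s for pulsed activation) with
the signed-rank test at $\alpha = 0.05$, calling the direction from the
mean difference.

# The synthetic-data generator

The generator exists so that every stage is verifiable without recorded
data. It draws spike trains from an inhomogeneous Poisson process with a
piecewise-constant intensity, sampled exactly by thinning a homogeneous
process at the maximum rate. Defaults emulate the recorded conditions:

* baseline rates log-normal with median 6 Hz (`sdlog` 0.35), the scale of
  PL putative projection neurons; spike widths uniform on 240-450 µs so
  default units satisfy the projection criterion (> 225 µs, < 15 Hz);
* excitatory responses: a 3x gain on the first 500 ms of each tone;
* inhibitory responses: rate clamped to a 2 Hz floor from a per-unit
  onset lag (uniform on [0, 1] s by default) for 8 s (brief) or the whole
  tone (sustained), emulating the recorded 6 to 2 Hz drop;
* sessions: nine 30-s tones, onset-to-onset gaps minus the tone uniform
  on [120, 240] s (mean 3 min), 2-s shocks co-terminating with the tone
  for conditioned groups, none for naive sessions; fear-group sessions
  have tones and shocks but no platform;
* behavior: platform entry on each trial with probability 0.7, at a
  log-normal latency with median 3.55 s and `sdlog` 0.945 — the two
  anchors the recordings provide are the median and that 91% of entries
  exceed 1 s, and this `sdlog` is the value implied by them (the full
  latency distribution is otherwise unspecified, so the log-normal shape
  is a modeling choice); entries later than 28 s are redrawn; a head turn
  precedes each entry; exit follows tone end; presses form a 0.5 Hz
  Poisson stream thinned to zero during platform occupancy, which is what
  produces conditioned suppression;
* cohort composition mirrors the recorded populations (205/166/191 units
  with 30/20/25 excited and 22/3/3 inhibited), with all inhibited units
  in rostral PL.

What the generator does **not** model: refractoriness (negligible overlap
at ≤ 15 Hz, but regular-spiking statistics are not reproduced), spike
waveforms (width is a metadata scalar), rate drift within sessions,
multi-rat session structure (one session per group, because the
interchange format has no session axis — so behavioral latencies are
shared across units of a group), and any correlation between neural
inhibition and the behavioral choice to avoid. Passing tests therefore
demonstrate correctness of the *analysis* under Poisson assumptions, not
that real PL data would behave this way.

# Determinism and numerical choices

Every simulation accepts a seed, and one top-level seed fans out to
deterministic child seeds through a fixed linear congruential step modulo
$2^{31}-1$, so each stage is independently reproducible. CSV writers emit
canonical formatting (fixed column order, 9-decimal times), making
write-read-write byte-identical; pipeline outputs carry the seed and a
configuration hash in their header line. Ties in the heat-map ordering
break by unit id. Degenerate inputs follow explicit conventions stated
above (zero-SD baselines, all-zero press rates, all-zero signed-rank
differences, empty trial sets).

Problem sizes used by the validation suite — 2,000 units for null
calibration, 200 for sensitivity and latency recovery, 200,000 replicates
for the frozen Monte-Carlo reference, small three-group cohorts for
end-to-end determinism — were chosen so the whole suite runs in about a
minute while leaving the checked proportions with narrow binomial error
bands.

# Known limitations

The classifier's null rates depend on the baseline rate through Poisson
discreteness, so the frozen reference values hold at the 6 Hz / 5-trial
condition they were computed for. The ISI detector's per-ISI false-alarm
rate makes single-trial latencies noisy; only averaged or population-level
statements are supported. The brief/sustained split is a thresholded
heuristic over a qualitative description. Region assignment in the
generator is deterministic by response class (inhibited implies rostral),
which reproduces the recorded contrast but cannot model partial
lateralization.
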