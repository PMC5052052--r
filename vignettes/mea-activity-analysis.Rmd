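---
title: "Detecting excitability changes in multiwell MEA recordings"
author: "MEAactivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting excitability changes in multiwell MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(MEAactivity)
```

## The problem

Cultured neuronal networks grown on multiwell microelectrode array (MEA)
plates fire spontaneously, and the statistics of that firing — rate,
bursting, and plate-wide synchrony — change when the network's excitability
is perturbed, for instance by knocking down a microRNA. A typical experiment
records every well for 15 minutes a day across the culture's maturation
(day in vitro, DIV, 3 through 19), with treated and control wells on the
same plates. The acquisition system emits a *spike list*: one row per
detected spike with its timestamp, well, electrode, and amplitude.

`MEAactivity` turns those spike lists into per-well activity features and
answers the question "does the treatment change activity?" with
nonparametric statistics that respect the experiment's unit of replication
— the well.

## Pipeline and model

The pipeline has four stages.

**1. Activity QC.** An electrode counts as *active* on a day when it
recorded at least 5 spikes per minute (boundary inclusive; 75 spikes in a
15-minute recording is exactly at threshold and counts). A well is removed
from analysis when fewer than 16 of its 64 electrodes were active on
strictly more than 30% of its recorded days. Both thresholds are
parameters. Activity is re-assessed per day, so the denominator of every
per-electrode rate is that day's active set; the alternative (one fixed set
per well) is available by building a mask from a single day's recordings.
The day-fraction denominator is the number of days the plate was actually
recorded, making the rule robust to missed days.

**2. Burst detection.** Per-electrode bursts are found with the fixed-
parameter *max-interval* method: a burst opens at a spike whose following
inter-spike interval (ISI) is at most `maxBeginISI` (default 0.1 s),
extends while ISIs stay at most `maxEndISI` (0.25 s), bursts closer than
`minIBI` (0.8 s) merge, and bursts shorter than `minDuration` (0.05 s) or
with fewer than `minSpikes` (5) spikes are discarded. A merged burst owns
every spike in its span; burst duration is last-spike minus first-spike
time, not padded by the ISI allowances. The defaults are the standard
parameterisation of this detector family for cortical cultures; all five
are exposed in `burstParams()` because published experiments differ in
them, and reproducing a particular dataset may require changing them in one
place.

**3. Network events.** A *network spike* is a population event: the time
axis is cut into fixed 25 ms bins, a bin where spikes from at least
`minParticipants` distinct electrodes occur qualifies, and consecutive
qualifying bins merge. A *network burst* is an interval during which at
least `minParticipants` electrodes are simultaneously inside a detected
burst (closed intervals; simultaneity is evaluated by a boundary sweep).
`minParticipants` defaults to 25% of the well's electrodes — 16 of 64 —
and events with fewer participants are filtered out. The 25 ms bin width is
a typical population-spike window for multiwell MEA work; it is a free
parameter (`nsBin`) because there is no single canonical value. Network
bursts are not merged across gaps by default (`nbMergeGap = 0`).

**4. Features and statistics.** Each included well-day yields: number of
active electrodes; mean firing rate (MFR) in Hz *per active electrode*;
bursts per minute per active electrode; mean burst duration; mean
inter-burst interval (IBI, end-of-burst to next start on the same
electrode, pooled over the well's electrodes); network-spike count;
network bursts per second; and the percentage of spikes inside bursts and
inside network events. A day on which an included well has no active
electrode yields missing values, never zeros.

Two statistical tiers compare conditions, both two-sided and nonparametric:

* **Per-DIV MWU + Fisher.** For each DIV in the analysis window
  (default DIV8–DIV16) a Mann–Whitney U test compares the wells of the two
  conditions; the per-day p-values combine by Fisher's method,
  $\chi^2 = -2\sum_i \ln p_i$ on $2k$ degrees of freedom. Days with fewer
  than two wells per group are skipped and reported.
* **Pooled-window permutation test.** Each well's values over the window
  reduce to one observation (default: the mean over available days), an
  MWU test compares the two well sets, and the well labels are then
  permuted 10,000 times with group sizes preserved. The reported p-value is
  $(1 + \#\{p_{perm} \le p_{obs}\})/(n_{perm}+1)$: ties count against the
  observed statistic, and complete separation reports the attainable
  minimum $1/(n_{perm}+1)$ — i.e. "p < 0.0001" at 10,000 permutations.

The window reduction uses the per-well mean because the permutation unit is
the well label: one observation per well keeps the permutation
exchangeable. A `"concat"` mode (every well-day an observation, labels
still permuted per well) is provided for sensitivity analysis. Inside the
permutation loop the observed and permuted MWU p-values are both computed
with the same normal-approximation formula (tie and continuity corrected),
so they are compared on one scale; the standalone `mwuTest()` switches to
the exact enumeration null when both groups have at most 8 observations
and no ties. No multiplicity correction is applied across features; the
report lists all features side by side.

## The synthetic-data generator

`simulationConfig()`/`simulateExperiment()` generate complete experiments
so every stage is testable offline. Per alive electrode (alive with
probability 0.85), three stationary point processes superpose:

* homogeneous Poisson background firing (default 1 Hz at full maturation);
* a burst process: Poisson onsets (5/min), each emitting a
  $1 + \mathrm{Poisson}(7)$ spike cluster with exponential within-burst
  ISIs (mean 10 ms);
* well-level synchronous events: Poisson onsets (2/min); each recruits
  every alive electrode independently with probability 0.6, and recruited
  electrodes fire a short high-rate cluster (mean ISI 2 ms) at the event
  time.

Rates are modulated multiplicatively by (a) the condition's effect
multipliers on background rate, burst rate, burst duration, IBI and
network-event rate (control is all 1; the default treatment is 1.5, 1.5,
1.3, 0.7, 1.5 — an excitability phenotype: faster firing, denser and
longer bursts, more synchronous events); (b) a per-DIV maturation curve,
by default the logistic $1/(1+e^{-(d-6.5)/1.2})$ rising from DIV3 and
plateauing near DIV10, mimicking culture maturation; and (c) a per-well
lognormal random effect with mean 1 and coefficient of variation 0.3,
drawn once per well and held across days. The between-well effect is what
makes the permutation test's null realistic: wells are exchangeable but
not identical. The default design is 17 control and 16 treatment wells,
daily 900 s recordings, 64 electrodes per well — at these settings a
single active well produces well over 10,000 spikes per 15-minute
recording, the order of magnitude real cortical cultures show.

What the generator does *not* emulate: spatial structure on the 8×8
electrode grid (the analysis is grid-blind), electrode drift or impedance
artifacts, refractoriness, day-level random effects beyond the maturation
curve, and any biophysics. Passing tests therefore demonstrate the
*analysis* is correct under the model's statistical structure, not that
the model reproduces any particular biological culture.

## Numerical choices and degenerate inputs

* Recording duration is a configured constant (default 900 s), never
  inferred from the last spike, so rate denominators cannot shrink.
* Timestamps stay as continuous seconds; nothing is resampled at ingest.
* Boundary semantics are fixed: activity threshold inclusive ("at least
  five per minute"), day-fraction rule strictly greater than 30%,
  network-event participation at least 16.
* Burst-interval overlap for network bursts treats bursts as closed
  intervals: one burst ending exactly when another starts counts as
  momentary simultaneity.
* A Mann–Whitney comparison of a fully degenerate pooled sample (every
  value identical, e.g. a feature that is zero in every well) reports
  p = 1 — no evidence either way — rather than an undefined statistic.
* Zero active electrodes, empty spike trains, empty burst sets and empty
  windows all return empty/missing results rather than zeros or errors;
  conflicting group assignments and malformed spike-list rows are errors
  (lenient mode drops and counts bad rows instead).
* All permutation randomness flows through a single seed recorded in the
  output; identical seeds give byte-identical pipeline outputs.

## Verification problem sizes

The test suite validates the optimized detectors against literal
brute-force transcriptions of their rules (1,000 random spike trains for
the burst detector; 500 random interval sets for the network-burst sweep;
exhaustive rank-arrangement enumeration for the exact MWU path up to 6+6),
checks the Fisher combination against numerical integration, and exercises
the resampling machinery end to end: a null calibration (1,000 simulated
null experiments, 17 vs 16 wells, 1,000 permutations each, rejection rate
required inside the 95% binomial band around 5%) and a power study (100
experiments with a 1.5× firing-rate effect at CV 0.3, at least 90
detections required). The resampling studies run the full pipeline on
deliberately small recordings (one DIV, 4 electrodes per well, 30 s,
background process only) — the permutation test sees only well-level
features, so its calibration is governed by the between-well variability,
which is kept at the defaults; isolating the background process also makes
the imposed 1.5× multiplier exactly the MFR effect being detected, which
is what the power study is about. `scripts/acceptance.R` runs the complete
pipeline at full plate width (33 wells × 64 electrodes, DIV3–DIV19) with
300 s recordings; every reported feature is a duration-normalised rate or
percentage, so the shorter recording changes only sampling noise, not the
estimands.

## Known limitations

* The max-interval burst detector is the fixed-parameter family only; no
  adaptive (Poisson-surprise, CMA) detectors.
* Network-spike detection uses fixed bins, not a sliding window; a
  population spike straddling a bin edge merges via the
  consecutive-qualifying-bin rule, but sub-bin timing is not recovered.
* Synchrony is within-well only; no cross-well or propagation analysis.
* The MWU normal approximation inside the permutation loop is the standard
  tie-corrected one; for very small well counts (both groups ≤ 8) the
  standalone exact test will differ slightly from the permutation tier's
  approximate observed p — by design, since the permuted statistics use
  the same approximation.
* Amplitudes are carried through I/O but never used.

## A worked example

```{r example, eval = FALSE}
library(MEAactivity)

cfg <- simulationConfig(seed = 1, duration = 300)
experiment <- simulateExperiment(cfg)          # 33 wells, DIV3-DIV19
analysis <- analyzeExperiment(experiment)      # QC + bursts + events
cmp <- compareGroups(analysis$features, window = 8:16,
                     nPerm = 10000, seed = 1001)
cmp$table[, c("feature", "fisher_p", "perm_p")]
```

With the default treatment effects the rate and burst features come out
highly significant (permutation p at or near the attainable minimum
1/10,001) while `pct_spikes_in_network_events` — a synchrony feature whose
numerator and denominator scale together — does not.
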