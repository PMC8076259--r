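---
title: "Rodent sleep EEG analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rodent sleep EEG analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(murisleep)
```

# Overview

`murisleep` implements a complete analysis chain for rodent polysomnography
under a light/dark schedule: two-channel (EEG, EMG) recordings sampled at
250 Hz are band-limited as acquisition hardware would (EEG 0.1–100 Hz, EMG
1–100 Hz), downsampled to 125 Hz, cut into non-overlapping 4 s epochs and
scored into the three vigilance states WAKE, NREMS and REMS. The resulting
hypnograms feed four analysis layers:

1. **Architecture** — circadian state percentages (2 h bins and 12 h light /
   11 h dark aggregates), bout numbers and durations, transition counts and
   percentages, and sleep latencies.
2. **Spectra** — per-epoch Welch power spectral density at 0.25 Hz
   resolution, normalized per epoch, summarized per state and phase.
3. **Spindles** — two-threshold detection of 10–15 Hz NREMS spindle events
   on the cubed RMS envelope of the sigma-filtered EEG.
4. **Statistics** — exact Mann–Whitney U tests, AUC effect sizes with
   bootstrap confidence intervals, and two-way repeated-measures ANOVA with
   Sidak post-hoc comparisons, for two-group (strain) contrasts.

Because raw recordings of the motivating study are not deposited, the
package ships a ground-truthed synthetic generator with two strain presets
(an "S1-like" poorly rhythmic, fragmented sleeper and a "BL6-like" control)
so that every stage can be exercised and validated end to end.

# The synthetic generator

## Bout process

Hypnograms are simulated as a semi-Markov chain over the three states with
geometric dwell times at epoch resolution: in state $i$ during phase $p$
the chain leaves after each 4 s epoch with probability
$4 / \bar d_{i,p}$, where $\bar d_{i,p}$ is the profile's mean bout
duration in seconds. Direct WAKE→REMS transitions are excluded (rodent
sleep shows essentially five transition types), so the embedded bout chain
has two free routing probabilities per phase; these are solved from the
requested stationary state probabilities via the bout rates
$\nu_i \propto \pi_i / \bar d_i$:

$$P(\mathrm{N}\to\mathrm{W}) = 1 - \nu_R/\nu_N,\qquad
  P(\mathrm{R}\to\mathrm{N}) = (\nu_N - \nu_W)/\nu_R.$$

Not every $(\pi, \bar d)$ combination is reachable under the missing
WAKE→REMS edge; infeasible profiles error at construction rather than
silently drifting from the requested stationary distribution. At the
light→dark boundary the running bout is truncated and the dwell re-drawn
under the new phase's parameters; by memorylessness this is equivalent to
per-epoch simulation with phase-dependent parameters.

The two presets take their stationary probabilities and mean bout durations
directly from the published group medians of the motivating strain
comparison (per phase and state), which is why the simulated cohorts
reproduce the direction of every reported architecture contrast without
further tuning.

## Sleep-onset latency

The first-5-bout latency (mean elapsed time from lights-on to the onsets of
the first five NREMS or REMS bouts of at least 12 s) has a floor of roughly
13 min that follows from the preset bout durations alone: even with
immediate sleep onset, the 2nd–5th qualifying bouts are spread out by
WAKE/REMS cycling. The published absolute latency medians (21.2 vs 9.4 min)
sit below that floor for the control strain and are therefore not
reproducible from the phase-level bout statistics — matching absolute
medians is an explicit non-goal. What the presets do reproduce is the
published latency *difference*: the lights-on WAKE bout is modeled as a
consolidated sleep-onset process with a narrow gamma dwell (shape 10,
CV ≈ 0.32) whose mean is the profile's latency offset (13 min S1-like,
2 min BL6-like), giving cohort medians of ≈26 vs ≈14 min. A memoryless
(exponential) first bout would make per-animal latencies far more variable
than the published rank separation (U = 8 at n = 8 vs 7) allows.

## Signals

The EEG is a state-weighted sum of unit-RMS band-limited noise components
(delta 1–4.5 Hz, theta 6–9 Hz, sigma 10–15 Hz, broadband white) plus a
narrowband ~8 Hz component during REMS, so REMS spectra peak in the theta
band and NREMS spectra are delta-dominant. The S1-like preset lowers the
NREMS delta weight, raises theta/sigma, and attenuates the REMS 8 Hz peak —
the published spectral directions. Amplitude units are arbitrary
throughout; no µV calibration is attempted. The EMG is white noise with
state-dependent amplitude (WAKE 1.0, NREMS 0.25, REMS 0.12), ranked
WAKE > NREMS ≥ REMS.

Spindles are injected into NREMS as Hann-windowed 11 Hz sinusoids (the peak
spindle frequency in mice) at the profile's rate per NREMS minute, with
peak sinusoid RMS equal to a multiple (default 5×) of the NREMS sigma-band
background RMS. The recorded ground-truth interval is the support where the
burst's instantaneous RMS exceeds that background RMS — an oscillation
below background is not annotatable, so the near-silent Hann taper tails
are not part of the event — and the drawn duration (mean 1.97 s S1-like,
1.77 s BL6-like, truncated to 0.5–10 s) refers to that interval.

## What the generator does not emulate

Electrode drift, movement artifacts, the 1 h daily recording gap,
scorer disagreement, within-state spectral nonstationarity (e.g. slow-wave
homeostasis across the light period) and µV scales. Tests passing on
synthetic cohorts therefore validate the *analysis chain* — that each
metric measures what it claims on data with known structure — not the
biology of any particular strain.

# Scoring

The published analysis used semi-automated scoring software whose internals
are not described in the source text; the package substitutes a transparent
two-feature threshold classifier: an epoch is WAKE when its EMG RMS exceeds
a muscle-tone threshold, and sleep epochs are split into REMS vs NREMS by
the EEG theta/delta power ratio (threshold 1.0). The muscle-tone threshold
defaults to the midpoint (in log space) of a 2-means split of the epoch EMG
RMS values. A fixed-quantile cut was considered and rejected: any fixed
quantile misclassifies whenever the true WAKE fraction crosses it (dark
recordings of a good sleeper easily exceed 80% WAKE), whereas the bimodal
EMG distribution makes the 2-means split stable across state mixes. Both a
numeric and a quantile override remain available. Downstream analyses
depend only on the hypnogram, not on the scorer's internals.

The rescoring rule absorbs every run shorter than 3 epochs (12 s) into its
preceding run (a leading short run merges forward), repeated to fixpoint —
deterministic, idempotent, and touching only epochs that belonged to
sub-minimum runs. The source text is ambiguous between "longer than 3
epochs" (≥ 4) and "at least 12 s" (≥ 3); the floor defaults to 3 and is a
parameter.

# Spectral analysis

A 0.25 Hz grid on 4 s epochs at 125 Hz forces a single 500-sample segment
per epoch, so the Welch estimate reduces to one Hamming-windowed
periodogram per epoch (one-sided, density-scaled; Parseval-consistent to
within numerical precision). Before the PSD, each epoch is demeaned exactly
and high-pass filtered at 1 Hz (zero-phase, 2nd-order Butterworth): on 4 s
windows, IIR edge transients make DC rejection by the filter alone
unreliable, and the mean *is* the 0 Hz component. Normalization divides
each bin by the epoch's total power over the full 0–62.5 Hz grid (the
source text does not state the denominator's range; the full grid is the
parameter-free choice), so relative spectra sum to exactly 1 and are
invariant to amplitude rescaling. Band powers sum bins inclusively over
delta (1.0–5.0 Hz), theta (6.0–9.0 Hz), alpha (10.0–15.0 Hz) and eta
(16.0–22.75 Hz); the inter-band gaps are deliberate and left unassigned.

Group spectra aggregate per-animal medians rather than pooled epochs so
each animal contributes equally (the pooling order is not stated in the
source text). The eta-band QC rule flags animals whose median NREMS eta
relative power falls below 0.5× the cohort median; flags affect only
spectral aggregation — flagged animals remain in architecture and spindle
analyses.

# Spindle detection

The sigma filter is the minimum-order zero-phase Butterworth band-pass
(10–15 Hz) whose forward–backward response attenuates both stopband edges
(3 and 22 Hz) by at least 24 dB — with the default specification this is a
4th-order band-pass, consistent with the quoted 24 dB/octave roll-off. The
envelope is a centered 750 ms moving RMS (window truncated at the recording
edges), cubed to sharpen burst-to-background separation. Detection baseline
is the mean cubed RMS over NREMS samples (configurable to the whole
recording); candidate events are maximal runs above 1.0× baseline
containing at least one sample above 2.5× baseline, merged when separated
by less than 0.1 s, kept when 0.5–10 s long and starting within an NREMS
epoch (start-only membership; full containment is switchable). Because both
thresholds are baseline-relative, detection is exactly invariant to
rescaling the EEG by a positive constant.

One behavior worth knowing: with very sparse spindles the baseline sits at
the background level, so event boundaries (lower-threshold crossings)
extend into adjacent background fluctuations and isolated background
excursions can cross the upper threshold. At realistic densities
(~5–6 events per NREMS minute) the bursts themselves inflate the baseline
and both effects vanish — recovery of injected events at 5× background
reaches recall = precision ≈ 0.97 at 0.25 s onset tolerance.

# Statistics

* **Exact Mann–Whitney U**: U is the smaller of the two group statistics
  with mid-rank tie handling. The tie-free exact two-tailed p is
  2·P(U′ ≤ U) under the partition-count null (capped at 1), computed by the
  classic counting recursion; tied samples fall back to full enumeration of
  group labelings (feasible through n ≈ 20) or a seeded Monte-Carlo
  permutation; larger samples use the normal approximation with tie
  correction. No continuity correction is applied in the exact path.
* **AUC effect size**: P(group-B value > group-A value), ties half-counted.
  In pipeline reports group A is S1-like and group B is BL6-like, so
  AUC < 0.5 means the S1-like median is larger. The published AUC values are
  recoverable from the printed U statistics as U/(n_a·n_b) or its
  complement, which the acceptance checks exploit.
* **Bootstrap CI**: percentile interval over 10,000 resamples, the two
  groups resampled independently with replacement, seed mandatory. Whether
  the original analysis resampled jointly is not stated; independent
  per-group resampling is the standard choice for a two-sample effect size.
* **RM-ANOVA**: mixed design (between = strain, within = time = 2 h bins)
  via the standard sums-of-squares decomposition (`aov` with a subject
  error stratum). No sphericity correction is applied (none is mentioned in
  the source text). Post-hoc per-time-point comparisons use Welch t tests
  with Sidak adjustment 1 − (1 − p)^m, m = number of time points (12 for a
  23 h session); the original post-hoc machinery is proprietary and
  unstated, so the post-hoc is documented rather than matched.
* **QQ data**: observed order statistics against normal quantiles at
  plotting positions (i − 0.5)/n, for normality assessment before choosing
  rank-based tests.

# Numerical choices and degenerate inputs

* Zero-phase (forward–backward) filtering everywhere, to avoid
  state-dependent lag in epoch features; hardware emulation uses 4th-order
  Butterworth high-/low-pass cascades, decimation an 8th-order low-pass at
  0.8× the target Nyquist.
* A bout straddling the light/dark boundary belongs to the phase of its
  first epoch; a transition belongs to the phase where its second bout
  starts.
* Latency with fewer than k qualifying bouts returns an explicit
  "insufficient bouts" result, never a number. Dark-phase REMS latency uses
  k = 1 (first bout) by default, k being exposed.
* All-zero epochs cannot be normalized and are flagged and excluded from
  spectral aggregation. Empty states in a phase yield empty, flagged
  summaries.
* Constant input matrices give F = 0, p = 1 in the RM-ANOVA (the 0/0 limit
  is resolved to "no effect"); zero within-noise with a real group offset
  gives F = ∞, p = 0.
* Every stochastic routine takes an explicit seed and restores the caller's
  RNG state.

# Problem sizes used in validation

The validation suites run at sizes chosen to make Monte-Carlo noise small
relative to the margins being tested: 100 synthetic cohorts of 8 + 7
animals (23 h hypnograms; 15 min dark segments for the spindle contrast)
for direction recovery; 10,000 random epochs for the spectral invariants;
1,000 random hypnograms for the bout-consolidation properties; a 30 min
NREMS recording (~150 injected events) for detector recall/precision; 100
random balanced designs against the ANOVA sums-of-squares oracle; and
exhaustive enumeration of all group labelings up to total n = 12 for the
exact Mann–Whitney null.

# Known limitations

* The scorer is a stand-in; agreement with the generator's ground truth
  (≈99% of epochs) says nothing about agreement with a human scorer on
  real data.
* Geometric dwells underestimate the heavy tails of real bout-duration
  distributions; the presets match means, not shapes.
* The spindle detector inherits the two-threshold method's density
  dependence described above; spindle frequency characterization, slow
  oscillation coupling and topography are out of scope.
* EDF support covers the 16-bit continuous two-channel subset the pipeline
  needs, not the full standard.
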