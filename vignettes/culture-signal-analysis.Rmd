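---
title: "Methods: feature extraction for cultured-neuron recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: feature extraction for cultured-neuron recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`neurophys` implements the signal-analysis conventions used to phenotype
cultured human neurons (for example, iPSC-derived dopaminergic or
hippocampal cultures from patients and controls): whole-cell patch-clamp
feature extraction, spontaneous-EPSC statistics, calcium-imaging ROI
classification with synchrony and spectral summaries, and a gene-set
enrichment network over differential-expression results. Because patient
recordings are rarely redistributable, the package pairs every analysis
stage with a synthetic-data generator whose ground truth makes the stage
testable end to end.

```{r setup}
library(neurophys)
cfg <- analysis_config()
```

## Evoked excitability

Current-clamp families follow a 38-step, 3 pA, 400 ms depolarization
ladder starting 12 pA below the holding current that keeps the cell at
-60 mV. The evoked-excitability score is the total number of action
potentials over the first `n_steps_counted` steps — 32 for dopaminergic
and 30 for hippocampal neurons — and cells that need more than 50 pA of
holding current to sit at -60 mV are excluded rather than scored, with
the exclusion reason logged.

Spike apexes are strict local maxima above -10 mV separated by at least
3 ms (larger apex wins, ties to the earlier sample). The counting
criterion is not standardized across laboratories; both the level and the
refractory interval are configurable in `analysis_config()`.

```{r evoked}
sim <- gen_current_clamp(ephys_sim_params(rheobase_step = 5), seed = 1)
count_evoked_aps(sim$sweeps, cfg)$total
sum(sim$truth$spike_counts[1:32])
```

## Rheobase-spike shape

Shape features come from the first spike evoked with the least injected
current. The threshold is the potential at the first maximum of the
second derivative of voltage versus time on the rising phase; raw second
differences at 20 kHz are noise-dominated, so the trace is first smoothed
with a 5-sample moving mean and the first plateau-aware strict local
maximum of the central second difference within the 10 ms preceding the
apex is used. The search is additionally anchored to the steep rising
phase (it starts just before the last pre-apex point whose slope is below
10% of the maximal rise), because on noisy traces curvature fluctuations
in the shallow subthreshold approach would otherwise pre-empt the true
onset; on noiseless templates this changes nothing, and on sweeps with
0.3 mV of noise it keeps the threshold within a few hundred microvolts
of truth. Amplitude is apex minus threshold; width is the full width
at half maximum with sub-sample linear interpolation of the two
half-amplitude crossings; the fast afterhyperpolarization (fAHP) is the
threshold minus the potential exactly 5 ms after the falling phase
returns to the threshold (reaching the threshold exactly counts as the
return, so a trace that settles at threshold has fAHP 0).

```{r shape}
spike_shape(sim$sweeps, cfg)
```

## Sodium and potassium currents

Voltage-clamp families step from -90 to +80 mV (10 mV increments, 400 ms,
-60 mV holding). Per step, and normalized by the cell capacitance
(pA/pF): the sodium peak is the most negative current within 10 ms of
step onset (inward currents are negative; the value is clipped at zero
for purely outward steps); the fast potassium current is the maximal
outward current within 10 ms of onset ("right after the depolarization
step"); the slow potassium current is the current at the end of the
400 ms phase, averaged over the final 5 ms for noise robustness rather
than read from a single sample. Group statistics restrict test potentials
to -20..0 mV for sodium and 40..80 mV for potassium and compare groups by
one-way ANOVA on the per-cell window mean.

## Spontaneous EPSCs

Gap-free recordings at -60 mV are baseline-corrected with a rolling
median spanning 1 s (computed on a 10x decimated copy — millisecond
events do not move a 1 s median). Noise is estimated robustly as
1.4826 x MAD of the residual. Candidate events are excursions of a
0.5 ms-smoothed copy below `threshold_sd` (3.5) times that noise scale;
one event is scored per excursion, the detector re-arms only once the
trace recovers above half the threshold (so a slow decay tail cannot
re-trigger), and troughs closer than 5 ms are merged in favour of the
deeper one. The published analysis did not describe its detector; these
choices are standard for template-free mini detection and are all
configurable. The event rate divides the count by the recording length
and silent cells are retained with rate 0; the mean amplitude is defined
over detected events only. Pooled per-group amplitudes are summarized as
empirical cumulative distributions, where a uniform amplitude increase in
one group shifts its curve rightward by exactly that amount.

## Calcium imaging

Recordings are ROI-mean fluorescence series, typically 1800 frames at
~10 Hz. Classification follows a two-stage rule. First, the lag-6
difference series (about 0.6 s) is normalized by the trace's
peak-to-trough amplitude over the whole recording; an ROI whose maximum
normalized difference exceeds 0.05 is an active neuron. "Normalized by
the maximum amplitude" is read as peak-to-trough (max - min) because the
alternative (dividing by the raw maximum) is offset-sensitive; a
configuration flag preserves the alternative reading of baseline choice
elsewhere. Second, among the remaining ROIs a fluorescence ratio
delta-f/f0 = (max - min) / min is computed, the minimum of the trace
serving as baseline; ROIs below 10% of the largest such ratio — the most
active astrocyte — are inactive, the rest are active astrocytes. The
reference for "most active astrocyte" is taken over all non-neuron ROIs,
which resolves the apparent circularity of needing astrocytes before
astrocytes are identified. Constant traces are inactive by convention,
and non-positive baselines raise an error advising offset correction.

Neuronal events are local maxima with topographic prominence of at least
20% of the trace amplitude and 5-frame separation. Synchrony follows the
windowed-correlation convention: 5-frame moving-average smoothing, Pearson
correlations over sliding 35-frame windows (stride one frame), per-ROI
summation over all partners and windows, ranking by that sum, and the
mean over the top 10 ROIs; both the raw sum and a normalized version
(dividing by partners x windows, hence in [-1, 1] and exactly 1 for
identical traces) are reported. `top_k` is configurable because published
figures sometimes rank the top 5 instead. The spectral summary sorts
neurons by event count, estimates each PSD by averaged periodogram
(256-frame segments, 50% overlap, per-segment linear detrend, Hann
taper — no installed R package provides a Welch estimator, so it is
implemented here), and reports the mean ratio of the trapezoidal area
under the full spectrum to the area above 0.1 Hz. The ratio is >= 1 by
construction; note that as defined it *decreases* for faster-oscillating
cells, a direction the user should keep in mind when interpreting group
differences.

```{r calcium}
pop <- gen_calcium_population(seed = 2)
table(classify_rois(pop$fluor, cfg)$label, pop$truth$labels)
```

## Enrichment network

Differentially expressed genes are those with FDR < 0.05 and
|log2FC| > 1.1, both strict as printed. Gene-set over-representation uses
the one-sided hypergeometric test with Benjamini-Hochberg adjustment — a
deterministic, self-contained stand-in for the web-service enrichment the
original analysis used; the universe is a required user input because the
background gene list a service uses is rarely stated. Nodes are sets with
adjusted FDR < 0.05 sized by DEG hits; edges connect sets whose overlap
coefficient, `(|A&B|/|A| + |A&B|/|B|) / 2`, is at least 0.3 (inclusive),
weighted by the shared-gene count. Gene identifiers are case-sensitive
strings with no aliasing.

## Statistical conventions

Group values are reported as mean +/- SE (sample SD over sqrt(n)).
Comparisons use the two-tailed two-sample t test (with optional Welch
correction), the Mann-Whitney U test (exact for min(n) <= 8 without ties,
normal approximation with tie and continuity correction otherwise — the
switch is configurable), and one-way ANOVA; all delegate to R's standard
implementations. For report text, halves round away from zero; note that
a cohort mean of 61.5 printed as "61" is a truncation, so reports emit
both raw and rounded values rather than hiding the discrepancy.
Degenerate inputs follow explicit conventions: both groups constant and
equal gives statistic 0 with p = 1.

## What the generators emulate — and what they do not

The generators are designed for exactness, not biophysics:

* **Spikes** are parametric templates (slow 12 ms ramp to threshold,
  linear rise and fall, descent to the fAHP trough 5 ms after the
  threshold return, recovery), with knots snapped to the 20 kHz sample
  grid so every recovered feature is exact to within a sample. They are
  not conductance-based; real spikes have curved rising phases, so
  threshold estimates on real data carry a few hundred microvolts of
  smoothing bias that the template suite cannot reveal.
* **Voltage-clamp currents** are separable voltage-dependent densities
  times fixed time courses whose peaks are exactly the mapped values
  (alpha-function transients, a ramp-to-plateau slow component). No
  activation/inactivation kinetics.
* **EPSCs** are homogeneous Poisson trains of negative biexponentials
  (1 ms rise, 5 ms decay, 30 +/- 5 pA, 2 Hz, 60 s at 20 kHz, 2 pA white
  noise). Real recordings have correlated noise, seal drift and
  multiquantal events. At 2 Hz roughly 1-2% of event pairs overlap within
  the detector's merge window, so recovered rates sit ~3-5% below truth.
* **Calcium populations** (1800 frames at 10 Hz) contain fast-transient
  neurons (2-frame rise, 8-frame exponential decay, 0.2 Hz Poisson
  events, amplitude 40 a.u. on a 100 a.u. baseline), astrocytes with
  raised-cosine slow waves (60 s period, delta-f/f0 of 1), and inactive
  ROIs. Synchrony is a common event stream adopted per event with
  probability `shared_drive_fraction`, which makes the synchrony score
  provably monotone in that knob. Every ROI carries a slow sinusoidal
  baseline wander (amplitude 4 a.u., ~120 s period) plus small white
  noise (0.04 a.u.). The wander, not the white noise, dominates an
  inactive ROI's amplitude: ROI-averaged fluorescence over hundreds of
  pixels has little frame-to-frame noise, while focus and illumination
  drift are slow. This matters because the lag-6 rule normalizes by the
  trace's own amplitude, so a trace dominated by fast noise would always
  look "steep"; the astrocyte period (60 s) and wander scale are chosen
  so that the slow-wave lag-6 statistic stays below the 0.05 threshold by
  construction, giving the classifier a ground truth that is consistent
  with its own definition. Passing the label-recovery suite therefore
  shows the rules are implemented correctly, not that they separate cell
  types under arbitrary noise regimes; photobleaching, motion and
  neuropil contamination are out of scope.
* **Gene sets** are equal-size sets over a synthetic universe whose
  pairwise overlap coefficients are realized exactly by dedicated shared
  blocks (higher-order overlaps zero); each requested coefficient must be
  a multiple of 1/set_size and pairwise shared genes must fit in a set,
  otherwise the request is rejected as infeasible.

One generator contract needed reconciling: the f-I rule gives step `s >=
rheobase` `round(fi_slope * (s - rheobase + 1))` spikes, which would be
zero everywhere for `fi_slope = 0`; since the rheobase step must by
definition carry the first spike, the count is floored at one spike per
suprathreshold step, which also yields the closed-form total
`32 - rheobase_step` used in the tests.

## Numerical choices and problem sizes

Tolerances in the template-recovery suite are one sample interval
(0.05 ms at 20 kHz) for time features and 0.05 mV for voltage features —
the worst-case drift of the plateau-centre threshold locator under
floating-point jitter. Window ties in spike detection and event merging
resolve toward the earlier, larger event. The test and acceptance suites
run at deliberately modest sizes chosen to estimate each quantity well
inside its tolerance: 25-50 simulated cells for feature recovery, 20
seeds for the EPSC, classifier, synchrony and PSD calibrations, 500
simulations for the type-I-error checks, and the two-cohort age vectors
(n = 3 and n = 2) for the summary statistics.

## Known limitations

Patient recordings are not redistributable, so the package validates
against synthetic ground truth; group-difference effect sizes from the
original study are not reproduced here. ABF and HDF5 ingestion are not
implemented (the csv bundle is the interchange format). The enrichment
stage tests over-representation only — no ranked (GSEA-style) statistics
— and performs no identifier mapping.
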