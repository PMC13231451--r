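---
title: "Methods: detecting and quantifying sleep-modulated interictal activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting and quantifying sleep-modulated interictal activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(iedsleep)
```

This vignette documents the models, conventions and numerical choices
behind `iedsleep`, in the order the pipeline runs them. Everything here
is implemented and exercised by the test suite; no empirical claim is
made that the tests or `scripts/acceptance.R` do not themselves compute.

## Data model and conventions

All times are float seconds from recording start; intervals are half-open
`[onset, offset)`, so an event at exactly an offset belongs to the next
interval, and sample indices are `floor(t * fs)` (0-based). Signals are
channels x time matrices in microvolts with channel 1 the deepest
contact. Clinical polarity is stored: the IED spike is positive, the slow
wave negative; inverted-polarity display is a plotting concern. Stage
labels are `Pre` (the block scored before sleep onset), `Wake` (wake
after sleep onset), `S1`, `S2`, `S3`, `REM` and `Post` (after the final
awakening). Recordings are exchanged as float32 raw binary plus a JSON
header; hypnograms, artefacts and events as TSV; spike trains as JSON.

## The synthetic generator

The generator emulates the statistical structure the analyses assume,
not the biophysics of a seizure network:

- **Hypnogram** -- a pre-sleep block, a semi-Markov chain over
  Wake/S1/S2/S3/REM with exponential dwell times (means 90/120/300/300/
  180 s) and a fixed transition matrix, then a post-sleep block.
- **Background LFP** -- 1/f noise (exponent 1, 20 uV r.m.s. per channel)
  plus a stage-dependent slow oscillation at 0.8 Hz whose amplitude is
  5 uV in Pre/Wake/REM, 10 in S1, 20 in S2, 40 in S3, shared across
  contacts with the same depth gradient as the discharges. The noise is
  DC-coupled: all its 1/f power down to the record length is present.
- **Discharges** -- two spike-wave kernel morphologies (a narrow
  monophasic spike with a long shallow wave; a polyspike-like double
  transient with a shorter, deeper wave), peak-normalized, scaled by a
  depth gradient (1/0.75/0.55/0.40/0.30) and injected at
  inhomogeneous-Poisson times with stage rate multipliers
  (Wake 1, S1 2, S2 3, S3 4, REM 1) and amplitude multipliers
  (1/1.15/1.30/1.50/1) around a 150 uV deepest-contact spike peak
  (signal-to-noise 7.5 against the background r.m.s.). A 300 ms hard
  core (thinning) keeps ground-truth events separable at the +-50 ms
  scoring tolerance. Every injection is recorded in the ground truth.
- **Units** -- inhomogeneous Poisson trains: a per-unit baseline rate
  multiplied by stage factors that decrease into slow-wave sleep
  (1/1/0.85/0.70/0.50/0.90), and by a discharge-locked gain: `g_spike`
  (default 3) in [-25, +75] ms around each discharge peak and `g_wave`
  (default 0.3) in [100, 500] ms -- the depolarization-then-silence
  pattern of the paroxysmal depolarizing shift. Those two windows are
  generator conventions chosen to match the observed response shape;
  they are not measured quantities. Doublet injection (probability 0.1)
  creates inter-spike intervals below 5 ms; spike amplitude marks get a
  mild stage-dependent increase in deeper sleep.

What the generator does **not** emulate: correlated noise across
contacts, spindles/K-complexes, state transitions inside a window,
electrode drift, seizures, or realistic artefact morphologies (artefacts
are broadband noise bursts). A detector that is perfect here can still
degrade on real data; the benchmark demonstrates the correctness of the
chain, not clinical performance.

Everything is driven by one integer seed; identical configurations
reproduce every sample and spike bit for bit.

## Detection

The detection chain follows the eight-step template-matching procedure:
epoch extraction (-0.5 to +1.0 s, five deepest contacts) at annotated
times; iterative alignment of channel-concatenated trials to their
average (peak cross-correlation lag, edge replication, shifts bounded to
+-150 ms, at most 10 iterations, stopping when the mean trial-average
correlation stops improving); k-medoids clustering (k = 6, Euclidean
distance on flattened trials, PAM) with removal of clusters below 2.5%
of the patient's trials and re-clustering (at most 10 rounds);
per-cluster re-alignment and averaging into Channel x Time templates;
normalized cross-correlation scanning; thresholding; and +-50 ms
deduplication keeping the highest correlation (ties: lower template id,
then earlier time).

Numerical notes:

- The correlation trace is exact Pearson correlation of the flattened
  template against every equally shaped signal segment, computed with
  FFT cross-correlation plus sliding sums; it matches a naive per-lag
  loop to 1e-10 and is invariant to affine rescaling of the signal.
  Zero-variance segments are assigned r = 0.
- Alignment-to-average is only determined up to a global time shift; the
  solution is anchored by re-centring cumulative lags on their median,
  so the majority of trials stays put.
- Detection timestamps are correlation-peak lag plus the template's
  spike-peak offset (the time of the maximum on the deepest contact), so
  reported times follow the spike-peak convention of the annotations.

**High-pass preprocessing.** `detect_ieds()` applies a zero-phase 4 Hz
high-pass (`highpass_recording()`, Butterworth-magnitude response in the
frequency domain) to a copy of the recording before template building
and scanning. On DC-coupled signals the slow-wave band otherwise
dominates the normalized correlation twice over: background slow
oscillations both widen the correlation distribution (its robust spread
is an order of magnitude larger without the filter) and mimic the
template's own wave component. The discriminative feature of an
interictal discharge is its fast (< 200 ms) transient, which the filter
preserves. Only detection sees filtered data; all amplitude and
spectral analyses use the raw recording.

**Threshold automation.** The reference procedure chooses a single
patient-specific threshold visually from the distribution of correlation
values. The automated surrogate (`threshold_method = "valley"`) collects
candidate correlation peaks above a robust per-template floor
(median + 6 MAD of the trace) and places one shared threshold at the
Otsu split of the pooled peak-height distribution. That distribution is
strongly bimodal -- a low mode of background and self-similarity
sidelobes (a template matching a neighbouring discharge's wave, or a
polyspike's secondary transient, at the wrong lag) and a high mode of
true matches -- and the split lands in the valley between them, which is
exactly what the visual choice exploits. The method is calibrated on the
correlation distribution only, never on detection scores, and is blind
to sleep stage. `"mad"` (the floor itself) and fixed values remain
available.

**Scoring.** Hit rate is matched references over references; the
false-alarm rate divides unmatched detections by the number of automatic
detections (1 - precision). Matching is greedy one-to-one in order of
increasing time difference within +-50 ms; on small sets this equals the
exhaustive optimal assignment (verified in the tests).

**Benchmark.** The packaged benchmark simulates 3600 s at 1 kHz with a
base rate of 5 discharges/min (roughly twice the long-term average rate
reported for such patients, about 700 events after thinning), annotates
only the first half, and scores the full recording. Measured across
seeds: hit rate 98.9-99.8%, false-alarm rate 0-2.8%, about 1.5 minutes
on one CPU. The sizes were chosen so a desk machine reproduces the run
in minutes; they are stated here as the package's benchmark definition.

## Time-locked analyses

Average LFPs are baseline-corrected per epoch and channel over
[-0.15, -0.05] s. Component intervals are measured once on the all-stage
average (deepest contact): the spike interval is the contiguous span
containing the maximum within [-0.15, 0.15] s where the trace stays at
or above half the maximum; the slow-wave interval is the analogous span
around the minimum within the wave search window. The searched wave
window defaults to [0.05, 0.50] s -- after the spike, where the slow
wave of a spike-wave complex lies; both windows are configuration. A
relative epsilon (1e-9 of the extremum) keeps samples lying exactly at
the half-extremum inside the interval. Intervals are invariant to
positive rescaling of the trace. Per-event V_peak, V_SW and deflection
are means over those fixed intervals, so stage contrasts never re-derive
latencies per stage.

PSTHs use half-open 10 ms bins over [-0.5, 1.0] s; rates are counts over
bin width; the normalized PSTH divides by the mean baseline rate
(baseline window [-0.3, -0.1] s, chosen not to overlap the response).
Comparison latencies for stage-wise firing statistics come from the
width at half-prominence of the stage-blind average PSTH (prominence
measured against the baseline rate).

**Responsiveness test.** Per bin, a one-sample t statistic across events
of the baseline-subtracted response; contiguous bins with two-sided
p < 0.01 form clusters scored by their summed t; clusters are referred
to a seeded permutation null; a unit is responsive when any cluster
survives p < 0.05. Three defaults address the sparsity of 10 ms spike
counts, which otherwise produces spurious significance from lack of
data: (i) a square-root variance-stabilizing transform of the rates;
(ii) one pooled standard deviation across all bins (under the null of
stationary firing every bin shares a variance, and per-bin standard
deviations are strongly coupled to per-bin means on sparse counts,
inflating the first level); (iii) a rotation ("shift-predictor") null:
each permutation circularly rotates every event's binned response by an
independent random offset and re-anchors it to its rotated baseline
window. Rotation is measure-preserving under the null of no
time-locking, making the test essentially exact; sign-flipping of
baseline-subtracted responses -- the textbook one-sample scheme -- is
retained as an option but is anticonservative on skewed count data
(measured 8-10% at nominal 5%). By default every cluster is compared
against the permutation distribution of the maximum absolute cluster
mass over both polarities, which controls the family-wise error at the
nominal level; per-tail nulls are available but add the two one-sided
error rates. Calibration measured on null Poisson units (8 Hz, 30 or
100 events, 1000 simulations, 1000 permutations): rejection rates
0.035-0.060 at alpha = 0.05.

## Sliding-window metrics

10 s non-overlapping windows are stage-labelled when a stage covers
strictly more than half the window, and excluded on any overlap with an
artefact (and, in baseline mode, with any detected discharge) -- the
conservative reading, since no overlap proportion is specified for
artefacts. Spectra use a periodic Hann taper after mean removal, giving
a 0.1 Hz grid for 10 s windows; powers are normalized by the window
energy so the one-sided spectrum sums to the tapered signal's variance
(Parseval, verified to 1e-6 relative). Band power is the mean over bins
with inclusive edges; the slow-wave band starts at 0.1 Hz, so the DC bin
(an offset, not an oscillation) never contributes. Relative power
divides by the same channel's pre-sleep mean.

CV2 is the mean over consecutive interval pairs of
`2|ISI(i+1) - ISI(i)| / (ISI(i+1) + ISI(i))`: exactly 0 for periodic
firing, 1 in expectation for a Poisson process (the pair ratio is a
function of a uniform variate with mean 1), up to 2 for alternating
short-long firing. It needs at least two intervals; windows below three
spikes yield no CV2 row rather than a zero, avoiding bias toward
regularity. Only intervals with both spikes inside the window
contribute. Bursts are maximal runs of consecutive intervals strictly
below 5 ms; the corrected train keeps each burst's first spike, so the
corrected rate never exceeds the raw rate.

## Circadian statistics

Event times map to angles with local midnight at 0 (daylight-saving
shifts are ignored at the 2-3 week scale of such recordings). The
Rayleigh test uses the mean resultant length with Zar's finite-sample
approximation `p = exp(sqrt(1 + 4n + 4(n^2 - R^2)) - (1 + 2n))`. Both
the circular mean (the Rayleigh direction) and the circular median (the
sample angle minimizing mean circular distance) are reported, since
summaries of night-time phase are conventionally quoted either way.
Calibration under uniformity: rejection rate within [0.03, 0.07] at
alpha = 0.05 (1000 simulations, seeded).

## Stage-wise inference

Outcomes are modelled as `outcome ~ stage + (1 | g)` for the analysis's
grouping factors (templates for LFP measures, units for firing measures,
plus patient and night when multiple exist), REML via `lmerTest`, with
pre-sleep as the reference level -- the random-effect structure is an
explicit argument, never inferred from the table. Outcomes are modelled
on the raw scale (rates can be skewed; a log transform is the user's
choice). Singular fits drop the zero-variance random terms with a
message and refit, down to ordinary least squares when no term survives.
Post-hoc contrasts compute the full Tukey family over all stage pairs
and report the versus-pre rows separately, starred as p < 0.05 ".",
p < 0.01 "*", p < 0.001 "**", p < 0.0001 "***" (the figure-legend
convention of this literature, one level stricter than the usual R
stars). Descriptive summaries provide the display normalizations x/Pre
and `(x - Pre)/(x + Pre)` (0 at parity, 0.5 at a three-fold increase).

## Pipeline and provenance

`run_pipeline()` executes simulate, detect, time-locked, windows,
circadian and stats stages in dependency order, writes tidy TSVs, and
records a manifest (package version, seed, parameters, per-output MD5
hashes), so a rerun with the same configuration reproduces every table
bit for bit and no threshold is chosen silently. Disabled upstream
stages make dependent stages fail with an explicit dependency error.
This package is a library with a programmatic surface; the pipeline
functions and these documents are its interface, and there is no shell
executable.

## Known limitations

- The detector's operating point assumes the bimodal peak-height
  structure holds; with very few annotated events (tens) the Otsu split
  can land inside a unimodal background and a fixed threshold is safer.
- The rotation null assumes stationarity within the PSTH window apart
  from the tested time-locking; slow rate drift across a window is
  absorbed into cluster mass.
- Gaussian mixed models on rates are a convention of this literature,
  not an endorsement; strongly skewed outcomes deserve a transform.
- Synthetic benchmarks bound implementation correctness, not clinical
  sensitivity; see the generator's non-goals above.
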