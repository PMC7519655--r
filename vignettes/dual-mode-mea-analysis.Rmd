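---
title: "Dual-mode HD-MEA analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-mode HD-MEA analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hdmea)
```

# The recording model

A dual-mode high-density microelectrode array samples the extracellular
field under a neuronal culture through two simultaneous readouts of one
electrode array:

* a **full-frame stream** covering every electrode at 11.6 kHz with
  10.4 µV rms noise in the action-potential band (0.3–5 kHz), and
* a **low-noise stream** of up to 246 freely selectable electrodes at
  24.4 kHz with 3.0 µV rms.

The full-frame stream sees the whole sample but only signals above roughly
5× its noise (~50 µV) are directly detectable; the low-noise stream
resolves signals down to ~15 µV but only on a subset of electrodes. The
package's central mechanism combines them: spikes are detected on the
low-noise stream, their times are mapped onto full-frame frames (the two
rates are not integer multiples, so alignment is by timestamps against a
shared clock origin; the mapping error is at most half a frame period,
43.1 µs), and spike-triggered averaging (STA) of the full-frame data then
reconstructs the unit's **electrical footprint** — its average
extracellular waveform on every electrode of the array — with noise
suppressed as $1/\sqrt{N}$ over $N$ triggers.

## Array geometry

The default lattice is hexagonal at 18.0 µm pitch: odd rows shifted by
half a pitch, rows spaced $18\sqrt{3}/2$ µm, so every interior electrode
has six nearest neighbours at exactly one pitch. The chip this models
advertises a 108 × 192 grid *and* a total of 19,584 electrodes, which are
arithmetically inconsistent (108 × 192 = 20,736). We follow the electrode
count, which the rest of the analysis depends on: the default is
102 × 192 = 19,584, which also reproduces the stated ~1.8 × 3.5 mm²
active area and ~3,050 electrodes/mm² density. Both grid dimensions are
ordinary parameters of `hex_array()`.

## The on-disk container

Recordings are stored as a directory: a JSON manifest, a full-precision
CSV geometry table, and int16 sample chunks (electrode-major, ≤ 1 s per
chunk, with an explicit µV-per-LSB scale), plus optional per-unit spike
trains and simulator ground truth as CSV. The round trip is bit-exact for
stored samples and exact for metadata. Everything is plain text or raw
integers, so containers are portable and diffable.

# The simulator

Every downstream stage is validated against `render_recording()` ground
truth, so the simulator's scope matters.

What it emulates:

* branching axonal arbors as curvature-limited random walks from the axon
  initial segment (AIS), one conduction velocity per branch (default
  `N(480, 90)` mm/s truncated at 100, matching mature cortical cultures);
* a biphasic extracellular template (1 ms; negative lobe then a 0.35×
  positive lobe) scaled per electrode by a lateral decay
  $1/(1 + d/\lambda)$ with $\lambda = 10$ µm, clipped below 1 µV — chosen
  so axonal signals of ~30 µV source amplitude appear at 5–10 µV one
  pitch away, the range observed on this array class. Somata default to
  −150 µV at the AIS;
* each electrode takes its **dominant** (largest-amplitude) source point
  of a neuron; arrival latency is path distance divided by branch
  velocity;
* Poisson spiking (default mean 2.4 Hz) modulated by network bursts
  (default ~0.15 bursts/s of 0.8 s, gain 8×) and pairwise monosynaptic
  couplings (each presynaptic spike copied to the postsynaptic train at a
  fixed millisecond latency with a transmission probability);
* per-mode white Gaussian noise scaled so its 0.3–5 kHz band rms equals
  the nominal mode noise (the convention in which the hardware figures
  are quoted): broadband sd 11.55 µV for the full-frame stream at
  11.6 kHz.

What it does **not** emulate — and what passing tests therefore do not
show about real data: biophysical (compartmental) waveform diversity,
bursting waveform attenuation and electrode drift, spike-sorting errors
and overlapping spikes, correlated or common-mode noise, electrode-tissue
filtering, and dendritic signals. Spike sorting itself is out of scope
throughout: the pipeline consumes unit spike trains (from the container
or from ground truth) and provides only a single-electrode threshold
detector for extracting low-noise-stream triggers.

Branch lengths default to 650–950 µm. Two practical choices are worth
stating. First, branches steer smoothly away from the array bounds
(curvature radius ≥ 60 µm) instead of reflecting: a hard reflection
creates hairpin folds that no cultured axon shows and that break any
chord-summed path-length estimate. Second, at 500 mm/s an action
potential travels 43 µm per 11.6 kHz frame, and the tracker (below)
discards the five frames nearest the initiation site; branches much
shorter than ~600 µm would leave too few frames to fit a velocity at the
fast end of the velocity range.

# Detection and spike-triggered averaging

Defaults follow standard practice for this system: 4th-order Butterworth
300–3000 Hz applied forward–backward (zero phase), detection at 7.5×
the noise standard deviation, electrode preselection above 80 µV,
12 ms STA template centred on the trigger (a ±2 ms window is available by
setting `template_ms = 4`), 1–300 Hz as the LFP preset. The noise
standard deviation is estimated robustly as `median(|x|)/0.6745` — the
plain standard deviation is inflated by the spikes themselves. Threshold
crossings within 1.5 ms are merged into one event timed at the minimum
sample.

Each footprint records, per electrode, the negative-peak amplitude, the
peak latency relative to the initiation site (the amplitude maximum; ties
break to the smaller electrode id, and its latency defines zero), and a
peak-time dispersion ("jitter"). One estimator choice deserves emphasis:
at axonal signal-to-noise (5–25 µV signal against 10.4 µV rms noise) the
argmin of a *single* trigger window is noise-dominated and nearly
uniformly distributed, so a literal per-event peak-time standard
deviation would reject every axonal electrode. Jitter is therefore
estimated from **sub-averages**: triggers are grouped (target group size
50, at least 6 groups), each group is averaged, and the group peak is
searched within ±2 ms of the electrode's footprint peak; the reported
jitter is the standard deviation of the group peak times. Noise-only
electrodes still produce near-uniform group peaks (sd ≈ 1.15 ms for a
±2 ms search window) and fail the 0.7 ms rule, while genuine axonal
electrodes concentrate tightly. Setting `jitter_group = 1` restores the
literal per-event definition. A sub-sample (parabolic) peak refinement is
also stored per electrode; the tracker never uses it, but the velocity
fit can (`fit_velocity(seg, interp = TRUE)`), which mainly helps at high
conduction velocities where the per-electrode latency step is a fraction
of a frame.

# Footprint cleaning and axonal tracing

Cleaning keeps electrodes with amplitude above 5.5× the per-electrode
noise sd **of the averaged footprint** (estimated by MAD over the outer
15% of the window, which is baseline) and jitter below 0.7 ms. Note the
scale: averaging N windows divides the raw noise by $\sqrt{N}$, so with
300 triggers the amplitude threshold is ~3.7 µV, which is what lets
5–10 µV axonal electrodes survive.

The tracker walks each axonal branch **backward in time**. Terminals are
delay-map local maxima within the 80 µm search radius, processed in
decreasing-delay order (ties by ascending id). From the terminal's peak
frame $N$, the walk selects among cleaned electrodes peaking in frame
$N-1$ within 80 µm of the current electrode, choosing the largest
amplitude (ties to the smaller id); if no electrode peaks there — weak
axonal signals produce gaps — the search widens to frame $N-r$ and radius
$r \times 80$ µm for $r = 2..5$. The walk stops when the next step would
land within 5 frames of the initiation frame (the initiation-site signal
is large and visible on many electrodes, so timings there are unreliable)
or when no candidate remains. The path is reversed into
initiation-to-terminal order; cumulative distance is the sum of
consecutive inter-electrode distances; velocity is the least-squares
slope of cumulative distance (µm) versus latency (ms), which is mm/s
directly. Segments with fewer than 5 electrodes are discarded — too few
points for a meaningful fit.

Two refinements address the fact that one axon is seen by a *corridor*
of electrodes several pitches wide, not a line:

* a terminal candidate is rejected when an already-assigned electrode
  with equal or later delay lies within the search radius (otherwise the
  corridor flanks of a traced branch immediately re-qualify as terminals
  and every branch is traced twice);
* when a segment is accepted, electrodes within 40–60 µm (default 60) of
  its path are marked assigned along with the path itself — they record
  the same branch (the decay law attenuates ~7× at 60 µm).

Shared proximal trunks are attributed to the first-traced branch; with
the stop region (≥ 170 µm at 400 mm/s) this rarely matters in practice,
but it is a documented bias of the total-extension statistic. Because the
stop rule discards the first five frames by design, any comparison of
recovered total extension against ground truth must exclude the stop
region from the reference (`velocity × stop_frames × frame period` per
branch); comparing against full branch length would report a ~25%
"error" that is really the algorithm's specification.

Per-neuron morphometrics are the segment count, longest segment, total
extension (sum of assigned segment lengths), mean velocity over valid
fits, maximum footprint amplitude, and firing rate.

Validated performance on the bundled simulator (the acceptance script
recomputes these): a noiseless straight 500 mm/s axon is traced exactly,
with velocity within 1% (frame quantization only); over 50 noisy arbors
with velocities uniform in 300–700 mm/s and 300 averaged spikes, the
median absolute velocity error is ~3–4% and the median total-extension
error ~5%. The error tail is wider (~15% of neurons exceed 10% velocity
error), dominated by fast axons — where the per-frame latency step spans
60 µm and terminal selection rides the quantization noise — and by
two-branch arbors whose branches cross.

# Network analysis

The **population rate** is the spike count of all units in 0.01 s bins,
converted to Hz and smoothed with a normalized Gaussian kernel of
σ = 0.3 s (truncated at 4σ, zero-padded). **Bursts** are contiguous
intervals above 1.35× the baseline rate; the baseline is the **median**
of the smoothed rate — robust to the bursts themselves — with the mean
available by flag. Duration is threshold-crossing to threshold-crossing,
one rate peak is reported per burst, and the interburst interval runs
from a burst's offset to the next burst's onset (onset-to-onset by flag).
A 0.3 s kernel necessarily broadens a rate window; crossing positions
coincide with the underlying activity edges only when the burst elevation
is ~0.86× the baseline (the tests construct exactly that case), and
detected durations for very strong bursts exceed the underlying activity
window — a property of the definition, not a bug.

**Connectivity** is inferred from pairwise cross-correlograms (CCGs) at
1 ms binning over ±50 ms, the lag-0 bin centred on zero. The null model
is the CCG convolved with a **partially hollow Gaussian** (σ = 10 ms,
60% of the centre-bin weight removed, kernel renormalized, edges
renormalized over available bins): the hollow centre prevents a sharp
monosynaptic peak from predicting itself, while the wide kernel tracks
slow co-modulation. Significance is the pointwise Poisson
$1-\alpha$ quantile at the predicted mean (α = 0.01). A connection is
called when a bin within ±5 ms, excluding lag 0, strictly exceeds the
band; the lag of the largest excess gives latency, its sign the
direction. A significant lag-0 bin alone is flagged ambiguous (likely
common input) and produces no edge. Pairs with fewer than 50 spikes in
either train are skipped and reported as untested. Connection distance is
between unit centres, taken as the footprint amplitude-maximum electrode.
Kernel width, hollow fraction, and the pointwise band are configuration
(`ccg_params()`); the calibration test compares the realized
false-positive rate on independent Poisson pairs against an independently
coded Monte-Carlo implementation of the identical test, rather than
against a nominal α, because ±5 ms spans ten tested bins of a discrete
statistic. Trough-based (inhibitory) detection is out of scope.

# Pipeline, sizes and determinism

`run_pipeline()` executes simulate → sta → trace → network, persisting
every intermediate (container, per-unit footprint tables, segment and
neuron tables, burst/edge/degree tables) as plain text under the output
directory, with the seed and a config hash in the report; runs are
byte-identical given the same configuration and seed. `compare_sessions()`
summarizes the per-neuron and network metric distributions of several
reports side by side (median and quartiles), aligned by population
statistics only — no cross-session unit matching is attempted. A thin
command-line wrapper (`inst/cli/hdmea`, verbs `simulate`, `sta`, `trace`,
`network`, `run`, `compare`) exposes the same functions with YAML
configuration.

Validation problem sizes are chosen to exercise the full mechanism at
desk scale: a 32 × 64 sub-array (2,048 electrodes) for arbor recovery
with five co-rendered neurons per recording (their spike trains are
mutually incoherent — 13.5 ms refractory floor plus exponential ISI
jitter — so one unit's STA averages the others away), 300 averaged
spikes per unit, 40 units × 300 s for connectivity, 1,000 independent
pair simulations for null calibration. The full 19,584-electrode lattice
is used where geometry alone is tested.

# Known limitations

* Dominant-source rendering: electrodes take one source point per neuron
  rather than the sum over the arbor; amplitudes near dense branch
  crossings are therefore conservative.
* The velocity estimator averages per-segment fits without weighting;
  short marginal segments can drag a neuron's mean.
* Terminal selection maximizes a noisy delay map, which biases the
  terminal frame late by one to two frames at high velocity; the
  interpolated fit mitigates but does not remove this.
* The burst detector reports crossing-to-crossing durations, which for
  strong bursts exceed the underlying co-activity window (kernel
  broadening).
* Graph inference tests both directions of each pair from one CCG; a
  reciprocal pair at equal strength yields only the larger-excess
  direction.
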