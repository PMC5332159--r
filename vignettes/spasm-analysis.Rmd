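---
title: "Quantifying spasm-related activity in spinal recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spasm-related activity in spinal recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spasmpipe)
```

## The problem

After a complete spinal cord transection, sensory stimulation that is
innocuous in the acute state comes to trigger muscle spasms: long-lasting,
involuntary contractions visible as sustained motor-unit firing on EMG and
ventral-root recordings. A spasm-evoking trial has a stereotyped temporal
structure — a brief stimulus train, a *silent period* of suppressed activity,
the spasm itself, and a post-spasm silence — and the interplay of motor-neuron
plateau properties with excitatory and inhibitory interneuron (eIN/iIN)
populations unfolds on that skeleton. spasmpipe implements the quantitative
analyses this experimental program requires, plus a synthetic-session
generator that emulates every recorded modality with known ground truth so
each stage has a parameter-recovery test without any animal data.

The pipeline has five analysis surfaces:

1. **Motor-unit phenotyping** (`detect_spikes()`, `template_match()`,
   `instantaneous_frequency()`, `classify_firing_pattern()`): spikes are
   sorted by amplitude template matching (a unit accepts a spike only if its
   amplitude differs from the template by strictly less than 20%) and each
   unit's instantaneous-frequency profile is labeled *long_lasting*
   (gradually declining rate), *bimodal* (a high, unstable phase followed by
   a lower, stable one), *high* or *low*.
2. **Plateau properties** (`ramp_thresholds()`, `fi_hysteresis()`,
   `classify_plateau()`): slow triangular current ramps yield the recruitment
   and de-recruitment currents, their difference `delta_i = i_de - i_re`, and
   the direction of the f–I hysteresis; negative `delta_i` with
   counter-clockwise hysteresis is the signature of a persistent-inward-current
   plateau.
3. **Synaptic drive** (`detect_synaptic_events()`, `ei_balance()`): EPSP/IPSP
   barrages in 20 s windows before and after dorsal-root stimulation,
   normalized to `inhibition = IPSPs/(IPSPs+EPSPs)` and
   `excitation = EPSPs/(IPSPs+EPSPs)`.
4. **Root responses and epochs** (`reflex_measures()`,
   `stimulus_response_curve()`, `segment_epochs()`): rectified-area reflex
   quantification (10 ms monosynaptic window; 50–4000 ms long-lasting
   window), stimulus–response threshold/slope fits, and the four-epoch
   segmentation every downstream normalization relies on.
5. **Calcium imaging** (`compute_dff()`, `peak_time()`,
   `normalize_peak_time()`, `fit_peak_distribution()`,
   `population_raster()`): dF/F traces per ROI, peak times as the maximum of
   a 500 ms moving average, mapping of peaks onto the canonical normalized
   axis, and Gaussian/mixture fits of population peak-time distributions.

## The normalized epoch axis

Trials differ in silent-period and spasm durations, so interneuron peak times
are compared on a canonical axis: each of the four epochs maps linearly onto
a unit interval with offsets −1, 0, 1, 2 (stimulation `[-1, 0]`, silence
`[0, 1]`, spasm `[1, 2]`, post-spasm `[2, 3]`), each carrying 100 bins. The
map is continuous and strictly increasing; boundary times land exactly on
−1, 0, 1, 2 and the recording end on 3. `denormalize_time()` inverts it,
which the generator uses to realize programmed normalized peak times as
absolute transient times. Bins are `floor(100 * fraction)` clamped to 99 at
the right edge; when a bin is re-expressed as a normalized time we use its
center (left edge plus half a bin).

## The synthetic-session generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline's recovery claims hold.

**What it emulates.** Spike trains of the four firing phenotypes riding on
the epoch skeleton (units fire only inside the spasm), with published class
statistics as defaults: long-lasting 27 ± 6.3 Hz with a linear decline from
1.35 to 0.65 of the unit mean; bimodal with an initial 41.48 ± 13.15 Hz
unstable phase and a stable second phase at a ratio 23.85/41.48 of the first;
high 45.55 ± 13.64 Hz; low 17.87 ± 2.5 Hz. Triangular 8 s current ramps with
programmed recruitment/de-recruitment currents and hysteresis direction.
Poisson EPSP/IPSP barrages with alpha-function kernels (2 ms rise / 10 ms
decay). GCaMP-like transients (50 ms rise / 600 ms decay, double
exponential) whose normalized peak times follow per-class Gaussian mixtures;
`chronic_peak_specs()` and `acute_peak_specs()` carry the published
distribution parameters (acute: eIN −0.22 ± 0.24, iIN 0.06 ± 0.13; chronic:
eIN −0.33 ± 0.07 and 1.17 ± 0.2, iIN 0.17 ± 0.19 and 1.855 ± 0.25; component
weights are not published and default to 0.5/0.5). Sampling rates default to
typical acquisition rates: 20 kHz EMG/root, 10 kHz
intracellular, 10–20 frames/s imaging.

**Design choices worth knowing about.**

* *Stratified population draws.* Across-unit firing means and across-cell
  peak times are stratified Gaussian samples (one draw per quantile stratum,
  shuffled; mixture component counts proportional to the weights). The
  marginal distributions are exactly the programmed ones, but the generated
  population realizes the printed class mean and SD instead of fluctuating
  around them, so a parameter-recovery test measures pipeline error rather
  than Monte-Carlo luck. Within-session unit draws (one to a few units per
  trace) remain iid.
* *Bimodal units are two-phased by construction.* The second-phase/first-phase
  ratio is drawn around the published class-mean ratio and clipped to
  [0.40, 0.66], and within-phase jitter scales with the phase mean. A
  "bimodal" unit whose phases are statistically inseparable would contradict
  its own phenotype definition; with the clip, the dip test detects every
  generated unit.
* *Recoverable peak placement.* The calcium transient is placed so that the
  maximum of the 500 ms moving average — the estimator used downstream —
  falls at the drawn peak time. The compensation offset is calibrated
  against the discrete estimator at the session's frame rate, averaged over
  sub-frame phases; without it every recovered peak would carry a
  kernel-asymmetry bias that is a generator artifact.
* *Spike templates* are biphasic, 2 ms, with a dominant positive lobe so that
  peak alignment during matching is unambiguous; only the amplitude enters
  the 20% criterion. Amplitude jitter is ±8%, inside the tolerance.
* *Noise defaults* give spike SNR ≈ 10 and transient SNR ≈ 5 (acquisition reports do
  not state noise levels; these are conventional for such recordings and are
  configurable).
* *Out-of-range normalized draws* are truncated into [−1, 3] and counted
  (`n_truncated`), not re-drawn; at the published distribution parameters the
  truncated mass is negligible.
* *Post-spasm epoch length* defaults to the spasm duration, capped at the
  recording end.
* *Strength modulation.* `epochs_for_strength()` encodes the direction the
  root analysis must reproduce — stronger stimulation shortens the silent
  period and lengthens the spasm — with a linear law chosen once
  (silent `3.2 − 0.55 × strength` s with a 0.3 s floor; spasm
  `8 + 5 × strength` s).

**What the generator does not emulate** — and hence what passing tests do
not show about real data: electrode drift and waveform non-stationarity
(amplitude jitter is iid), movement and light artifacts in imaging, cell
overlap in ROIs, correlated network state fluctuations, non-Gaussian noise,
and rostro-caudal conduction delays. Recovery results bound algorithmic
error under the published statistics, not robustness to every experimental
pathology.

## The dip test of bimodality

No dip-test implementation is available among our dependencies, so the
Hartigan dip statistic is implemented in C++ from its definition: the dip of
an empirical cdf is the smallest sup-norm distance to a unimodal cdf (convex
then concave, with at most one atom at the mode). For a candidate mode at a
sample point, a feasible unimodal fit at half-width `d` exists iff the
greatest convex minorant of the upper step corners left of the mode and the
least concave majorant of the lower corners right of it each stay within
`2d` of the opposite corners; the dip is half the minimal worst-case gap
over mode placements, found by binary search (the left gap is nondecreasing
and the right gap nonincreasing in the mode index). The implementation is
validated against closed-form values derived by hand: `1/(2n)` for equally
spaced samples, `0.25` for two points or two tight equal clusters, `0` for
constant data. The p-value is a bootstrap against the uniform null — the
least favourable unimodal distribution — with 2000 resamples; on Gaussian
samples the test is conservative (observed false-positive rate well below
the nominal 5%).

## Classification rules and numerical choices

* **Firing phenotype order:** bimodal (dip p < 0.05) is tested first; then a
  significant negative least-squares frequency trend (p < 0.05) marks
  long_lasting; remaining units split at 30 Hz — the midpoint of the
  published high/low class means — into high vs low. Units with fewer than
  20 frequency samples, or recordings shorter than 5 minutes, are
  unclassified.
* **ISI plausibility cleaning:** before classification, frequency samples
  outside 0.6–1.7 times the running-median frequency (window 21) are
  dropped. A missed spike halves one sample and a collision-born double
  detection roughly doubles one; such artifacts otherwise masquerade as
  spurious modes. Contiguous phases and trends pass through unchanged.
* **Template matching:** when waveforms are available the spike amplitude is
  estimated by least-squares projection onto the peak-aligned template shape
  (a single-sample extremum is noise-biased upward), and a waveform
  correlation floor (0.8) rejects collision-distorted spikes. The 20%
  criterion is strict: a relative difference equal to the tolerance (up to
  representation error) is rejected.
* **Ramp analysis:** action potentials are upward crossings of −20 mV with a
  2 ms refractory period (no canonical threshold exists for sharp-electrode recordings).
  Frequencies attach to inter-spike-interval midpoints, which keeps a linear
  rate profile unbiased on both limbs. The hysteresis index is the mean
  descending-minus-ascending frequency difference over the overlapping
  current range; `epsilon` is twice the SD of within-limb residuals around a
  linear f–I fit with a 0.2 Hz floor for noise-free fixtures. A cell still
  firing as the command returns to zero gets a censored `i_de` and should be
  excluded from population `delta_i` statistics.
* **Plateau classes:** full = ccw hysteresis and `delta_i < 0`;
  intermediate = as full but with slow sustained firing (mean rate below the
  30 Hz boundary) — the published slow-firing plateau profile is narrative
  only, so this rule is a documented package choice; partial = negative
  `delta_i` with a linear f–I plot; none = non-negative `delta_i`. A
  clockwise f–I with negative `delta_i` is contradictory for a plateau
  mechanism and is classified by the `delta_i` sign (partial), which keeps
  the invariants *full ⇒ delta_i < 0* and *none ⇒ delta_i ≥ 0*.
* **Synaptic events:** the trace is median-filtered (1 ms), differentiated
  over a 1 ms step (a PSP rise spans milliseconds; the wide step averages
  sample noise out of the derivative), and thresholded at 3 robust SDs.
  Amplitudes are read at the end of the monotone rise from a 3 ms median
  trace; events below 0.5 mV are discarded. An opposite-polarity deflection
  within 35 ms that merely returns toward the previous event's baseline is
  that event's decay and is dropped; a genuine opposite event overshoots.
  On seeded barrages at SNR 5 this yields ≥ 90% recall and precision.
* **E/I balance:** `excitation` is computed as `1 − inhibition`, which equals
  `EPSPs/(IPSPs+EPSPs)` exactly on counts and guarantees the two fractions
  sum to 1 without floating-point residue.
* **Segmentation:** envelope = zero-phase 10 Hz low-pass of the rectified
  trace; baseline statistics from the 5 s before the train; threshold
  `median + 3 × MAD`; onset/offset require 0.2 s of sustained supra-/
  sub-threshold envelope. All four parameters are configurable; the defaults
  recover programmed boundaries within 100 ms at the generator's SNR. A
  trace without a supra-threshold episode returns a "no spasm" segmentation
  rather than an error. The first 2 ms after each stimulus pulse are treated
  as artifact and blanked in reflex windows.
* **dF/F baseline:** `Fo` is the mean raw fluorescence over the 2 s before
  stimulation onset (the window length is a package convention).
* **Stimulus–response slope:** threshold T is the lowest strength whose
  response exceeds the noise floor (default 5% of the curve maximum); the
  slope is a least-squares line from the first supra-threshold point to the
  curve maximum. If the curve saturates, the maximal point participates in
  the fit and flattens the slope slightly; the noise-free linear case is
  exact.
* **Mixture fits** use mclust (model "V", unequal variances) with the number
  of components set by the caller — two for the chronic pattern, one for the
  acute — or chosen by BIC when unset. Components are reported sorted by
  mean. `peak_moments()` provides the plain sample-moment alternative since
  it is ambiguous whether published values are fit parameters or windowed
  moments; the mixture fit is the default.

## Problem sizes in the test-suite

The packaged tests run the full recovery experiments at the published
population sizes: 198/184 chronic and 98/98 acute cells for the peak-time
fits, 25 units per firing-phenotype class, three plateau fixtures, and
1000 random sessions for the warp-property checks. Phenotype spike trains
span a 40 s spasm (within the range of observed spasm durations), and
estimator calibration is checked over 100 statistical replicates of the
draw-and-fit chain. The seeded barrage and session fixtures use one to two
units per trace, matching single-unit fine-wire recordings; a
many-unit single trace would be dominated by spike collisions that no
amplitude-based sorter resolves.

## Known limitations

* Amplitude-only template matching cannot recover units whose spikes
  systematically collide with much larger units; the phenotype-recovery
  guarantee holds for recordings with one or two well-separated units per
  trace, as in fine-wire single-unit recordings.
* The dip test's bootstrap null makes it conservative on unimodal
  non-uniform data; marginally separated phases (ratio above ~0.7 of the
  first phase) are not reliably called bimodal.
* The silent-period onset is defined from the root envelope for all
  modalities; intracellularly defined silent periods may differ slightly.
* `stimulus_response_curve()` assumes a single rising limb; non-monotone
  curves (e.g. H-reflex suppression at high strengths) need windowing by the
  caller.
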