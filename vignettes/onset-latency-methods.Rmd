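---
title: "Measuring evoked-response onset latencies: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring evoked-response onset latencies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(megonset)
```

## The scientific question

When a sound or an image is presented, how quickly does each sensory
cortex begin to respond — not only the cortex of the stimulated modality,
but also the opposite one? Cross-sensory activations (visual cortex
responding to sounds, auditory cortex to images) and audiovisual
interactions — deviations from additivity when both modalities are
stimulated together — are informative about the pathways connecting the
sensory systems. The observable that carries this information is the
*onset latency* of the evoked response: the earliest post-stimulus time at
which a region's activity exceeds its own baseline noise. Differences of
onsets across regions and conditions then yield conduction delays
(cross-sensory onset minus sensory-specific onset of the same stimulus),
convergence latencies (the later of the two unimodal onsets in a region),
and interaction lags (interaction onset minus convergence).

`megonset` implements this measurement chain for MEG planar-gradiometer
recordings, and ships a synthetic-session generator with known
ground-truth onsets so that the whole chain is testable.

## The onset statistic

For a nonnegative response time course $x(t)$ sampled at 600 Hz with a
200 ms pre-stimulus baseline, the detector (`detect_onset()`) reports the
earliest grid time $t \ge t_{\min}$ such that

$$x(t') > \mu_b + k\,\sigma_b \quad \text{for all } t' \in [t, t + \Delta],$$

where $\mu_b, \sigma_b$ are the baseline sample mean and SD (denominator
$n-1$), $k = 3$, the minimum latency $t_{\min} = 15$ ms reflects finite
conduction delays in the sensory pathways, and the sustain window
$\Delta = 20$ ms protects against brief noise spikes.

Three conventions deserve note:

* **The threshold includes the baseline mean.** Combined gradiometer
  amplitudes and ROI dSPM magnitudes are nonnegative with a positive noise
  floor; a threshold of $3\sigma_b$ alone would sit below the floor.
* **The sustain test holds the response above the same threshold**, not
  merely above the baseline mean. Its purpose is spike rejection, and a
  spike that dips below threshold within 20 ms should not qualify. The
  laxer reading (`sustain_above = "noise_mean"`) is available as an
  option.
* **Onsets are reported on the sampling grid** (1.67 ms steps), inclusive
  of the onset sample in the sustain window; a sustain window truncated by
  the epoch end fails the criterion. No sub-sample interpolation is
  attempted — the statistic is a threshold crossing, and interpolating it
  would fabricate precision the noise model cannot support.

The detector is verified against an exhaustive scan over all candidate
samples on random fixtures, and recovers ground-truth onsets within ±1
sample in ≥ 95% of simulations when the response amplitude is 20× the
baseline noise SD. At 10× amplitude the first sample of a 20 ms half-sine
rise carries only 13% of the amplitude, so detection is systematically
about two samples late; this is a property of any threshold statistic on
a finite-rise response, not an implementation artifact.

## Sensor-space pipeline and order of operations

`reject_trials()` discards epochs exceeding 150 µV on EOG or 3000 fT/cm on
any gradiometer, scanning the whole epoch including the baseline. The
surviving epochs are processed in a fixed order:

1. average per condition (`average_evoked()`; runs with different ISIs are
   pooled, which equals trial-count-weighted averaging of per-run means),
2. zero-phase FIR low-pass at 40 Hz (`lowpass()`),
3. baseline correction of the signed channels (`baseline_correct()`),
4. combination of each sensor location's gradiometer pair into the
   amplitude $\sqrt{b_x^2 + b_y^2}$ (`gradient_amplitude()`).

Averaging before combining matters: the amplitude is a convex function, so
combining first and averaging after would inflate the noise floor and bias
onsets late. The combined amplitude itself is *not* re-baselined — it has
a positive noise floor by construction, which the onset detector absorbs
into $\mu_b$.

The filter is a Hamming-window FIR applied forward and backward
(`signal::fir1` + `signal::filtfilt`), order $2\lceil 1.65\,f_s/f_c\rceil$.
The contract is behavioral: passband gain within 1% below half the
cutoff, at least 20 dB attenuation above twice the cutoff, zero phase.
Zero-phase filtering smears response energy *backwards* in time by up to
the filter's half-width; at very high SNR this biases detected onsets
early. The ground-truth recovery tests therefore run the source pipeline
unfiltered, and users comparing onsets across filter settings should keep
the cutoff fixed.

## Source estimation and dSPM

The inverse operator is the textbook minimum-norm solution with identity
source covariance,

$$W = L^\top (L L^\top + \lambda^2 C_{\mathrm{eff}})^{-1},
\qquad C_{\mathrm{eff}} = C / n_{\mathrm{ave}},$$

where $C$ is the empirical covariance of single-trial baseline samples
(with diagonal loading $\varepsilon\,\mathrm{tr}(C)/p$, $\varepsilon =
10^{-3}$, to guarantee invertibility) and $n_{\mathrm{ave}}$ the number of
trials averaged into the data being localized. Scaling the covariance by
$1/n_{\mathrm{ave}}$ is essential: the averaged data's noise is
$n_{\mathrm{ave}}$-fold smaller in variance, and regularizing against the
single-trial covariance would over-smooth the inverse by the same factor
(in development this masked cross-sensory onsets entirely). The default
$\lambda^2 = 1/9$ encodes the conventional assumed amplitude SNR of 3 in
the average.

dSPM normalization divides each source's estimate by its projected noise
SD $\sqrt{w_s C_{\mathrm{eff}} w_s^\top}$, giving unit-SD baselines per
source (verified to ±10% on pure-noise simulations). ROI time courses are
means of absolute source values over the ROI's indices —
magnitudes, because with a fixed-orientation model the sign of a source is
an arbitrary orientation convention, and the normalized magnitude behaves
as a $\sqrt{F}$ statistic. Hemisphere pairs with similar timing can be
averaged sample-wise (`combine_hemispheres = TRUE`).

No depth weighting, loose orientation or cortical-surface machinery is
included: the inverse here serves timing extraction on a synthetic
leadfield, not anatomical mapping.

## The interaction contrast

`interaction_response()` forms AV − (A + V) on *signed* waveforms (sensor
signals or signed source estimates), never on rectified amplitudes —
additivity is a statement about fields, and rectification destroys it.
Because the contrast sums three independent noise processes, its noise SD
is √3 times a constituent's (verified to ±3% on 10,000-sample baselines);
the contrast is therefore low-passed more strictly, at 20 Hz, by default.

Two caveats, both measured during development and worth knowing:

* **Threshold calibration under heavy filtering.** After a 20 Hz
  zero-phase low-pass, the 120-sample baseline contains only ~8
  statistically independent values, so $\sigma_b$ — and hence the 3 SD
  threshold — is itself noisy, and the 20 ms sustain window no longer
  spans multiple independent samples. On null simulations the detector
  then reports spurious interaction onsets in roughly a third of runs.
  Onset claims for heavily filtered contrasts should lean on bootstrap
  distributions rather than a single threshold crossing.
* **Amplitude jitter breaks exact additivity.** With multiplicative
  trial-to-trial amplitude variability (the generator's default is 10%),
  AV − (A + V) retains a response-shaped residual of relative scale
  $\sqrt{2}\,j\,A/\sqrt{n}$ against evoked noise $\sigma/\sqrt{3n}$ — a
  ratio *independent of trial count*. A null interaction is therefore only
  a null in expectation. The package's null-control test uses an exactly
  additive generator (zero jitter) and the unfiltered contrast, where the
  measured false-positive rate is 0 of 100.

## Bootstrap onset distributions

`bootstrap_onset()` resamples epochs with replacement (same size as the
original), re-averages, re-runs the pipeline and the detector, and
summarizes the resulting onset distribution; resamples in which no onset
qualifies are counted and excluded from the moments. The scheme resamples
at the trial level within condition; across-subject tables then aggregate
subject-level values (means ± SDs and medians) via
`build_latency_table()`.

The bootstrap is intended for *high-SNR averaged signals*. At
threshold-marginal SNR a resample mean carries roughly √2 the noise of the
original average, and the detector's nonlinearity inflates bootstrap SDs
several-fold; in its operating regime (response ≥ ~16× single-trial
noise in our cross-check) the bootstrap SD matches the across-session SD
of the onset within a factor of two.

## Temporal-searchlight decoding

Single-trial ROI time courses (`single_trial_roi_timecourses()`: the
dSPM-weighted inverse applied per epoch, magnitudes averaged within ROI)
are decoded in 50 ms windows (30 samples) sliding one sample (1.7 ms) at a
time. Each window's accuracy is the mean over 100 random stratified 80/20
train/test splits of a linear SVM with cost 1 (`e1071::svm`, libsvm).
Significance per window is a one-sided t-test against chance 0.5 across
replicates, Benjamini–Hochberg-corrected across windows at q = 0.05; the
first significant window *centroid* is reported — note this is the center
of a 50 ms window, not a neurophysiological onset, and leads the true
onset by up to half the window width.

Design choices left open by convention and fixed here: folds are
stratified by class; the t-test is one-sided (greater), since below-chance
decoding is not interpretable as information; q = 0.05. Short-ISI runs can
be excluded (`include_runs`) because consecutive trials overlap there.
Noise exemplars for stimulus-vs-noise contrasts are epochs time-locked to
silent points placed in long inter-stimulus gaps (`make_noise_design()`);
since the generator builds epochs independently, these are exactly
zero-signal epochs. The interaction decoding contrast compares AV trials
against synthesized A+V composites (`make_av_composites()`: sample-wise
sums of randomly paired unimodal trials), which are indistinguishable from
AV trials under pure additivity.

One calibration subtlety: a single finite dataset of $n$ structureless
trials carries spurious separability of order $1/\sqrt{n}$ that is shared
across all windows, so chance-level checks average over independent
permuted datasets rather than trusting one draw.

## The synthetic-session generator

The generator emulates the design of a rapid audiovisual letter
experiment: equiprobable auditory (A), visual (V) and audiovisual (AV)
stimuli with 10% rare targets, three runs with mean ISIs of 1.5 / 3.1 /
6.1 s jittered in 1.15 s steps (all ISIs are exact positive multiples of
the step, drawn as $\lfloor m\rfloor$ plus a Bernoulli carry so the run
mean matches), and 150 / 125 / 100 non-target trials per category —
375 per category in total.

Each epoch's source activity is a *ramp-burst*: zero before the onset, a
half-sine rise (default 20 ms) into a plateau lasting the 300 ms stimulus
duration, then exponential decay (τ = 50 ms). The rise is evaluated at
$(t - t_0 + \delta t)$ so the first sample at or after the configured
onset is already nonzero — this keeps the ground truth on the grid and
exactly recoverable. Default ground-truth onsets represent the canonical
timing pattern of the letter paradigm: sensory-specific 25 ms (auditory
cortex) and 48 ms (visual cortex), cross-sensory 65 and 62 ms (i.e.
conduction delays of 17 and 37 ms), and interaction components at 125 and
133 ms (60 and 71 ms after convergence), with cross-sensory and
interaction amplitudes weaker than sensory-specific ones. Trial-to-trial
variability is a 10% multiplicative Gaussian amplitude jitter — enough to
make bootstrap distributions non-degenerate; single-trial latency jitter
of real cortex is not modeled, and the defaults are exposed in
`sim_config()` for users who want to vary them.

The leadfield is a random Gaussian gain matrix (default 30 sensor
locations = 60 gradiometer channels, 20 sources, optional column
correlation), with the first sources assigned to the four ROIs
(A1/V1 × left/right). Sensor noise is i.i.d. Gaussian (default 30 fT/cm
per single trial), plus an EOG channel of pure noise; `inject_artifacts()`
adds blink transients and gradiometer spikes at a configurable rate, and
returns the contaminated indices for oracle tests.

What the generator does **not** emulate — and hence what passing tests do
and do not show: real head geometry and sensor physics (a random gain has
no spatial smoothness, so dSPM point spread is more severe than with a
real forward model); correlated, non-stationary sensor noise (alpha
rhythms, slow drifts); response latency jitter; inter-trial response
overlap at short ISIs (epochs are generated independently, which is why
ISI-gap "noise epochs" are exactly signal-free). Passing tests demonstrate
the correctness and calibration of the *algorithms* under the stated noise
model, not performance on real recordings.

## Reproducibility and problem sizes

All randomness flows from a master seed through deterministically derived
child seeds (per run, per window, per bootstrap), so identical
configurations give bit-identical outputs. The test suite and the
acceptance script use deliberately reduced problem sizes — single runs of
tens of trials per category, leadfields of 8–20 sources, epochs truncated
at 300–500 ms, bootstrap B ≈ 100, searchlights with subsampled window
grids — chosen so the full distributional checks (200-simulation recovery
rates, 1,000-fixture oracle scans, 500-replication FDR calibration) remain
cheap while preserving each estimator's operating regime. The
chance-decoding calibration keeps the full 200-trial, 100-fold scale
because its tolerance (±0.02) demands it.

## Known limitations

* Zero-phase filtering biases onsets early at very high SNR (backward
  smearing); compare onsets only across matched filter settings.
* The 3 SD threshold is weakly calibrated on heavily low-passed time
  courses (few independent baseline samples); see the interaction caveats
  above.
* dSPM's point-spread improvement over raw MNE is modest on random
  leadfields and holds on average over sources, not for every source.
* The Wilcoxon implementation enumerates sign assignments for tied
  differences only up to n = 14; beyond that it falls back to the normal
  approximation.
* No ICA/SSP artifact correction, magnetometers, notch filtering, depth
  weighting, beamformers, or cortical-surface handling.
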