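---
title: "Modeling cellular aging mechanisms in a cortical microcircuit and their EEG biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cellular aging mechanisms in a cortical microcircuit and their EEG biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(agecircuit)
```

## The scientific question

Healthy human aging changes cortical physiology through several distinct
cellular and synaptic mechanisms. Three are quantifiable from published
human data: loss of inhibitory interneurons (SST, VIP and PV classes, from
age regressions on single-cell RNA-seq cell-type proportions), loss of
NMDA-receptor conductance on layer 2/3 pyramidal neurons (from GluN2A/B
western blots), and loss of dendritic spines (from Golgi staining). Each
mechanism alters microcircuit activity, and through it the scalp EEG. This
package asks, with a fully synthetic and reproducible pipeline:

1. How do the three mechanisms - separately and combined - change baseline
   and stimulus-evoked spiking of a cortical microcircuit?
2. How do those changes appear in EEG biomarkers (aperiodic offset and
   exponent, alpha peak frequency, band power, oscillation events)?
3. Can a classifier recover *which* mechanism produced an observed EEG
   feature vector?

## Aging parameterization

All mechanism strengths derive from per-year rates: 1.21 %/yr (SST),
0.88 %/yr (VIP), 0.52 %/yr (PV), 2.5 %/yr (NMDA conductance), 1 %/yr
(spines), applied linearly over a +20-year offset (middle age, ~50 yr, to
older, ~70 yr) and clamped to [0, 1]. Note that 0.52 %/yr x 20 yr gives a
10.4% PV loss; reports that round the regression coefficient print 10.3%.
We implement the rate.

Spine loss maps onto two circuit parameters:

* a 20% reduction of the pyramidal-to-pyramidal connection probability;
* a reduction of dendritic leak conductance and membrane capacitance from
  lost membrane area. Thin spines make up 25% of spines in older
  individuals; back-projecting a 20% loss that falls on thin spines gives
  a 31.25% middle-age thin fraction. Modeling a thin spine as a truncated
  cone (length 1.2 um, tip diameter 0.35 um, base diameter half the tip
  diameter, tip end-cap included) gives ~1.09 um^2 per spine and
  ~2782.6 um^2 across 8169 x 31.25% spines, i.e. 8.6% of the combined
  spine + dendrite area (11954 + 20410 um^2). A 20% loss of that area is a
  1.72% reduction applied to G_pas and c_m. The cone orientation (base
  narrower than tip) and the end-cap inclusion were chosen because this
  combination reproduces the published 2782.57 um^2 to within 0.2%; the
  opposite orientation misses by roughly a factor of two.

```{r}
make_profile("older", 20)
```

## The surrogate microcircuit

The reference for this line of work is a morphologically detailed
1000-neuron multicompartment model. Rebuilding it is out of scope here;
instead the package provides a surrogate: four populations (80% Pyr, 5%
SST, 7% PV, 8% VIP) of single-compartment leaky integrate-and-fire neurons
with conductance synapses (AMPA 0.3/3 ms, NMDA 2/65 ms with a standard
magnesium block, GABA-A 1/10 ms rise/decay), the canonical connectivity
motif (Pyr excites everything; SST inhibits Pyr apically; PV inhibits Pyr
basally; VIP disinhibits by targeting SST and PV), and an independent
excitatory Ornstein-Uhlenbeck conductance per neuron as background drive.
Pyramidal neurons additionally carry a spike-triggered adaptation current
(100 pA increment, 150 ms decay): without it, the strong recurrent
excitation needed below makes stimulus-evoked activity self-sustaining,
and the network would not return to baseline between trials.

Aging profiles act on the circuit exactly where the data say they should:
survival fractions scale interneuron counts (round-half-up, deleted cells
drawn uniformly); the NMDA multiplier scales every NMDA conductance onto
pyramidal targets, including external stimulus synapses; the connection
multiplier scales the Pyr-Pyr wiring probability; the passive multiplier
scales pyramidal leak conductance and capacitance.

### Calibration and what it means

Connection probabilities and synaptic weights are configuration with
defaults calibrated - once, before freezing - to a regime stated in
advance: pyramidal baseline near ~1 Hz and irregular (ISI CV > 0.5),
interneurons at a few Hz, a 1/f-shaped dipole spectrum with a periodic
peak, and the published direction pattern of the aging effects (inhibitory
loss raises the pyramidal baseline rate; NMDA loss, spine loss and the
combined older condition lower it). Reproducing those *directions*
requires an inhibition-stabilized operating point: recurrent excitation
strong enough that removing 20% of Pyr-Pyr connections bites harder than
the (excitability-increasing) passive reduction, balanced by strong fast
PV feedback. The direction pattern was verified on three disjoint sets of
five seeds before the defaults were frozen.

Two numerical reductions deserve mention:

* **Stimulus gain.** The stimulus protocols specify conductances delivered
  to dendrites of morphological neurons (e.g. 4 nS on 55 Pyr basal
  dendrites), where dendritic filtering attenuates their somatic effect.
  Applied verbatim to point neurons they saturate the response and the
  signal-detection overlap is then governed by all-or-none ignition
  failures rather than by the graded response the published metrics
  reflect. `stimulus_gain = 0.4` stands in for dendritic attenuation and
  places the response at a few times the baseline rate, the regime in
  which aging degrades detection and decoding.
* **OU placement.** The reference model scales many dendritic OU processes
  with distance from the soma; a point neuron admits one somatic OU
  process per neuron with per-population gain, calibrated to the same
  firing regime.

What the surrogate does *not* emulate: absolute spike rates and EEG
magnitudes (no morphology, no layer structure), layer-specific dipole
geometry, short-term plasticity (its parameter values are not published;
the hooks exist in the synapse model but default off), and the exact
~10 Hz position of the periodic peak - the surrogate's network rhythm
sits at the alpha/low-beta boundary (~10-17 Hz depending on realization),
because the E-I loop frequency is set by membrane and GABA time constants
plus a 1 ms delay, and pushing it lower destabilized the calibrated
direction pattern. Passing tests therefore certify pipeline correctness
and direction-level agreement, not quantitative agreement with human EEG.

## EEG forward model

The dipole proxy sums pyramidal synaptic currents weighted by signed depth
offsets of their compartment class (apical inhibition at +300 um, basal
excitation and inhibition at -150 um), decimated to 2 kHz. The four-sphere
volume conductor (brain/CSF/skull/scalp radii 79/80/85/90 mm,
conductivities 0.047/1.71/0.02/0.41 S/m) maps a current dipole to scalp
potential via the Legendre-series solution; per-order radial coefficients
come from a 7-unknown boundary system solved with per-shell-normalized
bases for numerical stability, truncated adaptively at 1e-12 relative
contribution. The solver is validated against an independently derived
homogeneous-sphere closed form (equal conductivities) to better than
0.1%; tangential sources obey the expected axis antisymmetry. The default
dipole is radial at 78 mm with the electrode at the vertex directly above,
the conventional geometry for a cortical column under the electrode;
projection is then a single static gain, which makes the mapping exactly
linear and time-invariant.

## Spectral biomarkers

* **Welch PSD**: 2 s Hann windows, 50% overlap, per-segment constant
  detrend, one-sided density scaling; 0.5 Hz resolution.
* **Aperiodic/periodic decomposition** over 3-30 Hz, in log10 power:
  robust aperiodic fit (offset and exponent; no knee term, matching the
  two-parameter form used for these biomarkers) that refits on the
  lower-residual half of points to resist peak contamination; iterative
  detection of up to 3 Gaussian peaks above 2 SD of the flattened
  spectrum; joint Gaussian refit with bandwidth clamped to 2-6 Hz; final
  aperiodic refit on the peak-subtracted spectrum. Mean absolute recovery
  error on the generative family is below 0.05 (offset, exponent) and
  0.3 Hz (peak frequency).
* **Band areas** (theta 4-8, alpha 8-12, beta 12-30 Hz - the conventional
  ranges consistent with a 3-30 Hz fit window) by trapezoidal integration
  with edge interpolation, so adjacent bands add exactly; the **1/f AUC**
  is the closed-form integral of the fitted aperiodic curve, with the
  exponent-1 case handled logarithmically.
* **Oscillation events**: Morlet spectrogram (7-cycle width) on a
  1-100 Hz grid in 0.5 Hz steps, per-frequency median normalization,
  connected suprathreshold regions at 4x median, bounding boxes merged at
  >= 50% fractional overlap, band assignment by peak frequency, and wave
  height as the peak-to-trough of the band-passed signal (4th-order
  zero-phase Butterworth) inside the event window. Because the normalized
  wavelet power of noise is approximately exponential, threshold-4 pixels
  occur by chance at the percent level and raw connected components alone
  would produce hundreds of spurious events per window; events are
  therefore additionally screened to span at least 6 cycles of their peak
  frequency and to contain a pixel at >= 20x the median. On pure pink
  noise this leaves at most ~1 band event per 24 s while a 10-cycle burst
  at 10x the noise amplitude is recovered in 10/10 seeds. The surrogate
  EEG is analyzed at 2 kHz rather than the reference 40 kHz; all detector
  settings are expressed in sampling-rate-independent units, so only the
  100 Hz ceiling relative to Nyquist changes.

## Circuit-function metrics

Signal-detection error is the percent overlap between the baseline
firing-rate distribution (40 ms windows sliding by 1 ms over the 3 s
pre-stimulus period) and the recurrent-period distribution (20 trials,
10-50 ms post-stimulus), on shared equal-width bins (Freedman-Diaconis on
the pooled sample, floored at 10 bins - the binning is not prescribed, so
it is configurable), with a 1000-resample bootstrap interval. Decoding
accuracy labels per-trial pyramidal spike-count vectors (50 ms
pre-stimulus vs 25-75 ms post-stimulus, i.e. 40 windows per condition as
20 trials x 2 window classes) and scores a linear SVM (C = 1) or a small
ReLU MLP over 100 random 70/30 splits. Cohen's d uses the pooled-SD
formula with the sign convention comparison-minus-reference, so negative
d means a decrease with aging; group tests are two-sided equal-variance
t-tests, with |d| > 0.5 and p < 0.05 flagged together.

## Mechanism decoder

The classifier is a 4-20-20-5 multilayer perceptron (ReLU hidden layers,
softmax output) trained with Nadam (Adam with Nesterov momentum, learning
rate 0.001) on categorical cross-entropy, batch size 32, at most 100
epochs with early stopping after 10 epochs without validation-loss
improvement, weights initialized from a zero-centered normal (SD 0.05).
Fifty members are trained on independent stratified 60/10/30 splits.
Features are standardized by training-split statistics stored with each
member; spectra with no detected peak have their center frequency imputed
with the training-split median (the choice is not dictated by the data;
median imputation keeps the feature usable without inventing a peak).
Feature importance is the mean absolute Shapley value of each input for
the predicted-class probability against a fixed background set; with four
features the 16-coalition exact computation is used directly and also
serves as the oracle for the permutation-sampling estimator.

## Problem sizes and numerical choices

Integration uses a fixed 0.025 ms step; synaptic states decay by exact
exponential factors, so only membrane integration and spike timing depend
on the step. The OU update is the exact discretization. Simulated
experiments in the test suite use 400-neuron circuits, five seeds per
condition, 3-4 s baselines and 20-trial stimulus runs; the full-scale
defaults (1000 neurons, 20 circuits, 28 s spectral baselines) are the
study conditions and run unchanged, just longer. Determinism is
bit-exact under fixed seeds: circuit construction and stimulus timing use
R's RNG through an isolated seed scope, and the C++ core uses its own
mt19937-based generator.

## Known limitations

* Direction-level fidelity only; magnitudes (0.76 Hz baselines, 84.1%
  mechanism-decoding accuracy, microvolt-scale EEG) require the detailed
  morphological model.
* One electrode, one radial dipole; no montage or head-position effects.
* The periodic peak sits slightly above the classical alpha band (see
  calibration notes).
* Interneuron loss acts only through cell deletion; synaptic compensation
  or sprouting is not modeled.
* The linear per-year rates extrapolate poorly far beyond the +20-year
  range they were derived for; profiles clamp rather than model saturation.
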