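---
title: "Measuring and explaining ECG intervals with residual CNNs"
author: "ecgradcam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and explaining ECG intervals with residual CNNs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A 12-lead electrocardiogram is a set of voltage time series whose
characteristic waves (P, QRS, T) carry most of the clinically used
information: the PR, QRS and QT intervals, the heart rate, and the R-peak,
T-peak and J-point amplitudes. Deep networks can regress these quantities
directly from the raw signal, but a clinical reader needs to know *where*
in the signal a model looked before trusting its output. This package
implements that full loop: a residual 1-D convolutional network for
interval/amplitude regression and sex classification, ECGradCAM attention
maps that resolve the model's temporal focus per lead, and a wave-blanking
occlusion study that verifies the attention findings causally. Because the
clinical datasets this methodology was developed on are not public, the
package also ships a parametric ECG simulator with exact ground-truth
fiducials, so every component is testable end to end.

## The network

The architecture (`fullArchitecture()`) is: two initial convolutions (64
and 32 filters, kernel sizes 8 and 3), each followed by batch
normalization and ReLU; one average pooling (size 2, stride 2); eight
residual modules, each `conv(64, k50) - BN - ReLU - conv(32, k50) - BN -
dropout(0.5) - add skip - ReLU` with "same" padding so the skip addition
is well defined; a global average pool; and a single neuron with linear
activation (logistic link for classification). The large residual kernels
(50 samples = 100 ms at 500 Hz) let a single convolution span adjacent
waves, e.g. a P wave and the following QRS complex.

Because the head is a global average pool, the network is
length-agnostic: the same weights accept a 600-sample median beat and a
5000-sample rhythm strip, and the parameter count is independent of the
input length.

### The parameter-count convention

A 12-lead ECG carries only 8 linearly independent signals: leads III,
aVR, aVL and aVF are fixed linear combinations of leads I and II. Under
the convention that the network consumes these 8 independent channels
(`independentLeads = TRUE`, the default for `fullArchitecture()`), and
counting every tensor a Keras-style "total params" summary would count —
convolution kernels and biases, batch-norm scale/offset *and* batch-norm
moving mean/variance — the construction yields exactly

```
conv1   8*64*8 + 64      =   4,160      bn1   4*64  =  256
conv2   64*32*3 + 32     =   6,176      bn2   4*32  =  128
8 x [ 32*64*50+64 + 4*64 + 64*32*50+32 + 4*32 ]  = 1,642,240
head    32 + 1           =      33
total                                            = 1,652,993
```

`countParameters()` reports this number by default and the trainable-only
count (1,651,265) with `includeNontrainable = FALSE`. Feeding all 12
leads instead adds the 4 derived leads times 64 filters times kernel 8 =
2,048 first-layer weights (1,655,041 total). Both counts are exposed so
the convention is auditable.

### Desk preset

`deskArchitecture()` (16/8 filters, kernel 15, two residual modules,
dropout 0.2) is the preset used for every training-based test and study
in this package: it preserves all structural properties of the full
network — residual skip additions, length agnosticism, batch-norm
scaling behavior, GradCAM layer semantics — at a size a single CPU can
train in minutes. It takes all 12 leads so attention maps resolve every
lead directly. The full network is built and inspected (parameter count,
forward pass, gradient access) but not trained here: its training is a
GPU-cluster workload, and none of the claims tested here depend on the
full width.

## Training protocol

Per measurement, one model is trained with the Nadam optimizer at
learning rate 0.0005, mean-squared error for regression and cross-entropy
for classification, under k-fold cross-validation (five folds at full
scale; two folds in the fast studies). Remaining optimizer constants
(beta1 0.9, beta2 0.999, eps 1e-8, schedule decay 0.004), batch size 32
and Glorot-uniform initialization are this package's documented defaults.
Median beats are augmented by a fresh random circular time shift in
[-40, +40] ms each epoch, so the network cannot exploit the fixed
manufacturer centering of median beats; rhythm strips are never shifted
(their alignment is already random). Interval labels are invariant to
the shift, which the test suite asserts.

Two numerical choices matter on short desk-scale runs:

* **Label standardization.** Regression labels are z-scored inside
  `fitNetwork()` and the scale folded back into the head weights
  afterwards, so a single learning rate works across labels spanning
  three orders of magnitude (ms vs uV) and predictions stay in original
  units.
* **Batch-norm recalibration.** Momentum-based running statistics
  (momentum 0.99) need thousands of updates to converge; desk runs take
  a few hundred. After training, `fitNetwork()` recomputes every
  batch-norm layer's moving mean/variance exactly from one pass over the
  training data (dropout off). Without this, evaluation-mode predictions
  are systematically mis-scaled relative to training-mode behavior and
  validation error is erratic even as training loss falls smoothly.

Inputs are fed in microvolts; the first batch normalization learns the
scale. This means amplitude tasks force the network to recover absolute
voltage information through the batch-norm affine parameters — visible
in attention maps as low-level attention to baseline segments.

## ECGradCAM

For feature maps $A^k(t)$ at a chosen convolutional layer and model
output $y$, channel weights are temporal averages $\alpha_k =
\overline{\partial y / \partial A^k}$ and the layer-level map is
$G(t) = \mathrm{ReLU}(\sum_k \alpha_k A^k(t))$ — GradCAM, applied to a
regression output exactly as to a class score. The default layer is the
final convolution of the last residual module, i.e. the features feeding
the prediction; `intermediateMaps()` walks all modules to show focus
narrowing.

Two conventions matter numerically:

* **Post-activation feature maps.** The feature maps taken for a
  convolution are its rectified unit output — the activation at the ReLU
  completing the layer's block (after batch norm and, for a module-final
  convolution, after the skip addition). Raw convolution outputs carry
  arbitrary per-channel offsets that smear constant background mass over
  the whole record; the rectified maps are sparse and localize. A bare
  convolution with no following ReLU is explained through its own
  output.
* **Predicted-class gradients.** For the single-logit classification
  head, maps explain the score of the *predicted* class (the negated
  logit when the prediction is class 0). Explaining the raw logit
  instead would rectify away precisely the evidence that drove a class-0
  prediction.

Leads are mixed by the first convolution, so a per-lead map needs a
defined attribution rule. This package distributes the upsampled
profile $G(t)$ over leads by normalized absolute input gradients:
$w_l(t) = |\partial y/\partial x_l(t)| \,/\, \sum_m |\partial y/\partial
x_m(t)|$ (uniform where all gradients vanish), giving
`perLead[l, t] = G(t) w_l(t)`. This rule was chosen because its lead
average provably reduces to $G$ itself, so the lead-averaged map is the
plain GradCAM profile regardless of the attribution; the test suite
verifies the reduction, and a plain input-saliency alternative is
available via `method = "saliency"`. Raw per-lead maps are averaged
first and normalized afterwards (`normalization = "unit"` maps the
maximum to 1; identically zero maps stay zero rather than erroring,
since a zero map is itself informative). The ReLU is kept for regression
outputs per GradCAM convention; `rectify = FALSE` exposes signed maps
for diagnostics, where negative contributions are meaningful.

`localizationScore()` turns maps into numbers: the share of
lead-averaged attention mass inside a wave window. A uniform map scores
the window's length fraction, so "attends to the QRS" is operationalized
as a score well above that fraction.

## Wave blanking

`blankWave()` removes a wave by replacing each lead's samples strictly
between the wave's onset and offset with the straight line joining the
onset and offset values — endpoints anchored at true signal values, no
padding margin — then re-quantizes, keeping the record integer-valued.
The operation is idempotent and bit-local outside the wave. The T-wave
interval runs from the symmetric T onset (`2*tPeak - tOff`) to `tOff`;
blanking on rhythm records is applied beat by beat (an extension beyond
the median-beat protocol). `blankingStudy()` evaluates every task model
on each blanked variant; a model that genuinely reads a wave degrades
drastically when that wave is interpolated away, which is the causal
counterpart of the attention-map evidence.

## The simulator

`generatePopulation()` emulates the statistical structure of the study
populations without any clinical data. One beat is a sum of Gaussian
deflections (an ECGSYN-style reduction) on a constant baseline; the 12
leads are scale projections of a single template with lead V5 fixed at
projection 1, making V5 the amplitude reference lead; the projections of
the derived limb leads obey the Einthoven/Goldberger relations so
records are internally consistent. Fiducials are analytic support
boundaries (`center +/- kSigma * width`, kSigma 2.5), so ground truth is
exact by construction rather than detected from the signal:

* intervals are fiducial arithmetic and round-trip exactly;
* the R, T and ST-component amplitudes are solved from a 3x3 linear
  system so the template evaluated at the sample-grid-snapped R peak, T
  peak and J point hits the requested amplitudes exactly;
* quantization (4.88 uV per LSB, rounding half away from zero for
  symmetry at negative voltages) bounds the record-vs-truth error by
  half an LSB per sample.

Measurement marginals are drawn from split-normal distributions that
reproduce each target's median and 5th/95th percentiles exactly in
expectation; infeasible draws (e.g. QT too close to QRS for the T wave
to clear the S wave) are rejected and redrawn. Records are 1.2-s median
beats (single beat, R peak at 560 ms) or 10-s rhythm strips (beats at RR
intervals with 3% fractional jitter and a recording start random with
respect to the beat phase, so heart rate is only estimable from multiple
beats).

The planted sex difference is morphological: class 1 has a steeper
R-wave downslope (right-hand R sigma scaled by 0.6 at `sexEffect = 1`),
a slightly earlier/deeper S wave, and a 6-ms shorter QRS duration.
Per-record lognormal variability on P amplitude, Q/S depth and downslope
width — plus 5-ms jitter on the S-timing shift — keeps every single
ground-truth feature an imperfect predictor. The design places most of
the class signal in the downslope width, which is deliberately *not* a
probe feature: a logistic regression on QRS duration alone reaches
~0.62 accuracy, adding R/S amplitudes and timings ~0.75, and the CNN,
which can read the downslope shape itself, more — reproducing the
qualitative ordering (network > rich probe > duration-only probe) that
motivates attention-driven feature discovery. At `sexEffect = 0` the
classes are identical in distribution and everything collapses to
chance.

What the simulator does **not** emulate: physiological correlations
between measurements (heart rate is sampled independently of QT, so
heart rate is unlearnable from a median beat here, unlike in real
cohorts), pathology morphologies (bundle branch block, AV block,
abnormal T waves), realistic noise spectra (noise is white at 5 uV SD
plus a slow sinusoidal wander, both free parameters — the source
protocol states no noise model), electrode placement variability, or
beat-to-beat morphology change. Tests passing on synthetic data
therefore validate the *machinery* (training, explanation, occlusion,
metrics), not clinical error magnitudes, which require the original
non-public cohorts and cluster-scale training and are explicitly out of
scope.

## Study sizes and seeds

The shipped studies use desk-scale problem sizes chosen to keep a full
run on one CPU within minutes while leaving the tested effects far from
threshold: 2000 median beats (1600 train / 400 validation) and 12 epochs
for the QRS-duration learning check; 6 epochs for amplitude tasks (which
converge much faster); 800 records and 15 epochs for the sex classifier;
batch size 64 for training throughput. All randomness — population
sampling, weight initialization, batching, augmentation — is derived
from explicit integer seeds, and training is bit-reproducible given the
seed (the test suite asserts this).

## Known limitations

* The NN engine is CPU-only and minimal by design: conv/BN/ReLU/
  pool/dropout/residual-add/GAP/dense, stride 1, no serialization of
  optimizer state. It exists to make the method self-contained, not to
  compete with a framework.
* Per-lead attribution is a defined contract, not a claim about the only
  correct decomposition; the lead-averaged map is attribution-invariant.
* `independentLeads = TRUE` nets attribute zero importance to derived
  leads (their information lives in leads I/II).
* Median-beat heart-rate regression is unlearnable on synthetic data by
  construction (see above) — a deliberate simulator simplification.
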