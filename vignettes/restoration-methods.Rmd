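---
title: "Physics-informed restoration of low-scan FTIR spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed restoration of low-scan FTIR spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

FTIR imaging of thin biological specimens trades acquisition speed against
spectral quality: a single interferometer scan per pixel is fast but the
resulting absorbance spectrum is dominated by high-frequency noise and by
low-frequency baseline drift from scattering and atmospheric variability,
while a 32-scan average is clean but roughly 32 times slower. `ftircascade`
implements and benchmarks three computational routes from a low-quality
(LQ, 1- or 8-scan) spectrum to a high-quality (HQ, 32-scan-like),
baseline-free spectrum:

* **SG + SNIP** — supervised-tuned Savitzky–Golay smoothing followed by
  SNIP baseline subtraction in the physical absorbance domain;
* **single network** — one 1D encoder–decoder regression network mapping
  the normalized LQ input directly to the normalized baseline-free target;
* **cascade** — two networks joined by a deterministic *physics bridge*:
  network 1 denoises (its target keeps the native baseline), the bridge
  inverts the normalization, subtracts the SNIP baseline in absorbance
  units and re-normalizes, and network 2 refines the result against the
  baseline-free target.

Everything runs on synthetic paired data: the real cell-line dataset behind
the published benchmark is not publicly available, so the package ships a
generator that reproduces the statistical structure the methods rely on.

# Preprocessing and the invertibility contract

Spectra are normalized in two steps: standard normal variate (SNV) per
spectrum, then a global min–max map fitted on *training rows only*. The
pipeline stores every statistic it uses (`normalization_state`) and is
exactly invertible (round-trip error below 1e-12 relative); held-out rows
that land outside [0, 1] are deliberately **not clipped**, because clipping
would destroy the invertibility the physics bridge depends on.

Numerical conventions fixed here (the literature leaves them open):

* SNV uses the sample standard deviation (denominator L−1).
* A constant spectrum has no SNV image and raises an error — except inside
  the bridge during training, where an untrained network can emit a
  constant row; there the degenerate row maps to the image of zero
  (`to_stage2(..., guard = TRUE)`) so optimization can continue.
* Stage-1 min–max bounds are fitted over the union of the SNV-transformed
  LQ inputs and HQ-with-baseline targets (the two operands of the stage-1
  loss share one scale); stage-2 bounds over the SNV-transformed
  baseline-free HQ training rows.

Cube preparation follows the standard imaging workflow: Otsu's threshold on
the integrated fingerprint (1000–1800 cm⁻¹) plus C–H stretching
(2800–3000 cm⁻¹) intensity selects foreground pixels; the mean spectrum of
the background pixels is subtracted from each foreground spectrum, which
removes water-vapor lines exactly insofar as they are shared across the
field of view; detector edges and the atmospheric CO₂ band
(2250–2401 cm⁻¹) are trimmed. The default retained edge range is
964–3800 cm⁻¹ (instrument-specific and configurable). After trimming the
axis is non-uniform, so peak positions are always read off the stored
wavenumber axis rather than reconstructed from the nominal interval.

# SNIP and Savitzky–Golay

`snip_baseline()` implements iterative geometric peak clipping with an
increasing half-window schedule m = 1..M: each sweep replaces every
interior point by the minimum of itself and the mean of its two m-distant
neighbours, all points updated simultaneously. Endpoints are held fixed.
The estimate is pointwise ≤ the input, so the corrected spectrum is
non-negative. The default M = 64 points corresponds to ~120 cm⁻¹ on a
2 cm⁻¹ grid, wider than the widest biological band half-width. The
log-log-sqrt compression transform used by some SNIP variants is available
behind `lls = TRUE` but off by default: SNV-inverted absorbance values sit
near (or below) zero, where the log transform misbehaves.

`sg_filter()` is a local least-squares polynomial filter. Interior points
use the closed-form convolution kernel; the first and last half-windows
evaluate the polynomial fitted to the first/last full window, so
polynomials up to the filter order are reproduced exactly at *every* point.
The fits run in centered, scaled coordinates because a raw Vandermonde
matrix for a 61-point window is numerically singular. Derivatives are
returned with respect to wavenumber (scaled by the sampling interval).

`tune_sg()` searches odd windows 5–61 × orders 2–5 (116 nominal
combinations) under the composite objective mean(MSE) + λ·mean(SAM) with
λ = 0.1 ("small" is all the literature specifies; λ is exposed). The
window 5 / order 5 corner is infeasible for a least-squares fit and is
evaluated with the order capped at 4. The search is a seeded uniform draw
over the grid rather than a Bayesian sampler — no TPE implementation exists
in the target environment, and the contract that matters (argmin over the
evaluated trials; full-budget search equals the exhaustive argmin) is
sampler-independent.

# The cascade and the physics bridge

The bridge (`bridge()`) is deterministic and has zero trainable parameters.
For each batch row it: (1) inverts the stage-1 min–max and SNV using that
row's stored statistics, recovering absorbance units; (2) subtracts the
SNIP baseline there — geometric clipping only makes sense on absolute
intensities; (3) re-normalizes into the stage-2 domain. It is part of the
forward graph during both training and inference; `predict_cascade()` can
bypass it only via an explicit ablation flag used by tests.

**Gradient treatment.** SNIP's min() operations are at best piecewise
differentiable, and the deep-supervision scheme already gives each network
its own exit loss. We therefore train the two networks decoupled: network 1
sees only the stage-1 MSE against the HQ-with-baseline target, network 2
only the stage-2 MSE against the baseline-free target, and no gradient
crosses the bridge (full stop-gradient). Tests assert the decoupling
structurally: changing the stage-2 target leaves network 1's trained
weights bit-identical.

**Networks.** No deep-learning framework exists in the target R
environment, so the 1D U-Nets are implemented directly over BLAS: im2col
convolutions, ReLU, stride-2 downsampling, nearest-neighbour upsampling,
skip concatenation, residual bottleneck blocks, optional sigmoid spectral
attention gates in the decoder, and an Adadelta optimizer with early
stopping on a seeded validation split (10% of training rows) and
best-weight restoration. Backpropagation is hand-derived and verified
against numerical gradients in the test suite.

A `residual = TRUE` network computes `output = input + f(input)` with a
zero-initialized output convolution, so it starts exactly at the identity.
For the cascade this has a useful consequence: an untrained residual
cascade reproduces the processed-input baseline exactly (identity →
bridge → identity), and training can only improve on it. The refinement
role of the second network is literally a residual correction, which this
parameterization encodes.

# The synthetic world

`synthetic_config()` states one fixed data-generating world:

| parameter | default | meaning |
|---|---|---|
| axis | 950–4000 cm⁻¹, 1584 points | instrument geometry (~1.93 cm⁻¹/step) |
| bands | 1080, 1240, 1400, 1545, 1655, 2850, 2925, 2960 cm⁻¹ | nucleic acid/carbohydrate, Amide III, COO⁻, Amide II, Amide I (Lorentzian), lipid CH₂/CH₃ |
| amplitudes | 0.08–0.5 a.u., ±30% jitter | single-cell absorbance scale |
| `sigma0` | 0.015 a.u. | single-scan white-noise sd (~3% of Amide I); N-scan noise is `sigma0/sqrt(N)` |
| baseline | quadratic, coef sd 0.08 a.u. + 0.04 a.u. oscillation, period 1500 cm⁻¹ | scattering/instrumental drift |
| water vapor | 12 lines, ≤0.004 a.u., in 1300–1900 / 3550–3900 cm⁻¹, shared per FOV | removable by mean-background subtraction precisely because it is spatially shared |
| scatter gain | log-uniform 0.8–1.25 per spectrum | what SNV is designed to remove |
| drift FOV | baseline ×3 + cubic term | out-of-distribution, non-averageable drift |

The LQ and HQ acquisitions of a pixel share the gain, baseline and
water-vapor component (back-to-back measurements of one spot) and differ
in noise; without that assumption the stage-1 task — predict the HQ
spectrum *with its baseline* from the LQ input — would be unlearnable in
principle. The generator returns every injected component, so tests can
assert the exact decomposition `measured − baseline − vapor − gain·clean =
noise`.

What the generator does **not** emulate: resonant Mie scattering and other
physically rigorous scattering models, detector nonlinearity, wavenumber
calibration error, and spatial correlation of the biological signal. A
green end-to-end test therefore establishes that the implementation
realizes the intended computational behaviour on data with the assumed
statistical structure — not that the method would attain any particular
accuracy on real cells.

# Evaluation

All methods are compared in a common domain: the stage-2-normalized,
baseline-free HQ reference. The *processed input baseline* is the raw LQ
spectrum passed through SNIP subtraction and stage-2 normalization, with no
learning; reported "reduction %" is `100·(M_LQ − M_method)/M_LQ` against
it. Leave-one-sample-out cross-validation holds out one field of view per
fold; every statistic (normalization bounds, SG parameters, network
weights) is derived from the training FOVs only — a property the tests
assert by perturbing held-out rows and checking the fitted statistics are
bit-identical. Per-spectrum metrics (RMSE, MAE, spectral angle in degrees
with the cosine clamped to [−1, 1], Pearson correlation) are summarized by
the FOV median, then mean ± sd across folds.

Peak-aware evaluation detects local maxima by topographic prominence
(threshold 0.02 in the normalized domain, at most 20 peaks retained by
prominence) and matches target to predicted peaks one-to-one within ±4
spectral samples. The matching is the exact maximum-cardinality,
minimum-total-distance assignment computed by a non-crossing dynamic
program over the index-sorted peaks — a greedy nearest-neighbour pass can
drop feasible pairs (targets {10, 14} and predictions {13, 17} under a
±4-sample tolerance leave greedy with one pair where two exist), and for
sorted points on a line the optimal assignment is non-crossing, so the DP
is exact and deterministic. Position errors are reported in cm⁻¹ off the
actual axis; height bias is signed (predicted − target).

Auxiliary diagnostics: the band-free stability metric (sd of the residual
after a straight-line fit in 2500–2600 cm⁻¹), whose scan-count ratios
should follow 1/√N under white noise; the per-spectrum difficulty score
(z-scored RMSE + spectral angle + residual-noise proxy after SG(11, 3)
smoothing + low-frequency Fourier power fraction over bins 1–8 above DC —
cutoffs the literature does not fix; both are exposed); and the
second-derivative view (SG window 17, order 3, derivative 2).

# Desk-scale choices

The reference training protocol — Adadelta, learning rate 0.05, batch 32,
early-stopping patience 30, up to 5000 epochs — is the `train_config()`
default. It is not attainable inside this package's CPU budget (pure-R
networks, one core, minutes not hours), so the end-to-end tests and the
default pipeline scale *runtime* parameters down while keeping the
synthetic world fixed:

* fingerprint-region axis (950–1800 cm⁻¹, 128 points) instead of the full
  1584-point axis, with the SNIP half-window scaled to the same ~120 cm⁻¹;
* 70 training epochs with a unit Adadelta learning rate — Adadelta's
  accumulator-driven steps start near `lr·sqrt(eps)`, which is why the
  reference protocol needs thousands of epochs; a larger multiplier
  reaches the same regime within the epoch budget;
* desk-scale architecture: depth 2, 8 base channels, kernel 5, one
  residual block, attention gates off, residual input skip. The small
  receptive field matters: a stage-1 denoiser with a wide receptive field
  learns partly global corrections that do not transfer to the
  out-of-distribution drift baselines, while a local filter does.
  `unet_config()`'s defaults (depth 3, 16 channels, kernel 9, attention
  on) remain the larger reference preset.

Under these settings the package reproduces the qualitative hierarchy the
cascade is designed for — on the drift-affected held-out FOV the cascade
improves on the processed input and outperforms the
identically-configured end-to-end network — without asserting any dataset-specific
magnitude from the published benchmark, whose data are not available.

# Known limitations

* The networks are deliberately small; parameter counts and wall-clock
  comparisons of the published architectures are out of scope.
* The SG search is a seeded uniform grid draw, not TPE.
* Peak matching differs from a greedy pass when greedy is suboptimal; this
  is intentional (see above).
* The synthetic drift family is a stand-in: no quantitative drift model is
  available for the real drift-affected sample beyond its noise-ratio
  diagnostics.
* Mie-scattering correction (e.g. EMSC-based) is explicitly not attempted.
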