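---
title: "Spatial-frequency reliance and adversarial robustness: methods"
author: "sfreliance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial-frequency reliance and adversarial robustness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(sfreliance)
```

This vignette is the package's account of its science: the models it
implements, the parameters that matter, the numerical decisions taken where
the methods leave room, and what the synthetic experiments do and do not
establish.

## 1. Frequency geometry

All frequency-domain objects live on the grid of the 2-D discrete Fourier
transform, indexed by signed integer frequencies $(u, v)$ with radial
frequency $r = \sqrt{u^2 + v^2}$ in cycles per image (cpi). The highest
resolvable axis frequency is $\min(H, W)/2$ — 112 cpi at the 224-pixel
ImageNet-standard resolution, 32 cpi on the 64-pixel desk-scale grid.
Everything is stored in the *unshifted* layout of `stats::fft()` (DC at
`[1, 1]`), so masks multiply `fft()` output elementwise without any
recentering step. For non-square images the signed indices are used directly;
"cpi" is then cycles per axis length (a documented limitation — all shipped
analyses use square grids).

Octave bands partition $(0, \mathrm{Nyquist})$ as
$(0, 3.5), [3.5, 7), [7, 14), [14, 28), [28, 56), [56, 112)$ on the 224
grid. The two lowest octaves are merged because Fourier coefficients are
sparse at small radii; every band above 3.5 cpi spans exactly one octave.
$[28, 56)$ is the mid-frequency "human channel". On other grids the edges
scale with Nyquist/112, so the 64-pixel analog is
$(0,1), [1,2), [2,4), [4,8), [8,16), [16,32)$ with $[8, 16)$ playing the
human-channel role. Bands are half-open; the Nyquist bin itself sits outside
the partition, which is why per-band shifts sum to zero only when no retained
power lies in that bin.

## 2. Masks

Three families, all radially symmetric with weights in $[0, 1]$:

* **Gaussian log-frequency band-pass** (`gaussianLogFreqMask()`):
  $M(f) \propto \exp\!\left(-(\log_2 f - \mu)^2 / 2\sigma^2\right)$,
  unit-peak normalized. Defaults $\mu = 4.5$ octaves, $\sigma = 0.4246$
  octaves (the human-channel parameterization). Note an internal tension
  these parameters carry: $2^{4.5} \approx 22.6$ cpi peaks in the $[14, 28)$
  octave, not in $[28, 56)$. The formula is implemented literally and $\mu$
  is exposed in the interface; the package does not silently "correct"
  either the parameter or the band.
* **Extreme-LSF**: the same Gaussian centered at the geometric mean of 1.75
  and 3.5 cpi ($\mu = \log_2\sqrt{1.75 \times 3.5}$) with a hard pass
  (weight 1) at all frequencies at or below the center. No bandwidth is
  prescribed for this condition; the default reuses $\sigma = 0.4246$ for a
  matched rolloff sharpness, and the parameter is configurable.
* **Blur-magnitude low-pass** (`blurMagnitudeMask()`): the unit-peak DFT
  magnitude of a discretized isotropic Gaussian kernel ($\sigma$ in pixels;
  1.5 for the fixed-σ condition, mixtures over $\{1,2,3,4,5\}$ or
  $\{1,2,4,8\}$ for the mixed-σ conditions with the published sampling
  probabilities). Discretization: truncation at radius $\lceil 4\sigma
  \rceil$ (odd support), unit-sum normalization, zero-padding with the
  kernel center at the origin. The square truncation makes these masks
  radial only up to $\sim 10^{-4}$; the analytic masks are radial to
  machine precision.

**DC policy.** $\log_2 0$ is undefined, so DC is excluded from the Gaussian
formula and assigned by type: 1 for low-pass-style masks (hard-pass
extreme-LSF, blur-derived), 0 for pure band-passes, overridable via
`dcWeight`. This only matters for `filterAugment()` (whether mean luminance
survives filtering); the scrambling operator preserves DC phase regardless.

Inverse masks are the exact complement $1 - M$ and are used to concentrate
scrambling *inside* a band for necessity checks.

## 3. Soft phase scrambling

`phaseScramble()` blends original and random phasors per coefficient,
weighted by the mask, and reconstructs each channel from its original
amplitude spectrum. Consequences that the test suite verifies directly:

* per-channel amplitude spectra — hence total spectral energy (Parseval) —
  are preserved exactly before range handling;
* $M \equiv 1$ reproduces the input, $M \equiv 0$ fully scrambles;
* one random phase field per image per augmentation event, shared across
  the three color channels (color coherence), Hermitian-antisymmetric so
  reconstructions are real.

Numerical decisions:

* **Degenerate blend.** At $M = 0.5$ with antipodal phasors the blend is the
  angle of a numerically zero vector; when the blend magnitude falls below
  $10^{-12}$ the original phase is kept — a deterministic, bias-free
  tie-break.
* **Out-of-range pixels.** Reconstruction can leave $[0, 1]$ slightly. The
  default is a hard clamp (bit-reproducible); a smooth compressor (`clip =
  "tanh"`, identity on $[s, 1-s]$ with $s = 0.05$, tanh saturation at the
  violated boundary) is available, and `clip = "none"` exposes the raw
  reconstruction for fidelity checks.
* **Order of operations.** Scrambling operates on raw $[0,1]$ pixels before
  any model normalization, and in a training pipeline it should follow
  geometric augmentations so the mask grid matches the final resolution.

The augmentation policy replaces each training image independently with
probability $p$ (0.3 weak, 0.5 strong); mixed-σ conditions use the published
per-width probabilities directly as replacement mass (weak sums to 0.3063,
strong to 0.8), each replaced image receiving exactly one mask. The printed
strong-variant probabilities are followed verbatim rather than capped at
0.5. Evaluation data never passes through a policy.

## 4. Attacks

`pgdAttack()` maximizes cross-entropy under an $\ell_\infty$ (or $\ell_2$)
bound by projected gradient ascent: uniform random initialization in the
$\varepsilon$-ball, $\mathrm{sign}$-gradient steps (gradient-normalized for
$\ell_2$), projection onto the ball *and* onto the valid pixel range after
every step, no early stopping. Defaults where the method leaves them open:
10 steps, step size $\varepsilon/4$ ($2.5\varepsilon/\mathrm{steps}$ for
$\ell_2$), all configurable. `sign(0) = 0`, so zero-gradient models yield no
ascent. Success means: correct top-1 on the clean input, wrong on the
perturbed one; only successful perturbations feed the spectral probe.
Correctness anchors: on a linear model, 10 steps at $\varepsilon/4$ provably
reach the closed-form worst case $\varepsilon \cdot \mathrm{sign}(w)$, and
FGSM coincides with single-step zero-init PGD; both are asserted in the
tests.

## 5. The spectral probe

Successful perturbations are Fourier-transformed per channel and their
squared magnitudes averaged; `radialProfile()` aggregates power into
unit-width bins centered at integer cpi ($[k - 0.5, k + 0.5)$), removes DC,
discards coefficients above Nyquist (grid corners reach
$\sqrt{2}\,\mathrm{Nyquist}$ but are unresolvable along axes), and
normalizes to proportions. Band AUC is the discrete sum of bin proportions
in the band — integration is over raw bins, not a log-frequency axis, a
choice the band statistics document (the alternative would reweight octaves
by their widths, not change signs or rankings of shifts).

Mean profiles carry percentile 95% bootstrap intervals across perturbations
(10,000 resamples by default; the desk-scale harness uses 1,000 where the
interval is not the quantity under test). Spearman correlations between
per-band shifts and robustness gains use average ranks and the large-sample
$t$ approximation; an exact permutation null is available behind a flag for
$n \le 10$ (the scale at which such model comparisons are actually run).

## 6. Synthetic data and the fixture classifier

`generateBandCodedDataset()` plants the ground truth the probe must recover:
per class, a fixed random template whose Fourier support is confined to the
informative band (independent fields per color channel, unit pixel
variance); images are $0.5 + s\,\mathrm{template} + \mathrm{noise}$ with
white Gaussian noise (`noiseSd = 0.06`), clamped to $[0,1]$ (the clamp
touches a negligible pixel fraction at these scales). Because templates are
fixed per class, *phase* structure carries identity — amplitude spectra are
class-uninformative — mirroring the premise that phase carries image
structure. The signal scale is set so that in-band signal power equals `snr`
times the out-of-band noise power. The broadband baseline condition uses
band $(0, \mathrm{Nyquist})$, leaving the unresolvable corners as the
out-of-band reference so the same definition applies.

**Why `snr = 0.1`.** The probe needs models that are simultaneously accurate
and attackable at the benchmark $\varepsilon = 4/255$, which is the regime
full-scale classifiers occupy. For a template-matching decision rule the
flip condition is roughly
$\varepsilon \|\nabla m\|_1 \gtrsim \mathrm{margin}$, and both sides scale
so that attackability depends on $\varepsilon / s$ with
$s = \mathrm{noiseSd}\sqrt{\mathrm{snr} \cdot f_\mathrm{out}}$. At
`snr = 0.1` desk-scale models hold clean accuracy near 1.0 while PGD flips a
substantial fraction of evaluation predictions in every band condition; at
`snr` around 0.5 and above the margin exceeds the $\ell_\infty$ budget and
the probe starves (few or no successful perturbations). The value was fixed
once from this analysis; the high-`snr` regime remains available and is used
where separability itself is the property under test.

**The fixture classifier** is a one-hidden-layer ReLU network on flattened
pixels (default 8 hidden units at 64×64×3, just under 100k parameters)
written in plain matrix algebra, with exact analytic input gradients and the
hidden layer exposed as the penultimate representation. Two design points:

* Inputs are normalized by per-channel mean subtraction inside the model —
  the analog of dataset normalization. Besides standardizing scale, this
  makes the network invariant to uniform luminance shifts; without it the
  trained fixture acquires a strong DC sensitivity and $\ell_\infty$
  attacks degenerate into near-constant luminance offsets, which say
  nothing about spatial-frequency reliance.
* Training is minibatch SGD with momentum 0.9, weight decay $10^{-4}$,
  label smoothing 0.1, and a single step learning-rate decay — the
  full-scale recipe's structure at desk scale (30 epochs, batch 64, lr 0.1
  decayed ×0.1 at epoch 20). The full-scale recipe itself (60 epochs, batch
  1024, decay at 45, five seeds, 224-pixel inputs, a deep residual
  backbone) ships as the `"fullscale"` configuration preset for reference; the
  desk preset is the executable default.

`generateReferenceResponses()` stands in for measured response patterns
(e.g. voxels): features are centered, globally rescaled to unit RMS (both
geometry-preserving), passed through a Haar-random partial isometry to
`nUnits` units, and perturbed with Gaussian noise. With at least as many
units as feature dimensions and zero noise, pairwise distances are preserved
exactly and the RDM rank-correlates at 1 with the source; `noiseSd` reads as
a noise-to-signal ratio. An earlier iid-Gaussian readout was replaced by the
isometry because projection-induced anisotropy added geometry distortion
that confounded the noise manipulation.

## 7. Experiment harness and problem sizes

`runBandRecoveryProbe()` executes the full chain — generate, train (band
models and a broadband baseline per seed), attack, filter, profile, band
statistics — and reports, per (band, seed), whether the octave containing
the informative band received the largest positive power shift. The shipped
analyses use 4 classes × 125 images at 64×64 (100 training, 25 evaluation
per class), two target bands ($[2,4)$ and $[8,16)$ cpi), three training
seeds, PGD with 10 steps at $4/255$; the RSA experiment uses two
independently initialized fixtures on the same data, 500-image RDMs, 32
reference units, 20 seeded trials per noise level over
$\{0, 0.5, 1, 2\}$. These sizes keep a full probe run in the low minutes on
a single CPU while leaving the recovery outcomes far from their decision
thresholds.

Seeding: every stochastic element (weight init, data order, augmentation
draws, attack init, bootstrap, reference generation) takes an explicit seed,
and library functions restore the caller's RNG state, so identical calls are
bit-reproducible and independent stages use independent substreams. Two
conditions run with the same seed share their weight initialization, making
matched comparisons across augmentation conditions meaningful.

## 8. What the synthetic experiments do and do not show

The generator produces stationary Gaussian textures with an exactly
band-limited class signal and white background noise. That gives the probe
an unambiguous ground truth, but real images differ in every inessential
respect: $1/f$ amplitude spectra, nonstationary structure, object shape,
class information spread across bands, label noise. Passing the recovery
suite therefore establishes that the *pipeline* — augmentation, attack,
spectral analysis, band statistics, RSA — is implemented correctly and is
sensitive enough to detect planted band structure through a trained model;
it does not by itself establish any claim about where natural-image-trained
networks place their reliance, nor reproduce full-scale robustness or
brain-similarity values, which require the large-scale datasets and trained
models those analyses consume.

Known limitations: the fixture is a shallow fully connected network, not a
convolutional hierarchy (no weight sharing, no spatial locality prior), so
absolute robustness numbers are not comparable to deep backbones; blur-mask
radial symmetry is approximate at the $10^{-4}$ level; non-square grids use
index units rather than true cpi; and the $\ell_2$ attack path, while
implemented and bound-checked, is exercised at desk scale only.
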