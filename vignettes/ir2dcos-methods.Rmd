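---
title: "From 1-D infrared spectra to species calls: 2D-COS images and a residual network"
author: "ir2dcos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From 1-D infrared spectra to species calls: 2D-COS images and a residual network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ir2dcos)
```

## The problem

Closely related medicinal-plant species — gentian and its relatives are the
motivating case — have mid-infrared absorbance spectra whose peak *positions*
are nearly identical; what differs between species is mostly peak
*intensity*.  A 1-D spectrum therefore carries the discriminative signal in a
subtle, highly collinear form.  Generalized two-dimensional correlation
spectroscopy (2D-COS) spreads a perturbation-induced series of spectra over
two wavenumber axes, turning intensity covariation into spatial structure
that an image classifier can exploit.  `ir2dcos` implements that chain end
to end: spectra in, correlation-map images out, species probabilities from a
small residual convolutional network.

## The correlation-map model

A perturbation applied in $n$ discrete steps turns one spectrum $y(\nu)$
into a series $y(\nu, t_i)$, $i = 1 \dots n$.  The *dynamic spectrum*
subtracts the per-wavenumber mean (the reference):

$$\tilde y(\nu, t_i) = y(\nu, t_i) - \bar y(\nu).$$

The three maps over a wavenumber grid are

$$\Phi(\nu_1, \nu_2) = \tfrac{1}{n-1}\, \tilde y(\nu_1)^\top \tilde y(\nu_2),
\qquad
\Psi(\nu_1, \nu_2) = \tfrac{1}{n-1}\, \tilde y(\nu_1)^\top N\, \tilde y(\nu_2),
\qquad
I = \Phi \odot \Psi,$$

where $N$ is the discrete Hilbert–Noda matrix, $N_{jk} = 0$ for $j = k$ and
$1/(\pi(k-j))$ otherwise, implemented exactly in that closed form (not via
FFT-based Hilbert transforms).  $\Phi$ is symmetric with non-negative
auto-peaks on its diagonal and is positive semidefinite by construction;
$\Psi$ is antisymmetric with a zero diagonal; $I$ is antisymmetric.  These
algebraic identities are asserted in the test suite against brute-force
double-loop oracles.

### The sinusoidal perturbation

The perturbation is a deterministic sinusoidal intensity modulation.  Step
$i$ at wavenumber $\nu$ multiplies the parent spectrum by
$1 + A \sin\!\big(2\pi c\,(i-1)/n + g\,(\nu - \nu_{\mathrm{ref}})\big)$
with modulation depth $A$, cycle count $c$ and phase gradient $g$ (radians
per cm$^{-1}$); an additive variant is available by flag.  The
multiplicative form keeps dynamic amplitude proportional to local
absorbance, so strong bands dominate the auto-peaks, consistent with 2D-COS
practice.  Defaults: $n = 16$, $A = 0.05$, $c = 1$, $g = 0$.

Two consequences of this parameterization matter and are easy to miss:

* **In-phase modulation gives $\Psi \equiv 0$.**  With $g = 0$ all
  wavenumbers oscillate in phase, there is no quadrature component, and the
  asynchronous map vanishes identically (up to floating-point roundoff).
  This is a genuine property of 2D-COS, not an implementation artifact.  A
  nonzero $g$ is required for informative asynchronous and integrative maps.
* **With a deterministic perturbation, $\Psi$ adds no class information.**
  For any fixed $g$, both maps reduce to $s(\nu_1)s(\nu_2)$ times a fixed,
  class-independent trigonometric mask.  In real perturbation series
  (temperature ramps, concentration series) asynchronous features are
  noise-sensitive, which is why synchronous maps tend to classify better;
  a synthetic emulation with a deterministic perturbation cannot reproduce
  that mechanism, only the degenerate in-phase case.  This is a known
  limitation of the simulation, discussed below under what the tests do and
  do not show.

### The phase law, checked as ratios

For two pure sinusoids with amplitudes $A_1, A_2$ and phase offset
$\Delta\varphi$, densely sampled over whole cycles, the cross-peaks obey
$\Phi_{12} \propto A_1 A_2 \cos\Delta\varphi$ and
$\Psi_{12} \propto A_1 A_2 \sin\Delta\varphi$.  The proportionality constant
of the asynchronous law is *not* $n/(2(n-1))$ in finite samples: the
truncated Hilbert–Noda kernel carries a systematic amplitude deficit
(about 13% at $n = 64$, decaying only slowly with $n$ — part window
truncation, part the $1 - \omega/\pi$ response of the discrete kernel).
The *ratios* $\Psi(\Delta\varphi)/\Psi(\pi/2) = \sin\Delta\varphi$ and
$\Phi(\Delta\varphi)/\Phi(0) = \cos\Delta\varphi$, however, are exact to
machine precision (the in-phase component is annihilated by antisymmetry:
$s^\top N s = 0$).  The test suite therefore checks the law in ratio form,
which is the form in which it is exact.

## The synthetic-data generator

The study data (173 field samples of seven species) are not deposited, so
the package ships a generator that emulates their statistical structure:

* ten shared peak positions at the characteristic fingerprint wavenumbers
  3292, 2922, 2849, 1732, 1610, 1510, 1422, 1371, 1030 and 920 cm$^{-1}$
  (O–H stretch, methylene C–H stretches, ester C=O, terpenoid C–C, lignin
  ring modes, methylene deformation, saccharide C–OH, C–H bending), with
  Gaussian line shapes by default (Lorentzian available; the line shape of
  the real material is not constrained by anything we model);
* class identity expressed *only* through peak amplitudes: each class
  multiplies the base amplitudes by log-normal factors with log-sd
  `amplitudeSpread` (default 0.25, the package's definition of "moderate"
  separation; an optional center jitter exists but is off by default);
* per-sample replicate scatter as a multiplicative amplitude jitter
  (log-sd `sampleJitter = 0.03`) plus i.i.d. Gaussian noise
  (`noiseSd = 0.005` a.u.) and a small linear baseline drift
  (slope within $\pm 2\times 10^{-5}$ a.u./cm$^{-1}$);
* the spectrometer-style grid 4010 → 365 cm$^{-1}$ at 4 cm$^{-1}$, stored
  descending, final partial step dropped (912 points ending at 366).

The intra-class variance values are choices, not measurements: nothing in
the source material quantifies replicate scatter, so these knobs encode what
a practitioner would call realistic for dried, powdered plant material on a
bench FT-IR.  What the generator deliberately does **not** model: real
chemical covariance between bands, water-vapor and CO$_2$ interference,
scattering baselines, instrument drift between sessions, or any actual
gentian chemistry.  Passing tests on these data therefore demonstrate that
the pipeline's machinery is correct and that the method can recover
amplitude-structured classes; they do not certify performance on real
herbarium samples.

All randomness flows through explicit integer seeds; no function touches
the global RNG state.  Identical arguments give bit-identical datasets,
which the tests assert through on-disk serialization.

## Preprocessing and bands

Spectra are normalized per sample, min–max to $[0, 1]$ by default (the
choice is recorded in the set's metadata; unit-norm scaling is the
alternative, and normalization precedes averaging where averages are
taken).  Four characteristic bands ship as presets — `bandA` 3500–3000,
`bandB` 3000–2750, `bandC` 1750–1100, `bandD` 1100–400 cm$^{-1}$ — plus
`full`; band bounds are inclusive at both ends.  The fused configuration
concatenates the four band extractions into one vector *before* the 2D-COS
expansion (the alternative, averaging per-band maps, was considered and not
adopted: concatenation keeps a single coherent map per sample and a single
image geometry).  A wavenumber shared by two adjacent bands is kept once so
the fused grid stays strictly monotonic.

## Rendering

Maps are rendered deterministically: values are scaled to $[-1, 1]$ by the
map's maximal absolute entry (`symmetric_max`, so zero always lands on the
midpoint of a diverging palette and rescaling a map by a positive constant
leaves the image unchanged), optionally quantized into filled-contour
levels, bilinearly resampled to a square raster (the row and column
mappings are identical, so resampling commutes with transposition and
symmetric maps give transpose-symmetric images), and passed through a
256-entry palette.  No axes or text are drawn — the classifier sees data
pixels only.

One numerical guard: when a family of maps is rendered together, a map
whose magnitude is eight orders below its siblings (the asynchronous map of
an in-phase perturbation is $\sim 10^{-17}$ where the synchronous map is
$\sim 10^{-3}$) is rendered flat rather than having its roundoff noise
amplified to full contrast by the per-map rescaling.

## Sample-set partitioning

The split mirrors standard chemometric practice: a stratified random 10%
external-validation holdout first (per-class `round(fraction * size)`, at
least one sample when the class has two or more; singleton classes stay in
the model set with a warning), then a single global Kennard–Stone pass over
the remaining model set selects the training portion —
`floor(7/9 * modelSize)` samples, i.e. 70% of the total — and the remainder
is the test set.  Kennard–Stone starts from the pair at maximal Euclidean
distance and greedily adds the point maximizing its minimal distance to the
selected set, ties broken by lowest index; distances are computed on the
min–max-normalized 1-D spectra, since the split happens before image
conversion.  The algorithm is deterministic; only the holdout consumes the
seed.  A per-class Kennard–Stone mode exists for users who want stratified
coverage, but the global pass is the default.

## The classifier

The network is the small residual pattern: stem convolution (7×7, stride 2,
pad 3) → batch normalization → ReLU → four stages → global average pooling
→ fully connected layer.  Each stage opens with one *convolution block*
(projection shortcut, 1×1 convolution; stride 2 except in stage 1) and
continues with *identity blocks* (identity shortcut); every block computes
$H(x) = F(x) + \mathrm{shortcut}(x)$ with two 3×3 convolutions and batch
normalization in $F$.  The default stage plan 1, 2, 2, 1 yields exactly 4
convolution and 6 identity blocks; the stem width (8) differs from stage 1's
width (16) so that every stage opener genuinely changes dimensions.  Spatial
sizes throughout obey $n_{out} = \lfloor (n_{in} + 2p - f)/s \rfloor + 1$,
and the test suite audits every convolution in the built graph against that
formula.  Defaults: input 224 px, stage widths 16/32/64/128 (the
experiments below use a slimmer 32 px, 8/16/32/64 instance of the same
family — same block structure, smaller problem size).

Training is stochastic gradient descent with momentum 0.9, initial learning
rate 0.01, weight decay $10^{-4}$, batch size 16, cross-entropy loss, 40
epochs.  Three engineering choices stabilize the small-data regime:

* **Step learning-rate schedule** — the rate is divided by 10 at 50% and
  75% of the epochs (the canonical recipe for this architecture family); a
  constant schedule remains available.
* **Precise batch-normalization statistics** — running statistics are
  re-estimated on the full training set after every epoch, so inference
  always uses statistics consistent with the current weights.  Without
  this, evaluation accuracy oscillated wildly between epochs while training
  loss was already below 0.05: the running averages lagged the fast-moving
  weights.
* **Optimal-model selection** — parameters are checkpointed at the epoch
  with the best test accuracy (earliest on ties) and restored before the
  single external validation, so the external score measures the selected
  model.  The per-epoch history still records every epoch, and both the
  selected and the final-epoch test accuracies are reported.

Augmentation defaults to a random resized crop (0.9–1.0 scale) plus a
transpose flip; the transpose is label-preserving only for the symmetric
synchronous maps and is switched off automatically when the pipeline trains
on asynchronous or integrative images.  All training randomness derives
from the configuration seed, so runs are bit-reproducible on one device
(cross-hardware bit-identity is not promised — BLAS differences can change
floating-point sums).

The engine itself (im2col + GEMM convolutions with full backpropagation,
batch normalization, global average pooling, SGD) is compiled Armadillo
code with an R orchestration layer, and its gradients were verified against
central finite differences at $\sim 10^{-9}$ relative error during
development; the shipped tests assert the observable contracts (shape
audit, residual identity, zero-learning-rate invariance, perfect fit of a
separable toy set, seed reproducibility).

## Problem sizes and what the experiments show

The package's reference experiment — also what `scripts/acceptance.R`
reruns — is deliberately desk-scale: 7 classes × 25 synthetic samples,
band 1750–1100 cm$^{-1}$, 32 px renderings, the slim network, 40 epochs,
roughly a minute per training run on one CPU core.  Under those conditions
the synchronous-map pipeline reaches test and external accuracies above
0.9, and the asynchronous-map pipeline sits near chance — consistent with
the qualitative ordering reported for the method on real data, though for
the degenerate reason discussed above (in-phase perturbation ⇒ featureless
asynchronous images).  A nearest-centroid baseline on the same images also
separates these synthetic classes, so the experiment validates pipeline
correctness and training stability rather than claiming the network is
necessary for data this clean.

## Numerical choices and degenerate inputs, collected

* Grid: stored descending; partial final step dropped; band bounds
  inclusive both ends; empty band intersection is an error.
* Min–max normalization of a constant spectrum is an error (zero range), as
  is unit-norm scaling of an all-zero spectrum.
* `hilbertNoda(n)` requires $n \ge 2$; dynamic spectra require at least two
  steps (the $1/(n-1)$ factor).
* Kennard–Stone ties break to the lowest index; duplicate rows are allowed.
* Rendering a zero (or roundoff-level, under `zeroFloor`) matrix gives a
  uniform midpoint image; `symmetric_max` makes rendering scale-invariant.
* Image files refuse silent overwrite without `force = TRUE`.
* Identity blocks reject channel or stride changes at construction.

## Known limitations

* The synthetic generator's independence assumptions (independent per-peak
  multipliers, white noise) make its classes easier than real biological
  replicates; reported synthetic accuracies are upper bounds in spirit.
* The deterministic sinusoidal perturbation cannot give asynchronous maps
  an independent information channel (see above), so comparisons between
  map types on synthetic data probe the degenerate case only.
* Single-device reproducibility only; no GPU path; the compiled engine is
  single-threaded by design so results do not depend on thread count.
* No baseline correction, smoothing, derivative spectra or atmospheric
  compensation — deliberately out of scope for this pipeline.
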