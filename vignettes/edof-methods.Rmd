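---
title: "Wavefront-coded extended depth of field: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavefront-coded extended depth of field: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edofscope)
```

## The problem

A miniaturized microscope with a high numerical aperture (NA 0.16, f = 1 mm,
6 mm conjugate distance) resolves subcellular detail (~3 um) but pays for it
with a depth of field of only a few tens of micrometers. Thick or tilted
samples — freshly resected tissue, whole insects, skin — are therefore mostly
out of focus in any single capture. Wavefront coding sidesteps the trade-off:
a cubic phase plate in the pupil spreads the PSF into a form that barely
changes over a ±150 um defocus range, and a deconvolution or learned
restoration step recovers a sharp, all-in-focus image from the coded capture.

`edofscope` implements the computational chain of such a system on purely
synthetic data: pupil-plane PSF/MTF simulation and modulation-strength
selection, low-rank shift-variant image formation, simulation-supervised
training-pair synthesis, classical restoration, and the restoration-network
family with exact parameter accounting.

## Optical model

PSFs come from the standard incoherent pupil-function model

$$\mathrm{PSF}(z, u, v) \propto \left| \mathcal{F}\left\{ A(\rho)\,
e^{i[\phi_{\mathrm{cubic}} + \phi_{\mathrm{defocus}}(z) +
\phi_{\mathrm{field}}(u, v)]} \right\} \right|^2,$$

with defocus phase $(2\pi/\lambda)\, z \, (\mathrm{NA}^2/2)\, \rho^2$ on the
normalized pupil radius $\rho$ and the cubic-mask phase
$2\pi (n-1)\, \alpha (x^3 + y^3)/\lambda$ evaluated on physical mask
coordinates ($n = 1.5$). A full diffraction treatment inside a lens-design
program is neither portable nor necessary for the quantities this package
computes; the pupil model preserves every qualitative contract the tests
assert (normalization, symmetry, MTF behavior, depth-invariance ordering).

Shift variance in the real instrument comes from the multi-element lens. The
model emulates it with parametric field aberrations — wavefront tilt (1.5
waves at unit field) and coma (0.4 waves) scaling linearly with the
normalized field vector. These are configuration values, deliberately small
but nonzero so that the factorization and forward-model stages face genuinely
nonuniform PSFs.

Key defaults, chosen once on physical grounds:

* **object pixel pitch 2.0 um** — slightly coarser than the 1.5 um that would
  Nyquist-sample the 3 um optical resolution, typical for a miniaturized
  sensor at this magnification; it sets the sensor Nyquist frequency
  (250 cycles/mm) at which the design constraint is enforced;
* **mask aperture semi-diameter 0.5 mm** — the front aperture of the lens
  group, which maps the swept modulation strengths (0.005–0.075 mm^-2) to
  roughly 1–9 waves of cubic phase per axis;
* **pupil grid 256, pad factor 2** — fine enough that the largest swept phase
  gradient stays below the sampling (anti-aliasing) bound; a guard raises a
  hard error rather than silently aliasing when a configuration violates it;
* **depth range ±150 um in 10 um steps** — the design scan range of the
  focal-stack protocol.

Simulated PSFs are integrated onto the sensor grid by exact area-overlap
binning (the sensor pitch need not be a multiple of the simulation pitch)
and cropped to an odd support, then renormalized to unit sum.

## Modulation-strength selection

The sweep enumerates 15 candidates, $\alpha = 0.005$ to $0.075$ in steps of
$0.005$. Each candidate is scored by a Fisher-information merit — the
discrete squared defocus derivative of the MTF, summed over all frequency
bins up to the sensor Nyquist frequency and over adjacent depth planes —
which is zero iff the MTF is perfectly defocus-invariant. Feasibility
requires the Nyquist-frequency MTF to stay at or above 0.1 at every design
depth, so that no spatial frequency below Nyquist is irrecoverably lost; the
selected design minimizes the Fisher merit among feasible candidates. MTF
profiles are taken along both axes and combined by pointwise minimum, a
conservative choice for the strongly non-isotropic cubic-phase MTF. On the
default model exactly one candidate is feasible, $\alpha = 0.03$, with a
minimum Nyquist MTF of about 0.106; the uncoded system falls to about 0.005
at the depth extremes.

The absolute scale of $\alpha$ depends on the pupil normalization, which the
original design protocol does not pin down; the agreement of the selected
value with the protocol's choice should be read as consistency of the
selection logic under this package's stated conventions, not as a derived
physical constant.

## Low-rank shift-variant image formation

The shift-variant system is calibrated at M field points per depth (a
regular side-by-side grid, up to 7 x 7 = 49). The vectorized PSF matrix
$P \in \mathbb{R}^{ab \times M}$ is factorized as $P \approx H W$ with
non-negative bases $H$ and coefficients $W$ by hierarchical alternating
least squares (HALS): cyclic exact coordinate updates clipped at zero, dead
components re-seeded from the worst-approximated column (coefficients reset
to zero first, which preserves the monotone non-increasing objective).
Initialization is uniform random under a caller-supplied seed; the sweep is
iteration-capped rather than tolerance-terminated so runs are reproducible.

Color handling follows the channel-uniform convention: one coefficient
matrix W is fit jointly against the channel-stacked matrix
$[P_r; P_g; P_b]$ with channel-stacked bases, which suppresses color
fringing that independent per-channel coefficient maps would cause. The
per-channel mode remains available and strictly generalizes it.

The rank default is N = 9 for a 3 x 3 calibration grid (N = M, which
round-trips the calibrated PSFs to ~1e-5 of peak); the `factorize` CLI
command prints a residual-vs-rank elbow report for choosing N on other
grids. Coefficients are interpolated bilinearly between calibration points
with constant extrapolation outside the hull, clipped at zero; at the
calibration points the maps reproduce W exactly.

The forward model is then
$i = \sum_{i=1}^{N} (s \odot w_i) * h_i$, computed by FFT with zero padding
to full linear convolution and a center crop ("same" semantics; pixel
indices 0-based, row-major, origin top-left, PSF center at the
floor-midpoint pixel). A brute-force superposition oracle — every scene
pixel deposits its own interpolated PSF — is part of the package surface and
anchors the headline correctness test: on 64 x 64 scenes with an exact
factorization the two paths agree to 1e-6 of peak. Scenes with continuous
depth maps are snapped one-hot to the nearest grid depth (soft assignment
was rejected for testability) and depth slices combine additively, without
occlusion.

## Training-pair synthesis

The simulation-supervision pipeline mirrors the acquisition protocol:
focal stacks scanned across ±150 um in 10 um steps are fused into an
all-in-focus label, and the label is depth-decomposed (by the fusion index
map) and propagated through the coded system to form the paired input.

* **Scenes** are seeded mixtures of Gaussian beads, resolution-target bar
  groups and band-passed texture on a tilted plane spanning the full depth
  range. Patterns are band-limited (Gaussian sigma 0.75 px ~ 1.5 um) because
  a 3 um-resolution instrument cannot form pixel-level detail at a 2 um
  pitch; an unresolvable phantom would make the all-in-focus label
  unattainable for any fusion method.
* **Stack rendering** blurs each pixel with the uncoded on-axis PSF at its
  relative defocus (pixel depth minus focal-plane position), emulating the
  conventional label microscope.
* **Depth fusion** uses local Laplacian energy in an 11 x 11 window,
  winner-take-all over slices, a 5 x 5 majority filter on the index map,
  and a focus-evidence floor (1% of the maximum focus measure): featureless
  background is prone to defocus-halo winners — a defocused slice has more
  local energy there than the truly in-focus, near-zero background — and
  such pixels inherit the modal index of the evidenced pixels.
* **Patches**: aligned random crops, reproducible per seed; the full-scale
  protocol's 20 patches of 512 x 512 are the defaults.

What the generator does not emulate: occlusion and 3-D radiometry, sample
scattering, illumination nonuniformity, registration errors between stack
slices, and chromatic focal shift beyond per-channel wavelengths. Passing
tests therefore certify the computational chain, not robustness to these
real-data effects.

## Restoration

Two classical solvers are provided.

**ADMM-TV** solves $\min_S \|A S - I\|_2^2 + \lambda_{TV} \|\mathcal{D}S\|_1$
for shift-invariant blur with the standard gradient splitting:
soft-thresholding for the l1 term, a closed-form Fourier solve for the
quadratic subproblem, penalty $\rho = 1$ by default. The image is
replicate-padded by the PSF half-width so the periodic solve approximates
the aperiodic problem, then cropped.

**Shift-variant RL-TV** is the multiplicative Richardson–Lucy iteration
against the low-rank forward operator with a total-variation factor
$1/(1 - \lambda_{TV}\,\mathrm{div}(\nabla S/|\nabla S|))$,
$\lambda_{TV} = 0.00015$ by default. Numerical choices:

* $|\nabla S|$ and the ratio denominator are guarded at
  $10^{-8} \times \max(I)$; the iteration is capped, never
  tolerance-terminated; a NaN/Inf guard stops hard.
* The back-projection defaults to the **exact adjoint** of the forward
  operator — correlation with each basis PSF, coefficient maps applied
  outside — rather than the unflipped-PSF, weights-inside form in which the
  iteration is usually written; the literal form is retained behind the
  `adjoint = "literal"` flag and coincides with the exact adjoint for
  centro-symmetric PSFs.
* The update includes the standard **sensitivity normalization** (the
  back-projection of a unit image). The iteration as usually printed omits
  it, implicitly assuming unit-sum PSFs and partition-of-unity coefficient
  maps; with unnormalized NMF components the unnormalized update loses the
  expectation-maximization monotonicity — the Kullback–Leibler data
  fidelity demonstrably increases — while the normalized form restores it.
* TV gradients are forward differences with a replicated boundary and the
  divergence is their negative adjoint.

For multi-depth captures, `depth_aware_components()` expands a per-depth
basis set and a depth map into flat (PSF, weight-map) components so RL
deconvolves against exactly the depth-resolved forward operator; this
matters because the cubic PSF's centroid translates laterally with defocus,
and deconvolving a ±150 um tilted capture with the mid-plane basis alone
misregisters depth planes and can lower PSNR.

## Restoration network family

The generator (U-Net encoder 4 x [4x4 conv, stride 2, LeakyReLU], nine
residual blocks of two 3x3 convolutions with shortcut, decoder 4 x
[bilinear upsample, 3x3 conv, ReLU], skip connections by channel
concatenation, tanh output — sigmoid behind a deployment flag) and the
70 x 70-receptive-field PatchGAN discriminator are represented as explicit
layer graphs with exact parameter counts — pure functions of the
specification, no weights instantiated. The counting convention (generator
only; convolution weights + biases; no normalization layers) is printed in
every pruning report; under it, pruning the encoder widths from
128/256/512/512 to 32/64/128/256 (residual width 256) reduces parameters by
78.9%.

Skip fusion is by channel concatenation, doubling the affected decoder
input widths — the standard U-Net choice where the architecture note says
only "skip connections". The composite loss is the weighted sum of GAN
(binary cross-entropy on discriminator scores), L2 and perceptual terms;
the perceptual extractor is pluggable and the default configuration uses
weight 0 so nothing in the package requires pretrained weights.

Full-resolution GAN training is out of scope by design. The package's
trainer (`train_toy()`) is a deliberately small, self-contained pure-R
convolutional trainer — 3x3 convolutions by shift-and-add, analytic
backpropagation, Adam (lr 2e-4, betas 0.9/0.999) on the L2 loss over a
reduced residual architecture — no deep-learning framework exists for R in
a portable base installation, and none is needed to exercise and test the
training loop end to end (loss decrease, bitwise seed reproducibility,
zero-epoch identity).

## Metrics

PSF size follows the calibration protocol: binarize at 10% of maximum, keep
the largest connected component (8-connected; the protocol's tool default
is ambiguous, so the convention is fixed here), report bounding extents —
for a Gaussian, 4.292 sigma per axis. FWHM uses linear-interpolated
half-maximum crossings, widest pair for multimodal profiles. SSIM uses the
standard constants (K1 = 0.01, K2 = 0.03, 11 x 11 Gaussian window,
sigma 1.5) with valid-region statistics (no padding), and PSNR the standard
definition with an infinity sentinel for identical images. "Size" is
bounding-box span, not maximum chord. Chromatic similarity is the SSIM
between per-channel PSFs at each calibration field point.

## Problem sizes and reproducibility

The package's own test and acceptance runs use reduced problem sizes chosen
to exercise every code path at full fidelity: pupil grids 64–256, scenes
96–128 pixels, calibration grids 3 x 3, factorization ranks 6–9, depth
steps 10–75 um. The end-to-end pipeline is deterministic for a fixed
configuration — every stochastic stage derives its stream from the global
seed plus a stage tag — and reruns reproduce identical artifact checksums.
All randomness goes through R's default RNG; no global RNG state leaks (the
caller's `.Random.seed` is saved and restored around every seeded
operation).

## Known limitations

* The pupil model is monochromatic per channel; no dispersion model beyond
  per-channel wavelengths, no ray tracing, no lens optimization.
* Depth slices combine additively; occluding 3-D samples are outside the
  model.
* The depth-dependent magnification option is a linear scale factor,
  default off.
* The toy trainer is a scale model of the optimization loop, not a path to
  the full-resolution restoration quality of the deployed network.
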