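---
title: "Confidence-weighted regularization by denoising for cryo-EM refinement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confidence-weighted regularization by denoising for cryo-EM refinement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cryored)
```

## The reconstruction problem

Single-particle cryo-EM recovers a 3D density map $x$ (represented here by
its discrete Fourier transform on the centred integer lattice
$k \in [-N/2, N/2)^3$) from many noisy 2D projection images
$y_1, \dots, y_m$ of identical particles in unknown orientations.  Image
formation is linear in frequency space: by the Fourier slice theorem each
image is a central slice of the model through the origin, perpendicular to
the viewing axis, multiplied by a translation phase ramp and the contrast
transfer function (CTF),

$$y_i = H_{g_i} x + \varepsilon_i,$$

with $g_i \in SE(3)$ the unknown pose and $\varepsilon_i$ complex Gaussian
noise with per-frequency power $\sigma^2$.  Because the poses are unknown
and the per-image SNR is far below 1, the maximum-a-posteriori (MAP)
estimator marginalizes over a discrete grid of candidate poses and is
solved by expectation-maximization:

* **E-step.**  Soft responsibilities
  $\Gamma_{ig} \propto \pi(g)\,
  \exp\{-\sum_k |y_{ik} - (H_g x)_k|^2 / 2\sigma_k^2\}$, normalized per
  image with logsumexp (at SNR of order $10^{-2}$ to $10^{-3}$, linear-domain
  weights underflow).  The responsibilities accumulate a numerator volume
  $B = \sum_{ig}\Gamma_{ig} H_g^*(y_i/\sigma^2)$ and a diagonal kernel
  $K = \sum_{ig}\Gamma_{ig}\,\mathrm{diag}(H_g^* H_g)/\sigma^2$
  (off-diagonal components of the normal operator are discarded).  $B/K$
  is the *unregularized* reconstruction.

* **M-step (Gaussian prior).**  With a zero-mean Gaussian prior of
  per-shell signal power $\tau^2_s$, the update is the per-voxel Wiener
  filter $x = B / (K + \tau^{-2})$.

* **M-step (RED / CW-RED).**  A real-space denoiser $f$ supplies a
  learned prior through the score-matching approximation
  $\nabla \log P(x) \approx \tau^{-2}(f(x) - x)$; the resulting update is

  $$x = \frac{B + \lambda\, \tau^{-2}\, \widehat{f(B/K)}}{K + \tau^{-2}},$$

  where the hat denotes the Fourier transform of the denoised
  unregularized map and $\lambda \in [0, 1]$ is a confidence weight.
  $\lambda = 0$ reproduces the Gaussian update bit-exactly, and
  $\tau^{-2} = 0$ returns $B/K$, so the denoiser acts on the map that
  carries the most recent alignment information.

## Gold-standard half-sets and the regularization parameters

Images are split alternately (odd/even index — deterministic and
seed-independent) into two half-sets refined independently.  Each
iteration the Fourier shell correlation (FSC) between the two
**unregularized** half-maps drives everything:

* the per-shell signal power is the empirical-Bayes estimate
  $\tau^2_s = \frac{F_s}{1 - F_s} P_s$ with $F_s$ the FSC clamped to
  $[0, 0.999]$ and $P_s$ the shell power of the averaged half-maps.  The
  clamp gives the correct limits: $F \to 0$ means full shrinkage to the
  prior mean, $F \to 1$ leaves the data untouched;
* the nominal resolution is the FSC = 0.143 crossing (the field's
  gold-standard half-map convention; 0.5 is used only against a known
  ground truth);
* for CW-RED the confidence weight is re-evaluated from the current
  nominal resolution.

Estimating $\tau^2$ from the *regularized* maps instead deadlocks the
refinement: the Wiener filter zeroes all shells beyond the current
resolution, so their FSC stays 0 and no new signal can ever accumulate.
Using the unregularized maps — exactly the quantities the
external-reconstruction file protocol exchanges — resolves this, and is
why no special seeding of $\tau^2$ is needed at the first iteration even
though both halves start from the same reference (a 30 Å low-pass of the
ground-truth map, the protocol used throughout).

## The confidence schedule

Single-pass assessment of the denoiser (the ratio
$\|f(\tilde{x}) - x_\text{true}\|_p / \|\tilde{x} - x_\text{true}\|_p$
binned by nominal resolution) shows the denoiser helps little on maps
worse than 10 Å and most beyond 4.5 Å.  The schedule therefore sets
$\lambda = 0$ at nominal resolutions worse than 10 Å, $\lambda = 1$
better than 4.5 Å, and interpolates linearly in between:
`lambdaAt(lambdaSchedule(), 7.25)` is exactly 0.5.  Both boundaries are
user-configurable (`lambdaSchedule(resZero, resOne)`, in Å).

## Numerical conventions

* Transforms are unitary and centred, so Parseval's identity holds with
  no scale factors and white real-space noise of variance 1 has
  frequency-space power exactly 1 per complex coefficient.  Shells are
  $s = \mathrm{round}(|k|)$, $s = 0..N/2$; per-shell filters clamp
  $s$ at $N/2$ for the corner voxels outside the Nyquist sphere.
* Slices are extracted by unpadded trilinear interpolation; the adjoint
  scatters with the transposed weights, so the dot-product identity
  $\langle H_g x, y\rangle = \langle x, H_g^* y\rangle$ holds to machine
  precision by construction.  Interpolation fidelity (not adjointness) is
  the resolution-limiting factor: an isotropic Gaussian test spectrum
  projects rotation-invariantly only to about 1% of its peak, and
  known-pose reconstruction of noiseless data recovers FSC > 0.95 up to
  0.8 Nyquist.  Oversampled (padded) gridding would improve this but is
  deliberately out of scope at desk scale.
* On lattice-aligned rotations (the 24 proper cube rotations) trilinear
  interpolation is exact and the diagonal-K approximation to $H^*H$ is
  exact, so MAP-EM ascent of the marginal log-posterior holds to
  $10^{-8}$ per iteration on such toy grids; with generic rotations the
  discarded off-diagonal terms make the M-step approximate, as in all
  production implementations of this scheme.
* Degenerate cases: $\tau^2_s = 0$ shrinks a shell fully to 0 (Gaussian)
  or to $\lambda \widehat{f}$ (RED limit); voxels with $K = 0$ and no
  regularization are set to 0; a zero-variance volume is rejected by the
  standardization contract; an E-step whose weights all underflow raises
  an error rather than producing NaN.

## The simulator

Phantoms are seeded random walks of Gaussian blobs (chain-like compact
densities emulating 40–100 kDa single-chain particles, with an
`elongation` factor controlling anisotropy), supported strictly inside a
0.45 N sphere so a solvent margin exists.  Projection data sets follow
the generating model exactly: uniform SO(3) orientations via normalized
quaternions of four normal deviates, optional uniform defocus in a
0.2–2.0 μm range with a standard phase CTF, and white real-space
Gaussian noise of unity variance.  The SNR is reported as the mean
per-pixel variance of the clean projections divided by the noise
variance.  All pose and CTF draws precede the noise draws, so
re-simulating with the same seed and `noiseSd = 0` yields the matched
clean images (this is how the unity-variance contract is verified).

Default geometry is N = 48 at 3.0 Å/voxel — the reference 96-pixel,
1.5 Å geometry scaled by two, keeping refinements in CPU-minutes while
preserving shell structure.

**What the generator does not emulate:** atomistic density, frequency-
dependent (colored) experimental noise, detector effects, structural
heterogeneity, and per-particle scale variation.  Passing tests
demonstrate correctness of the algorithmic machinery on data generated
by its own forward model, not performance on experimental micrographs.

## Denoiser training

Training pairs are (unregularized intermediate half-map, ground truth
low-pass filtered by that iteration's half-map FSC).  The corpus builder
runs Gaussian-prior refinements on simulated phantom data sets, keeping
both unregularized half-maps per iteration, optionally augmented by
proper 90° cube rotations.  A Gaussian-noise variant corrupts ground
truths with per-shell-shaped Hermitian frequency noise, dampened in the
solvent region by a soft spherical mask; its noise profile is measured
as the shell power of (intermediate − coarsened truth) residuals over a
corpus.

The denoiser is a volumetric residual U-Net written directly in R (no
deep-learning framework is involved): per-stage pairs of
InstanceNorm → ReLU → 3×3×3 convolution blocks, average-pooling
down-sampling, learned transposed-convolution up-sampling with
concatenative skips, channels doubling per stage, and a zero-initialized
final layer so the untrained network is the identity.  Convolutions are
evaluated as im2col GEMMs; backpropagation is hand-derived and guarded
by numeric gradient checks in the test suite.  Normalization is per
volume (desk-scale batches are tiny).  Training minimizes the empirical
MMSE risk on standardized volumes (input mean/sd standardize both input
and target, so the reversal of `standardizedDenoise()` returns map
units) with Adam and L2 weight decay.

Reference-scale hyperparameters (5 stages, base width 4, batch 10,
27 epochs, learning rate $10^{-4}$) remain available through
`unetSpec()`/`trainDenoiser()` arguments.  The desk-scale defaults used
by the tests are chosen for single-CPU wall-clock: 32-voxel volumes,
3 stages, base width 4, ≤ 3–5 epochs, learning rate $10^{-3}$ (fewer
steps warrant larger steps).

### Desk-scale study conditions

The reference experiments refine 10,000 images per data set at per-image
SNR 0.001–0.004.  At desk scale we use a few hundred images, and hold
the *total* accumulated signal $m \times \mathrm{SNR}$ comparable:
240–400 images at per-image SNR ≈ 0.05 (intensity scale 0.3 on the
default phantoms) matches $10{,}000 \times 0.002$.  The simulator's
defaults otherwise keep the reference conditions — unity noise variance,
uniform orientations, halved box geometry.  A consequence of the small
image budget and the coarse 384-pose search grid is that desk-scale
refinements plateau near 14 Å (Nyquist is 6 Å at 3 Å/voxel), so corpus
intermediates span a narrow resolution range; the single-pass benefit of
the trained denoiser is therefore demonstrated on the best-tertile
intermediates (mean L2 ratio ≈ 0.84 in the shipped test), while the
low-resolution failure regime reported for the full-scale experiments is
represented only weakly.

## Design choices made where the design was open

* **Per-half denoising.**  Each half-map is denoised independently,
  never the combined map, preserving gold-standard independence.
* **Score modulation.**  `redGradient(x, d, v)` returns
  $(f(x) - x)/v$, the Tweedie score estimate for noise variance $v$;
  the M-step evaluates it shell-wise with $v = \tau^2$, the modulated
  (conservative) form that suppresses the denoiser where data certainty
  is high.
* **Estimated pose for angular error** is the maximum-responsibility
  pose of the final E-step (hard assignment at evaluation only);
  handedness/symmetry ambiguities are reported raw since phantoms are
  asymmetric by construction.
* **Pose grid** is a fixed global quasi-uniform covering (Fibonacci
  directions × equispaced in-plane angles, default 74 × 8 = 592
  orientations, optional integer translation lattice) with a uniform
  prior; no adaptive local search.
* **Noise power is not re-estimated** during refinement; the simulator's
  known value is used throughout.
* **External protocol dialect.**  B is complex but MRC stores reals, so
  the protocol writes `_B_real`/`_B_imag` MRC pairs plus K and a STAR
  table of per-shell FSC and τ²; results are delivered atomically via
  temp-file rename so the file's appearance signals completeness.  The
  layout is this package's documented dialect, not byte-compatible with
  other engines.

## Known limitations

Unpadded trilinear gridding bounds achievable FSC near Nyquist;
orientation search is global and fixed-resolution; σ² is radial and
shared across images; no astigmatism, beam tilt or Ewald curvature; the
desk-scale denoiser sees a narrow resolution range and a single noise
model.  All are deliberate scope choices for a single-CPU, minutes-scale
engine.

## A worked run

```{r}
gt <- makePhantom(phantomSpec(side = 48, voxelSize = 3, seed = 1))
ds <- simulateDataset(gt, 300, intensityScale = 0.3, noiseSd = 1, seed = 2)
run <- runRefinement(ds, refinementConfig(
  regularizer = "cwred", denoiser = classicalDenoiser(1.5),
  grid = poseGridUniform(64, 6), maxIterations = 6, verbose = TRUE))
run$final
```
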