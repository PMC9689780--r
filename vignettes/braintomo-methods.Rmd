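---
title: "Methods: desk-scale microwave brain tomography with learned inversion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: desk-scale microwave brain tomography with learned inversion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Microwave brain imaging reconstructs the spatial distribution of two
electrical properties — relative permittivity $\varepsilon_r(\mathbf r)$ and
conductivity $\sigma(\mathbf r)$ (S/m) — inside the head from scattered
electromagnetic fields measured by an antenna array operating in the VHF/UHF
band. At the 300 MHz operating frequency used throughout this package the two
properties combine into the complex relative permittivity

$$\tilde\varepsilon_r = \varepsilon_r + \frac{\sigma}{j\omega\varepsilon_0},$$

with the $e^{+j\omega t}$ time convention, so lossy tissue has a negative
imaginary part. Head tissues have $\varepsilon_r$ up to about 70 at this
frequency against the free-space background of 1, which makes the inverse
problem strongly nonlinear and ill-posed: classical iterative inversion is
expensive and resolution-limited. The approach implemented here replaces the
iterative inversion with a learned mapping: a fully convolutional
encoder–decoder network maps a compact measurement vector directly to the
property volumes, and a 2-D U-Net then sharpens the preliminary
reconstruction slice by slice.

`braintomo` implements the complete desk-scale workflow: a procedural
generator of nested-tissue brain phantoms, a volume-integral-equation
forward solver for a four-layer array of 60 dipole transceivers, the
reconstruction network, the U-Net enhancement stage, and a misfit/noise
benchmark protocol.

## Measurement model

**Array geometry.** Sixty z-oriented point electric dipoles act as both
transmitters and receivers, in four circular layers: 32 on a 0.12 m circle
at $z=-0.06$ m (11.25° steps), 16 on 0.115 m at $z=0$ (22.5°), 8 on 0.10 m
at $z=0.06$ m (45°), and 4 on 0.06 m at $z=0.10$ m (90°), all around a
0.24 m cubic imaging domain centred at the origin. Each transmitter
illuminates in turn; every other element records the three Cartesian field
components, giving $3\times 60\times 59 = 10{,}620$ raw measurements. The
network input aggregates these to one complex sum over the 59 transmitters
per (receiver, component), i.e. $M = 60\times3 = 180$ complex values, stored
as 180 real parts followed by 180 imaginary parts (length $2M = 360$).

**Forward solver.** The forward problem is discretized as a volume integral
equation on the phantom's voxel grid: each voxel is a polarizable cell with
contrast $\chi = \tilde\varepsilon_r - 1$, coupled through the free-space
dyadic Green's function, with a static depolarization self-term
$(1+\chi/3)$. Two modes are provided:

* `born` — the single-scattering linearization. It is exact in the
  weak-contrast limit, strictly linear in $\chi$, and fast enough to
  generate hundreds of samples per minute on one CPU; it is the default for
  dataset generation and for the data-misfit re-simulation (both use the
  same code path, so data misfits are internally consistent).
* `full` — the coupled-dipole solve of the same discretized operator by
  BiCGSTAB with an FFT-accelerated block-Toeplitz matrix–vector product,
  Jacobi-scaled by the self-term. A dense direct solve of the identical
  operator serves as an independent oracle in the test suite (agreement to
  better than $10^{-8}$ relative at $10^3$–$12^3$ grids).

At brain-level contrasts the Born approximation is far outside its formal
validity region; we use it as a deterministic, linear surrogate forward
operator that preserves the geometry of the measurement process. This is a
deliberate desk-scale simplification: the learned inversion sees data whose
physics is simplified, so absolute misfit values are not comparable to a
full-wave study, while the *structure* of the pipeline (what the network
must learn, how noise propagates, how the enhancement stage behaves) is
preserved.

## Phantom generation

The training-set strategy emulates anatomical variability around one base
model:

1. **Base model** — since no anatomical mesh ships with the package, the
   base head is procedural: 16 nested smooth closed surfaces (a
   superellipsoid with a small seeded low-order spherical-harmonic
   perturbation, shrunk by a fixed fraction per layer), assigned tissues
   outermost to innermost. Surfaces are radial functions
   $r_t(\theta,\varphi)$ on a $25\times48$ control grid, which guarantees
   closed, star-shaped, strictly nested boundaries under every later
   operation. The innermost-layer fraction grows as the tissue count
   shrinks, so reduced stacks stay rasterizable at coarse grids.
2. **Scaling** — a factor drawn uniformly from $\{0.8,0.9,1.0,1.1,1.2\}$
   multiplies both the geometry and every tissue's $\varepsilon_r$ and
   $\sigma$ ($\varepsilon_r$ floored at 1). The same factor is used for
   geometry and properties; an independent draw would also be defensible,
   but the joint reading keeps a single "size of the head" latent variable.
3. **Deformation** — in a seeded random tissue order, every control point is
   displaced by an i.i.d. Normal$(0, \sigma_d^2)$ vector per axis
   ($\sigma_d$ = 2 mm by default; the magnitude of inter-individual
   variability is a free parameter of the generator, chosen at a few voxel
   pitches), then re-radialized and clipped so nesting survives. If more
   than half of all control points have to be clipped the requested
   deformation is refused rather than silently flattened.
4. **Anomaly** — optionally one spherical inclusion emulating a lesion or
   tumour, with radius from $\{4, 7, 10\}$ mm, $\varepsilon_r$ from
   $\{90, 120, 150\}$ and $\sigma$ from $\{1.038, 1.384, 1.73\}$ S/m, placed
   uniformly inside the (deformed) brain.

**Tissue table.** The default 16-row table holds literature-plausible
300 MHz values ($\varepsilon_r \in [5.6, 72]$,
$\sigma \in [0.1, 2.22]$ S/m). The ceiling (CSF, $\varepsilon_r = 72$) is
chosen so that even after 1.2× property scaling every normal tissue stays
below the anomaly menu minimum of 90, keeping inclusions separable by a
permittivity threshold (default 88) in the detection report. The table is a
configuration object, not a constant: any validated table can be passed to
the generator.

## Reconstruction network

The stage-1 network maps the 2-channel, length-$M$ measurement vector to a
2-channel property volume (or to one block of it; see below).

* **Encoder**: eight 1-D convolutions with kernel sizes
  $(2,2,2,2,2,2,4,1)$, channels $(32,32,64,64,128,128,256,256)$, and
  down-sampling strides 2, 4, 2, 4 at layers 1, 3, 5, 7; every convolution
  is followed by batch normalization,
  $\hat y = \gamma\,(y-\mu_\beta)/\sqrt{\sigma_\beta^2+\chi}+\beta$ with
  $\chi = 10^{-3}$, and ReLU $f(x)=\max(0,x)$.
* **Length adaptation**: the input channels (length $M=180$) are tiled
  periodically to length $8\times64 = 512$ before the first convolution, so
  the strided encoder lands exactly on an $8\times256$ feature vector,
  reshaped to a $2\times2\times2\times256$ volume seed. Tiling, rather than
  zero-padding, matters: the final feature cells have local receptive fields
  (about 86 of the 512 positions each), and with end-padding the cells past
  the signal would see only zeros, making most of the output volume
  structurally independent of the measurements. A kernel that spans the
  whole sequence would fix this too, but such a layer is a fully connected
  layer in disguise, and the architecture is deliberately convolution-only.
* **Decoder**: three transposed 3-D convolutions with channels
  $(128, 64, 32)$ and kernel = stride, the three strides auto-factorized so
  their product is `block_side / 2` (e.g. $3\times2\times2$ for a $24^3$
  output); each is followed by batch normalization and ReLU. With
  kernel = stride the layer is an exact learned upsampling and the shape
  arithmetic is validated at build time; internally the decoder runs on
  flat (cells × channels) matrices with a single precomputed permutation to
  raster order at the output, which keeps the whole pass inside BLAS.
* **Head**: a kernel-1 transposed convolution to 2 channels. There are no
  fully connected layers anywhere; the default desk-scale model has well
  under $10^7$ parameters (about $5\times10^5$–$4\times10^6$ depending on
  block size).

**Block partition.** The output volume can be split into $N$ (a perfect
cube) disjoint blocks, each reconstructed by an independent sub-model with
no information exchange; predictions are assembled by exact tiling. The
desk-scale default is $N=1$: at a $24^3$ grid one model is both faster and
at least as accurate in our runs, while the block machinery is exercised and
tested separately.

**Training.** Targets are min–max normalized per channel to $[0,1]$ and
inputs standardized per feature, with statistics computed on the training
split only. Optimization is Adam (desk-scale default: learning rate $3\times10^{-3}$
decayed exponentially to $10^{-3}$ over the run, minibatch 8) on the MSE loss
$\frac1m\sum_i (y_i-\hat y_i)^2$ over normalized targets. After the last
epoch the batch-norm running statistics are recalibrated to the exact mean
of the training-set batch moments, removing the eval/train drift of the
momentum average. Predictions are de-normalized and clamped to the physical
ranges $\varepsilon_r \ge 1$, $\sigma \ge 0$.

## U-Net enhancement

The stage-2 network refines the preliminary volume slice by slice in the XY
plane, on the normalized property scale. It is a standard 2-D U-Net: four
stages of (two 3×3 convolutions + ReLU) with 2×2 max pooling, a bottleneck
conv pair, four up-sampling stages of (2×2 transposed convolution, skip
concatenation with the matching encoder feature map, two 3×3 convolutions +
ReLU), and a 1×1 head to the 2 channels; widths double per stage
(default base 32; the desk-scale pipeline uses base 16 for speed). Slices
are edge-replicated to a multiple of 16 and cropped back.

Two choices depart from the textbook architecture and are worth making
explicit. First, both channels are enhanced jointly by one network — the
parsimonious reading of a 2-channel image. Second, a global input→output
residual connection is on by default, with the head initialized near zero:
an enhancement network should start as (approximately) the identity and
learn a correction, which both stabilizes short training runs and guarantees
that an untrained enhancer cannot corrupt a reconstruction. Training pairs
come exclusively from the stage-1 training phantoms (no leakage from the
held-out set), sub-sampled to every second slice by default.

## Evaluation protocol

**Model misfit** is the relative L2 error of the reconstructed properties,
in percent. The two channels live on different scales, so each channel is
standardized by the truth's channel norm before concatenation:

$$\mathrm{misfit}_{\mathrm{model}} = 100\sqrt{\tfrac12\left(
  \frac{\lVert\varepsilon_R-\varepsilon_T\rVert^2}{\lVert\varepsilon_T\rVert^2}
 +\frac{\lVert\sigma_R-\sigma_T\rVert^2}{\lVert\sigma_T\rVert^2}\right)},$$

which makes a perfect reconstruction 0% and a zero reconstruction 100%
regardless of channel scales; per-channel values are also reported.
**Data misfit** re-simulates the scattered fields of the reconstruction
through the forward solver and reports the relative L2 difference from the
truth record's noise-free fields (a reconstruction-fidelity measure, not a
noise-realization measure), in percent. By default the evaluation grid
equals the generation grid; an anti-inverse-crime option evaluates on a
finer grid.

**Noise robustness.** White circular complex Gaussian noise is added to the
raw 10,620 measurements with total power $10^{L/10}$ times the total signal
power, for relative levels $L = -10, -20, -30, -40$ dB ("relative noise
level" is not a standardized term; noise-to-signal power over the whole raw
array is the conventional reading, and noise is injected before the
59-transmitter aggregation, with a post-aggregation option). The benchmark
evaluates the held-out phantoms at the noise-free condition and all four
levels, for both stages, averaging over phantoms and (by protocol) three
noise realizations per level with common random numbers across levels —
the same noise seed is scaled to each level, so level-to-level comparisons
are paired rather than independently noisy.

## Study conditions and what the tests show

The in-package benchmark runs at desk scale: a $24^3$ voxel grid
(10 mm pitch) on the 0.24 m domain, a reduced 3-tissue nested stack
(skin-like, fluid-like, cortex-like layers spanning the property range —
16 thin shells cannot be rasterized at 10 mm), 100 training phantoms,
3 held-out phantoms, Born-mode data, and intentionally short training
(tens of epochs, minutes of CPU). The acceptance suite asserts the
qualitative pattern that motivates the two-stage design: the stage-1
network reconstructs far better than the best constant volume, enhancement
never hurts at any noise level, and the enhanced misfit improves
monotonically as the noise level drops from −10 dB to −40 dB.

Passing these tests shows that the pipeline learns genuine
measurement-to-structure mappings and that the enhancement stage behaves as
designed *under the generator's assumptions*. It does not show clinical
realism: the phantoms are topologically nested (no folded cortex, no
bilateral structures), the forward data is linearized, tissue dispersion is
ignored, and the grid is two orders of magnitude coarser than a
super-resolution study. Those are scope boundaries, not bugs.

## Numerical choices and degenerate inputs

* Voxel-centred sampling, x-fastest ordering, domain centred at the origin;
  `voxel_size_mm(0.24, 256)` = 0.94 and `voxel_size_mm(0.24, 512)` = 0.47.
* Surfaces are clipped with a 0.2 mm margin to keep strict nesting; a
  deformation that would clip more than half the control points aborts.
* An anomaly sphere smaller than a voxel claims the voxel containing its
  centre; a sphere touching air is an error.
* The full-mode solver refuses grids above $48^3$ by default and reports
  its final residual on non-convergence; dataset generation retries a
  failed sample with a perturbed seed up to a cap.
* Zero-variance normalization channels are an error (degenerate targets);
  near-zero input-feature standard deviations fall back to 1.
* All randomness flows from one root seed through fixed sub-stream
  derivations; every operation is a pure function of its inputs and seed,
  and `.Random.seed` is always restored.

## Known limitations

* The Born surrogate misstates absolute scattering amplitudes at tissue
  contrast; full coupled-dipole data generation is available but slow above
  small grids.
* Batch-norm coupling means train-mode outputs depend weakly on batch
  composition; determinism is guaranteed for fixed seeds and batch plans.
* The measurement aggregation (summing 59 transmitters coherently) discards
  most of the raw information by design; reconstruction quality is bounded
  by that compression, which is part of the studied method.
* Dataset storage uses one `.rds` record per sample plus a YAML config
  snapshot; volumes can be exported to NIfTI for inspection.
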