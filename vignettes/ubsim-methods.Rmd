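---
title: "Unrolled blind structured illumination microscopy: models and methods"
author: "ubsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unrolled blind structured illumination microscopy: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The imaging model

Speckle-illumination blind SIM acquires a burst of `L` diffraction-limited
camera frames, each taken under a different random speckle illumination.
The forward model for one sub-frame is

    M_l = (I_l * rho) conv h ,

where `rho` is the fluorophore density, `I_l` the l-th (unknown) speckle
intensity pattern, and `h` the detection PSF. Because the speckles carry
spatial frequencies up to the illumination cutoff, the products `I_l * rho`
alias object frequencies up to the sum of the two cutoffs into the
detection passband: with illumination at the same NA as detection the
recoverable band doubles, which is the source of the (at most) two-fold
resolution gain.

The patterns are unknown, but fully developed speckle averages to a
uniform field: `sum_l I_l ~ L * I0`, with a relative error that decays as
`1/sqrt(L)` (each pixel averages `L` independent exponential draws). The
package treats this constraint as exact for the last pattern: only
`L - 1` illuminations are free variables and the last one is derived,
`I_L = L*I0 - sum_{l<L} I_l`.

`ubsim` implements this model end to end: `make_psf()` builds the
aberration-free incoherent OTF (pupil autocorrelation, cutoff
`2 NA / lambda`); `make_speckle_stack()` synthesises fully developed
speckle as the squared modulus of a pupil-filtered random-phase field;
`forward_subframes()` applies the forward model with scaled-Poisson shot
noise plus Gaussian read noise (the standard sCMOS model).

## The variational problem

Nonnegativity of object and illuminations is enforced by square-root
auxiliary variables, `rho = xi^2`, `I_l = i_l^2`. The data-fidelity cost is

    F(xi, i_1, ..., i_{L-1}) =
      sum_{l<L} || M_l - (xi^2 i_l^2) conv h ||^2
      + || M_L - (xi^2 I_L) conv h ||^2 ,

with `I_L` derived as above. `blind_sim_gradients()` returns the analytic
descent directions (note `dI_L/di_l = -2 i_l` flips the sign of the last
residual's contribution); their correctness is established against a
central-finite-difference oracle (`finite_diff_check()`), which is also a
package export because any change to the cost must be re-validated the
same way.

Three classical solvers share one step-size rule (Armijo backtracking,
`c = 1e-4`, shrink `0.5`, restart at twice the last accepted step): plain
gradient descent, Polak-Ribiere+ conjugate gradient (nonnegative `beta`
with automatic restart when the conjugate direction fails the decrease
test), and Nesterov momentum with the standard `t`-schedule. Nesterov is
not monotone; the implementation restarts the momentum whenever the cost
increases, which we found necessary to keep the extrapolation from
running away on this quartic landscape. The stopping rule treats a
plateau as "the best cost seen improved by less than `tol` over the last
10 iterations", which is meaningful for non-monotone methods too.

### Degenerate inputs and numerical choices

All convolutions are circular and evaluated in the frequency domain, with
a cached real OTF; simulator and solver share the same convention, and
phantoms carry a cosine-taper border (8 px) so structure never touches
the periodic boundary. The derived pattern `I_L` may go negative during
optimization; it is reported (`negative_pattern_fraction()`) but never
clamped, since the square parameterization does not require it and
clamping would break the gradients. All-zero stacks, non-positive steps,
and shape mismatches are rejected with explicit errors.

## The unrolled network

The unrolled model replaces the scalar step of gradient descent with a
learned update: each of `n_blocks = 6` iteration blocks computes the
analytic gradient bundle, passes each gradient image through one shared
small convolutional network, and advances the state by
`state + alpha_n * CNN(g_n)` with a per-block learnable scale `alpha_n`
(initialised at 0.1). With the network replaced by the identity the
blocks reduce *bit-exactly* to fixed-step gradient descent — the package
treats this equivalence as the key architectural invariant and tests it.

The shared network is a two-stage encoder-decoder with skip connections:
3x3 convolutions, leaky-ReLU activations, average-pool downscaling,
nearest-neighbour upsampling with 1x1 channel reduction, and a
zero-initialised 3x3 output layer added residually to the input. The
residual + zero-init choice makes the untrained model behave like plain
gradient descent, so training starts from a physically sensible operating
point instead of noise. At the default width (16 channels) the network has
about 49k parameters — comfortably below the 250k budget the architecture
is specified against; `count_parameters()` reports the exact count.

Two application modes exist. The default (`per_image`) applies the
single-channel network to every gradient image independently, which keeps
the model agnostic to `L`. The alternative (`stacked`) feeds all `L`
gradients as channels of one tensor; it fixes `L` at construction time
and is provided because the block-diagram reading of the architecture
admits both interpretations.

### Gradient conditioning

Raw gradient magnitudes vary by orders of magnitude across iterations and
image scales. Each bundle is therefore normalised by its global maximum
absolute value before entering the network. The scale is *not* restored
afterwards: the update magnitude is controlled by `alpha_n` alone, making
the block invariant to the gradient's absolute scale. We chose this over
restoring the scale because the restored variant is exactly a fixed-step
gradient update at initialisation, whose stable step on these instances
is two to three orders of magnitude smaller than any useful learned
scale — the 0.1 initialisation would diverge before training could act.
One normalisation for the whole bundle (rather than per image) preserves
the relative weighting between the object and illumination gradients.
The normalisation factor is treated as a constant in the backward pass
(a stop-gradient), the usual choice for input conditioning.

## Unsupervised training

Training minimises the physical cost `F` on raw sub-frame stacks — no
ground-truth objects exist anywhere in the training API, which is what
makes the scheme unsupervised and is asserted structurally in the tests.
The reference training recipe is Adam at `1e-4` with
reduction-on-plateau. Back-propagation runs through the entire unrolled
computation, including through the analytic gradient of the cost (i.e.
Hessian-of-F products); the package ships a small tape-based reverse-mode
engine for exactly this purpose, and its end-to-end gradients are verified
against finite differences in the test suite.

Two loss placements are available: the cost of the final block output
(`loss_mode = "final"`, the reference reading) and the mean cost over all
block outputs (`loss_mode = "blocks"`). The intermediate costs fall out
of the next block's gradient computation at no extra expense. At the
small training scales used in this package the per-block loss trains far
faster — every block receives a direct signal instead of one attenuated
through the whole chain — so the desk-scale study below uses it; at full
scale with hundreds of epochs the final-cost loss is the default.

## Desk-scale study conditions

The package's tests and the acceptance script reproduce the study at a
reduced scale chosen once:

* optics: 500 nm emission, NA 1.0 detection and illumination, 40 nm
  pixels (the super-resolved band then sits at 0.64 of Nyquist, safely
  sampled);
* training data: 24 stacks of 32 x 32 px, `L = 16` sub-frames, phantom
  classes cycled through filaments / puncta / tubule meshes / rings,
  peak signal 500 photons with 2-count read noise;
* model: 6 blocks, width-12 network (about 28k parameters);
* training: 10 epochs of Adam at `3e-3` (per-block loss, gradient-norm
  clip 5, step-scale learning rate x5, plateau patience 5) — a few
  hundred optimizer steps in total, a small fraction of the reference
  200-epoch recipe, which bounds how far the learned update can move
  from its gradient-descent starting point;
* evaluation: held-out 64 x 64 stacks at `L = 16` of unseen phantoms;
  resolution via image decorrelation analysis; convergence-speed parity
  via `iterations_to_target()` (how many classical iterations reach the
  6-block model's final cost).

The learning rate deserves a note: the reference recipe (`1e-4`, 200
epochs) is the package default, but a 16-epoch run moves the step scales
only by about `16 * 24 * 1e-4` under Adam, far too little; the micro runs
therefore use `3e-3`. Phantom classes emulate the *structure* of
fluorescence samples (curvilinear filaments, puncta, meshes, rings with
sub-diffraction detail); they do not reproduce the texture statistics of
experimentally derived image sets, so passing the desk-scale checks
demonstrates correct mechanics and qualitative behaviour, not
experimental image quality.

## Resolution estimation

`decorrelation_resolution()` implements reference-free decorrelation
analysis: the normalised cross-correlation between the image spectrum and
its phase-normalised copy is swept over 50 low-pass mask radii, the sweep
repeated for 10 Gaussian high-pass pre-filterings, and the
highest-frequency qualified local maximum over all curves gives the
cutoff `k_c` (resolution `2 * pixel_size / k_c`). A maximum qualifies
only if the curve afterwards drops by at least 0.01 before exceeding it
again; without this prominence rule the noise-induced rising tail of the
curves at high frequency produces spurious maxima. On analytically
band-limited noise the estimator recovers the designed cutoff within a
few percent (tested across seeds), and it is scale-consistent under
Fourier resampling.

## Known limitations

* 2-D only; no aberrations, drift, or photobleaching kinetics in the
  forward model (bleaching is tolerated in the video pipeline only through
  per-window renormalisation).
* The desk-scale trained model is a small fraction of the reference
  training budget; its convergence-speed advantage over the classical
  solvers at that scale is correspondingly smaller than what a full
  training run achieves.
* Decorrelation analysis parameters follow the cited method's reference
  conventions; the exact settings used alongside the original experiments
  are not restated there and may differ in detail.
* The uniform-sum constraint is imposed exactly through the derived last
  pattern; for very small `L` the approximation error of that constraint
  is part of the model error.
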