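# ubsim — unrolled blind structured illumination microscopy

`ubsim` is an R toolkit for super-resolution fluorescence imaging with
*unknown* speckle illumination (blind SIM), and for the unrolled,
physics-trained network that accelerates its reconstruction. It is aimed
at microscopists and computational-imaging researchers who want a fully
inspectable, CPU-only implementation of the whole chain: forward
simulation, classical iterative solvers, the learned unrolled
reconstructor, quality metrics, and a rolling-window video pipeline.

## The model

A blind-SIM acquisition is a burst of `L` diffraction-limited sub-frames,
one per speckle illumination realisation,

```
M_l = (I_l ρ) * h ,          l = 1, …, L
```

with `ρ` the fluorophore density, `I_l` the unknown speckle intensity
patterns, `h` the detection PSF (`*` is convolution). Speckles carry
illumination frequencies up to their own diffraction cutoff, so the
products `I_l ρ` fold sample detail from up to twice the detection cutoff
into the passband — a 2× resolution gain is recoverable even though no
pattern is known, because fully developed speckle sums to a uniform
field, `Σ_l I_l ≈ L·I_0`, with error falling as `1/√L`.

Nonnegativity is built in through square-root variables (`ρ = ξ²`,
`I_l = i_l²`, the last pattern derived from the uniform sum), and the
reconstruction minimises the data-fidelity cost

```
F(ξ, i_1, …, i_{L−1}) = Σ_{l<L} ‖M_l − (ξ² i_l²)*h‖² + ‖M_L − ξ² I_L*h‖²
```

by plain gradient descent, Polak-Ribière+ conjugate gradient, or Nesterov
momentum (`blind_sim_reconstruct()`), or by the **unrolled network**
(`unrolled_forward()`): six iteration blocks, each passing the analytic
cost gradients through one small shared convolutional network before the
additive update `ξ_n = ξ_{n−1} + α_n · CNN(g_n)`. The network is trained
*without ground truth* by minimising `F` itself on raw stacks
(`train_unrolled()`); with the identity network the blocks reduce
bit-exactly to gradient descent.

## Worked example

```r
library(ubsim)

cfg <- optical_config(wavelength = 500, na_detection = 1.0,
                      pixel_size = 40, image_shape = 64)
acq <- simulate_acquisition(cfg, kind = "filaments", L = 16,
                            noise = noise_params(500, 2), seed = 101)
stk <- normalize_stack(acq$stack)

tr <- blind_sim_reconstruct(stk, acq$psf,
                            solver_config("prcg", max_iters = 80))
tr
rep <- quality_report(tr$rho, widefield_image(stk), acq$phantom$object,
                      pixel_size = cfg$pixel_size)
rep
```

```
ubsim prcg trace: 80 iterations (max_iters), cost 7.153e+04 -> 3002
ubsim quality report (images min-max normalised to [0,1]):
  mse 0.001315 | psnr 28.81 dB | ssim 0.8704
  resolution: widefield 294, reconstruction 106 (x2.78 improvement)
```

The trace shows the data-fidelity cost falling by a factor ~24; the
report compares the reconstruction with the diffraction-limited
widefield image: decorrelation analysis estimates 294 nm for widefield
(near the 250 nm diffraction limit of this configuration) against 106 nm
for the reconstruction. Training and applying the unrolled model follows
the same pattern:

```r
ds  <- simulate_dataset(optical_config(image_shape = 32), n_stacks = 24,
                        L = 16, base_seed = 1)
fit <- train_unrolled(unrolled_model(6, update_cnn(width = 12)),
                      ds$stacks, ds$psf,
                      train_config(learning_rate = 3e-3, epochs = 10,
                                   loss_mode = "blocks"))
uf  <- unrolled_forward(fit$model, stk, acq$psf)   # one fixed-cost pass
```

A thin command-line interface over these functions is installed with the
package (`system.file("cli", "ubsim.R", package = "ubsim")`) with
subcommands `simulate`, `train`, `reconstruct`, `reconstruct-iterative`,
`video`, `evaluate` and `benchmark`.

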