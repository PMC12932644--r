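# Shared fixtures and independent oracles for the test suite. Everything is
# generated in code at test time; heavyweight fixtures (the trained micro
# model) are built once per run and cached in `.fixtures`.

.fixtures <- new.env(parent = emptyenv())

tiny_config <- function(n = 16, pixel_size = 100) {
  optical_config(wavelength = 500, na_detection = 1.0,
                 pixel_size = pixel_size, image_shape = n)
}

# small noiseless acquisition used across the cost/solver tests
tiny_instance <- function(n = 16, L = 4, seed = 2, noisy = FALSE) {
  key <- sprintf("inst_%d_%d_%d_%s", n, L, seed, noisy)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  cfg <- tiny_config(n)
  np <- if (noisy) noise_params(500, 2) else noise_params(Inf, 0)
  sim <- simulate_acquisition(cfg, "puncta", L, np, seed = seed,
                              density_params = list(n = max(4, n %/% 3)))
  sim$stack <- normalize_stack(sim$stack)
  .fixtures[[key]] <- sim
  sim
}

# acquisition whose patterns satisfy the uniform-sum constraint EXACTLY:
# L-1 reduced-contrast speckles plus the derived complement, so the
# generating state is an exact zero of the cost
consistent_instance <- function(n = 16, L = 4, seed = 2) {
  key <- sprintf("cons_%d_%d_%d", n, L, seed)
  if (!is.null(.fixtures[[key]])) return(.fixtures[[key]])
  cfg <- tiny_config(n)
  psf <- make_psf(cfg)
  ph <- make_phantom("puncta", n, density_params = list(n = max(4, n %/% 3)),
                     seed = seed)
  sp <- make_speckle_stack(cfg, L = L, seed = seed)
  for (contrast in c(0.3, 0.2, 0.1, 0.05)) {   # keep the complement positive
    pat <- (1 - contrast) + contrast * sp$patterns
    pat[, , L] <- L - apply(pat[, , -L, drop = FALSE], c(1, 2), sum)
    if (min(pat[, , L]) > 0) break
  }
  stopifnot(min(pat[, , L]) > 0)
  sp$patterns <- pat
  sp$mean_intensity <- 1
  stack <- forward_subframes(ph, sp, psf)
  out <- list(stack = stack, phantom = ph, speckles = sp, psf = psf,
              truth = aux_state(sqrt(ph$object),
                                sqrt(pat[, , -L, drop = FALSE])))
  .fixtures[[key]] <- out
  out
}

# independent O(N^4) spatial-domain circular convolution oracle
conv2_brute <- function(x, kernel_centred) {
  n <- nrow(x); m <- ncol(x)
  kc <- floor(dim(kernel_centred) / 2) + 1L   # kernel centre pixel
  out <- matrix(0, n, m)
  for (i in 1:n) for (j in 1:m) {
    acc <- 0
    for (p in 1:n) for (q in 1:m) {
      ki <- ((i - p + kc[1] - 1) %% n) + 1L
      kj <- ((j - q + kc[2] - 1) %% m) + 1L
      if (ki <= nrow(kernel_centred) && kj <= ncol(kernel_centred))
        acc <- acc + x[p, q] * kernel_centred[ki, kj]
    }
    out[i, j] <- acc
  }
  out
}

# brute-force blind-SIM cost: double loop over frames and pixels with the
# spatial-domain convolution oracle
cost_brute <- function(state, data, psf) {
  L <- dim(data$frames)[3]
  rho <- state$xi^2
  total <- 0
  for (l in seq_len(L)) {
    Il <- if (l < L) state$aux_illums[, , l]^2 else derived_last_pattern(state)
    model <- conv2_brute(rho * Il, psf$kernel)
    r <- data$frames[, , l] - model
    for (i in seq_len(nrow(r))) for (j in seq_len(ncol(r)))
      total <- total + r[i, j]^2
  }
  total
}

# random auxiliary state with values of order 1
random_state <- function(n, L, seed = 1) {
  ubsim:::with_seed(seed, aux_state(
    matrix(runif(n * n, 0.2, 1), n, n),
    array(runif(n * n * (L - 1), 0.5, 1.3), c(n, n, L - 1))))
}

# the trained micro model shared by the acceptance checks: 32 px training
# patches (L matching the evaluation stacks), evaluated on larger held-out
# acquisitions; built once per test run
micro_ubsim_fixture <- function() {
  if (!is.null(.fixtures$micro_fit)) return(.fixtures$micro_fit)
  cfg <- optical_config(image_shape = 32)
  ds <- simulate_dataset(cfg, n_stacks = 24, L = 16, base_seed = 1)
  model <- unrolled_model(6, update_cnn(width = 12, seed = 1), alpha0 = 0.1)
  fit <- train_unrolled(model, ds$stacks, ds$psf, micro_train_config())
  .fixtures$micro_fit <- fit
  fit
}

# desk-scale training settings (see the methods vignette for the rationale)
micro_train_config <- function(epochs = 10L, seed = 1L) {
  train_config(learning_rate = 3e-3, epochs = epochs, clip_norm = 5,
               loss_mode = "blocks", lr_patience = 5, alpha_lr_mult = 5,
               seed = seed)
}

held_out_eval_seeds <- function() 101:103
held_out_kind <- function(seed) {
  c("filaments", "tubule_mesh", "rings")[(seed - 101) %% 3 + 1]
}

expect_images_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(a - b)), tol)
}

with_seed_local <- function(seed, code) ubsim:::with_seed(seed, code)

conv_otf_ref <- function(x, psf) Re(ubsim:::ifft2(ubsim:::fft2(x) * psf$otf))

band_limited_noise <- function(n, cutoff, seed) {
  with_seed_local(seed, {
    wn <- matrix(rnorm(n * n), n, n)
    fr <- ubsim:::fftshift2(ubsim:::freq_radius(c(n, n), 1)) * 2
    Ik <- ubsim:::fftshift2(ubsim:::fft2(wn))
    Ik[fr > cutoff] <- 0
    Re(ubsim:::ifft2(ubsim:::ifftshift2(Ik)))
  })
}
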