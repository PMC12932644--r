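# Image-quality metrics and decorrelation resolution

test_that("identical images give zero error and unit similarity", {
  img <- normalize_range(make_phantom("rings", 64, seed = 4)$object)
  m <- image_metrics(img, img)
  expect_equal(m$mse, 0)
  expect_equal(m$psnr, 300)        # capped sentinel for infinite PSNR
  expect_equal(m$ssim, 1, tolerance = 1e-12)
})

test_that("a constant offset gives mse = c^2 and the PSNR identity holds", {
  img <- normalize_range(make_phantom("filaments", 64, seed = 5)$object)
  cshift <- 0.1
  m <- image_metrics(pmin(img + cshift, 1 + cshift), img)
  expect_equal(m$mse, cshift^2, tolerance = 1e-12)
  expect_equal(m$psnr, 10 * log10(1 / m$mse), tolerance = 1e-9)
  with_seed_local(6, {
    noisy <- img + matrix(rnorm(length(img), 0, 0.05), nrow(img))
    m2 <- image_metrics(noisy, img)
    expect_equal(m2$psnr, 10 * log10(1 / m2$mse), tolerance = 1e-9)
    # SSIM is symmetric and below 1 for distinct images
    expect_equal(ssim_sym <- image_metrics(img, noisy)$ssim, m2$ssim,
                 tolerance = 1e-12)
    expect_lt(m2$ssim, 1)
  })
  expect_error(image_metrics(img, img[1:32, ]), "disagree")
})

test_that("decorrelation analysis recovers a designed band limit", {
  for (seed in 1:5) {
    img <- band_limited_noise(128, 0.5, seed)
    est <- decorrelation_resolution(img, 1)
    expect_lt(abs(est$kc - 0.5), 0.05)
  }
})

test_that("decorrelation estimates are consistent under resampling", {
  img <- band_limited_noise(96, 0.4, seed = 9)
  r1 <- decorrelation_resolution(img, 1)$resolution
  # proper Fourier (sinc) upsampling x2: pixel size halves
  n <- nrow(img)
  Ik <- ubsim:::fftshift2(ubsim:::fft2(img))
  big <- matrix(0 + 0i, 2 * n, 2 * n)
  big[(n / 2 + 1):(3 * n / 2), (n / 2 + 1):(3 * n / 2)] <- Ik
  img2 <- Re(ubsim:::ifft2(ubsim:::ifftshift2(big))) * 4
  r2 <- decorrelation_resolution(img2, 0.5)$resolution
  expect_lt(abs(r1 - r2) / r1, 0.05)
})

test_that("degenerate images are rejected", {
  expect_error(decorrelation_resolution(matrix(1, 64, 64)), "flat")
  expect_error(decorrelation_resolution(matrix(rnorm(32 * 32), 32)), "64")
})

test_that("the quality report combines metrics and resolution ratio", {
  sim <- tiny_instance(16, L = 4, seed = 2)
  cfg <- optical_config(image_shape = 64)
  acq <- simulate_acquisition(cfg, "filaments", L = 16, seed = 31)
  stk <- normalize_stack(acq$stack)
  tr <- blind_sim_reconstruct(stk, acq$psf, solver_config("prcg",
                                                          max_iters = 80))
  rep <- quality_report(tr$rho, widefield_image(stk), acq$phantom$object,
                        pixel_size = cfg$pixel_size)
  expect_gt(rep$improvement_factor, 1)
  expect_true(is.finite(rep$psnr))
  expect_gt(rep$ssim, 0)
})

test_that("log-spectra expose the expected structure", {
  # delta image: perfectly flat magnitude spectrum
  d <- matrix(0, 32, 32); d[17, 17] <- 1
  s <- fourier_log_spectrum(d)
  expect_lt(diff(range(s)), 1e-9)
  # pure sinusoid: two symmetric peaks at the carrier frequency
  x <- outer(rep(1, 32), cos(2 * pi * 4 * (0:31) / 32))
  s2 <- fourier_log_spectrum(x)
  pk <- which(s2 > 0.99, arr.ind = TRUE)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk[, 2]), c(17 - 4, 17 + 4))
  # band-limited image: support radius matches the cutoff within one bin
  bl <- band_limited_noise(64, 0.5, seed = 3)
  s3 <- fourier_log_spectrum(bl)
  fr <- ubsim:::fftshift2(ubsim:::freq_radius(c(64, 64), 1)) * 2
  expect_lt(max(s3[fr > 0.5 + 2 / 64]), 1e-6)
  expect_gt(max(s3[fr <= 0.5 & fr > 0.45]), 1e-3)
})
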