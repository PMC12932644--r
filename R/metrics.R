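# Image-quality metrics against ground truth and reference-free resolution
# estimation by image decorrelation analysis.

#' MSE, PSNR and SSIM between a reconstruction and a reference
#'
#' Standard definitions on images normalised to a common dynamic range:
#' `psnr = 10 log10(range^2 / mse)` (capped at 300 dB for identical
#' images), SSIM with a 7x7 Gaussian window (sigma 1.5) and the usual
#' stabilising constants `C1 = (0.01 R)^2`, `C2 = (0.03 R)^2`.
#'
#' @param reconstruction,ground_truth nonnegative matrices of equal shape.
#' @param dynamic_range value range `R` of the images (default 1; use
#'   [normalize_range()] to map images onto `[0, 1]` first).
#' @return list with `mse`, `psnr` (dB), `ssim`.
#' @export
image_metrics <- function(reconstruction, ground_truth, dynamic_range = 1) {
  if (!all(dim(reconstruction) == dim(ground_truth)))
    stop("image shapes disagree")
  mse <- mean((reconstruction - ground_truth)^2)
  psnr <- if (mse == 0) 300 else 10 * log10(dynamic_range^2 / mse)
  list(mse = mse, psnr = min(psnr, 300), ssim = ssim_index(
    reconstruction, ground_truth, dynamic_range))
}

#' Min-max normalisation to a common range
#' @param img matrix.
#' @param range target upper bound (default 1).
#' @export
normalize_range <- function(img, range = 1) {
  lo <- min(img); hi <- max(img)
  if (hi <= lo) stop("cannot range-normalize a constant image")
  (img - lo) / (hi - lo) * range
}

# separable Gaussian filtering with edge renormalisation
gauss_filter <- function(img, sigma, half = 3L) {
  t <- (-half):half
  w <- exp(-t^2 / (2 * sigma^2)); w <- w / sum(w)
  pad_apply <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (k in seq_along(t)) {
      idx <- pmin(pmax(seq_len(n) + t[k], 1L), n)   # replicate border
      out <- out + w[k] * m[idx, , drop = FALSE]
    }
    out
  }
  t(pad_apply(t(pad_apply(img))))
}

ssim_index <- function(x, y, dynamic_range = 1, sigma = 1.5) {
  c1 <- (0.01 * dynamic_range)^2
  c2 <- (0.03 * dynamic_range)^2
  mx <- gauss_filter(x, sigma); my <- gauss_filter(y, sigma)
  sxx <- gauss_filter(x * x, sigma) - mx^2
  syy <- gauss_filter(y * y, sigma) - my^2
  sxy <- gauss_filter(x * y, sigma) - mx * my
  map <- ((2 * mx * my + c1) * (2 * sxy + c2)) /
    ((mx^2 + my^2 + c1) * (sxx + syy + c2))
  mean(map)
}

#' Reference-free resolution estimate by image decorrelation analysis
#'
#' Sweeps a family of low-pass mask radii over the normalised cross
#' correlation between the image spectrum and its phase-normalised (unit
#' modulus) spectrum, repeated for a series of Gaussian high-pass
#' pre-filterings of the image. The highest-frequency local maximum over
#' all decorrelation curves gives the cutoff `k_c` in Nyquist-normalised
#' units and the resolution `2 * pixel_size / k_c`.
#'
#' @param image 2-D image, at least 64 x 64 px.
#' @param pixel_size pixel size (nm); with the default 1 the result is in
#'   units of pixels.
#' @param n_radii number of mask radii swept (default 50).
#' @param n_filters number of high-pass strengths (default 10).
#' @param apodize cosine-taper border applied before the FFT (px).
#' @return list with `resolution` (same units as `pixel_size * 2`), `kc`
#'   (Nyquist-normalised cutoff in (0, 1]), and the `curves` matrix
#'   (n_radii x (n_filters + 1)) for diagnostics.
#' @export
decorrelation_resolution <- function(image, pixel_size = 1, n_radii = 50L,
                                     n_filters = 10L, apodize = 8L) {
  if (min(dim(image)) < 64)
    stop("decorrelation analysis needs at least 64 x 64 px")
  if (stats::sd(image) == 0)
    stop("flat image: resolution is undefined")
  img <- image - mean(image)
  if (apodize > 0) img <- img * cosine_taper(dim(img), apodize)
  Ik <- fftshift2(fft2(img))
  mod <- Mod(Ik)
  In <- Ik
  nz <- mod > 0
  In[nz] <- Ik[nz] / mod[nz]
  # Nyquist-normalised radial frequency per bin (1 = Nyquist)
  d <- dim(img)
  fr <- fftshift2(freq_radius(d, 1)) * 2
  radii <- seq(1 / n_radii, 1, length.out = n_radii)
  # Gaussian high-pass strengths, log-spaced in normalised frequency
  sigmas <- exp(seq(log(0.08), log(1.0), length.out = n_filters))
  curves <- matrix(NA_real_, n_radii, n_filters + 1L)
  for (j in 0:n_filters) {
    Ikj <- if (j == 0) Ik else Ik * (1 - exp(-fr^2 / (2 * sigmas[j]^2)))
    aj <- sum(Mod(Ikj)^2)
    for (i in seq_len(n_radii)) {
      mask <- fr <= radii[i]
      num <- sum(Re(Ikj[mask] * Conj(In[mask])))
      den <- sqrt(aj * sum(mask))
      curves[i, j + 1L] <- if (den > 0) num / den else 0
    }
  }
  kc <- 0
  for (j in seq_len(ncol(curves))) {
    pk <- curve_peak(radii, curves[, j])
    if (!is.null(pk) && pk$r > kc) kc <- pk$r
  }
  if (kc <= 0) stop("no decorrelation peak found: image appears structureless")
  list(resolution = 2 * pixel_size / kc, kc = kc, curves = curves,
       radii = radii)
}

# highest-frequency local maximum of a decorrelation curve, with parabolic
# refinement. A maximum qualifies only if the curve drops by at least
# `min_prominence` after it before exceeding it again, which rejects the
# small wiggles riding on the noise-induced rising tail at high frequency.
curve_peak <- function(radii, d, min_prominence = 0.01) {
  n <- length(d)
  best <- NULL
  for (i in 2:(n - 1)) {
    if (d[i] >= d[i - 1] && d[i] > d[i + 1]) {
      drops <- FALSE
      for (k in (i + 1):n) {
        if (d[k] <= d[i] - min_prominence) { drops <- TRUE; break }
        if (d[k] > d[i]) break
      }
      if (!drops) next
      denom <- d[i - 1] - 2 * d[i] + d[i + 1]
      shift <- if (denom != 0) 0.5 * (d[i - 1] - d[i + 1]) / denom else 0
      shift <- max(-0.5, min(0.5, shift))
      r <- radii[i] + shift * (radii[2] - radii[1])
      if (is.null(best) || r > best$r) best <- list(r = r, a = d[i])
    }
  }
  best
}

#' Quality report for a reconstruction
#'
#' Combines the ground-truth metrics (after min-max normalisation of both
#' images to `[0, 1]`) with decorrelation resolution estimates of the
#' reconstruction and of the widefield reference, and their ratio (the
#' resolution improvement factor).
#'
#' @param reconstruction matrix, the super-resolved estimate.
#' @param widefield matrix, the diffraction-limited reference image.
#' @param ground_truth optional matrix of the true object.
#' @param pixel_size nm per pixel.
#' @return list of class `ubsim_report`: `mse`, `psnr`, `ssim` (NA without
#'   ground truth), `resolution_widefield`, `resolution_reconstruction`
#'   (nm), `improvement_factor`.
#' @export
quality_report <- function(reconstruction, widefield, ground_truth = NULL,
                           pixel_size = 1) {
  m <- list(mse = NA_real_, psnr = NA_real_, ssim = NA_real_)
  if (!is.null(ground_truth))
    m <- image_metrics(normalize_range(reconstruction),
                       normalize_range(ground_truth))
  r_wf <- decorrelation_resolution(widefield, pixel_size)$resolution
  r_sr <- decorrelation_resolution(reconstruction, pixel_size)$resolution
  structure(list(mse = m$mse, psnr = m$psnr, ssim = m$ssim,
                 resolution_widefield = r_wf,
                 resolution_reconstruction = r_sr,
                 improvement_factor = r_wf / r_sr,
                 pixel_size = pixel_size),
            class = "ubsim_report")
}

#' @export
print.ubsim_report <- function(x, ...) {
  cat(sprintf(paste0(
    "ubsim quality report (images min-max normalised to [0,1]):\n",
    "  mse %.4g | psnr %.4g dB | ssim %.4g\n",
    "  resolution: widefield %.3g, reconstruction %.3g (x%.2f improvement)\n"),
    x$mse, x$psnr, x$ssim, x$resolution_widefield,
    x$resolution_reconstruction, x$improvement_factor))
  invisible(x)
}

#' Centred logarithmic Fourier magnitude spectrum
#'
#' `log(1 + |FFT(image)|)`, zero frequency at the array centre, normalised
#' to a maximum of 1; the standard visual check for recovered
#' high-frequency content.
#'
#' @param image 2-D image.
#' @return matrix in `[0, 1]`.
#' @export
fourier_log_spectrum <- function(image) {
  s <- log1p(Mod(fftshift2(fft2(image))))
  if (max(s) > 0) s <- s / max(s)
  s
}
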