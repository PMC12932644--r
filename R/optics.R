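# Optical configuration and the diffraction-limited detection PSF/OTF.

#' Optical configuration for simulation and reconstruction
#'
#' Bundles the physical parameters of the simulated microscope: emission
#' wavelength, detection and illumination numerical apertures, camera pixel
#' size and image shape. The pixel size must satisfy
#' `pixel_size <= wavelength / (4 * na_detection)` so that the doubled
#' (super-resolved) support up to `4 NA / lambda` is still below the sampling
#' Nyquist frequency.
#'
#' @param wavelength emission wavelength in nm.
#' @param na_detection detection objective numerical aperture.
#' @param na_illumination numerical aperture of the speckle illumination path
#'   (defaults to the detection NA, i.e. diffraction-limited speckles).
#' @param pixel_size camera pixel size in nm (sample plane).
#' @param image_shape integer `(rows, cols)`; a scalar is recycled.
#' @param seed integer seed used by stochastic generators that take this
#'   config (may be overridden per call).
#' @return an object of class `ubsim_config`.
#' @examples
#' cfg <- optical_config(wavelength = 500, na_detection = 1.0,
#'                       pixel_size = 40, image_shape = 64)
#' @export
optical_config <- function(wavelength = 500, na_detection = 1.0,
                           na_illumination = na_detection,
                           pixel_size = 40, image_shape = c(64, 64),
                           seed = 1L) {
  if (length(image_shape) == 1) image_shape <- rep(image_shape, 2)
  image_shape <- as.integer(image_shape)
  stopifnot(wavelength > 0, na_detection > 0, na_detection <= 1.5,
            na_illumination > 0, na_illumination <= 1.5, pixel_size > 0)
  if (any(image_shape < 16))
    stop("image_shape dimensions must be at least 16 pixels")
  if (pixel_size > wavelength / (4 * na_detection))
    stop(sprintf(paste0(
      "pixel_size %.1f nm undersamples the super-resolved band: need ",
      "pixel_size <= wavelength/(4*NA) = %.1f nm"),
      pixel_size, wavelength / (4 * na_detection)))
  structure(list(wavelength = wavelength, na_detection = na_detection,
                 na_illumination = na_illumination, pixel_size = pixel_size,
                 image_shape = image_shape, seed = as.integer(seed)),
            class = "ubsim_config")
}

#' @export
print.ubsim_config <- function(x, ...) {
  cat(sprintf(
    "ubsim optical config: %d x %d px @ %.3g nm, lambda %.3g nm, NA det %.2f / ill %.2f\n",
    x$image_shape[1], x$image_shape[2], x$pixel_size, x$wavelength,
    x$na_detection, x$na_illumination))
  invisible(x)
}

# closed-form incoherent OTF of an aberration-free circular pupil:
# autocorrelation of a disk, chat function of u = f / f_c with f_c = 2 NA / lambda
airy_otf_profile <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  (2 / pi) * (acos(u) - u * sqrt(1 - u^2))
}

#' Diffraction-limited detection PSF
#'
#' Builds the incoherent PSF of an aberration-free circular pupil on the
#' config's pixel grid. The OTF is the autocorrelation of the pupil (the
#' classical "chat" function), with incoherent cutoff
#' `f_c = 2 * na_detection / wavelength`; the kernel is its inverse DFT,
#' normalised to unit sum and centred at the geometric array centre.
#'
#' @param config an [optical_config()].
#' @return an object of class `ubsim_psf` with fields `kernel` (unit-sum,
#'   centred), `otf` (unshifted DFT layout, real), `cutoff_frequency`
#'   (cycles/nm) and the originating `config`.
#' @examples
#' psf <- make_psf(optical_config())
#' sum(psf$kernel)
#' @export
make_psf <- function(config) {
  stopifnot(inherits(config, "ubsim_config"))
  fc <- 2 * config$na_detection / config$wavelength
  nyq <- 1 / (2 * config$pixel_size)
  if (fc > nyq)
    stop(sprintf(paste0(
      "pixel grid too coarse to sample the detection cutoff: cutoff %.4g ",
      "cycles/nm exceeds the sampling Nyquist %.4g cycles/nm"), fc, nyq))
  fr <- freq_radius(config$image_shape, config$pixel_size)
  otf <- airy_otf_profile(fr / fc)
  otf[fr >= fc] <- 0
  k_unshift <- Re(ifft2(otf))
  k_unshift[k_unshift < 0] <- 0    # clip sub-eps negatives from roundoff
  k_unshift <- k_unshift / sum(k_unshift)
  otf <- Re(fft2(k_unshift))       # OTF consistent with the clipped kernel
  structure(list(kernel = fftshift2(k_unshift), otf = otf,
                 cutoff_frequency = fc, config = config),
            class = "ubsim_psf")
}

#' @export
print.ubsim_psf <- function(x, ...) {
  cat(sprintf("ubsim PSF: %d x %d px, cutoff %.4g cycles/nm\n",
              nrow(x$kernel), ncol(x$kernel), x$cutoff_frequency))
  invisible(x)
}
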