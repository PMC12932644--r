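# The imaging forward model: each sub-frame is the object multiplied by one
# speckle illumination pattern and blurred by the detection PSF,
# M_l = (I_l * rho) convolved with h, plus camera noise.

#' Camera noise parameters
#'
#' Scaled-Poisson shot noise plus additive Gaussian read noise (the standard
#' sCMOS model). `photon_scale` is the expected photon count at the peak of
#' the noiseless stack; `Inf` with `read_sigma = 0` gives noiseless frames.
#'
#' @param photon_scale expected counts at the brightest noiseless pixel
#'   (default 500); `Inf` disables shot noise.
#' @param read_sigma read-noise standard deviation in counts (default 2).
#' @export
noise_params <- function(photon_scale = 500, read_sigma = 2) {
  if (photon_scale <= 0 || read_sigma < 0)
    stop("noise parameters must be positive (photon_scale) / nonnegative (read_sigma)")
  list(photon_scale = photon_scale, read_sigma = read_sigma)
}

#' Simulate a stack of diffraction-limited sub-frames
#'
#' Applies the forward model frame by frame: elementwise product of the
#' object with each illumination pattern, circular convolution with the
#' detection PSF through the frequency domain, then optional shot and read
#' noise. Negative values produced by read noise are clipped at zero, as on
#' a camera after offset subtraction.
#'
#' @param phantom an `ubsim_phantom` (or a bare nonnegative matrix).
#' @param speckles an `ubsim_speckles` stack.
#' @param psf an `ubsim_psf`.
#' @param noise a [noise_params()] list; default is noiseless.
#' @param seed integer seed for the noise draw.
#' @return object of class `ubsim_stack`: list with `frames`
#'   (rows x cols x L), `pixel_size`, `noise`, and the generating `config`.
#' @examples
#' cfg <- optical_config(image_shape = 32)
#' ph  <- make_phantom("puncta", 32, seed = 2)
#' sp  <- make_speckle_stack(cfg, L = 4, seed = 2)
#' stk <- forward_subframes(ph, sp, make_psf(cfg))
#' @export
forward_subframes <- function(phantom, speckles, psf,
                              noise = noise_params(Inf, 0), seed = 1L) {
  rho <- if (inherits(phantom, "ubsim_phantom")) phantom$object else phantom
  stopifnot(inherits(speckles, "ubsim_speckles"), inherits(psf, "ubsim_psf"))
  if (any(rho < 0)) stop("object density must be nonnegative")
  d <- dim(speckles$patterns)
  if (!all(dim(rho) == d[1:2]) || !all(dim(psf$otf) == d[1:2]))
    stop("phantom, speckle and PSF shapes disagree")
  L <- d[3]
  frames <- array(0, d)
  for (l in seq_len(L))
    frames[, , l] <- conv_otf(speckles$patterns[, , l] * rho, psf$otf)
  frames[frames < 0 & frames > -1e-12] <- 0   # FFT roundoff only
  if (is.finite(noise$photon_scale) || noise$read_sigma > 0) {
    peak <- max(frames)
    if (peak <= 0) stop("cannot scale noise for an all-zero stack")
    frames <- with_seed(seed, {
      out <- frames
      if (is.finite(noise$photon_scale)) {
        s <- noise$photon_scale / peak
        out <- array(stats::rpois(length(out), lambda = pmax(out, 0) * s) / s,
                     dim = d)
      }
      if (noise$read_sigma > 0) {
        # read noise is in counts on the photon_scale count axis; with shot
        # noise disabled it is taken in the native frame units
        s <- if (is.finite(noise$photon_scale)) noise$photon_scale / peak else 1
        out <- out + array(stats::rnorm(length(out), 0, noise$read_sigma) / s,
                           dim = d)
      }
      out
    })
    frames[frames < 0] <- 0
  }
  structure(list(frames = frames, pixel_size = speckles$config$pixel_size,
                 noise = noise, config = speckles$config),
            class = "ubsim_stack")
}

#' @export
print.ubsim_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("ubsim sub-frame stack: L = %d frames of %d x %d px @ %.3g nm/px\n",
              d[3], d[1], d[2], x$pixel_size))
  invisible(x)
}

#' Normalise a sub-frame stack to unit mean intensity
#'
#' Divides all frames by the spatio-temporal mean so that the average
#' illumination intensity `I_0` equals 1, the convention assumed by the
#' solvers. Removes the arbitrary camera-gain unit.
#'
#' @param stack an `ubsim_stack` (or bare 3-D array).
#' @return stack of the same class with unit-mean frames.
#' @export
normalize_stack <- function(stack) {
  fr <- if (inherits(stack, "ubsim_stack")) stack$frames else stack
  m <- mean(fr)
  if (m <= 0) stop("cannot normalize an all-zero stack")
  if (inherits(stack, "ubsim_stack")) {
    stack$frames <- fr / m
    stack
  } else fr / m
}

#' Widefield (uniform-illumination) image of a stack
#'
#' The mean over sub-frames: with speckles summing to a uniform field this
#' approximates the diffraction-limited widefield image `I_0 * (rho * h)`.
#'
#' @param stack an `ubsim_stack` or 3-D array.
#' @return matrix.
#' @export
widefield_image <- function(stack) {
  fr <- if (inherits(stack, "ubsim_stack")) stack$frames else stack
  d <- dim(fr)
  matrix(rowMeans(matrix(fr, ncol = d[3])), d[1], d[2])
}
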