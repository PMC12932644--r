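# Frequency-domain primitives shared by the simulator, the cost function and
# the solvers. All convolutions in the package are circular (periodic) and
# evaluated through the DFT, so simulator and solver use one convention.

#' Centred spatial-frequency grids for an image shape
#'
#' Returns the radial spatial-frequency magnitude (cycles per length unit) for
#' every DFT bin of an `nr x nc` image sampled at `pixel_size`, in the
#' unshifted DFT layout (frequency 0 at element \[1,1\]).
#'
#' @param shape integer vector `(rows, cols)`.
#' @param pixel_size sampling step (same length unit as the wavelength).
#' @return matrix of `|f|` values, cycles / length-unit.
#' @keywords internal
freq_radius <- function(shape, pixel_size = 1) {
  fr <- fft_freqs(shape[1], pixel_size)
  fc <- fft_freqs(shape[2], pixel_size)
  sqrt(outer(fr^2, fc^2, "+"))
}

# DFT sample frequencies, unshifted layout (like numpy fftfreq)
fft_freqs <- function(n, pixel_size = 1) {
  k <- c(seq_len(ceiling(n / 2)) - 1L, seq.int(-floor(n / 2), -1L))
  k / (n * pixel_size)
}

# centre the zero-frequency bin (or the PSF peak) for display / kernels
fftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((floor(nr / 2) + 1):nr, 1:floor(nr / 2)),
    c((floor(nc / 2) + 1):nc, 1:floor(nc / 2))]
}

ifftshift2 <- function(x) {
  nr <- nrow(x); nc <- ncol(x)
  x[c((nr - floor(nr / 2) + 1):nr, 1:(nr - floor(nr / 2))),
    c((nc - floor(nc / 2) + 1):nc, 1:(nc - floor(nc / 2)))]
}

fft2 <- function(x) stats::fft(x)
ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

#' Circular convolution with a cached transfer function
#'
#' Multiplies the image spectrum by `otf` (unshifted layout) and returns the
#' real part of the inverse transform. The adjoint (correlation) is obtained
#' with `Conj(otf)`; for the centrosymmetric PSFs used here the OTF is real
#' and the two coincide.
#'
#' @keywords internal
conv_otf <- function(x, otf) Re(ifft2(fft2(x) * otf))

corr_otf <- function(x, otf) Re(ifft2(fft2(x) * Conj(otf)))

# cosine-taper (Tukey-like) border window used to suppress periodic
# wrap-around for objects that approach the array edge
cosine_taper <- function(shape, border = 8L) {
  ramp <- function(n) {
    w <- rep(1, n)
    if (border > 0 && n > 2 * border) {
      t <- (seq_len(border) - 0.5) / border
      edge <- 0.5 * (1 - cos(pi * t))
      w[seq_len(border)] <- edge
      w[n + 1 - seq_len(border)] <- edge
    }
    w
  }
  outer(ramp(shape[1]), ramp(shape[2]))
}

# run `expr` under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}
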