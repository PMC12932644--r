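# One-call simulation of speckle blind-SIM acquisitions and datasets.

#' Simulate one speckle blind-SIM acquisition
#'
#' Generates a phantom, a stack of L diffraction-limited speckle patterns
#' and the corresponding noisy sub-frames in one call. All randomness
#' derives from `seed`.
#'
#' @param config an [optical_config()].
#' @param kind phantom kind (see [make_phantom()]).
#' @param L number of sub-frames.
#' @param noise a [noise_params()] list.
#' @param seed integer seed.
#' @param density_params forwarded to [make_phantom()].
#' @return list with `stack` (`ubsim_stack`), `phantom`, `speckles`, `psf`.
#' @examples
#' sim <- simulate_acquisition(optical_config(image_shape = 32), L = 4,
#'                             seed = 1)
#' @export
simulate_acquisition <- function(config = optical_config(),
                                 kind = "filaments", L = 16L,
                                 noise = noise_params(), seed = 1L,
                                 density_params = list()) {
  psf <- make_psf(config)
  phantom <- make_phantom(kind, config$image_shape, density_params,
                          seed = seed)
  speckles <- make_speckle_stack(config, L, seed = seed + 10000L)
  stack <- forward_subframes(phantom, speckles, psf, noise,
                             seed = seed + 20000L)
  list(stack = stack, phantom = phantom, speckles = speckles, psf = psf)
}

#' Simulate a dataset of blind-SIM stacks
#'
#' Cycles through the requested phantom kinds, one stack per seed offset.
#' Used for training and evaluating the unrolled model.
#'
#' @inheritParams simulate_acquisition
#' @param n_stacks number of acquisitions.
#' @param kinds phantom kinds to cycle through.
#' @param base_seed seed of the first acquisition; stack `i` uses
#'   `base_seed + i - 1`.
#' @return list with `stacks` (list of `ubsim_stack`), `phantoms`, `psf`.
#' @export
simulate_dataset <- function(config = optical_config(), n_stacks = 8L,
                             L = 16L,
                             kinds = c("filaments", "puncta", "tubule_mesh",
                                       "rings"),
                             noise = noise_params(), base_seed = 1L) {
  psf <- make_psf(config)
  stacks <- vector("list", n_stacks)
  phantoms <- vector("list", n_stacks)
  for (i in seq_len(n_stacks)) {
    sim <- simulate_acquisition(config, kinds[((i - 1L) %% length(kinds)) + 1L],
                                L, noise, seed = base_seed + i - 1L)
    stacks[[i]] <- sim$stack
    phantoms[[i]] <- sim$phantom
  }
  list(stacks = stacks, phantoms = phantoms, psf = psf)
}

#' Display an image or cost trace
#'
#' Base-graphics helpers: `plot_image()` shows a matrix in microscope
#' orientation with a grayscale palette; `plot()` on an `ubsim_trace` draws
#' the cost history on a log scale.
#'
#' @param img matrix.
#' @param main plot title.
#' @param ... passed to [graphics::image()].
#' @export
plot_image <- function(img, main = "", ...) {
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(img) / ncol(img), main = main, ...)
}

#' @param x an `ubsim_trace`.
#' @param y ignored.
#' @rdname plot_image
#' @export
plot.ubsim_trace <- function(x, y, ...) {
  graphics::plot(seq_along(x$cost_history) - 1L, x$cost_history, log = "y",
                 type = "l", xlab = "iteration", ylab = "cost",
                 main = sprintf("blind-SIM %s", x$config$method), ...)
  invisible(x)
}
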