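# Fully developed speckle illumination patterns and the uniform-sum
# diagnostic. A speckle field is the inverse transform of a uniform-random
# phase screen restricted to the illumination pupil; its intensity is
# band-limited to twice the coherent pupil radius, i.e. to
# 2 * na_illumination / wavelength, matching a diffraction-limited
# illumination path.

#' Generate a stack of diffraction-limited speckle illumination patterns
#'
#' Each pattern is `|IFFT(pupil-masked uniform-random-phase field)|^2`,
#' rescaled jointly so the mean over all patterns and pixels equals
#' `mean_intensity` (the constant average intensity `I_0`). Fine-grained,
#' fully developed speckle has an exponential intensity histogram.
#'
#' @param config an [optical_config()]; the pupil radius is
#'   `na_illumination / wavelength`.
#' @param L number of patterns (sub-frames), at least 2.
#' @param mean_intensity target spatio-temporal mean `I_0` (default 1).
#' @param seed integer seed (default: `config$seed`).
#' @return object of class `ubsim_speckles`: list with `patterns`
#'   (rows x cols x L array), `mean_intensity`, `config`.
#' @examples
#' sp <- make_speckle_stack(optical_config(), L = 8, seed = 3)
#' mean(sp$patterns)
#' @export
make_speckle_stack <- function(config, L, mean_intensity = 1,
                               seed = config$seed) {
  stopifnot(inherits(config, "ubsim_config"))
  if (L < 2)
    stop("blind-SIM needs at least L = 2 speckle encodings per stack")
  fr <- freq_radius(config$image_shape, config$pixel_size)
  pupil <- fr <= config$na_illumination / config$wavelength
  if (sum(pupil) < 4)
    stop("pixel grid too coarse: illumination pupil contains <4 DFT bins")
  nr <- config$image_shape[1]; nc <- config$image_shape[2]
  pat <- with_seed(seed, {
    arr <- array(0, c(nr, nc, L))
    for (l in seq_len(L)) {
      phase <- matrix(stats::runif(nr * nc, 0, 2 * pi), nr, nc)
      field <- ifft2(pupil * exp(1i * phase))
      arr[, , l] <- Mod(field)^2
    }
    arr
  })
  pat <- pat * (mean_intensity / mean(pat))
  structure(list(patterns = pat, mean_intensity = mean_intensity,
                 config = config), class = "ubsim_speckles")
}

#' @export
print.ubsim_speckles <- function(x, ...) {
  d <- dim(x$patterns)
  cat(sprintf("ubsim speckle stack: L = %d patterns of %d x %d px, I0 = %.3g\n",
              d[3], d[1], d[2], x$mean_intensity))
  invisible(x)
}

#' Deviation of the speckle sum from a uniform field
#'
#' Blind-SIM assumes the L illumination patterns sum to the uniform field
#' `L * I_0`. This computes, for each supplied stack, the relative RMS
#' deviation `rms(sum_l I_l / (L I_0) - 1)` over pixels. For independent
#' fully developed speckles the deviation shrinks as `1/sqrt(L)`.
#'
#' @param speckle_stacks a list of [make_speckle_stack()] results (typically
#'   one per value of L).
#' @return data.frame with columns `L` and `deviation`.
#' @seealso [uniformity_scaling()] for the Monte-Carlo slope fit.
#' @export
uniformity_deviation <- function(speckle_stacks) {
  if (inherits(speckle_stacks, "ubsim_speckles"))
    speckle_stacks <- list(speckle_stacks)
  rows <- lapply(speckle_stacks, function(s) {
    stopifnot(inherits(s, "ubsim_speckles"))
    L <- dim(s$patterns)[3]
    rel <- rowMeans(matrix(s$patterns, ncol = L)) / s$mean_intensity - 1
    data.frame(L = L, deviation = sqrt(mean(rel^2)))
  })
  do.call(rbind, rows)
}

#' Monte-Carlo scaling of the uniform-sum error with L
#'
#' Generates independent speckle stacks for each requested L over several
#' seeds, averages the relative RMS deviation of the sum from uniformity,
#' and fits the log-log slope. Independent speckle realisations give a slope
#' of -1/2 (the `1/sqrt(L)` error rate of the uniformity approximation).
#'
#' @param config an [optical_config()].
#' @param L_values at least 3 distinct pattern counts (default
#'   `c(8, 16, 32, 64, 128)`).
#' @param n_seeds Monte-Carlo repeats per L (default 20).
#' @param base_seed offset applied to the per-repeat seeds.
#' @return list with `table` (L, mean deviation), `slope`, and the `lm` fit.
#' @export
uniformity_scaling <- function(config, L_values = c(8, 16, 32, 64, 128),
                               n_seeds = 20, base_seed = 1L) {
  L_values <- sort(unique(as.integer(L_values)))
  if (length(L_values) < 3)
    stop("need at least 3 distinct L values to fit the scaling slope")
  dev <- sapply(seq_along(L_values), function(i) {
    mean(sapply(seq_len(n_seeds), function(s) {
      st <- make_speckle_stack(config, L_values[i],
                               seed = base_seed + 1000L * i + s)
      uniformity_deviation(st)$deviation
    }))
  })
  tab <- data.frame(L = L_values, deviation = dev)
  fit <- stats::lm(log(deviation) ~ log(L), data = tab)
  list(table = tab, slope = unname(stats::coef(fit)[2]), fit = fit)
}
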