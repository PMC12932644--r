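# The blind-SIM data-fidelity objective over square-root auxiliary
# variables. The object and the first L-1 illumination patterns are
# parameterized as rho = xi^2 and I_l = i_l^2 (nonnegative by construction);
# the L-th pattern is derived from the uniform-sum constraint,
# I_L = L*I_0 - sum_{l<L} i_l^2, and may go negative (reported, not
# clamped). The cost is
#   F = sum_{l<L} || M_l - (xi^2 i_l^2)*h ||^2 + || M_L - (xi^2 I_L)*h ||^2 .

#' Auxiliary square-root state for blind-SIM
#'
#' @param xi real matrix, square-root object amplitude (`rho = xi^2`).
#' @param aux_illums rows x cols x (L-1) array of square-root illumination
#'   amplitudes (`I_l = i_l^2`).
#' @param i0 mean illumination intensity `I_0` (1 after [normalize_stack()]).
#' @return object of class `ubsim_aux_state`.
#' @export
aux_state <- function(xi, aux_illums, i0 = 1) {
  stopifnot(is.matrix(xi), length(dim(aux_illums)) == 3,
            all(dim(aux_illums)[1:2] == dim(xi)))
  structure(list(xi = xi, aux_illums = aux_illums, i0 = i0),
            class = "ubsim_aux_state")
}

#' @export
print.ubsim_aux_state <- function(x, ...) {
  cat(sprintf("ubsim aux state: %d x %d px, L = %d (last pattern derived)\n",
              nrow(x$xi), ncol(x$xi), dim(x$aux_illums)[3] + 1L))
  invisible(x)
}

state_L <- function(state) dim(state$aux_illums)[3] + 1L

#' Derived L-th illumination pattern
#'
#' Recomputed on demand from the uniform-sum constraint
#' `I_L = L*I_0 - sum_{l<L} i_l^2`; never stored, so it cannot drift out of
#' sync with the auxiliary variables. May contain negative pixels during
#' optimization; see [negative_pattern_fraction()].
#'
#' @param state an [aux_state()].
#' @return matrix.
#' @export
derived_last_pattern <- function(state) {
  L <- state_L(state)
  d <- dim(state$aux_illums)
  sum_sq <- matrix(rowSums(matrix(state$aux_illums^2, ncol = d[3])),
                   d[1], d[2])
  L * state$i0 - sum_sq
}

#' Fraction of negative pixels in the derived pattern
#'
#' Diagnostic for the uniform-sum parameterization: the derived pattern
#' `I_L` is not constrained to be nonnegative.
#' @param state an [aux_state()].
#' @export
negative_pattern_fraction <- function(state) {
  mean(derived_last_pattern(state) < 0)
}

#' Object estimate from an auxiliary state
#' @param state an [aux_state()].
#' @return nonnegative matrix `rho = xi^2`.
#' @export
object_estimate <- function(state) state$xi^2

#' Recovered illumination patterns
#' @param state an [aux_state()].
#' @return rows x cols x L array; the first L-1 are `i_l^2`, the last is the
#'   derived pattern.
#' @export
illumination_estimates <- function(state) {
  d <- dim(state$aux_illums)
  out <- array(0, c(d[1], d[2], d[3] + 1L))
  out[, , seq_len(d[3])] <- state$aux_illums^2
  out[, , d[3] + 1L] <- derived_last_pattern(state)
  out
}

#' Residual images of the blind-SIM cost
#'
#' `r_l = M_l - (xi^2 i_l^2)*h` for `l < L` and
#' `r_L = M_L - (xi^2 I_L)*h` with the derived last pattern.
#'
#' @param state an [aux_state()].
#' @param data an `ubsim_stack` (normalised so `I_0 = 1`).
#' @param psf an `ubsim_psf`.
#' @return rows x cols x L array of residuals.
#' @export
blind_sim_residuals <- function(state, data, psf) {
  fr <- data$frames
  d <- dim(fr)
  if (d[3] != state_L(state))
    stop(sprintf("stack has L = %d frames but state encodes L = %d",
                 d[3], state_L(state)))
  if (!all(dim(state$xi) == d[1:2]))
    stop("state and stack image shapes disagree")
  L <- d[3]
  rho <- state$xi^2
  res <- array(0, d)
  for (l in seq_len(L - 1))
    res[, , l] <- fr[, , l] -
      conv_otf(rho * state$aux_illums[, , l]^2, psf$otf)
  res[, , L] <- fr[, , L] - conv_otf(rho * derived_last_pattern(state), psf$otf)
  res
}

#' Blind-SIM data-fidelity cost
#'
#' Sum of squared residual pixels over all L frames, with the per-frame
#' squared norms returned for diagnostics.
#'
#' @inheritParams blind_sim_residuals
#' @return list with `total` and `per_frame` (length-L vector).
#' @export
blind_sim_cost <- function(state, data, psf) {
  res <- blind_sim_residuals(state, data, psf)
  per <- apply(res, 3, function(r) sum(r^2))
  list(total = sum(per), per_frame = per)
}

#' Analytic descent directions of the blind-SIM cost
#'
#' Returns the negative gradient of the cost with respect to `xi` and each
#' auxiliary illumination, so the gradient-descent update is literally
#' `state + alpha * g`. With `r_l` the residuals and `corr` the correlation
#' with the PSF (adjoint of the convolution):
#' `g_xi  = 4 * xi * ( sum_{l<L} i_l^2 corr(r_l) + I_L corr(r_L) )`,
#' `g_i,l = 4 * xi^2 * i_l * ( corr(r_l) - corr(r_L) )`;
#' the sign of the second term follows from `dI_L/di_l = -2 i_l`.
#' Validated against central finite differences by [finite_diff_check()].
#'
#' @inheritParams blind_sim_residuals
#' @return list of class `ubsim_gradient` with `g_xi` (matrix) and
#'   `g_illums` (rows x cols x (L-1) array); descent convention.
#' @export
blind_sim_gradients <- function(state, data, psf) {
  res <- blind_sim_residuals(state, data, psf)
  d <- dim(res); L <- d[3]
  corr <- array(0, d)
  for (l in seq_len(L)) corr[, , l] <- corr_otf(res[, , l], psf$otf)
  IL <- derived_last_pattern(state)
  g_xi <- IL * corr[, , L]
  for (l in seq_len(L - 1))
    g_xi <- g_xi + state$aux_illums[, , l]^2 * corr[, , l]
  g_xi <- 4 * state$xi * g_xi
  rho <- state$xi^2
  g_illums <- array(0, c(d[1], d[2], L - 1L))
  for (l in seq_len(L - 1))
    g_illums[, , l] <- 4 * rho * state$aux_illums[, , l] *
      (corr[, , l] - corr[, , L])
  structure(list(g_xi = g_xi, g_illums = g_illums), class = "ubsim_gradient")
}

# inner product / norm over a (xi, illums) bundle viewed as one long vector
bundle_dot <- function(a, b) sum(a$g_xi * b$g_xi) + sum(a$g_illums * b$g_illums)

#' Finite-difference validation of the analytic gradients
#'
#' Compares each analytic gradient component to central differences of the
#' cost at randomly probed pixels and returns the worst relative error.
#' Probes are split between `xi` and the auxiliary illuminations.
#'
#' @inheritParams blind_sim_residuals
#' @param n_probes number of probed coordinates (default 10).
#' @param step central-difference step (default 1e-5).
#' @param seed seed for the probe draw.
#' @return worst relative error, `|analytic - numeric| / max(|numeric|, eps)`.
#' @export
finite_diff_check <- function(state, data, psf, n_probes = 10, step = 1e-5,
                              seed = 1L) {
  if (n_probes < 1) stop("need at least one probe")
  if (step <= 0) stop("finite-difference step must be positive")
  g <- blind_sim_gradients(state, data, psf)
  d <- dim(state$aux_illums)
  worst <- 0
  with_seed(seed, {
    for (k in seq_len(n_probes)) {
      in_xi <- k %% 2 == 1
      i <- sample.int(d[1], 1); j <- sample.int(d[2], 1)
      l <- sample.int(d[3], 1)
      sp <- state; sm <- state
      if (in_xi) {
        sp$xi[i, j] <- sp$xi[i, j] + step
        sm$xi[i, j] <- sm$xi[i, j] - step
        ana <- -g$g_xi[i, j]           # analytic stores the descent direction
      } else {
        sp$aux_illums[i, j, l] <- sp$aux_illums[i, j, l] + step
        sm$aux_illums[i, j, l] <- sm$aux_illums[i, j, l] - step
        ana <- -g$g_illums[i, j, l]
      }
      num <- (blind_sim_cost(sp, data, psf)$total -
                blind_sim_cost(sm, data, psf)$total) / (2 * step)
      scale <- max(abs(num), abs(ana), 1e-12)
      worst <- max(worst, abs(ana - num) / scale)
    }
  })
  worst
}
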