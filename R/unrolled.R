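# The unrolled blind-SIM model: a fixed number of iteration blocks, each
# computing the analytic descent directions of the data-fidelity cost and
# passing them through one shared convolutional update network before the
# additive update with a per-block learnable step scale. With the network
# replaced by the identity map the blocks reduce exactly to fixed-step
# gradient descent.

#' Construct an unrolled blind-SIM model
#'
#' @param n_blocks number of iteration blocks (default 6).
#' @param cnn an [update_cnn()], or the string `"identity"` for the
#'   identity update (the model is then literally fixed-step gradient
#'   descent, useful as an architectural sanity check).
#' @param alpha0 initial value of the learnable per-block step scales
#'   (default 0.1); a vector of length `n_blocks` is used as-is.
#' @param mode `"per_image"` (default): the single-channel network is
#'   applied to each gradient image independently, keeping the model
#'   agnostic to L. `"stacked"`: all L gradient images enter as channels of
#'   one tensor, fixing L at construction time (pass `channels = L` to
#'   [update_cnn()]).
#' @param normalize normalise the gradient bundle by its maximum absolute
#'   value before the network (default `TRUE`; the normalisation factor is
#'   treated as a constant during training).
#' @return object of class `ubsim_model`.
#' @export
unrolled_model <- function(n_blocks = 6L, cnn = update_cnn(),
                           alpha0 = 0.1, mode = c("per_image", "stacked"),
                           normalize = TRUE) {
  mode <- match.arg(mode)
  if (n_blocks < 1) stop("need at least one iteration block")
  if (!identical(cnn, "identity") && !inherits(cnn, "ubsim_cnn"))
    stop("cnn must be an update_cnn() or \"identity\"")
  if (mode == "stacked" && identical(cnn, "identity"))
    stop("stacked mode requires a real update network")
  alphas <- if (length(alpha0) == n_blocks) as.numeric(alpha0)
    else rep(alpha0[1], n_blocks)
  structure(list(n_blocks = as.integer(n_blocks), cnn = cnn,
                 step_scales = alphas, mode = mode,
                 normalize = isTRUE(normalize),
                 weights_version = format(Sys.time(), "%Y%m%d%H%M%S")),
            class = "ubsim_model")
}

#' @export
print.ubsim_model <- function(x, ...) {
  cat(sprintf("ubsim unrolled model: %d blocks, %s update, %d parameters\n",
              x$n_blocks,
              if (identical(x$cnn, "identity")) "identity" else
                sprintf("CNN width %d (%s)", x$cnn$width, x$mode),
              count_parameters(x)))
  invisible(x)
}

#' Count the trainable parameters of an unrolled model
#'
#' Exact count of scalars in the shared update network plus the per-block
#' step scales. The default architecture stays well below 250,000.
#'
#' @param model an [unrolled_model()].
#' @return integer count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "ubsim_model"))
  n <- length(model$step_scales)
  if (inherits(model$cnn, "ubsim_cnn")) n <- n + cnn_parameter_count(model$cnn)
  as.integer(n)
}

norm_eps <- 1e-12

#' Run the unrolled network on a sub-frame stack
#'
#' Starting from [init_state()], each block computes the analytic descent
#' bundle, normalises it by the maximum absolute value over all gradient
#' images (so the block is invariant to the raw gradient magnitude and the
#' update size is controlled by the learned step scales), applies the shared
#' update network, and advances the state by `state + alpha_n * update`.
#' With the identity network the normalisation is skipped and each block is
#' exactly one fixed-step gradient-descent update.
#'
#' @param model an [unrolled_model()].
#' @param data an `ubsim_stack`; normalised internally so `I_0 = 1`. Spatial
#'   dimensions must be divisible by 4 (two pooling stages).
#' @param psf an `ubsim_psf`.
#' @return list with `state` (final [aux_state()]), `rho` (object estimate),
#'   `cost` (final data-fidelity cost), `block_costs` (cost after each
#'   block, preceded by the initial cost).
#' @export
unrolled_forward <- function(model, data, psf) {
  stopifnot(inherits(model, "ubsim_model"))
  data <- normalize_stack(data)
  d <- dim(data$frames)
  if (any(d[1:2] %% 4 != 0))
    stop("image sides must be divisible by 4 (two rescaling stages)")
  state <- init_state(data, psf)
  block_costs <- numeric(model$n_blocks + 1L)
  block_costs[1] <- blind_sim_cost(state, data, psf)$total
  for (n in seq_len(model$n_blocks)) {
    bundle <- blind_sim_gradients(state, data, psf)
    upd <- apply_update_network(model, bundle)
    state <- gd_step(state, upd, model$step_scales[n])
    block_costs[n + 1L] <- blind_sim_cost(state, data, psf)$total
  }
  list(state = state, rho = object_estimate(state),
       cost = block_costs[model$n_blocks + 1L], block_costs = block_costs)
}

# numeric (inference) application of the update network to a bundle
apply_update_network <- function(model, bundle) {
  if (identical(model$cnn, "identity")) return(bundle)
  d <- dim(bundle$g_illums)
  L <- d[3] + 1L
  imgs <- c(list(bundle$g_xi),
            lapply(seq_len(d[3]), function(l) bundle$g_illums[, , l]))
  # one normalisation for the whole bundle: preserves the relative scale of
  # the object and illumination gradients while making the block invariant
  # to the absolute gradient magnitude (the update size is set by alpha_n)
  scale <- if (isTRUE(model$normalize))
    max(vapply(imgs, function(g) max(abs(g)), numeric(1))) + norm_eps else 1
  if (model$mode == "per_image") {
    x <- array(0, c(d[1], d[2], L, 1L))
    for (b in seq_len(L)) x[, , b, 1L] <- imgs[[b]] / scale
    y <- cnn_forward(x, model$cnn$params, model$cnn$leak)
    out_imgs <- lapply(seq_len(L), function(b) y[, , b, 1L])
  } else {
    if (model$cnn$channels != L)
      stop(sprintf("stacked-mode network expects L = %d but stack has L = %d",
                   model$cnn$channels, L))
    x <- array(0, c(d[1], d[2], 1L, L))
    for (b in seq_len(L)) x[, , 1L, b] <- imgs[[b]] / scale
    y <- cnn_forward(x, model$cnn$params, model$cnn$leak)
    out_imgs <- lapply(seq_len(L), function(b) y[, , 1L, b])
  }
  g_ill <- array(0, d)
  for (l in seq_len(d[3])) g_ill[, , l] <- out_imgs[[l + 1L]]
  list(g_xi = out_imgs[[1L]], g_illums = g_ill)
}

## ---- differentiable forward (training path) --------------------------------

# build the residual / cost / gradient computation in autograd ops so the
# loss can be back-propagated through every block, including through the
# analytic gradient of the cost (a Hessian-vector product of the physics).
ag_blind_sim_residuals <- function(xi, illums, frames, otf, i0 = 1) {
  L <- length(illums) + 1L
  rho <- ag_square(xi)
  ill_sq <- lapply(illums, ag_square)
  s <- ag_sum_list(ill_sq)
  IL <- ag_node(L * i0 - ag_value(s), list(s), function(g) list(-g))
  res <- vector("list", L)
  for (l in seq_len(L - 1))
    res[[l]] <- ag_sub(frames[[l]], ag_conv_otf(ag_mul(rho, ill_sq[[l]]), otf))
  res[[L]] <- ag_sub(frames[[L]], ag_conv_otf(ag_mul(rho, IL), otf))
  list(res = res, rho = rho, ill_sq = ill_sq, IL = IL)
}

ag_blind_sim_gradients <- function(xi, illums, frames, otf, i0 = 1) {
  L <- length(illums) + 1L
  rr <- ag_blind_sim_residuals(xi, illums, frames, otf, i0)
  res <- rr$res; rho <- rr$rho; ill_sq <- rr$ill_sq; IL <- rr$IL
  corr <- lapply(res, function(r) ag_corr_otf(r, otf))
  acc <- vector("list", L)
  for (l in seq_len(L - 1)) acc[[l]] <- ag_mul(ill_sq[[l]], corr[[l]])
  acc[[L]] <- ag_mul(IL, corr[[L]])
  g_xi <- ag_neg_scale_const(ag_mul(xi, ag_sum_list(acc)), 4)
  g_ill <- vector("list", L - 1L)
  for (l in seq_len(L - 1))
    g_ill[[l]] <- ag_neg_scale_const(
      ag_mul(ag_mul(rho, illums[[l]]), ag_sub(corr[[l]], corr[[L]])), 4)
  list(g_xi = g_xi, g_illums = g_ill, residuals = res)
}

ag_cost_from_residuals <- function(res) {
  ag_sum_list(lapply(res, ag_sum_sq))
}

# full differentiable unrolled forward; returns the final-cost node, the
# per-block cost nodes (costs after each block; the intermediate ones fall
# out of the next block's gradient computation for free) and the parameter
# leaves so the caller can read gradients after ag_backward()
ag_unrolled_forward <- function(model, data, psf) {
  d <- dim(data$frames)
  L <- d[3]
  frames <- lapply(seq_len(L), function(l) data$frames[, , l])
  st0 <- init_state(data, psf)
  param_leaves <- lapply(model$cnn$params, ag_leaf)
  names(param_leaves) <- names(model$cnn$params)
  alpha_leaves <- lapply(model$step_scales, ag_leaf)
  xi <- ag_leaf(st0$xi)
  illums <- lapply(seq_len(L - 1L), function(l) ag_leaf(st0$aux_illums[, , l]))
  block_losses <- vector("list", model$n_blocks)
  for (n in seq_len(model$n_blocks)) {
    gb <- ag_blind_sim_gradients(xi, illums, frames, psf$otf)
    if (n > 1L) block_losses[[n - 1L]] <- ag_cost_from_residuals(gb$residuals)
    imgs <- c(list(gb$g_xi), gb$g_illums)
    # bundle-global normalisation, treated as a constant of the backward
    # pass (a stop-gradient, the usual choice for input conditioning)
    scale <- if (isTRUE(model$normalize))
      max(vapply(imgs, function(g) max(abs(ag_value(g))),
                 numeric(1))) + norm_eps else 1
    normed <- lapply(imgs, function(g) ag_neg_scale_const(g, 1 / scale))
    x <- ag_stack_images(normed)
    if (model$mode == "stacked") {
      # (H, W, L, 1) and (H, W, 1, L) share the same linear layout, so the
      # batch axis can be relabelled as channels without moving data
      x <- ag_reshape(x, c(d[1], d[2], 1L, L))
      y <- cnn_forward(x, param_leaves, model$cnn$leak)
      y <- ag_reshape(y, c(d[1], d[2], L, 1L))
    } else {
      y <- cnn_forward(x, param_leaves, model$cnn$leak)
    }
    outs <- lapply(seq_len(L), function(b) ag_unstack_image(y, b))
    xi <- ag_add(xi, ag_scale(outs[[1L]], alpha_leaves[[n]]))
    for (l in seq_len(L - 1L))
      illums[[l]] <- ag_add(illums[[l]],
                            ag_scale(outs[[l + 1L]], alpha_leaves[[n]]))
  }
  rr <- ag_blind_sim_residuals(xi, illums, frames, psf$otf)
  loss <- ag_cost_from_residuals(rr$res)
  block_losses[[model$n_blocks]] <- loss
  list(loss = loss, block_losses = block_losses, params = param_leaves,
       alphas = alpha_leaves)
}
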