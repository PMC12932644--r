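# Classical iterative blind-SIM. All three methods (plain gradient descent,
# Polak-Ribiere+ conjugate gradient, Nesterov momentum) update the
# concatenated (xi, i_1..i_{L-1}) vector with a single shared step size,
# chosen by Armijo backtracking unless a fixed step is requested.

#' Solver configuration
#'
#' @param method `"gd"`, `"prcg"` or `"nesterov"`.
#' @param max_iters iteration budget (default 500).
#' @param step_rule `"backtracking"` (Armijo, default) or `"fixed"`.
#' @param alpha0 initial / fixed step size (default 1e-2 for fixed;
#'   backtracking starts from twice the last accepted step).
#' @param armijo_c sufficient-decrease constant (default 1e-4).
#' @param shrink backtracking shrink factor (default 0.5).
#' @param tol_rel_cost plateau tolerance: stop when the relative cost change
#'   over a 10-iteration window falls below this (default 1e-6).
#' @param target_cost optional absolute cost at which to stop.
#' @param seed integer seed recorded in the trace.
#' @export
solver_config <- function(method = c("gd", "prcg", "nesterov"),
                          max_iters = 500L,
                          step_rule = c("backtracking", "fixed"),
                          alpha0 = NULL, armijo_c = 1e-4, shrink = 0.5,
                          tol_rel_cost = 1e-6, target_cost = NULL,
                          seed = 1L) {
  method <- match.arg(method)
  step_rule <- match.arg(step_rule)
  if (max_iters < 1) stop("max_iters must be at least 1")
  if (tol_rel_cost <= 0) stop("tol_rel_cost must be positive")
  if (is.null(alpha0)) alpha0 <- if (step_rule == "fixed") 1e-2 else 1e-1
  structure(list(method = method, max_iters = as.integer(max_iters),
                 step_rule = step_rule, alpha0 = alpha0,
                 armijo_c = armijo_c, shrink = shrink,
                 tol_rel_cost = tol_rel_cost, target_cost = target_cost,
                 seed = as.integer(seed)),
            class = "ubsim_solver_config")
}

#' Initial auxiliary state from the data
#'
#' Deterministic initialization: the square-root object is seeded with the
#' widefield mean image, `xi_0 = sqrt(max(widefield, eps))` with
#' `eps = 1e-6 * max(widefield)`, and every auxiliary illumination starts
#' uniform at `sqrt(I_0) = 1` (stack assumed normalised).
#'
#' @param data an `ubsim_stack`, normalised so `I_0 = 1`.
#' @param psf an `ubsim_psf` (shape check only).
#' @return an [aux_state()].
#' @export
init_state <- function(data, psf) {
  wf <- widefield_image(data)
  if (max(wf) <= 0) stop("cannot initialize from an all-zero stack")
  eps <- 1e-6 * max(wf)
  xi0 <- sqrt(pmax(wf, eps))
  d <- dim(data$frames)
  if (!all(dim(psf$otf) == d[1:2])) stop("PSF and stack shapes disagree")
  aux_state(xi0, array(1, c(d[1], d[2], d[3] - 1L)), i0 = 1)
}

#' One gradient-descent update of the auxiliary state
#'
#' Simultaneously advances `xi` and all auxiliary illuminations along the
#' supplied descent bundle with the same step: `state + alpha * g`.
#'
#' @param state an [aux_state()].
#' @param bundle an `ubsim_gradient` (or any list with `g_xi`, `g_illums`).
#' @param alpha nonnegative step size.
#' @return updated [aux_state()].
#' @export
gd_step <- function(state, bundle, alpha) {
  if (alpha < 0) stop("step size must be nonnegative")
  state$xi <- state$xi + alpha * bundle$g_xi
  state$aux_illums <- state$aux_illums + alpha * bundle$g_illums
  state
}

#' Polak-Ribiere+ conjugate direction
#'
#' `beta = max(0, <g_n, g_n - g_prev> / ||g_prev||^2)` over the concatenated
#' (xi, illums) vector, with `direction = g_n + beta * prev_direction`.
#' A zero or absent previous gradient restarts with `beta = 0`.
#'
#' @param grad current descent bundle.
#' @param prev_grad previous descent bundle or `NULL` (first iteration).
#' @param prev_dir previous direction bundle or `NULL`.
#' @return list with the direction bundle (`g_xi`, `g_illums`) and `beta`.
#' @export
prcg_direction <- function(grad, prev_grad = NULL, prev_dir = NULL) {
  if (is.null(prev_grad) || is.null(prev_dir) ||
      bundle_dot(prev_grad, prev_grad) == 0) {
    return(list(g_xi = grad$g_xi, g_illums = grad$g_illums, beta = 0))
  }
  beta <- (bundle_dot(grad, grad) - bundle_dot(grad, prev_grad)) /
    bundle_dot(prev_grad, prev_grad)
  beta <- max(0, beta)
  list(g_xi = grad$g_xi + beta * prev_dir$g_xi,
       g_illums = grad$g_illums + beta * prev_dir$g_illums,
       beta = beta)
}

#' One Nesterov momentum update
#'
#' Standard accelerated scheme on the concatenated vector: the gradient is
#' evaluated at the look-ahead point `y = state + mu * (state - prev_state)`
#' and the new state is `y + alpha * g(y)`. With `mu = 0` this reduces to a
#' plain gradient step. The caller supplies the bundle evaluated at the
#' look-ahead point (see [nesterov_lookahead()]).
#'
#' @param state current [aux_state()].
#' @param prev_state state from the previous iteration (or `NULL` at start).
#' @param bundle_at_lookahead descent bundle evaluated at the look-ahead.
#' @param alpha step size.
#' @param mu momentum coefficient in `[0, 1)`.
#' @return updated [aux_state()].
#' @export
nesterov_step <- function(state, prev_state, bundle_at_lookahead, alpha, mu) {
  y <- nesterov_lookahead(state, prev_state, mu)
  gd_step(y, bundle_at_lookahead, alpha)
}

#' Look-ahead point of the Nesterov scheme
#' @inheritParams nesterov_step
#' @return extrapolated [aux_state()].
#' @export
nesterov_lookahead <- function(state, prev_state, mu) {
  if (is.null(prev_state) || mu == 0) return(state)
  state$xi <- state$xi + mu * (state$xi - prev_state$xi)
  state$aux_illums <- state$aux_illums +
    mu * (state$aux_illums - prev_state$aux_illums)
  state
}

# Armijo backtracking from alpha_start along a descent bundle.
# Returns list(alpha, state, cost, evals); alpha = 0 if no decrease found.
armijo_search <- function(state, bundle, grad, data, psf, cost0, alpha_start,
                          c1 = 1e-4, shrink = 0.5, max_tries = 30L) {
  slope <- bundle_dot(grad, bundle)  # descent bundles: expected positive
  if (slope <= 0) return(list(alpha = 0, state = state, cost = cost0))
  alpha <- alpha_start
  for (t in seq_len(max_tries)) {
    cand <- gd_step(state, bundle, alpha)
    cc <- blind_sim_cost(cand, data, psf)$total
    if (is.finite(cc) && cc <= cost0 - c1 * alpha * slope)
      return(list(alpha = alpha, state = cand, cost = cc))
    alpha <- alpha * shrink
  }
  list(alpha = 0, state = state, cost = cost0)
}

#' Run the iterative blind-SIM solver
#'
#' Iterates the chosen method from [init_state()] until the iteration
#' budget, a cost plateau (relative change below `tol_rel_cost` over a
#' 10-iteration window), or `target_cost` is reached. A cost exceeding
#' 1000x the initial cost aborts with a divergence error.
#'
#' @param data an `ubsim_stack`; normalised internally to `I_0 = 1`.
#' @param psf an `ubsim_psf`.
#' @param config a [solver_config()].
#' @param state optional starting [aux_state()] (default [init_state()]).
#' @return object of class `ubsim_trace`: `cost_history` (cost before each
#'   update, ending with the final cost), `iterations_run`, `stop_reason`
#'   (`"max_iters"`, `"plateau"`, `"target"`, `"stalled"`), `final_state`,
#'   `rho` (`xi^2`), `config`.
#' @examples
#' cfg <- optical_config(image_shape = 32)
#' ph  <- make_phantom("puncta", 32, seed = 5)
#' sp  <- make_speckle_stack(cfg, L = 4, seed = 5)
#' stk <- forward_subframes(ph, sp, make_psf(cfg))
#' tr  <- blind_sim_reconstruct(stk, make_psf(cfg),
#'                              solver_config("gd", max_iters = 5))
#' @export
blind_sim_reconstruct <- function(data, psf, config = solver_config(),
                                  state = NULL) {
  stopifnot(inherits(config, "ubsim_solver_config"))
  data <- normalize_stack(data)
  if (is.null(state)) state <- init_state(data, psf)
  cost0 <- blind_sim_cost(state, data, psf)$total
  costs <- numeric(config$max_iters + 1L)
  costs[1] <- cost0
  stop_reason <- "max_iters"
  alpha_prev <- config$alpha0
  prev_grad <- NULL; prev_dir <- NULL; prev_state <- NULL
  t_mom <- 1
  iters <- 0L
  if (!is.null(config$target_cost) && cost0 <= config$target_cost) {
    return(finish_trace(costs[1], 0L, "target", state, config))
  }
  for (n in seq_len(config$max_iters)) {
    cur_cost <- costs[n]
    if (config$method == "nesterov") {
      t_next <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
      mu <- (t_mom - 1) / t_next
      y <- nesterov_lookahead(state, prev_state, mu)
      grad <- blind_sim_gradients(y, data, psf)
      if (config$step_rule == "fixed") {
        new_state <- gd_step(y, grad, config$alpha0)
        new_cost <- blind_sim_cost(new_state, data, psf)$total
        accepted <- TRUE
      } else {
        cost_y <- blind_sim_cost(y, data, psf)$total
        ls <- armijo_search(y, grad, grad, data, psf, cost_y,
                            2 * alpha_prev, config$armijo_c, config$shrink)
        accepted <- ls$alpha > 0
        new_state <- ls$state; new_cost <- ls$cost
        if (accepted) alpha_prev <- ls$alpha
      }
      prev_state <- state
      t_mom <- t_next
      if (new_cost > cur_cost) {
        # adaptive restart: drop the momentum when the cost increases, which
        # keeps the extrapolation from running away on this quartic landscape
        t_mom <- 1
        prev_state <- NULL
      }
    } else {
      grad <- blind_sim_gradients(state, data, psf)
      dir <- if (config$method == "prcg")
        prcg_direction(grad, prev_grad, prev_dir) else grad
      if (config$step_rule == "fixed") {
        new_state <- gd_step(state, dir, config$alpha0)
        new_cost <- blind_sim_cost(new_state, data, psf)$total
        accepted <- TRUE
      } else {
        ls <- armijo_search(state, dir, grad, data, psf, cur_cost,
                            2 * alpha_prev, config$armijo_c, config$shrink)
        if (ls$alpha == 0 && config$method == "prcg" && dir$beta > 0) {
          # conjugate direction failed the decrease test: restart on gradient
          dir <- prcg_direction(grad, NULL, NULL)
          ls <- armijo_search(state, dir, grad, data, psf, cur_cost,
                              2 * alpha_prev, config$armijo_c, config$shrink)
        }
        accepted <- ls$alpha > 0
        new_state <- ls$state; new_cost <- ls$cost
        if (accepted) alpha_prev <- ls$alpha
      }
      prev_grad <- grad; prev_dir <- dir
    }
    if (!accepted) {
      iters <- n - 1L
      stop_reason <- "stalled"
      break
    }
    if (!is.finite(new_cost) || new_cost > 1e3 * cost0)
      stop(sprintf(paste0(
        "solver diverged at iteration %d: cost %.3g exceeds 1000x the ",
        "initial cost %.3g; reduce the step size"), n, new_cost, cost0))
    state <- new_state
    costs[n + 1L] <- new_cost
    iters <- n
    if (!is.null(config$target_cost) && new_cost <= config$target_cost) {
      stop_reason <- "target"
      break
    }
    if (n >= 10L) {
      # plateau: the best cost seen has not improved by tol (relative)
      # over the last 10 iterations; robust to non-monotone methods
      best_recent <- min(costs[(n - 9L):(n + 1L)])
      best_before <- min(costs[1:(n - 9L)])
      if (best_before > 0 &&
          (best_before - best_recent) / best_before < config$tol_rel_cost) {
        stop_reason <- "plateau"
        break
      }
    }
  }
  finish_trace(costs[seq_len(iters + 1L)], iters, stop_reason, state, config)
}

finish_trace <- function(costs, iters, reason, state, config) {
  structure(list(cost_history = costs, iterations_run = iters,
                 stop_reason = reason, final_state = state,
                 rho = object_estimate(state), config = config),
            class = "ubsim_trace")
}

#' @export
print.ubsim_trace <- function(x, ...) {
  cat(sprintf(
    "ubsim %s trace: %d iterations (%s), cost %.4g -> %.4g\n",
    x$config$method, x$iterations_run, x$stop_reason,
    x$cost_history[1], x$cost_history[length(x$cost_history)]))
  invisible(x)
}

#' Iterations needed by each method to reach a target cost
#'
#' Runs the requested iterative methods on the same stack until their cost
#' falls to `target_cost`, recording the iteration counts — a
#' hardware-independent benchmark of convergence speed. Runs that hit the
#' iteration budget first are flagged as censored (their count is a lower
#' bound).
#'
#' @param data an `ubsim_stack`.
#' @param psf an `ubsim_psf`.
#' @param methods character vector from `c("gd", "prcg", "nesterov")`.
#' @param target_cost absolute cost level to reach.
#' @param max_iters per-method iteration budget.
#' @return data.frame with columns `method`, `iterations`, `censored`,
#'   `final_cost`.
#' @export
iterations_to_target <- function(data, psf,
                                 methods = c("gd", "prcg", "nesterov"),
                                 target_cost, max_iters = 2000L) {
  rows <- lapply(methods, function(m) {
    tr <- blind_sim_reconstruct(
      data, psf,
      solver_config(m, max_iters = max_iters, target_cost = target_cost))
    data.frame(method = m, iterations = tr$iterations_run,
               censored = tr$stop_reason != "target",
               final_cost = tr$cost_history[length(tr$cost_history)])
  })
  do.call(rbind, rows)
}
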