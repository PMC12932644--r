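# Iterative blind-SIM solvers

test_that("initialization is deterministic and uses the widefield image", {
  sim <- tiny_instance(16, L = 4, seed = 2)
  a <- init_state(sim$stack, sim$psf)
  b <- init_state(sim$stack, sim$psf)
  expect_identical(a, b)
  expect_true(all(a$aux_illums == 1))
  expect_equal(a$xi^2, pmax(widefield_image(sim$stack),
                            1e-6 * max(widefield_image(sim$stack))))
  # uniform data gives a spatially uniform object seed
  flat <- sim$stack
  flat$frames[] <- 0.8
  u <- init_state(flat, sim$psf)
  expect_lt(diff(range(u$xi)), 1e-12)
  # initial cost agrees with the brute-force oracle
  expect_equal(blind_sim_cost(a, sim$stack, sim$psf)$total,
               cost_brute(a, sim$stack, sim$psf), tolerance = 1e-9)
  zero <- sim$stack; zero$frames[] <- 0
  expect_error(init_state(zero, sim$psf), "all-zero")
})

test_that("gd_step semantics: identity at zero, fixed-direction updates", {
  sim <- tiny_instance(16, L = 4, seed = 2)
  st <- init_state(sim$stack, sim$psf)
  g <- blind_sim_gradients(st, sim$stack, sim$psf)
  expect_identical(gd_step(st, g, 0), st)
  # two half steps along a FIXED bundle differ from one full step only by
  # floating-point association; along a frozen direction they coincide
  one <- gd_step(st, g, 2e-4)
  two <- gd_step(gd_step(st, g, 1e-4), g, 1e-4)
  expect_lt(max(abs(one$xi - two$xi)), 1e-12)
  # but two half steps with re-evaluated gradients follow a different path
  g2 <- blind_sim_gradients(gd_step(st, g, 1e-4), sim$stack, sim$psf)
  two_flow <- gd_step(gd_step(st, g, 1e-4), g2, 1e-4)
  expect_gt(max(abs(one$xi - two_flow$xi)), 1e-12)
  expect_error(gd_step(st, g, -1), "nonnegative")
})

test_that("PR+ conjugate directions restart and combine correctly", {
  sim <- tiny_instance(16, L = 4, seed = 2)
  st <- init_state(sim$stack, sim$psf)
  g <- blind_sim_gradients(st, sim$stack, sim$psf)
  first <- prcg_direction(g, NULL, NULL)
  expect_equal(first$g_xi, g$g_xi)
  expect_equal(first$beta, 0)
  # hand-computed 3-vector example embedded in a 1x3-pixel bundle shape:
  # g_n = (1, 2, 0), g_prev = (0, 2, 1), d_prev = (1, 0, 0)
  mk <- function(v) list(g_xi = matrix(v[1], 1, 1),
                         g_illums = array(v[2:3], c(1, 1, 2)))
  gn <- mk(c(1, 2, 0)); gp <- mk(c(0, 2, 1)); dp <- mk(c(1, 0, 0))
  # beta = <gn, gn - gp> / ||gp||^2 = ((1)(1) + (2)(0) + (0)(-1)) / 5
  out <- prcg_direction(gn, gp, dp)
  expect_equal(out$beta, 1 / 5)
  expect_equal(out$g_xi[1, 1], 1 + 1 / 5 * 1)
  # negative PR beta is clipped to zero (restart)
  gn2 <- mk(c(0, 1, 0))   # <gn2, gn2 - gp> = 1 - 2 = -1
  expect_equal(prcg_direction(gn2, gp, dp)$beta, 0)
  # zero previous gradient restarts
  expect_equal(prcg_direction(gn, mk(c(0, 0, 0)), dp)$beta, 0)
})

test_that("conjugate gradient solves a 2-variable quadratic in two steps", {
  # f(x) = x' A x / 2 with exact line searches, via the same PR+ formula
  A <- matrix(c(3, 1, 1, 2), 2)
  x <- c(4, -3)
  g <- -(A %*% x)[, 1]            # descent direction
  d <- g
  for (k in 1:2) {
    alpha <- sum(d * g) / sum(d * (A %*% d))
    x <- x + alpha * d
    g_new <- -(A %*% x)[, 1]
    mk <- function(v) list(g_xi = matrix(v[1], 1, 1),
                           g_illums = array(v[2], c(1, 1, 1)))
    out <- prcg_direction(mk(g_new), mk(g), mk(d))
    d <- c(out$g_xi[1, 1], out$g_illums[1, 1, 1])
    g <- g_new
  }
  expect_lt(sqrt(sum(x^2)), 1e-10)
})

test_that("Nesterov with zero momentum reduces to a gradient step", {
  sim <- tiny_instance(16, L = 4, seed = 2)
  st <- init_state(sim$stack, sim$psf)
  g <- blind_sim_gradients(st, sim$stack, sim$psf)
  a <- nesterov_step(st, NULL, g, 1e-4, 0)
  b <- gd_step(st, g, 1e-4)
  expect_identical(a$xi, b$xi)
})

test_that("Nesterov iterates match the hand-rolled scalar recursion", {
  # f(x) = x^2 / 2, descent bundle g = -x, embedded in a 1x1 state
  alpha <- 0.4
  mk_state <- function(x) aux_state(matrix(x, 1, 1), array(0, c(1, 1, 1)))
  state <- mk_state(1); prev <- NULL
  t_mom <- 1
  xs <- numeric(5)
  for (k in 1:5) {
    t_next <- (1 + sqrt(1 + 4 * t_mom^2)) / 2
    mu <- (t_mom - 1) / t_next
    y <- nesterov_lookahead(state, prev, mu)
    bundle <- list(g_xi = matrix(-y$xi[1, 1], 1, 1),
                   g_illums = array(0, c(1, 1, 1)))
    new_state <- nesterov_step(state, prev, bundle, alpha, mu)
    prev <- state; state <- new_state; t_mom <- t_next
    xs[k] <- state$xi[1, 1]
  }
  # independent scalar recursion
  x <- 1; xp <- 1; t <- 1
  ref <- numeric(5)
  for (k in 1:5) {
    tn <- (1 + sqrt(1 + 4 * t^2)) / 2
    mu <- (t - 1) / tn
    y <- x + mu * (x - xp)
    xn <- y + alpha * (-y)
    xp <- x; x <- xn; t <- tn
    ref[k] <- x
  }
  expect_equal(xs, ref, tolerance = 1e-14)
})

test_that("gradient descent with backtracking descends monotonically", {
  sim <- tiny_instance(32, L = 8, seed = 5)
  tr <- blind_sim_reconstruct(sim$stack, sim$psf,
                              solver_config("gd", max_iters = 40))
  expect_true(all(diff(tr$cost_history) <= 1e-12))
  expect_lte(tr$iterations_run, 40)
  # outputs are nonnegative by construction
  expect_true(all(tr$rho >= 0))
  ill <- illumination_estimates(tr$final_state)
  expect_true(all(ill[, , 1:7] >= 0))
})

test_that("long noiseless runs reduce the cost by orders of magnitude", {
  sim <- tiny_instance(32, L = 8, seed = 12)
  tr <- blind_sim_reconstruct(sim$stack, sim$psf,
                              solver_config("prcg", max_iters = 300,
                                            tol_rel_cost = 1e-12))
  drop <- tr$cost_history[1] / tr$cost_history[length(tr$cost_history)]
  expect_gt(drop, 1e3)
})

test_that("solver runs are deterministic and respect target costs", {
  sim <- tiny_instance(16, L = 4, seed = 4)
  cfgs <- solver_config("prcg", max_iters = 25)
  a <- blind_sim_reconstruct(sim$stack, sim$psf, cfgs)
  b <- blind_sim_reconstruct(sim$stack, sim$psf, cfgs)
  expect_identical(a$cost_history, b$cost_history)
  expect_identical(a$rho, b$rho)
  init_cost <- a$cost_history[1]
  tr0 <- blind_sim_reconstruct(sim$stack, sim$psf,
                               solver_config("gd", max_iters = 25,
                                             target_cost = init_cost))
  expect_lte(tr0$iterations_run, 1)
  expect_equal(tr0$stop_reason, "target")
})

test_that("divergent fixed steps abort with a diagnostic", {
  sim <- tiny_instance(16, L = 4, seed = 4)
  expect_error(blind_sim_reconstruct(
    sim$stack, sim$psf,
    solver_config("gd", max_iters = 50, step_rule = "fixed", alpha0 = 1)),
    "diverged")
})

test_that("iterations_to_target reports and censors correctly", {
  sim <- tiny_instance(16, L = 4, seed = 4)
  init_cost <- blind_sim_cost(init_state(sim$stack, sim$psf),
                              sim$stack, sim$psf)$total
  tab <- iterations_to_target(sim$stack, sim$psf, c("gd", "prcg"),
                              target_cost = init_cost)
  expect_true(all(tab$iterations == 0))
  # an unreachable target is censored at the iteration budget
  tab2 <- iterations_to_target(sim$stack, sim$psf, "gd",
                               target_cost = 1e-300, max_iters = 12)
  expect_true(tab2$censored)
})
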