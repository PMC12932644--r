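# Blind-SIM objective: residuals, cost, analytic gradients

test_that("residuals vanish at the generating state on noiseless data", {
  sim <- consistent_instance(16, L = 4, seed = 2)
  res <- blind_sim_residuals(sim$truth, sim$stack, sim$psf)
  expect_lt(max(abs(res)), 1e-8)
  cc <- blind_sim_cost(sim$truth, sim$stack, sim$psf)
  expect_lt(cc$total, 1e-12 * sum(sim$stack$frames^2))
})

test_that("a zero object leaves the raw frames as residuals", {
  sim <- tiny_instance(16, L = 4, seed = 2)
  st <- init_state(sim$stack, sim$psf)
  st$xi[] <- 0
  res <- blind_sim_residuals(st, sim$stack, sim$psf)
  for (l in 1:4) expect_images_equal(res[, , l], sim$stack$frames[, , l])
})

test_that("cost equals the brute-force double loop and sums per-frame terms", {
  sim <- tiny_instance(16, L = 3, seed = 6)
  st <- random_state(16, 3, seed = 13)
  cc <- blind_sim_cost(st, sim$stack, sim$psf)
  expect_equal(cc$total, sum(cc$per_frame), tolerance = 1e-9)
  expect_equal(cc$total, cost_brute(st, sim$stack, sim$psf),
               tolerance = 1e-9)
  expect_gte(cc$total, 0)
})

test_that("residuals match an independent spatial-domain implementation", {
  sim <- tiny_instance(16, L = 3, seed = 6)
  st <- random_state(16, 3, seed = 14)
  res <- blind_sim_residuals(st, sim$stack, sim$psf)
  rho <- st$xi^2
  for (l in 1:3) {
    Il <- if (l < 3) st$aux_illums[, , l]^2 else derived_last_pattern(st)
    ref <- sim$stack$frames[, , l] - conv2_brute(rho * Il, sim$psf$kernel)
    expect_lt(max(abs(res[, , l] - ref)), 1e-8)
  }
})

test_that("analytic gradients agree with central finite differences", {
  for (seed in 1:3) {
    sim <- tiny_instance(16, L = 4, seed = seed, noisy = TRUE)
    st <- random_state(16, 4, seed = seed + 20)
    err <- finite_diff_check(st, sim$stack, sim$psf, n_probes = 10,
                             step = 1e-5, seed = seed)
    expect_lt(err, 1e-4)
  }
})

test_that("a sign error in the gradient is detected by the oracle", {
  sim <- tiny_instance(16, L = 4, seed = 2)
  st <- random_state(16, 4, seed = 3)
  g <- blind_sim_gradients(st, sim$stack, sim$psf)
  # recompute the check against the negated bundle by hand
  d <- dim(st$aux_illums)
  worst <- 0
  num_deriv <- function(i, j, l, in_xi, step = 1e-5) {
    sp <- st; sm <- st
    if (in_xi) {
      sp$xi[i, j] <- sp$xi[i, j] + step; sm$xi[i, j] <- sm$xi[i, j] - step
    } else {
      sp$aux_illums[i, j, l] <- sp$aux_illums[i, j, l] + step
      sm$aux_illums[i, j, l] <- sm$aux_illums[i, j, l] - step
    }
    (blind_sim_cost(sp, sim$stack, sim$psf)$total -
       blind_sim_cost(sm, sim$stack, sim$psf)$total) / (2 * step)
  }
  num <- num_deriv(3, 5, 1, TRUE)
  ana_neg <- g$g_xi[3, 5]          # descent = -gradient; flipping the sign
  expect_gt(abs(ana_neg - num) / abs(num), 1.5)
  expect_lt(abs(-ana_neg - num) / abs(num), 1e-4)
})

test_that("the gradient vanishes at the generating state (stationarity)", {
  sim <- consistent_instance(16, L = 4, seed = 2)
  g <- blind_sim_gradients(sim$truth, sim$stack, sim$psf)
  scale <- max(abs(sim$stack$frames))
  expect_lt(max(abs(g$g_xi)), 1e-6 * scale)
  expect_lt(max(abs(g$g_illums)), 1e-6 * scale)
})

test_that("convolution and correlation are adjoint (inner-product identity)", {
  psf <- make_psf(tiny_config(32))
  with_seed_local(17, {
    x <- matrix(rnorm(1024), 32, 32)
    y <- matrix(rnorm(1024), 32, 32)
    lhs <- sum(ubsim:::conv_otf(x, psf$otf) * y)
    rhs <- sum(x * ubsim:::corr_otf(y, psf$otf))
    expect_equal(lhs, rhs, tolerance = 1e-12)
  })
})

test_that("small steps along the descent bundle reduce the cost", {
  sim <- tiny_instance(16, L = 4, seed = 9, noisy = TRUE)
  st <- random_state(16, 4, seed = 9)
  c0 <- blind_sim_cost(st, sim$stack, sim$psf)$total
  g <- blind_sim_gradients(st, sim$stack, sim$psf)
  for (alpha in 10^seq(-6, -4)) {
    c1 <- blind_sim_cost(gd_step(st, g, alpha), sim$stack, sim$psf)$total
    expect_lt(c1, c0)
  }
})

test_that("derived-pattern bookkeeping is consistent", {
  st <- random_state(8, 3, seed = 5)
  IL <- derived_last_pattern(st)
  expect_equal(IL, 3 * st$i0 - st$aux_illums[, , 1]^2 - st$aux_illums[, , 2]^2)
  ill <- illumination_estimates(st)
  expect_equal(dim(ill), c(8, 8, 3))
  expect_true(all(ill[, , 1:2] >= 0))
  expect_equal(ill[, , 3], IL)
  expect_equal(negative_pattern_fraction(st), mean(IL < 0))
  expect_error(finite_diff_check(st, tiny_instance(16, 3)$stack, NULL,
                                 step = -1), "positive")
})
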