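# Unrolled network: architecture, equivalences, weights I/O

test_that("identity blocks reproduce fixed-step gradient descent bit for bit", {
  sim <- tiny_instance(16, L = 4, seed = 2)
  alpha <- 0.005
  n_blocks <- 5
  mod <- unrolled_model(n_blocks, cnn = "identity", alpha0 = alpha)
  uf <- unrolled_forward(mod, sim$stack, sim$psf)
  stk <- normalize_stack(sim$stack)   # the forward normalises identically
  st <- init_state(stk, sim$psf)
  for (n in seq_len(n_blocks))
    st <- gd_step(st, blind_sim_gradients(st, stk, sim$psf), alpha)
  expect_identical(uf$state$xi, st$xi)
  expect_identical(uf$state$aux_illums, st$aux_illums)
  expect_identical(uf$cost, blind_sim_cost(st, stk, sim$psf)$total)
})

test_that("zero step scales leave the initial state untouched", {
  sim <- tiny_instance(16, L = 4, seed = 2)
  mod <- unrolled_model(4, update_cnn(width = 4, seed = 1), alpha0 = 0)
  uf <- unrolled_forward(mod, sim$stack, sim$psf)
  st0 <- init_state(normalize_stack(sim$stack), sim$psf)
  expect_identical(uf$state$xi, st0$xi)
  expect_true(all(diff(uf$block_costs) == 0))
})

test_that("inference is deterministic and keeps outputs nonnegative", {
  sim <- tiny_instance(16, L = 4, seed = 6, noisy = TRUE)
  mod <- unrolled_model(3, update_cnn(width = 8, seed = 3))
  a <- unrolled_forward(mod, sim$stack, sim$psf)
  b <- unrolled_forward(mod, sim$stack, sim$psf)
  expect_identical(a$rho, b$rho)
  expect_identical(a$block_costs, b$block_costs)
  expect_true(all(a$rho >= 0))
  ill <- illumination_estimates(a$state)
  expect_true(all(ill[, , 1:3] >= 0))
})

test_that("spatial dimensions must be divisible by four", {
  cfg <- optical_config(image_shape = c(20, 20), pixel_size = 100)
  sim <- simulate_acquisition(cfg, "puncta", L = 3, noise_params(Inf, 0), 1)
  mod <- unrolled_model(2, update_cnn(width = 4, seed = 1))
  expect_no_error(unrolled_forward(mod, sim$stack, sim$psf))
  cfg2 <- optical_config(image_shape = c(18, 18), pixel_size = 100)
  sim2 <- simulate_acquisition(cfg2, "puncta", L = 3, noise_params(Inf, 0), 1)
  expect_error(unrolled_forward(mod, sim2$stack, sim2$psf), "divisible")
})

test_that("the default update network fits the parameter budget", {
  mod <- unrolled_model()
  expect_lt(count_parameters(mod), 250000)
  expect_gt(count_parameters(mod), 1000)
  # conv parameter count scales roughly with the squared width
  small <- count_parameters(unrolled_model(6, update_cnn(width = 8)))
  big <- count_parameters(unrolled_model(6, update_cnn(width = 16)))
  expect_gt(big / small, 3.2)
  expect_lt(big / small, 4.3)
  expect_error(update_cnn(width = 0), "width")
  expect_error(unrolled_model(0), "at least one")
})

test_that("stacked mode fixes L and rejects mismatched stacks", {
  sim <- tiny_instance(16, L = 4, seed = 2)
  mod <- unrolled_model(2, update_cnn(width = 4, channels = 4, seed = 1),
                        mode = "stacked")
  expect_no_error(unrolled_forward(mod, sim$stack, sim$psf))
  sim3 <- tiny_instance(16, L = 3, seed = 2)
  expect_error(unrolled_forward(mod, sim3$stack, sim3$psf), "L = 4")
  expect_error(unrolled_model(2, "identity", mode = "stacked"),
               "update network")
})

test_that("numeric and differentiable forwards agree", {
  sim <- tiny_instance(16, L = 4, seed = 7, noisy = TRUE)
  for (mode in c("per_image", "stacked")) {
    cnn <- update_cnn(width = 4, channels = if (mode == "stacked") 4 else 1,
                      seed = 5)
    mod <- unrolled_model(3, cnn, alpha0 = 0.05, mode = mode)
    uf <- unrolled_forward(mod, sim$stack, sim$psf)
    ubsim:::ag_reset()
    fw <- ubsim:::ag_unrolled_forward(mod, normalize_stack(sim$stack),
                                      sim$psf)
    expect_equal(ubsim:::ag_value(fw$loss), uf$cost, tolerance = 1e-9)
    ubsim:::ag_reset()
  }
})

test_that("weights survive a save/load round trip exactly", {
  sim <- tiny_instance(16, L = 4, seed = 2)
  mod <- unrolled_model(3, update_cnn(width = 4, seed = 9), alpha0 = 0.07)
  path <- tempfile(fileext = ".ckpt")
  save_weights(mod, path)
  back <- load_weights(path)
  expect_identical(back$cnn$params, mod$cnn$params)
  expect_identical(back$step_scales, mod$step_scales)
  a <- unrolled_forward(mod, sim$stack, sim$psf)
  b <- unrolled_forward(back, sim$stack, sim$psf)
  expect_identical(a$rho, b$rho)
  unlink(path)
})

test_that("corrupted or mismatched checkpoints are refused", {
  mod <- unrolled_model(3, update_cnn(width = 4, seed = 9))
  path <- tempfile(fileext = ".ckpt")
  save_weights(mod, path)
  # template with a different block count names the offending field
  tpl <- unrolled_model(6, update_cnn(width = 4, seed = 9))
  expect_error(load_weights(path, template = tpl), "n_blocks")
  # corrupted payload
  bad <- tempfile(fileext = ".ckpt")
  saveRDS(list(garbage = TRUE), bad)
  expect_error(load_weights(bad), "corrupted")
  writeLines("not an rds", bad)
  expect_error(load_weights(bad), "cannot read|corrupted")
  unlink(c(path, bad))
})
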