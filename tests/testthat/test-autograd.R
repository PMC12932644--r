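# Reverse-mode autodiff engine: every primitive is checked against central
# finite differences, and the whole unrolled graph is checked end-to-end.

fd_grad <- function(f, x, i, h = 1e-6) {
  xp <- x; xm <- x
  xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
  (f(xp) - f(xm)) / (2 * h)
}

test_that("elementwise and reduction primitives have exact adjoints", {
  set.seed(5)
  a <- matrix(rnorm(36), 6, 6)
  b <- matrix(rnorm(36), 6, 6)
  cases <- list(
    list(f = function(x) sum((x + b)^2),
         build = function(xn) ubsim:::ag_sum_sq(ubsim:::ag_add(xn, b))),
    list(f = function(x) sum((x * b)^2),
         build = function(xn) ubsim:::ag_sum_sq(ubsim:::ag_mul(xn, b))),
    list(f = function(x) sum((x^2 - b)^2),
         build = function(xn) ubsim:::ag_sum_sq(
           ubsim:::ag_sub(ubsim:::ag_square(xn), b))),
    list(f = function(x) sum((3.7 * x)^2),
         build = function(xn) ubsim:::ag_sum_sq(
           ubsim:::ag_neg_scale_const(xn, 3.7))))
  for (cs in cases) {
    ubsim:::ag_reset()
    xn <- ubsim:::ag_leaf(a)
    loss <- cs$build(xn)
    ubsim:::ag_backward(loss)
    expect_equal(loss$value, cs$f(a), tolerance = 1e-12)
    for (i in c(1, 17, 36)) {
      expect_equal(xn$grad[i], fd_grad(cs$f, a, i), tolerance = 1e-6)
    }
  }
})

test_that("PSF convolution nodes use the correlation adjoint", {
  psf <- make_psf(tiny_config(16))
  set.seed(6)
  x <- matrix(rnorm(256), 16, 16)
  f <- function(z) sum(ubsim:::conv_otf(z, psf$otf)^2)
  ubsim:::ag_reset()
  xn <- ubsim:::ag_leaf(x)
  loss <- ubsim:::ag_sum_sq(ubsim:::ag_conv_otf(xn, psf$otf))
  ubsim:::ag_backward(loss)
  for (i in c(3, 100, 200))
    expect_equal(xn$grad[i], fd_grad(f, x, i), tolerance = 1e-6)
})

test_that("network primitives (conv, pool, upsample, concat) back-propagate", {
  set.seed(7)
  x <- array(rnorm(8 * 8 * 2 * 3), c(8, 8, 2, 3))
  W <- matrix(rnorm(27 * 4, 0, 0.3), 27, 4)
  b <- rnorm(4)
  f <- function(xx) {
    y <- ubsim:::plain_conv2d(xx, W, b, 3L)
    y <- ubsim:::plain_avgpool2(y)
    y <- ubsim:::plain_upsample2(y)
    sum(ubsim:::plain_concat_c(y, xx)^2)
  }
  ubsim:::ag_reset()
  xn <- ubsim:::ag_leaf(x)
  y <- ubsim:::ag_conv2d(xn, ubsim:::ag_leaf(W), ubsim:::ag_leaf(b), 3L)
  y <- ubsim:::ag_avgpool2(y)
  y <- ubsim:::ag_upsample2(y)
  loss <- ubsim:::ag_sum_sq(ubsim:::ag_concat_c(y, xn))
  ubsim:::ag_backward(loss)
  expect_equal(loss$value, f(x), tolerance = 1e-10)
  for (i in c(1, 77, 250))
    expect_equal(xn$grad[i], fd_grad(f, x, i), tolerance = 1e-5)
})

test_that("leaky ReLU and 1x1 convolutions back-propagate", {
  set.seed(8)
  x <- array(rnorm(4 * 4 * 1 * 3), c(4, 4, 1, 3))
  W <- matrix(rnorm(3 * 2, 0, 0.5), 3, 2)
  b <- rnorm(2)
  f <- function(xx) {
    z <- ubsim:::plain_conv2d(xx, W, b, 1L)
    neg <- z < 0; z[neg] <- 0.1 * z[neg]
    sum(z^2)
  }
  ubsim:::ag_reset()
  xn <- ubsim:::ag_leaf(x)
  Wn <- ubsim:::ag_leaf(W)
  loss <- ubsim:::ag_sum_sq(ubsim:::ag_leaky_relu(
    ubsim:::ag_conv2d(xn, Wn, ubsim:::ag_leaf(b), 1L)))
  ubsim:::ag_backward(loss)
  for (i in c(2, 20, 48))
    expect_equal(xn$grad[i], fd_grad(f, x, i), tolerance = 1e-5)
  fW <- function(WW) {
    z <- ubsim:::plain_conv2d(x, WW, b, 1L)
    neg <- z < 0; z[neg] <- 0.1 * z[neg]
    sum(z^2)
  }
  for (i in c(1, 6))
    expect_equal(Wn$grad[i], fd_grad(fW, W, i), tolerance = 1e-5)
})

test_that("training gradients are exact for the full unrolled graph", {
  # with normalisation disabled the differentiable forward is exactly the
  # numeric forward, so its parameter gradients must match finite
  # differences through all blocks (Hessian-of-the-cost products included)
  sim <- tiny_instance(16, L = 4, seed = 3, noisy = TRUE)
  mod <- unrolled_model(3, update_cnn(width = 4, seed = 2), alpha0 = 1e-4,
                        normalize = FALSE)
  with_seed_local(4, {
    mod$cnn$params$out_W[] <- rnorm(length(mod$cnn$params$out_W), 0, 0.05)
  })
  g <- ubsim:::train_step_grads(mod, sim$stack, sim$psf)
  for (probe in list(c("out_W", 3), c("enc1_W", 2), c("fuse1_W", 11))) {
    nm <- probe[1]; i <- as.integer(probe[2]); h <- 1e-5
    mp <- mod; mp$cnn$params[[nm]][i] <- mp$cnn$params[[nm]][i] + h
    mm <- mod; mm$cnn$params[[nm]][i] <- mm$cnn$params[[nm]][i] - h
    num <- (ubsim:::unrolled_mean_loss(mp, list(sim$stack), sim$psf) -
              ubsim:::unrolled_mean_loss(mm, list(sim$stack), sim$psf)) /
      (2 * h)
    expect_equal(g$g_params[[nm]][i], num, tolerance = 1e-4)
  }
  # step-scale gradient
  h <- 1e-7
  mp <- mod; mp$step_scales[2] <- mp$step_scales[2] + h
  mm <- mod; mm$step_scales[2] <- mm$step_scales[2] - h
  num <- (ubsim:::unrolled_mean_loss(mp, list(sim$stack), sim$psf) -
            ubsim:::unrolled_mean_loss(mm, list(sim$stack), sim$psf)) / (2 * h)
  expect_equal(g$g_alphas[2], num, tolerance = 1e-4)
})
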