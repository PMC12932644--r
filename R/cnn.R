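# The shared convolutional update network: a small 2-stage encoder-decoder
# with skip connections that maps a (normalised) gradient image to a refined
# update direction. A global residual connection with a zero-initialised
# output layer makes the untrained network start as the identity, so an
# untrained unrolled model behaves like plain gradient descent and training
# only has to learn the correction.

cnn_layer_shapes <- function(width, in_channels = 1L, out_channels = in_channels) {
  w <- as.integer(width)
  list(
    enc1  = c(9L * in_channels, w),        # 3x3, in -> w
    enc2  = c(9L * w, 2L * w),             # 3x3 after pool, w -> 2w
    bott  = c(18L * w, 4L * w),            # 3x3 after pool, 2w -> 4w
    up2   = c(4L * w, 2L * w),             # 1x1 channel reduction
    fuse2 = c(9L * 4L * w, 2L * w),        # 3x3 on concat(up, skip)
    up1   = c(2L * w, w),                  # 1x1 channel reduction
    fuse1 = c(9L * 2L * w, w),             # 3x3 on concat(up, skip)
    out   = c(9L * w, out_channels)        # 3x3, w -> out (zero-init)
  )
}

#' Construct the shared convolutional update network
#'
#' Builds the weight set for the small encoder-decoder applied to gradient
#' images inside each iteration block: two average-pool downscaling stages,
#' a bottleneck, nearest-neighbour upsampling with 1x1 channel reduction,
#' skip connections fused by 3x3 convolutions, leaky-ReLU activations, and
#' a zero-initialised 3x3 output layer added residually to the input. Fully
#' convolutional: any input whose sides are divisible by 4 is accepted.
#'
#' @param width base channel width (default 16; all layer widths scale with
#'   it, parameter count roughly with its square).
#' @param channels input/output channel count: 1 for the default per-image
#'   mode, L for the stacked mode.
#' @param seed seed for the He-style weight initialisation.
#' @return object of class `ubsim_cnn`: list of weight matrices/bias vectors
#'   plus the architecture description.
#' @export
update_cnn <- function(width = 16L, channels = 1L, seed = 1L) {
  if (width < 1) stop("network width must be at least 1")
  shapes <- cnn_layer_shapes(width, channels, channels)
  params <- with_seed(seed, {
    p <- list()
    for (nm in names(shapes)) {
      sh <- shapes[[nm]]
      sd <- sqrt(2 / sh[1])
      W <- matrix(stats::rnorm(prod(sh), 0, sd), sh[1], sh[2])
      if (nm == "out") W[] <- 0      # start as the identity block
      p[[paste0(nm, "_W")]] <- W
      p[[paste0(nm, "_b")]] <- numeric(sh[2])
    }
    p
  })
  structure(list(params = params, width = as.integer(width),
                 channels = as.integer(channels), leak = 0.1),
            class = "ubsim_cnn")
}

#' @export
print.ubsim_cnn <- function(x, ...) {
  cat(sprintf("ubsim update CNN: width %d, %d channel(s), %d parameters\n",
              x$width, x$channels, cnn_parameter_count(x)))
  invisible(x)
}

cnn_parameter_count <- function(cnn) {
  sum(vapply(cnn$params, length, integer(1)))
}

# forward pass through the update network; x and weights may be ag nodes or
# plain arrays (the same code path serves training and inference)
cnn_forward <- function(x, params, leak = 0.1) {
  lrelu <- function(z) if (is_ag(z)) ag_leaky_relu(z, leak) else {
    out <- ag_value(z)
    neg <- which(out < 0)
    out[neg] <- leak * out[neg]
    out
  }
  conv <- function(z, nm, kernel = 3L) {
    if (is_ag(z) || is_ag(params[[paste0(nm, "_W")]]))
      ag_conv2d(z, params[[paste0(nm, "_W")]], params[[paste0(nm, "_b")]],
                kernel)
    else plain_conv2d(z, ag_value(params[[paste0(nm, "_W")]]),
                      ag_value(params[[paste0(nm, "_b")]]), kernel)
  }
  pool <- function(z) if (is_ag(z)) ag_avgpool2(z) else plain_avgpool2(z)
  up <- function(z) if (is_ag(z)) ag_upsample2(z) else plain_upsample2(z)
  cat_c <- function(a, b) if (is_ag(a) || is_ag(b)) ag_concat_c(a, b) else
    plain_concat_c(a, b)
  add <- function(a, b) if (is_ag(a) || is_ag(b)) ag_add(a, b) else
    ag_value(a) + ag_value(b)

  e1 <- lrelu(conv(x, "enc1"))
  e2 <- lrelu(conv(pool(e1), "enc2"))
  bt <- lrelu(conv(pool(e2), "bott"))
  u2 <- lrelu(conv(up(bt), "up2", kernel = 1L))
  f2 <- lrelu(conv(cat_c(u2, e2), "fuse2"))
  u1 <- lrelu(conv(up(f2), "up1", kernel = 1L))
  f1 <- lrelu(conv(cat_c(u1, e1), "fuse1"))
  add(x, conv(f1, "out"))           # global residual
}

## plain (tape-free) twins of the network primitives, used at inference

plain_conv2d <- function(x, W, b, kernel = 3L) {
  d <- dim(x); Cout <- ncol(W)
  y <- if (kernel == 3L) im2col3(x) %*% W else matrix(x, ncol = d[4]) %*% W
  y <- sweep(y, 2, b, "+")
  array(y, c(d[1], d[2], d[3], Cout))
}

plain_avgpool2 <- function(x) {
  d <- dim(x)
  io <- seq(1, d[1], 2); jo <- seq(1, d[2], 2)
  (x[io, jo, , , drop = FALSE] + x[io + 1, jo, , , drop = FALSE] +
     x[io, jo + 1, , , drop = FALSE] + x[io + 1, jo + 1, , , drop = FALSE]) / 4
}

plain_upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

plain_concat_c <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}
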