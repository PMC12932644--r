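# Minimal tape-based reverse-mode automatic differentiation.
#
# Training the unrolled network requires back-propagating the final
# data-fidelity cost through the iteration blocks, including through the
# analytic cost-gradient computation itself (products, squares and
# PSF convolutions of the state) and through the shared convolutional
# update network. The engine below records every primitive on a tape during
# the forward pass and replays it in reverse; each primitive stores a
# vector-Jacobian closure. Values are plain R arrays: 2-D images in the
# physics part, (H, W, B, C) activations in the network part.

ag_env <- new.env(parent = emptyenv())
ag_env$tape <- NULL
ag_env$n <- 0L

ag_reset <- function() {
  ag_env$tape <- vector("list", 512L)
  ag_env$n <- 0L
  invisible(NULL)
}

ag_record <- function(node) {
  n <- ag_env$n + 1L
  if (n > length(ag_env$tape))
    ag_env$tape <- c(ag_env$tape, vector("list", length(ag_env$tape)))
  ag_env$tape[[n]] <- node
  ag_env$n <- n
  node
}

# create a differentiable node; parents is a list of ag nodes, vjp a
# function(grad_out) returning one gradient array per parent
ag_node <- function(value, parents = list(), vjp = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$parents <- parents
  node$vjp <- vjp
  node$grad <- NULL
  class(node) <- "ag_node"
  ag_record(node)
}

is_ag <- function(x) inherits(x, "ag_node")
ag_value <- function(x) if (is_ag(x)) x$value else x

# leaf with gradient tracking (parameters and differentiable inputs)
ag_leaf <- function(value) ag_node(value)

ag_accum <- function(node, g) {
  if (is.null(node$grad)) node$grad <- g else node$grad <- node$grad + g
}

# reverse sweep from a scalar loss node
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1)
  loss$grad <- 1
  for (k in seq.int(ag_env$n, 1L)) {
    node <- ag_env$tape[[k]]
    if (is.null(node$grad) || is.null(node$vjp)) next
    gs <- node$vjp(node$grad)
    for (i in seq_along(node$parents)) {
      p <- node$parents[[i]]
      if (is_ag(p) && !is.null(gs[[i]])) ag_accum(p, gs[[i]])
    }
  }
  invisible(NULL)
}

## ---- elementwise primitives (shape-agnostic) --------------------------------

ag_add <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(av + bv, list(a, b), function(g) list(g, g))
}

ag_sub <- function(a, b) {
  ag_node(ag_value(a) - ag_value(b), list(a, b), function(g) list(g, -g))
}

ag_mul <- function(a, b) {
  av <- ag_value(a); bv <- ag_value(b)
  ag_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ag_square <- function(a) {
  av <- ag_value(a)
  ag_node(av^2, list(a), function(g) list(2 * av * g))
}

# multiply by a scalar (possibly a scalar node, e.g. a learnable step size)
ag_scale <- function(a, s) {
  av <- ag_value(a); sv <- ag_value(s)
  ag_node(av * sv, list(a, s),
          function(g) list(g * sv, sum(g * av)))
}

ag_neg_scale_const <- function(a, k) {   # a * k for constant k
  av <- ag_value(a)
  ag_node(av * k, list(a), function(g) list(g * k))
}

ag_sum_sq <- function(a) {
  av <- ag_value(a)
  ag_node(sum(av^2), list(a), function(g) list(2 * g * av))
}

ag_sum_list <- function(nodes) {
  vals <- lapply(nodes, ag_value)
  ag_node(Reduce(`+`, vals), nodes,
          function(g) rep(list(g), length(nodes)))
}

## ---- physics primitives -----------------------------------------------------

# circular convolution of a 2-D image with a fixed real OTF; the adjoint is
# correlation (conjugate OTF)
ag_conv_otf <- function(a, otf) {
  av <- ag_value(a)
  ag_node(conv_otf(av, otf), list(a),
          function(g) list(corr_otf(g, otf)))
}

ag_corr_otf <- function(a, otf) {
  av <- ag_value(a)
  ag_node(corr_otf(av, otf), list(a),
          function(g) list(conv_otf(g, otf)))
}

## ---- network primitives -----------------------------------------------------
# activations are (H, W, B, C) arrays; weights for a 3x3 conv are stored as a
# (9 * Cin) x Cout matrix plus a length-Cout bias.

# Precomputed flat-index tables for the 3x3 neighbourhood gather. For a
# zero-padded (H+2, W+2, B) block, entry [, o] holds the linear indices of
# the H*W*B pixels shifted by offset o (column-major over dc, dr), so both
# the gather and the scatter reduce to fast matrix row indexing.
conv3_index <- function(H, W, B) {
  key <- paste(H, W, B, sep = "x")
  if (is.null(ag_env$idx_cache)) ag_env$idx_cache <- list()
  hit <- ag_env$idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  base <- outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+")     # (i, j) at offset 0
  base <- as.vector(outer(as.vector(base), (seq_len(B) - 1L) * Hp * Wp, "+"))
  idx <- matrix(0L, H * W * B, 9L)
  o <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    o <- o + 1L
    idx[, o] <- base + dr + dc * Hp
  }
  out <- list(idx = idx, interior = idx[, 5L], Hp = Hp, Wp = Wp)
  ag_env$idx_cache[[key]] <- out
  out
}

# gather the 3x3 zero-padded neighbourhood into an (H*W*B) x (9*Cin)
# matrix; column blocks are offset-major with channels contiguous
im2col3 <- function(x) {
  d <- dim(x)  # H W B C
  H <- d[1]; W <- d[2]; B <- d[3]; C <- d[4]
  ci <- conv3_index(H, W, B)
  P <- matrix(0, ci$Hp * ci$Wp * B, C)
  P[ci$interior, ] <- x
  col <- matrix(0, H * W * B, 9L * C)
  for (o in 1:9) col[, (o - 1L) * C + seq_len(C)] <- P[ci$idx[, o], ]
  col
}

# scatter-add of a column-gradient back onto the (H, W, B, C) input
col2im3 <- function(dcol, H, W, B, C) {
  ci <- conv3_index(H, W, B)
  P <- matrix(0, ci$Hp * ci$Wp * B, C)
  for (o in 1:9) {
    ix <- ci$idx[, o]
    P[ix, ] <- P[ix, ] + dcol[, (o - 1L) * C + seq_len(C)]
  }
  out <- P[ci$interior, ]
  dim(out) <- c(H, W, B, C)
  out
}

# 3x3 same-padding convolution; kernel is either 3x3 (kw = 1) or 1x1 (kw = 0)
ag_conv2d <- function(x, weight, bias, kernel = 3L) {
  xv <- ag_value(x); wv <- ag_value(weight); bv <- ag_value(bias)
  d <- dim(xv); H <- d[1]; W <- d[2]; B <- d[3]; Cin <- d[4]
  Cout <- ncol(wv)
  col <- if (kernel == 3L) im2col3(xv) else {
    xm <- xv
    dim(xm) <- c(H * W * B, Cin)
    xm
  }
  y <- col %*% wv
  y <- sweep(y, 2, bv, "+")
  out <- y
  dim(out) <- c(H, W, B, Cout)
  ag_node(out, list(x, weight, bias), function(g) {
    gm <- g
    dim(gm) <- c(H * W * B, Cout)
    db <- colSums(gm)
    dW <- crossprod(col, gm)          # col kept from the forward pass
    dx <- if (kernel == 3L) col2im3(gm %*% t(wv), H, W, B, Cin)
      else {
        d2 <- gm %*% t(wv)
        dim(d2) <- c(H, W, B, Cin)
        d2
      }
    list(dx, dW, db)
  })
}

ag_leaky_relu <- function(x, slope = 0.1) {
  xv <- ag_value(x)
  neg <- which(xv < 0)     # which() drops NAs from non-finite overflow
  out <- xv
  out[neg] <- slope * xv[neg]
  ag_node(out, list(x), function(g) {
    g[neg] <- slope * g[neg]
    list(g)
  })
}

ag_avgpool2 <- function(x) {
  xv <- ag_value(x)
  d <- dim(xv); H <- d[1]; W <- d[2]
  io <- seq(1, H, 2); jo <- seq(1, W, 2)
  out <- (xv[io, jo, , , drop = FALSE] + xv[io + 1, jo, , , drop = FALSE] +
            xv[io, jo + 1, , , drop = FALSE] +
            xv[io + 1, jo + 1, , , drop = FALSE]) / 4
  ag_node(out, list(x), function(g) {
    dx <- array(0, d)
    g4 <- g / 4
    dx[io, jo, , ] <- g4; dx[io + 1, jo, , ] <- g4
    dx[io, jo + 1, , ] <- g4; dx[io + 1, jo + 1, , ] <- g4
    list(dx)
  })
}

ag_upsample2 <- function(x) {   # nearest neighbour x2
  xv <- ag_value(x)
  d <- dim(xv); H <- d[1]; W <- d[2]
  ri <- rep(seq_len(H), each = 2); ci <- rep(seq_len(W), each = 2)
  out <- xv[ri, ci, , , drop = FALSE]
  ag_node(out, list(x), function(g) {
    io <- seq(1, 2 * H, 2); jo <- seq(1, 2 * W, 2)
    list(g[io, jo, , , drop = FALSE] + g[io + 1, jo, , , drop = FALSE] +
           g[io, jo + 1, , , drop = FALSE] +
           g[io + 1, jo + 1, , , drop = FALSE])
  })
}

ag_concat_c <- function(a, b) {   # concatenate along the channel axis
  av <- ag_value(a); bv <- ag_value(b)
  da <- dim(av); db_ <- dim(bv)
  out <- array(0, c(da[1], da[2], da[3], da[4] + db_[4]))
  out[, , , seq_len(da[4])] <- av
  out[, , , da[4] + seq_len(db_[4])] <- bv
  ag_node(out, list(a, b), function(g)
    list(g[, , , seq_len(da[4]), drop = FALSE],
         g[, , , da[4] + seq_len(db_[4]), drop = FALSE]))
}

# stack a list of (H, W) image nodes into an (H, W, B, 1) activation
ag_stack_images <- function(imgs) {
  vals <- lapply(imgs, ag_value)
  H <- nrow(vals[[1]]); W <- ncol(vals[[1]]); B <- length(vals)
  out <- array(unlist(vals, use.names = FALSE), c(H, W, B, 1L))
  ag_node(out, imgs, function(g)
    lapply(seq_len(B), function(b) g[, , b, 1L]))
}

# relabel array dims without moving data (e.g. batch axis <-> channel axis)
ag_reshape <- function(x, new_dim) {
  xv <- ag_value(x)
  old_dim <- dim(xv)
  out <- xv
  dim(out) <- new_dim
  ag_node(out, list(x), function(g) {
    dim(g) <- old_dim
    list(g)
  })
}

# slice image b back out of an (H, W, B, 1) activation
ag_unstack_image <- function(x, b) {
  xv <- ag_value(x)
  d <- dim(xv)
  ag_node(xv[, , b, 1L], list(x), function(g) {
    dx <- array(0, d)
    dx[, , b, 1L] <- g
    list(dx)
  })
}
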