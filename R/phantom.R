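# Synthetic fluorophore-density phantoms with sub-diffraction features.
# These stand in for experimentally derived structure classes (microtubule
# filaments, clathrin pits/rings, ER tubule meshes) when testing the
# simulator and the reconstruction algorithms.

# accumulate a Gaussian splat of width sigma (px) at each (r, c) point
splat_points <- function(img, r, c, sigma = 0.7, amp = 1) {
  nr <- nrow(img); nc <- ncol(img)
  half <- max(2L, ceiling(3 * sigma))
  amp <- rep_len(amp, length(r))
  for (k in seq_along(r)) {
    i0 <- max(1L, floor(r[k]) - half); i1 <- min(nr, floor(r[k]) + half)
    j0 <- max(1L, floor(c[k]) - half); j1 <- min(nc, floor(c[k]) + half)
    if (i0 > i1 || j0 > j1) next
    ii <- i0:i1; jj <- j0:j1
    g <- exp(-(outer((ii - r[k])^2, (jj - c[k])^2, "+")) / (2 * sigma^2))
    img[ii, jj] <- img[ii, jj] + amp[k] * g
  }
  img
}

# points along a random quadratic Bezier curve, ~2 samples per pixel
bezier_points <- function(p0, p1, p2, n) {
  t <- seq(0, 1, length.out = n)
  r <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
  c <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
  cbind(r, c)
}

#' Generate a synthetic fluorophore-density phantom
#'
#' Produces a nonnegative 2-D object image containing structures with
#' sub-diffraction detail: random curved filaments, point-like puncta, a
#' tubule mesh, thin rings, or parallel line pairs at a controlled spacing
#' (the classical resolution target). A cosine taper (default 8 px) keeps
#' structure away from the periodic boundary.
#'
#' @param kind one of `"filaments"`, `"puncta"`, `"tubule_mesh"`, `"rings"`,
#'   `"line_pairs"`.
#' @param image_shape integer `(rows, cols)`; scalar recycled.
#' @param density_params list of kind-specific settings:
#'   `n` (count of filaments / puncta / rings / pairs),
#'   `sigma` splat width in px (structure thickness, default 0.7),
#'   `radius` ring radius in px, `spacing` line-pair separation in px.
#' @param seed integer seed; the same seed reproduces the phantom exactly.
#' @param taper_border cosine-taper width in px (0 disables).
#' @return object of class `ubsim_phantom`: list with `object` (matrix,
#'   max-normalised to 1) and `kind`.
#' @examples
#' ph <- make_phantom("filaments", 64, seed = 7)
#' range(ph$object)
#' @export
make_phantom <- function(kind = c("filaments", "puncta", "tubule_mesh",
                                  "rings", "line_pairs"),
                         image_shape = c(64, 64), density_params = list(),
                         seed = 1L, taper_border = 8L) {
  kind <- match.arg(kind)
  if (length(image_shape) == 1) image_shape <- rep(image_shape, 2)
  nr <- as.integer(image_shape[1]); nc <- as.integer(image_shape[2])
  p <- utils::modifyList(list(n = NULL, sigma = 0.7, radius = NULL,
                              spacing = NULL), density_params)
  img <- matrix(0, nr, nc)
  with_seed(seed, {
    if (kind == "filaments") {
      n <- if (is.null(p$n)) max(4L, round(nr / 12)) else p$n
      if (n < 1) stop("filament phantom needs density n >= 1")
      for (k in seq_len(n)) {
        p0 <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
        p2 <- c(stats::runif(1, 1, nr), stats::runif(1, 1, nc))
        mid <- (p0 + p2) / 2 + stats::rnorm(2, 0, nr / 5)
        pts <- bezier_points(p0, mid, p2, 2L * max(nr, nc))
        img <- splat_points(img, pts[, 1], pts[, 2], p$sigma)
      }
    } else if (kind == "puncta") {
      n <- if (is.null(p$n)) max(10L, round(nr * nc / 80)) else p$n
      if (n < 1) stop("puncta phantom with density 0 would be empty")
      r <- stats::runif(n, 2, nr - 1); c <- stats::runif(n, 2, nc - 1)
      amp <- stats::runif(n, 0.4, 1)
      img <- splat_points(img, r, c, p$sigma, amp)
    } else if (kind == "tubule_mesh") {
      # network of wavy tubules joining random anchor nodes, ER-like
      n_nodes <- if (is.null(p$n)) 8L else p$n
      if (n_nodes < 2) stop("tubule mesh needs at least 2 nodes")
      nodes <- cbind(stats::runif(n_nodes, 4, nr - 3),
                     stats::runif(n_nodes, 4, nc - 3))
      for (k in seq_len(n_nodes)) {
        d2 <- rowSums((nodes - matrix(nodes[k, ], n_nodes, 2, TRUE))^2)
        nb <- order(d2)[2:min(4, n_nodes)]
        for (j in nb) {
          mid <- (nodes[k, ] + nodes[j, ]) / 2 + stats::rnorm(2, 0, nr / 10)
          pts <- bezier_points(nodes[k, ], mid, nodes[j, ], 2L * max(nr, nc))
          img <- splat_points(img, pts[, 1], pts[, 2], p$sigma)
        }
      }
    } else if (kind == "rings") {
      n <- if (is.null(p$n)) 5L else p$n
      if (n < 1) stop("ring phantom needs density n >= 1")
      radius <- if (is.null(p$radius)) max(3, nr / 16) else p$radius
      for (k in seq_len(n)) {
        cr <- stats::runif(1, radius + 3, nr - radius - 2)
        cc <- stats::runif(1, radius + 3, nc - radius - 2)
        th <- seq(0, 2 * pi, length.out = ceiling(4 * pi * radius))
        img <- splat_points(img, cr + radius * sin(th), cc + radius * cos(th),
                            p$sigma)
      }
    } else if (kind == "line_pairs") {
      n <- if (is.null(p$n)) 3L else p$n
      if (n < 1) stop("line-pair phantom needs density n >= 1")
      spacing <- if (is.null(p$spacing)) 3 else p$spacing
      cols <- if (n == 1) nc / 2 else seq(nc * 0.15, nc * 0.85,
                                          length.out = n)
      for (cc in cols) {
        rr <- seq(nr * 0.15, nr * 0.85, length.out = 2L * nr)
        img <- splat_points(img, rr, rep(cc - spacing / 2, length(rr)), p$sigma)
        img <- splat_points(img, rr, rep(cc + spacing / 2, length(rr)), p$sigma)
      }
    }
  })
  if (taper_border > 0) img <- img * cosine_taper(c(nr, nc), taper_border)
  if (max(img) <= 0) stop("generated phantom is empty; increase the density")
  img <- img / max(img)
  structure(list(object = img, kind = kind), class = "ubsim_phantom")
}

#' @export
print.ubsim_phantom <- function(x, ...) {
  cat(sprintf("ubsim phantom '%s': %d x %d px, %d nonzero px\n", x$kind,
              nrow(x$object), ncol(x$object), sum(x$object > 0)))
  invisible(x)
}
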