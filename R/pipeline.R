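# End-to-end plumbing: TIFF stack I/O with YAML sidecars, rolling-window
# video reconstruction, the iterations benchmark report, and run manifests
# for exact replay.

#' Write / read a multi-page TIFF stack with a YAML sidecar
#'
#' Frames are stored as 32-bit float pages scaled to `[0, 1]` (the TIFF
#' writer's domain); the intensity scale, the optical configuration and
#' the pixel size go into the sidecar (same path with `.yaml` appended),
#' so reading restores the original values and units.
#'
#' @param stack an `ubsim_stack` or 3-D array.
#' @param path output TIFF path.
#' @param meta optional named list merged into the sidecar.
#' @return `write_stack_tiff` returns `path` invisibly; `read_stack_tiff`
#'   returns an `ubsim_stack` (with `config` when the sidecar holds one).
#' @export
write_stack_tiff <- function(stack, path, meta = list()) {
  fr <- if (inherits(stack, "ubsim_stack")) stack$frames else stack
  d <- dim(fr)
  scale <- max(fr, 1e-300)
  pages <- lapply(seq_len(d[3]), function(l) fr[, , l] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  side <- list(frames = d[3], shape = d[1:2], intensity_scale = scale)
  if (inherits(stack, "ubsim_stack")) {
    side$pixel_size <- stack$pixel_size
    side$config <- unclass(stack$config)
  }
  side <- utils::modifyList(side, meta)
  yaml::write_yaml(side, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  fr <- array(0, c(dim(pages[[1]])[1:2], length(pages)))
  for (l in seq_along(pages)) {
    p <- pages[[l]]
    if (length(dim(p)) == 3) p <- p[, , 1]
    fr[, , l] <- p
  }
  side_path <- paste0(path, ".yaml")
  cfg <- NULL; px <- 1
  if (file.exists(side_path)) {
    side <- yaml::read_yaml(side_path)
    if (!is.null(side$intensity_scale)) fr <- fr * side$intensity_scale
    if (!is.null(side$pixel_size)) px <- side$pixel_size
    if (!is.null(side$config))
      cfg <- do.call(optical_config, side$config[
        c("wavelength", "na_detection", "na_illumination", "pixel_size",
          "image_shape", "seed")])
  }
  structure(list(frames = fr, pixel_size = px, noise = NULL, config = cfg),
            class = "ubsim_stack")
}

#' Number of super-resolved frames of a rolling-window job
#'
#' `floor((T - window) / step) + 1` windows fit in `T` raw frames.
#' @param n_frames total raw frame count `T`.
#' @param window sub-frames per SR frame.
#' @param step frame advance between consecutive windows.
#' @export
rolling_frame_count <- function(n_frames, window, step) {
  if (window > n_frames) stop("window exceeds the number of raw frames")
  if (step < 1 || step > window)
    stop("step must satisfy 1 <= step <= window")
  as.integer(floor((n_frames - window) / step) + 1L)
}

#' Rolling-window super-resolution video reconstruction
#'
#' Slides a window of `window` raw sub-frames along the acquisition with a
#' stride of `step` frames and reconstructs one SR frame per position with
#' the chosen backend, so the effective SR frame rate is the raw rate
#' divided by `step`. Adjacent windows share `window - step` raw frames,
#' which smooths fast dynamics; window and step are recorded with the
#' result so the temporal support of each SR frame is auditable. Each
#' window is intensity-normalised independently, which tolerates slow
#' photobleaching.
#'
#' @param frames 3-D array (rows x cols x T) or `ubsim_stack` of raw frames.
#' @param psf an `ubsim_psf`.
#' @param window sub-frames per SR frame (default 20).
#' @param step stride between windows (default 2).
#' @param backend reconstruction backend: an [unrolled_model()] or a
#'   [solver_config()].
#' @return object of class `ubsim_video`: `sr_frames` (rows x cols x
#'   n_windows), `window`, `step`, `frame_offsets` (first raw frame of each
#'   window).
#' @export
rolling_reconstruct <- function(frames, psf, window = 20L, step = 2L,
                                backend = solver_config("prcg",
                                                        max_iters = 60L)) {
  fr <- if (inherits(frames, "ubsim_stack")) frames$frames else frames
  d <- dim(fr)
  n_out <- rolling_frame_count(d[3], window, step)
  px <- if (inherits(frames, "ubsim_stack")) frames$pixel_size else 1
  cfg <- if (inherits(frames, "ubsim_stack")) frames$config else NULL
  sr <- array(0, c(d[1], d[2], n_out))
  offsets <- integer(n_out)
  for (w in seq_len(n_out)) {
    first <- (w - 1L) * step + 1L
    offsets[w] <- first
    sub <- structure(list(frames = fr[, , first:(first + window - 1L)],
                          pixel_size = px, noise = NULL, config = cfg),
                     class = "ubsim_stack")
    sub <- normalize_stack(sub)
    sr[, , w] <- if (inherits(backend, "ubsim_model"))
      unrolled_forward(backend, sub, psf)$rho
    else blind_sim_reconstruct(sub, psf, backend)$rho
  }
  structure(list(sr_frames = sr, window = as.integer(window),
                 step = as.integer(step), frame_offsets = offsets),
            class = "ubsim_video")
}

#' @export
print.ubsim_video <- function(x, ...) {
  d <- dim(x$sr_frames)
  cat(sprintf(
    "ubsim SR video: %d frames of %d x %d px (window %d, step %d)\n",
    d[3], d[1], d[2], x$window, x$step))
  invisible(x)
}

#' Iterations benchmark of iterative methods against the unrolled model
#'
#' For each stack, runs the unrolled model to obtain its final cost, then
#' counts the iterations each classical method needs to reach that cost.
#' Reports per-stack counts and the log10 iteration ratios relative to the
#' model's block count, with median and interquartile summaries.
#'
#' @param stacks list of `ubsim_stack` objects.
#' @param model a (trained) [unrolled_model()].
#' @param psf an `ubsim_psf`.
#' @param methods iterative methods to benchmark.
#' @param max_iters per-method iteration budget (censored counts flagged).
#' @param csv,json optional output paths for the per-stack table / summary.
#' @return list of class `ubsim_benchmark`: `per_stack` data.frame,
#'   `summary` data.frame (per-method median and IQR of iterations).
#' @export
benchmark_report <- function(stacks, model, psf,
                             methods = c("gd", "prcg", "nesterov"),
                             max_iters = 2000L, csv = NULL, json = NULL) {
  rows <- list()
  for (i in seq_along(stacks)) {
    stk <- normalize_stack(stacks[[i]])
    uf <- unrolled_forward(model, stk, psf)
    if (length(methods) > 0) {
      it <- iterations_to_target(stk, psf, methods, uf$cost, max_iters)
      it$stack <- i
      it$ubsim_cost <- uf$cost
      it$log10_ratio <- log10(pmax(it$iterations, 1) / model$n_blocks)
      rows[[i]] <- it
    }
  }
  per_stack <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(method = character(), iterations = integer(),
               censored = logical(), final_cost = numeric(),
               stack = integer(), ubsim_cost = numeric(),
               log10_ratio = numeric())
  summary <- if (nrow(per_stack) > 0) {
    agg <- lapply(split(per_stack, per_stack$method), function(d)
      data.frame(method = d$method[1],
                 median_iterations = stats::median(d$iterations),
                 iqr_iterations = stats::IQR(d$iterations),
                 median_log10_ratio = stats::median(d$log10_ratio),
                 any_censored = any(d$censored)))
    do.call(rbind, agg)
  } else data.frame(method = character(), median_iterations = numeric(),
                    iqr_iterations = numeric(),
                    median_log10_ratio = numeric(), any_censored = logical())
  rownames(summary) <- NULL
  if (!is.null(csv)) utils::write.csv(per_stack, csv, row.names = FALSE)
  if (!is.null(json) && requireNamespace("jsonlite", quietly = TRUE))
    jsonlite::write_json(summary, json, auto_unbox = TRUE, digits = NA)
  structure(list(per_stack = per_stack, summary = summary),
            class = "ubsim_benchmark")
}

#' @export
print.ubsim_benchmark <- function(x, ...) {
  cat("ubsim iterations benchmark (iterations to reach the unrolled cost):\n")
  print(x$summary)
  invisible(x)
}

## ---- run manifests ----------------------------------------------------------

#' Write a run manifest for exact replay
#'
#' Records the function call, configuration, seeds and MD5 hashes of the
#' input files so a deterministic run can be replayed and verified.
#' Refuses to overwrite an existing manifest unless `force = TRUE`.
#'
#' @param path manifest path (YAML).
#' @param config named list of configuration values (must include any seeds).
#' @param inputs character vector of input file paths to hash.
#' @param force overwrite an existing manifest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config, inputs = character(), force = FALSE) {
  if (file.exists(path) && !force)
    stop(sprintf("manifest '%s' already exists; use force = TRUE to replace",
                 path))
  if (is.null(config$seed)) {
    config$seed <- 1L
    message("manifest: no seed in config, recorded default seed 1")
  }
  hashes <- if (length(inputs) > 0) as.list(tools::md5sum(inputs)) else list()
  manifest <- list(package = "ubsim",
                   version = as.character(utils::packageVersion("ubsim")),
                   created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                   config = config, input_md5 = hashes)
  yaml::write_yaml(manifest, path)
  invisible(manifest)
}

#' Verify a manifest before replaying a run
#'
#' Re-hashes the recorded input files and refuses if any hash differs
#' (tampered or replaced inputs) unless `force = TRUE`.
#'
#' @param path manifest path.
#' @param force proceed despite hash mismatches.
#' @return the manifest list.
#' @export
check_manifest <- function(path, force = FALSE) {
  manifest <- yaml::read_yaml(path)
  for (f in names(manifest$input_md5)) {
    now <- unname(tools::md5sum(f))
    if (is.na(now) || now != manifest$input_md5[[f]]) {
      msg <- sprintf("input '%s' does not match its manifest hash", f)
      if (force) warning(msg) else stop(paste0(msg, "; replay refused"))
    }
  }
  manifest
}
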