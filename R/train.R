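# Unsupervised training of the unrolled model. The loss is the physical
# data-fidelity cost of the final block output on raw sub-frame stacks —
# no ground-truth objects enter anywhere. Weights of the shared update
# network and the per-block step scales are optimised with Adam; the
# learning rate is reduced when the validation loss plateaus.

#' Training configuration for the unrolled model
#'
#' @param learning_rate initial Adam learning rate (default 1e-4; small
#'   desk-scale runs typically use a larger rate, see the vignette).
#' @param epochs passes over the training stacks.
#' @param batch_size stacks per Adam step (default 1; losses are averaged
#'   within a batch).
#' @param lr_patience epochs of non-improving validation loss before the
#'   learning rate is halved (reduce-on-plateau).
#' @param lr_factor multiplicative reduction factor (default 0.5).
#' @param clip_norm global gradient-norm clip (default 10; `Inf` disables).
#' @param val_fraction fraction of stacks held out for validation
#'   (default 0.2, at least one stack when possible).
#' @param loss_mode `"final"` (default): the cost of the final block output,
#'   as stated for the original training scheme; `"blocks"`: the mean cost
#'   over all block outputs, which gives every block a direct learning
#'   signal and speeds up small training runs.
#' @param alpha_lr_mult learning-rate multiplier for the per-block step
#'   scales (default 1).
#' @param seed integer seed for shuffling and splits.
#' @export
train_config <- function(learning_rate = 1e-4, epochs = 20L, batch_size = 1L,
                         lr_patience = 3L, lr_factor = 0.5, clip_norm = 10,
                         val_fraction = 0.2, loss_mode = c("final", "blocks"),
                         alpha_lr_mult = 1, seed = 1L) {
  loss_mode <- match.arg(loss_mode)
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (epochs < 1) stop("need at least one epoch")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_patience = as.integer(lr_patience),
                 lr_factor = lr_factor, clip_norm = clip_norm,
                 val_fraction = val_fraction, loss_mode = loss_mode,
                 alpha_lr_mult = alpha_lr_mult, seed = as.integer(seed)),
            class = "ubsim_train_config")
}

# loss used during optimization: mean squared residual per pixel per frame
# (the data-fidelity cost divided by L * n_pixels, a constant factor that
# keeps gradient magnitudes comparable across image sizes)
train_loss_scale <- function(stack) 1 / length(stack$frames)

# per-stack loss and parameter gradients through the full unrolled graph
train_step_grads <- function(model, stack, psf, loss_mode = "final") {
  ag_reset()
  fwd <- ag_unrolled_forward(model, stack, psf)
  scale <- train_loss_scale(stack)
  loss_node <- if (loss_mode == "blocks")
    ag_neg_scale_const(ag_sum_list(fwd$block_losses),
                       scale / length(fwd$block_losses))
  else ag_neg_scale_const(fwd$loss, scale)
  ag_backward(loss_node)
  g_params <- lapply(fwd$params, function(p)
    if (is.null(p$grad)) array(0, dim(p$value) %||% length(p$value)) else p$grad)
  g_alphas <- vapply(fwd$alphas, function(a)
    if (is.null(a$grad)) 0 else a$grad, numeric(1))
  out <- list(loss = ag_value(loss_node), g_params = g_params,
              g_alphas = g_alphas)
  ag_reset()   # release the tape
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate the (scaled) loss of the numeric forward on a set of stacks
unrolled_mean_loss <- function(model, stacks, psf) {
  mean(vapply(stacks, function(s) {
    s <- normalize_stack(s)
    unrolled_forward(model, s, psf)$cost * train_loss_scale(s)
  }, numeric(1)))
}

#' Train the unrolled model without ground truth
#'
#' Minimises the mean physical cost of the final block output over a set of
#' raw sub-frame stacks with Adam. Only the stacks and the PSF are consumed:
#' the API has no slot for ground-truth objects, so training is unsupervised
#' by construction. The learning rate is halved when the validation loss
#' stops improving. A non-finite loss aborts the run with a divergence
#' warning and returns the best checkpoint seen.
#'
#' @param model an [unrolled_model()] with a real (non-identity) network.
#' @param stacks list of `ubsim_stack` objects (raw sub-frame stacks).
#' @param psf an `ubsim_psf`.
#' @param config a [train_config()].
#' @return list of class `ubsim_fit`: `model` (trained), `history`
#'   (data.frame epoch/train_loss/val_loss/lr), `initial_val_loss`.
#' @export
train_unrolled <- function(model, stacks, psf, config = train_config()) {
  stopifnot(inherits(model, "ubsim_model"), inherits(config, "ubsim_train_config"))
  if (identical(model$cnn, "identity"))
    stop("the identity model has no trainable network")
  if (length(stacks) < 2) stop("need at least two training stacks")
  stacks <- lapply(stacks, normalize_stack)
  n_val <- max(1L, min(length(stacks) - 1L,
                       round(config$val_fraction * length(stacks))))
  split <- with_seed(config$seed, sample(seq_along(stacks)))
  val_idx <- split[seq_len(n_val)]
  train_idx <- setdiff(split, val_idx)

  theta <- c(model$cnn$params, list(.alphas = model$step_scales))
  adam_m <- lapply(theta, function(p) p * 0)
  adam_v <- lapply(theta, function(p) p * 0)
  lr <- config$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  t_step <- 0L

  val_model <- function() {
    m <- model
    m$cnn$params <- theta[names(model$cnn$params)]
    m$step_scales <- theta$.alphas
    m
  }
  initial_val <- unrolled_mean_loss(val_model(), stacks[val_idx], psf)
  best_val <- initial_val
  best_theta <- theta
  bad_epochs <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric(), lr = numeric())

  for (ep in seq_len(config$epochs)) {
    order_idx <- with_seed(config$seed + ep, sample(train_idx))
    ep_losses <- numeric(0)
    batch <- list()
    flush_batch <- function(batch) {
      grads <- lapply(batch, function(st)
        train_step_grads(val_model(), st, psf, config$loss_mode))
      loss <- mean(vapply(grads, `[[`, numeric(1), "loss"))
      if (!is.finite(loss))
        stop(structure(class = c("ubsim_divergence", "error", "condition"),
                       list(message = "non-finite training loss",
                            call = sys.call(-1))))
      t_step <<- t_step + 1L
      gsum <- grads[[1]]$g_params
      for (k in seq_along(grads)[-1])
        gsum <- Map(`+`, gsum, grads[[k]]$g_params)
      gsum <- lapply(gsum, function(g) g / length(grads))
      ga <- rowMeans(vapply(grads, `[[`, numeric(length(theta$.alphas)),
                            "g_alphas"))
      g_all <- c(gsum, list(.alphas = ga))
      gn <- sqrt(sum(vapply(g_all, function(g) sum(g^2), numeric(1))))
      if (is.finite(config$clip_norm) && gn > config$clip_norm)
        g_all <- lapply(g_all, function(g) g * (config$clip_norm / gn))
      for (nm in names(theta)) {
        lr_nm <- if (nm == ".alphas") lr * config$alpha_lr_mult else lr
        adam_m[[nm]] <<- beta1 * adam_m[[nm]] + (1 - beta1) * g_all[[nm]]
        adam_v[[nm]] <<- beta2 * adam_v[[nm]] + (1 - beta2) * g_all[[nm]]^2
        mhat <- adam_m[[nm]] / (1 - beta1^t_step)
        vhat <- adam_v[[nm]] / (1 - beta2^t_step)
        theta[[nm]] <<- theta[[nm]] - lr_nm * mhat / (sqrt(vhat) + eps)
      }
      loss
    }
    diverged <- FALSE
    tryCatch({
      for (idx in order_idx) {
        batch[[length(batch) + 1L]] <- stacks[[idx]]
        if (length(batch) == config$batch_size) {
          ep_losses <- c(ep_losses, flush_batch(batch))
          batch <- list()
        }
      }
      if (length(batch) > 0) ep_losses <- c(ep_losses, flush_batch(batch))
    }, ubsim_divergence = function(e) diverged <<- TRUE)
    if (diverged) {
      # roll back to the last checkpoint that improved validation
      warning(sprintf(paste0(
        "training diverged (non-finite loss) in epoch %d; returning the ",
        "best checkpoint (validation loss %.4g)"), ep, best_val))
      theta <- best_theta
      break
    }

    val <- unrolled_mean_loss(val_model(), stacks[val_idx], psf)
    hist <- rbind(hist, data.frame(epoch = ep,
                                   train_loss = mean(ep_losses),
                                   val_loss = val, lr = lr))
    if (val < best_val - 1e-12) {
      best_val <- val
      best_theta <- theta
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= config$lr_patience) {
        lr <- lr * config$lr_factor
        bad_epochs <- 0L
      }
    }
  }
  theta <- best_theta
  out_model <- val_model()
  structure(list(model = out_model, history = hist,
                 initial_val_loss = initial_val,
                 final_val_loss = best_val, config = config),
            class = "ubsim_fit")
}

#' @export
print.ubsim_fit <- function(x, ...) {
  cat(sprintf(
    "ubsim fit: %d epochs, validation loss %.4g -> %.4g (initial %.4g)\n",
    nrow(x$history), x$history$val_loss[1],
    x$final_val_loss, x$initial_val_loss))
  invisible(x)
}

## ---- weights I/O ------------------------------------------------------------

model_arch_signature <- function(model) {
  cnn_sig <- if (identical(model$cnn, "identity")) "identity"
    else sprintf("cnn[width=%d,channels=%d,leak=%g]",
                 model$cnn$width, model$cnn$channels, model$cnn$leak)
  sprintf("ubsim/1|n_blocks=%d|mode=%s|%s", model$n_blocks, model$mode, cnn_sig)
}

#' Save / load unrolled-model weights
#'
#' The checkpoint embeds an architecture signature and the weights version;
#' loading verifies the signature field by field and refuses a mismatched or
#' corrupted file.
#'
#' @param model an [unrolled_model()].
#' @param path file path for the checkpoint.
#' @return `save_weights` returns `path` invisibly; `load_weights` returns
#'   the restored model.
#' @export
save_weights <- function(model, path) {
  stopifnot(inherits(model, "ubsim_model"))
  payload <- list(signature = model_arch_signature(model),
                  weights_version = model$weights_version,
                  n_blocks = model$n_blocks, mode = model$mode,
                  step_scales = model$step_scales,
                  cnn = if (identical(model$cnn, "identity")) "identity"
                    else unclass(model$cnn))
  saveRDS(payload, path)
  invisible(path)
}

#' @rdname save_weights
#' @param template optional [unrolled_model()] whose architecture the file
#'   must match (signature check field by field).
#' @export
load_weights <- function(path, template = NULL) {
  payload <- tryCatch(readRDS(path), error = function(e)
    stop(sprintf("cannot read checkpoint '%s': %s", path, conditionMessage(e))))
  need <- c("signature", "n_blocks", "mode", "step_scales", "cnn")
  if (!is.list(payload) || !all(need %in% names(payload)))
    stop(sprintf("checkpoint '%s' is corrupted or not a ubsim checkpoint", path))
  cnn <- if (identical(payload$cnn, "identity")) "identity"
    else structure(payload$cnn, class = "ubsim_cnn")
  model <- unrolled_model(payload$n_blocks, cnn,
                          alpha0 = payload$step_scales, mode = payload$mode)
  model$weights_version <- payload$weights_version
  if (model_arch_signature(model) != payload$signature)
    stop("checkpoint signature does not match its own contents (corrupted file)")
  if (!is.null(template)) {
    if (template$n_blocks != model$n_blocks)
      stop(sprintf("architecture mismatch in field 'n_blocks': file has %d, template has %d",
                   model$n_blocks, template$n_blocks))
    if (template$mode != model$mode)
      stop(sprintf("architecture mismatch in field 'mode': file has '%s', template has '%s'",
                   model$mode, template$mode))
    t_sig <- model_arch_signature(template)
    f_sig <- model_arch_signature(model)
    if (t_sig != f_sig)
      stop(sprintf("architecture mismatch: file '%s' vs template '%s'",
                   f_sig, t_sig))
  }
  model
}
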