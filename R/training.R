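#' Optimization settings for network training
#'
#' Defaults follow the published training recipe: Adam with learning rate
#' 0.001, beta1 = 0.9, beta2 = 0.999, zero decay, mean-squared-error loss on
#' the normalized dose over the full voxel grid, batch size 4, at most 120
#' epochs, and early stopping with a 30-epoch patience on the validation
#' loss. Adam's epsilon is 1e-7 (the default of the framework the recipe
#' was tuned in).
#'
#' @param epochs Maximum epochs (>= 1).
#' @param batch_size Samples per Adam step (>= 1).
#' @param learning_rate Adam step size (> 0).
#' @param beta1,beta2 Adam moment decay rates.
#' @param epsilon Adam denominator offset.
#' @param patience Epochs without validation improvement before stopping;
#'   `Inf` disables early stopping.
#' @param warmup_steps Number of initial Adam steps taken at
#'   `warmup_factor * learning_rate` before switching to the full rate.
#'   Adam's bias-corrected first step moves every parameter by a full
#'   `learning_rate` regardless of gradient magnitude, which can
#'   catastrophically overshoot on a freshly initialized deep network and
#'   poison the second-moment estimate for thousands of steps; a brief
#'   reduced-rate warmup removes that failure mode without altering the
#'   published optimizer settings thereafter. Set to 0 to disable.
#' @param warmup_factor Learning-rate multiplier during warmup.
#' @param min_delta Minimum decrease in validation loss that counts as an
#'   improvement.
#' @param restore_best Keep the weights of the best-validation epoch rather
#'   than the final ones (checkpoint-on-best).
#' @param seed Seed for shuffling and dropout.
#' @param verbose Print one line per epoch.
#' @return An object of class `train_control`.
#' @export
train_control <- function(epochs = 120L, batch_size = 4L,
                          learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                          epsilon = 1e-7, patience = 30,
                          warmup_steps = 10L, warmup_factor = 0.01,
                          min_delta = 0, restore_best = TRUE,
                          seed = 1L, verbose = FALSE) {
  if (epochs < 1) stop_kbp("epochs must be >= 1")
  if (batch_size < 1) stop_kbp("batch_size must be >= 1")
  if (learning_rate <= 0) stop_kbp("learning_rate must be positive")
  if (is.finite(patience) && patience > epochs)
    stop_kbp("patience cannot exceed epochs")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, patience = patience,
                 warmup_steps = as.integer(warmup_steps),
                 warmup_factor = warmup_factor,
                 min_delta = min_delta, restore_best = isTRUE(restore_best),
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_control")
}

#' Mean-squared error between two dose volumes
#'
#' `(1/n) * sum_i (predicted_i - truth_i)^2` over all n voxels; the training
#' loss, computed on the normalized-dose scale over the full grid with no
#' structure masking.
#'
#' @param predicted,truth Numeric arrays/vectors of identical shape, finite.
#' @return Scalar loss.
#' @export
mse_loss <- function(predicted, truth) {
  if (!identical(dim(predicted) %||% length(predicted),
                 dim(truth) %||% length(truth)))
    stop_kbp("shape mismatch between predicted and ground-truth volumes")
  mean((as.numeric(predicted) - as.numeric(truth))^2)
}

# One training pair: x an input_tensor (n x 12 matrix with dims attr),
# y the normalized dose as a length-n vector.
validate_pairs <- function(pairs, what) {
  if (length(pairs) == 0) stop_kbp("empty ", what, " set")
  for (p in pairs) {
    if (is.null(p$x) || is.null(p$y))
      stop_kbp(what, " pairs need elements x (input tensor) and y (dose)")
    if (nrow(p$x) != length(p$y))
      stop_kbp("voxel count mismatch between x and y in ", what, " pair")
  }
  invisible(TRUE)
}

adam_init <- function(params) {
  lapply(params, function(ly) list(mW = ly$W * 0, vW = ly$W * 0,
                                   mb = ly$b * 0, vb = ly$b * 0))
}

adam_step <- function(params, grads, state, t, ctl) {
  b1 <- ctl$beta1; b2 <- ctl$beta2
  corr1 <- 1 - b1^t; corr2 <- 1 - b2^t
  lr <- ctl$learning_rate
  if (t <= (ctl$warmup_steps %||% 0L)) lr <- lr * ctl$warmup_factor
  eps <- ctl$epsilon
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$mW <- b1 * st$mW + (1 - b1) * g$gW
    st$vW <- b2 * st$vW + (1 - b2) * g$gW^2
    st$mb <- b1 * st$mb + (1 - b1) * g$gb
    st$vb <- b2 * st$vb + (1 - b2) * g$gb^2
    params[[nm]]$W <- params[[nm]]$W -
      lr * (st$mW / corr1) / (sqrt(st$vW / corr2) + eps)
    params[[nm]]$b <- params[[nm]]$b -
      lr * (st$mb / corr1) / (sqrt(st$vb / corr2) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

#' Train a dose-prediction network
#'
#' Minimizes the voxelwise mean-squared error on the normalized dose with
#' Adam, one optimizer step per minibatch, one full shuffled pass per epoch
#' (incomplete final batch kept). Validation loss is computed once per epoch
#' on the held-out set; training stops at `epochs` or when the validation
#' loss has not improved for `patience` consecutive epochs, whichever comes
#' first. With `restore_best`, the returned network carries the weights of
#' the best-validation epoch. All randomness (shuffling, dropout) is keyed
#' to `control$seed`.
#'
#' @param net A `dose_unet` from [build_attention_unet()] or
#'   [build_baseline_unet()].
#' @param train List of training pairs `list(x = input_tensor, y = normalized
#'   dose vector)`, e.g. from [prepare_pair()]; must be nonempty.
#' @param val Validation pairs; may be `NULL` to train without validation
#'   (disables early stopping).
#' @param control A [train_control()].
#' @return The trained `dose_unet`, with `curve` (a data frame of per-epoch
#'   training and validation loss), `best_epoch` and `epochs_run` filled in.
#' @export
train_network <- function(net, train, val = NULL, control = train_control()) {
  stopifnot(inherits(net, "dose_unet"), inherits(control, "train_control"))
  validate_pairs(train, "training")
  if (!is.null(val)) validate_pairs(val, "validation")
  set.seed(control$seed)

  params <- net$params
  state <- adam_init(params)
  t_step <- 0L
  n_tr <- length(train)
  curve <- data.frame(epoch = integer(), train_loss = numeric(),
                      val_loss = numeric())
  best_val <- Inf
  best_epoch <- NA_integer_
  best_params <- NULL
  wait <- 0L

  net_eval <- net
  for (epoch in seq_len(control$epochs)) {
    ord <- sample.int(n_tr)
    starts <- seq(1, n_tr, by = control$batch_size)
    ep_loss <- 0
    for (s in starts) {
      batch <- ord[s:min(s + control$batch_size - 1L, n_tr)]
      bs <- length(batch)
      grads <- NULL
      bloss <- 0
      for (i in batch) {
        pair <- train[[i]]
        dims <- attr(pair$x, "dims")
        net_eval$params <- params
        fw <- unet_forward(net_eval, pair$x, dims, training = TRUE,
                           keep_cache = TRUE)
        pred <- fw$out[, 1]
        loss_i <- mean((pred - pair$y)^2)
        if (!is.finite(loss_i))
          stop_kbp("non-finite training loss at epoch ", epoch,
                   "; aborting (diverged?)")
        bloss <- bloss + loss_i
        gout <- matrix(2 * (pred - pair$y) / length(pair$y), ncol = 1)
        g <- unet_backward(net_eval, fw$cache, gout)
        grads <- if (is.null(grads)) g else accumulate_grads(grads, g)
      }
      grads <- scale_grads(grads, 1 / bs)
      t_step <- t_step + 1L
      upd <- adam_step(params, grads, state, t_step, control)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + bloss
    }
    train_loss <- ep_loss / n_tr

    val_loss <- NA_real_
    if (!is.null(val)) {
      net_eval$params <- params
      vl <- vapply(val, function(pair) {
        fw <- unet_forward(net_eval, pair$x, attr(pair$x, "dims"),
                           training = FALSE)
        mean((fw$out[, 1] - pair$y)^2)
      }, numeric(1))
      val_loss <- mean(vl)
    }
    curve <- rbind(curve, data.frame(epoch = epoch, train_loss = train_loss,
                                     val_loss = val_loss))
    if (control$verbose)
      message(sprintf("epoch %3d  train %.6f  val %s", epoch, train_loss,
                      ifelse(is.na(val_loss), "-", sprintf("%.6f", val_loss))))

    if (!is.null(val) && is.finite(control$patience)) {
      if (val_loss < best_val - control$min_delta) {
        best_val <- val_loss
        best_epoch <- epoch
        wait <- 0L
        if (control$restore_best) best_params <- params
      } else {
        wait <- wait + 1L
        if (wait >= control$patience) break
      }
    } else if (!is.null(val) && (is.na(best_val) || val_loss < best_val)) {
      best_val <- val_loss
      best_epoch <- epoch
    }
  }

  if (!is.null(best_params)) params <- best_params
  net$params <- params
  net$curve <- curve
  net$control <- control
  net$best_epoch <- best_epoch
  net$epochs_run <- nrow(curve)
  net$trained <- TRUE
  net
}

accumulate_grads <- function(a, b) {
  for (nm in names(a)) {
    a[[nm]]$gW <- a[[nm]]$gW + b[[nm]]$gW
    a[[nm]]$gb <- a[[nm]]$gb + b[[nm]]$gb
  }
  a
}

scale_grads <- function(g, f) {
  for (nm in names(g)) {
    g[[nm]]$gW <- g[[nm]]$gW * f
    g[[nm]]$gb <- g[[nm]]$gb * f
  }
  g
}

#' Fit a dose-prediction U-Net to a cohort of plans
#'
#' The one-call fitting interface: builds the network (attention-gated by
#' default), He-initializes it, prepares the plan samples (crop, normalize,
#' zero-fill, stack), and trains with Adam and early stopping. Returns a
#' fitted model object with the usual methods (`print`, `summary`, `coef`,
#' `predict`, `plot`, `residuals`).
#'
#' @param train List of `plan_sample` objects (or prepared pairs).
#' @param val Validation samples, same form; `NULL` for none.
#' @param config A [model_config()].
#' @param control A [train_control()].
#' @param out_size Cropped input edge length (default 64; must be divisible
#'   by `2^(n_levels - 1)`).
#' @param seed He-initialization seed.
#' @return A trained `dose_unet`.
#' @export
dose_unet <- function(train, val = NULL, config = model_config(),
                      control = train_control(), out_size = 64, seed = 1L) {
  as_pair <- function(s) {
    if (inherits(s, "plan_sample")) prepare_pair(s, out_size)[c("x", "y")]
    else s
  }
  train <- lapply(train, as_pair)
  if (!is.null(val)) val <- lapply(val, as_pair)
  net <- if (config$use_attention) build_attention_unet(config, seed)
         else build_baseline_unet(config, seed)
  train_network(net, train, val, control)
}

#' Predict a 3D dose distribution
#'
#' Runs the forward pass on a prepared input tensor (or a raw plan sample,
#' which is prepared first) and rescales the normalized output back to Gy by
#' multiplying with the prescription; negative voxels are clipped to zero
#' for reporting.
#'
#' @param object A `dose_unet`.
#' @param newdata An `input_tensor`, a `plan_sample`, or a list of either.
#' @param prescription Prescription dose in Gy used for rescaling.
#' @param normalized If `TRUE`, return the raw dimensionless output (no
#'   rescaling, no clipping).
#' @param out_size Crop size used when `newdata` contains raw plan samples.
#' @param ... Unused.
#' @return A 3D dose array in Gy (or a list of them).
#' @export
predict.dose_unet <- function(object, newdata, prescription = 70,
                              normalized = FALSE, out_size = 64, ...) {
  predict_one <- function(x) {
    if (inherits(x, "plan_sample")) x <- prepare_pair(x, out_size)$x
    dims <- attr(x, "dims")
    if (is.null(dims)) stop_kbp("input tensor lacks a 'dims' attribute")
    fw <- unet_forward(object, x, dims, training = FALSE)
    pred <- fw$out[, 1]
    if (!normalized) pred <- pmax(denormalize_dose(pred, prescription), 0)
    unflatten_volume(pred, dims)
  }
  if (inherits(newdata, "plan_sample") || inherits(newdata, "input_tensor"))
    return(predict_one(newdata))
  if (is.list(newdata)) return(lapply(newdata, predict_one))
  stop_kbp("newdata must be an input_tensor, a plan_sample, or a list")
}
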