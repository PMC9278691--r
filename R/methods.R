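#' @export
print.dose_unet <- function(x, ...) {
  cfg <- x$config
  cat(if (cfg$use_attention) "Attention-gated" else "Baseline",
      "3D U-Net dose-prediction model\n")
  cat("  levels:", cfg$n_levels,
      " features:", paste(cfg$features, collapse = "-"), "\n")
  cat("  input channels:", cfg$in_channels,
      " output channels:", cfg$out_channels, "\n")
  cat("  trainable parameters:",
      format(count_trainable_parameters(x), big.mark = ","), "\n")
  if (isTRUE(x$trained)) {
    cat("  trained:", x$epochs_run, "epochs")
    if (!is.na(x$best_epoch)) {
      bv <- x$curve$val_loss[x$best_epoch]
      cat(sprintf("; best validation loss %.6f at epoch %d",
                  bv, x$best_epoch))
    }
    cat("\n")
  } else {
    cat("  trained: no (freshly initialized)\n")
  }
  invisible(x)
}

#' Layer-by-layer summary of a dose-prediction network
#'
#' @param object A `dose_unet`.
#' @param ... Unused.
#' @return Invisibly, a data frame with one row per layer (kernel, input and
#'   output channels, parameter count).
#' @export
summary.dose_unet <- function(object, ...) {
  print(object)
  df <- do.call(rbind, lapply(names(object$params), function(nm) {
    ly <- object$params[[nm]]
    data.frame(layer = nm, kernel = paste0(ly$k, "^3"),
               in_channels = ly$cin, out_channels = ly$cout,
               params = length(ly$W) + length(ly$b))
  }))
  cat("\n")
  print(df, row.names = FALSE)
  invisible(df)
}

#' Extract all trainable parameters as a flat vector
#'
#' @param object A `dose_unet`.
#' @param ... Unused.
#' @return Named numeric vector of every weight and bias.
#' @export
coef.dose_unet <- function(object, ...) {
  unlist(lapply(object$params, function(ly) list(W = as.numeric(ly$W),
                                                 b = ly$b)))
}

#' Plot the learning curve of a trained network
#'
#' Training and validation loss (normalized-dose MSE) per epoch.
#'
#' @param x A trained `dose_unet`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.dose_unet <- function(x, ...) {
  if (is.null(x$curve) || nrow(x$curve) == 0)
    stop_kbp("no learning curve: the network has not been trained")
  has_val <- any(is.finite(x$curve$val_loss))
  y <- if (has_val) cbind(x$curve$train_loss, x$curve$val_loss)
       else cbind(x$curve$train_loss)
  graphics::matplot(x$curve$epoch, y, type = "l", lty = 1,
                    col = c("black", "firebrick")[seq_len(ncol(y))],
                    xlab = "Epoch", ylab = "MSE loss (normalized dose)", ...)
  if (has_val)
    graphics::legend("topright", legend = c("training", "validation"),
                     col = c("black", "firebrick"), lty = 1, bty = "n")
  if (!is.na(x$best_epoch))
    graphics::abline(v = x$best_epoch, lty = 3, col = "grey50")
  invisible(x)
}

#' Dose residual maps for a set of plans
#'
#' Predicts each plan and returns the voxelwise difference maps
#' (predicted minus ground truth), in Gy, on the cropped grid.
#'
#' @param object A `dose_unet`.
#' @param newdata A `plan_sample` or list of them.
#' @param out_size Crop size for preparation.
#' @param ... Unused.
#' @return A signed 3D array, or a list of them.
#' @export
residuals.dose_unet <- function(object, newdata, out_size = 64, ...) {
  one <- function(s) {
    stopifnot(inherits(s, "plan_sample"))
    pp <- prepare_pair(s, out_size)
    pred <- predict(object, pp$x, prescription = pp$prescription)
    difference_map(pred, pp$sample$dose)
  }
  if (inherits(newdata, "plan_sample")) return(one(newdata))
  lapply(newdata, one)
}

#' @export
print.model_config <- function(x, ...) {
  cat("U-Net model configuration:",
      if (x$use_attention) "attention-gated" else "baseline", "\n")
  cat("  levels:", x$n_levels, " features:",
      paste(x$features, collapse = "-"), "\n")
  cat("  dropout (encoder):", paste(x$dropout_rates, collapse = ", "), "\n")
  cat("  upsampling:", x$upsample_mode,
      " gate width rule:", x$gate_width, "\n")
  invisible(x)
}
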