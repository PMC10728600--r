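# S3 methods for dcsanet models.

#' @export
print.dcsanet <- function(x, ...) {
  cfg <- x$config
  cat("DCSAnet segmentation model\n")
  cat(sprintf("  encoder: stem %d -> stages %s (kernels %dx1/%dx1, shuffle %s, attention %s)\n",
              cfg$stem_channels,
              paste(cfg$stage_widths, collapse = "/"),
              cfg$kernel_small, cfg$kernel_N,
              ifelse(cfg$use_shuffle, "on", "off"),
              ifelse(cfg$use_attention, "on", "off")))
  cat(sprintf("  decoder: %s, widths %s -> %d classes\n",
              cfg$decoder_variant,
              paste(cfg$decoder_widths, collapse = "/"), cfg$num_classes))
  cat(sprintf("  parameters: %s%s\n",
              format(count_params(x), big.mark = ","),
              if (is.null(x$history)) " (untrained)" else
                sprintf(" (trained %d epochs, final loss %.4f)",
                        max(x$history$epoch),
                        x$history$train_loss[nrow(x$history)])))
  invisible(x)
}

#' @export
summary.dcsanet <- function(object, input_size = 512L, ...) {
  model_summary(object, input_size)
}

#' Predict segmentation masks
#'
#' @param object a [dcsanet()] model.
#' @param images one `H x W x 3` array (values in `[0, 1]`) or a list of them;
#'   spatial sizes must be divisible by 32.
#' @param type `"class"` for integer label masks, `"prob"` for `H x W x K`
#'   probability arrays.
#' @param batch_size inference batch size (images of equal size are batched).
#' @param ... unused.
#' @return a mask (or probability array), or a list of them when `images` is
#'   a list.
#' @export
predict.dcsanet <- function(object, images, type = c("class", "prob"),
                            batch_size = 4L, ...) {
  type <- match.arg(type)
  single <- is.array(images) && length(dim(images)) == 3L
  if (single) images <- list(images)
  sizes <- vapply(images, function(im) paste(dim(im)[1:2], collapse = "x"), "")
  out <- vector("list", length(images))
  for (sz in unique(sizes)) {
    idx <- which(sizes == sz)
    logits <- infer_logits(object, images[idx], batch_size)
    for (k in seq_along(idx)) {
      d <- dim(images[[idx[k]]])
      L <- logits[[k]]
      out[[idx[k]]] <- if (type == "class") {
        mask_from_logits(L, d[1], d[2])
      } else {
        P <- exp(L - apply(L, 1, max))
        array(P / rowSums(P), c(d[1], d[2], ncol(L)))
      }
    }
  }
  if (single) out[[1]] else out
}

#' Plot training history
#'
#' Loss (and MIoU when recorded) against epoch for a trained model.
#'
#' @param x a [dcsanet()] model with a training history.
#' @param ... passed to [graphics::plot()].
#' @export
plot.dcsanet <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history; run train_dcsanet()")
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "cross-entropy loss", ...)
  if (any(!is.na(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", legend = c("train", "validation"),
                     lty = c(1, 2), bty = "n")
  }
  invisible(x)
}
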