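# Training and evaluation: pixelwise cross-entropy, Adam optimisation,
# confusion accumulation and mean intersection-over-union, plus the decoder
# ablation harness.

#' Training configuration
#'
#' Defaults follow the original DCSAnet training recipe: Adam with initial
#' learning rate 0.001, batch size 4, 400 epochs.
#'
#' @param initial_lr Adam step size.
#' @param batch_size images per optimisation step.
#' @param epochs training epochs (one pass over the training set each).
#' @param seed integer seed controlling shuffling (weight initialisation is
#'   seeded by [dcsanet()]).
#' @param val_every evaluate the validation set every this many epochs.
#' @param miou_every compute training MIoU every this many epochs (also the
#'   early-stop check interval when `target_miou` is set).
#' @param target_miou optional training-MIoU threshold at which training
#'   stops early.
#' @param verbose print a progress line per epoch.
#' @return an object of class `dcsa_train_config`.
#' @export
train_config <- function(initial_lr = 0.001, batch_size = 4L, epochs = 400L,
                         seed = 1L, val_every = 1L, miou_every = 10L,
                         target_miou = NULL, verbose = FALSE) {
  stopifnot(initial_lr > 0, batch_size >= 1, epochs >= 1)
  structure(list(initial_lr = initial_lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 val_every = as.integer(val_every),
                 miou_every = as.integer(miou_every),
                 target_miou = target_miou, verbose = isTRUE(verbose)),
            class = "dcsa_train_config")
}

#' Pixelwise cross-entropy loss
#'
#' Evaluates `-(1/N) * sum_i sum_c y_ic * log(p_ic)` where `N` is the number
#' of pixels, `y_ic` indicates the true class of pixel `i` and `p_ic` is the
#' predicted probability. Probabilities are clamped at machine epsilon before
#' the logarithm.
#'
#' @param prob an `N x M` matrix of per-pixel class probabilities (or an
#'   `H x W x M` array).
#' @param truth integer labels in `0..M-1` (vector or `H x W` matrix), or an
#'   `N x M` one-hot matrix.
#' @return nonnegative scalar loss.
#' @export
cross_entropy_loss <- function(prob, truth) {
  if (is.array(prob) && length(dim(prob)) == 3L) {
    d <- dim(prob)
    prob <- matrix(prob, d[1] * d[2], d[3])
  }
  n <- nrow(prob)
  M <- ncol(prob)
  if (is.matrix(truth) && ncol(truth) == M && nrow(truth) == n &&
      all(truth %in% c(0, 1))) {
    lab <- max.col(truth, ties.method = "first") - 1L
  } else {
    lab <- as.integer(truth)
  }
  if (length(lab) != n) {
    stop("truth (", length(lab), " pixels) does not match prob (", n, " rows)")
  }
  if (any(lab < 0L | lab >= M)) stop("labels must lie in 0..", M - 1L)
  p <- pmax(prob[cbind(seq_len(n), lab + 1L)], .Machine$double.eps)
  -mean(log(p))
}

#' Per-class confusion counts of two label masks
#'
#' One-vs-rest pixel counts per class: TP (predicted and labelled positive),
#' FP (predicted positive, labelled negative), FN (predicted negative,
#' labelled positive), TN (both negative).
#'
#' @param pred,truth integer masks of identical shape with values in
#'   `0..n_classes-1`.
#' @param n_classes the class-alphabet size `k + 1`.
#' @return object of class `confusion_counts`: per-class `tp`, `fp`, `fn`,
#'   `tn` and the total pixel count.
#' @export
confusion_from_masks <- function(pred, truth, n_classes) {
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (length(pred) != length(truth)) stop("masks must have identical shape")
  if (length(pred) == 0L) stop("empty masks")
  K <- as.integer(n_classes)
  if (any(pred < 0L | pred >= K) || any(truth < 0L | truth >= K)) {
    stop("mask values must lie in 0..", K - 1L)
  }
  cm <- matrix(tabulate(truth * K + pred + 1L, nbins = K * K),
               K, K, byrow = TRUE) # cm[t+1, p+1]
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  total <- length(pred)
  structure(list(classes = 0:(K - 1L), tp = tp, fp = fp, fn = fn,
                 tn = total - tp - fp - fn, total = total, n_classes = K),
            class = "confusion_counts")
}

# Elementwise accumulation of confusion counts.
add_confusion <- function(a, b) {
  if (is.null(a)) return(b)
  stopifnot(a$n_classes == b$n_classes)
  for (f in c("tp", "fp", "fn", "tn")) a[[f]] <- a[[f]] + b[[f]]
  a$total <- a$total + b$total
  a
}

#' Mean intersection-over-union from confusion counts
#'
#' Per-class IoU is `TP / (TP + FN + FP)`; MIoU is the unweighted mean over
#' the `k + 1` classes (background included). Classes absent from both the
#' prediction and the truth (`TP + FP + FN = 0`) contribute no term to the
#' mean and carry `NA` in the per-class vector.
#'
#' @param confusion a [confusion_from_masks()] result.
#' @return object of class `miou_report` with `per_class_iou`, `miou` and the
#'   confusion counts.
#' @export
miou <- function(confusion) {
  stopifnot(inherits(confusion, "confusion_counts"))
  denom <- confusion$tp + confusion$fp + confusion$fn
  iou <- ifelse(denom > 0, confusion$tp / denom, NA_real_)
  structure(list(per_class_iou = iou, miou = mean(iou, na.rm = TRUE),
                 confusion = confusion),
            class = "miou_report")
}

#' @export
print.miou_report <- function(x, ...) {
  cat(sprintf("MIoU: %.4f\n", x$miou))
  cat("per-class IoU:",
      paste(sprintf("%d: %s", x$confusion$classes,
                    ifelse(is.na(x$per_class_iou), "absent",
                           sprintf("%.4f", x$per_class_iou))),
            collapse = "  "), "\n")
  invisible(x)
}

# ---- Adam --------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# ---- batched inference -------------------------------------------------------

# Forward a list of samples/images in eval mode; returns per-image logits
# matrices ((H*W) x K).
infer_logits <- function(model, images, batch_size = 4L) {
  out <- vector("list", length(images))
  i <- 1L
  while (i <= length(images)) {
    j <- min(i + batch_size - 1L, length(images))
    st <- stack_images(images[i:j])
    tape <- ag_tape()
    lg <- fw_dcsanet(model, tape, st$X, st$dim, training = FALSE)
    L <- ag_val(tape, lg)
    per <- st$dim[2] * st$dim[3]
    for (k in i:j) {
      out[[k]] <- L[((k - i) * per + 1L):((k - i + 1L) * per), , drop = FALSE]
    }
    i <- j + 1L
  }
  out
}

mask_from_logits <- function(L, H, W) {
  matrix(max.col(L, ties.method = "first") - 1L, H, W)
}

#' Evaluate a model on labelled samples
#'
#' Confusion counts are accumulated over all samples and MIoU is computed
#' once at the dataset level (not averaged per image).
#'
#' @param model a trained [dcsanet()] model.
#' @param samples nonempty list of segmentation samples (`image`, `mask`).
#' @param batch_size inference batch size.
#' @return a [miou()] report.
#' @export
evaluate_model <- function(model, samples, batch_size = 4L) {
  if (length(samples) == 0L) stop("no samples to evaluate")
  K <- model$config$num_classes
  logits <- infer_logits(model, lapply(samples, `[[`, "image"), batch_size)
  conf <- NULL
  for (k in seq_along(samples)) {
    d <- dim(samples[[k]]$image)
    pm <- mask_from_logits(logits[[k]], d[1], d[2])
    conf <- add_confusion(conf,
                          confusion_from_masks(pm, samples[[k]]$mask, K))
  }
  miou(conf)
}

# ---- training loop -----------------------------------------------------------

#' Train a DCSAnet model
#'
#' Minimises the pixelwise cross-entropy with Adam. Batches are reshuffled
#' every epoch under the configuration seed; per-epoch training loss (and
#' validation loss/MIoU when a validation set is given) is recorded in the
#' returned model's `history`. Training aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param model a [dcsanet()] model.
#' @param train nonempty list of segmentation samples (`image` `H x W x 3`
#'   array in `[0, 1]`, `mask` `H x W` integer matrix in `0..num_classes-1`).
#' @param val optional validation sample list.
#' @param config a [train_config()].
#' @return the model with updated weights, normalization statistics and a
#'   `history` data frame (epoch, train_loss, train_miou, val_loss, val_miou).
#' @export
train_dcsanet <- function(model, train, val = NULL, config = train_config()) {
  stopifnot(inherits(model, "dcsanet"), inherits(config, "dcsa_train_config"))
  if (length(train) == 0L) stop("empty training set")
  K <- model$config$num_classes
  params <- model$params
  opt <- adam_init(params)
  hist <- list()

  with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(length(train))
      losses <- c()
      for (start in seq(1L, length(train), by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, length(train))]
        st <- stack_images(lapply(train[idx], `[[`, "image"))
        labels <- unlist(lapply(train[idx], function(s) as.vector(s$mask)),
                         use.names = FALSE)
        tape <- ag_tape()
        model$params <- params
        lg <- fw_dcsanet(model, tape, st$X, st$dim, training = TRUE)
        loss <- nn_softmax_ce(tape, lg, labels)
        lv <- ag_val(tape, loss)
        if (!is.finite(lv)) {
          stop("training diverged at epoch ", epoch, ": loss = ", lv)
        }
        losses <- c(losses, lv)
        grads <- ag_backward(tape, loss)
        upd <- adam_step(params, grads, opt, config$initial_lr)
        params <- upd$params
        opt <- upd$state
      }
      model$params <- params

      row <- list(epoch = epoch, train_loss = mean(losses),
                  train_miou = NA_real_, val_loss = NA_real_,
                  val_miou = NA_real_)
      check_miou <- (epoch %% config$miou_every == 0L ||
                       epoch == config$epochs) &&
        (!is.null(config$target_miou) || is.null(val))
      if (check_miou) {
        row$train_miou <- evaluate_model(model, train,
                                         config$batch_size)$miou
      }
      if (!is.null(val) && (epoch %% config$val_every == 0L ||
                              epoch == config$epochs)) {
        vl <- infer_logits(model, lapply(val, `[[`, "image"),
                           config$batch_size)
        vloss <- mean(vapply(seq_along(val), function(k) {
          L <- vl[[k]]
          P <- exp(L - apply(L, 1, max))
          P <- P / rowSums(P)
          cross_entropy_loss(P, as.vector(val[[k]]$mask))
        }, numeric(1)))
        conf <- NULL
        for (k in seq_along(val)) {
          d <- dim(val[[k]]$image)
          pm <- mask_from_logits(vl[[k]], d[1], d[2])
          conf <- add_confusion(conf,
                                confusion_from_masks(pm, val[[k]]$mask, K))
        }
        row$val_loss <- vloss
        row$val_miou <- miou(conf)$miou
      }
      hist[[length(hist) + 1L]] <- row
      if (config$verbose) {
        cat(sprintf("epoch %4d  loss %.4f%s\n", epoch, row$train_loss,
                    if (!is.na(row$train_miou)) {
                      sprintf("  train MIoU %.4f", row$train_miou)
                    } else ""))
      }
      if (!is.null(config$target_miou) && !is.na(row$train_miou) &&
            row$train_miou >= config$target_miou) {
        break
      }
    }
  })
  model$history <- do.call(rbind, lapply(hist, as.data.frame))
  model$train_config <- config
  model
}

# ---- ablation harness --------------------------------------------------------

#' Run the decoder/encoder ablation grid
#'
#' Builds one model per configuration, reports analytic FLOPs (G) and
#' parameters (M), and, when training data is supplied, trains each variant
#' and reports the evaluation MIoU (%).
#'
#' @param grid a character vector of decoder variants and/or a list of
#'   [dcsa_config()] objects.
#' @param base_config configuration template used for character variants.
#' @param train,eval optional sample lists; when given, every variant is
#'   trained on `train` and scored on `eval`.
#' @param train_cfg a [train_config()] used when training.
#' @param input_size resolution for the cost columns.
#' @param seed weight-initialisation seed shared by all variants.
#' @return data frame with columns `model`, `flops_g`, `param_m`, `miou_pct`.
#' @export
run_ablation <- function(grid = DECODER_VARIANTS,
                         base_config = dcsa_config(),
                         train = NULL, eval = NULL,
                         train_cfg = train_config(),
                         input_size = 512L, seed = 1L) {
  if (is.character(grid)) {
    grid <- lapply(grid, function(v) {
      cfg <- base_config
      cfg$decoder_variant <- v
      cfg
    })
    names(grid) <- vapply(grid, function(cfg) cfg$decoder_variant, "")
  }
  labels <- names(grid)
  if (is.null(labels)) {
    labels <- vapply(grid, function(cfg) cfg$decoder_variant, "")
  }
  rows <- lapply(seq_along(grid), function(i) {
    model <- dcsanet(grid[[i]], seed = seed)
    cost <- model_summary(model, input_size)
    miou_pct <- NA_real_
    if (!is.null(train)) {
      model <- train_dcsanet(model, train, config = train_cfg)
      scored <- evaluate_model(model, if (is.null(eval)) train else eval)
      miou_pct <- 100 * scored$miou
    }
    data.frame(model = labels[i], flops_g = cost$flops_billions,
               param_m = cost$params_millions, miou_pct = miou_pct,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
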