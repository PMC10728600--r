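# DCSAnet assembly: a 3x3 stride-2 stem, three DCA stages producing feature
# maps at 1/4, 1/8 and 1/32 of the input resolution, and a stepwise-upsampling
# decoder with optional guided aggregation of the shallow skip by the deep
# semantic map. Channel widths default to the values calibrated by
# scripts/calibrate_widths.R against the reference parameter/FLOP budgets.

DECODER_VARIANTS <- c("plain", "feat2_guided", "feat3_guided",
                      "feat2_guided_residual", "feat3_guided_residual")

#' DCSAnet architecture configuration
#'
#' Stage widths are tied to the stem width by the block contract (every DCA-B
#' doubles the channel count): stages output `2 *`, `4 *` and `16 *` the stem
#' width. The default stem width 6 and decoder widths c(88, 40, 32, 72, 38)
#' are the calibrated values that place the full model at about 0.56 M
#' parameters / 18.0 GFLOPs and the plain-decoder variant at about 0.46 M /
#' 17.0 GFLOPs for 512 x 512 inputs.
#'
#' @param stem_channels output channels of the stem convolution.
#' @param kernel_N odd kernel length of the large asymmetric branch
#'   (the ablation knob; 5, 7 or 9).
#' @param kernel_small odd kernel length of the small branch (default 3).
#' @param use_shuffle apply channel shuffling in every DCA block.
#' @param use_attention apply squeeze-and-excitation in the deepest three
#'   DCA-A blocks of stage 3.
#' @param decoder_variant one of `r paste0('"', DECODER_VARIANTS, '"', collapse = ", ")`.
#' @param decoder_widths five channel widths used on the way up
#'   (1/16, 1/8, 1/4, 1/2 and full resolution).
#' @param num_classes segmentation classes (>= 2); default 4 = background,
#'   soybean, graminoid weed, broadleaf weed.
#' @return an object of class `dcsa_config`.
#' @export
dcsa_config <- function(stem_channels = 6L,
                        kernel_N = 7L,
                        kernel_small = 3L,
                        use_shuffle = TRUE,
                        use_attention = TRUE,
                        decoder_variant = "feat3_guided_residual",
                        decoder_widths = c(88L, 40L, 32L, 72L, 38L),
                        num_classes = 4L) {
  if (stem_channels < 1 || stem_channels != round(stem_channels)) {
    stop("stem_channels must be a positive integer")
  }
  if (kernel_N %% 2 == 0 || kernel_small %% 2 == 0) {
    stop("asymmetric kernel lengths must be odd")
  }
  if (!decoder_variant %in% DECODER_VARIANTS) {
    stop("decoder_variant must be one of: ",
         paste(DECODER_VARIANTS, collapse = ", "))
  }
  if (length(decoder_widths) != 5L || any(decoder_widths < 1)) {
    stop("decoder_widths must be five positive integers")
  }
  if (num_classes < 2) stop("num_classes must be >= 2")
  s <- as.integer(stem_channels)
  structure(list(
    stem_channels = s,
    stage_widths = c(2L * s, 4L * s, 16L * s),
    kernel_N = as.integer(kernel_N),
    kernel_small = as.integer(kernel_small),
    use_shuffle = isTRUE(use_shuffle),
    use_attention = isTRUE(use_attention),
    decoder_variant = decoder_variant,
    decoder_widths = as.integer(decoder_widths),
    num_classes = as.integer(num_classes),
    input_divisor = 32L
  ), class = "dcsa_config")
}

# Flatten nested parameter lists to dot-separated names.
flatten_params <- function(p, prefix = "") {
  out <- list()
  for (nm in names(p)) {
    full <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    if (is.list(p[[nm]])) {
      out <- c(out, flatten_params(p[[nm]], full))
    } else {
      out[[full]] <- p[[nm]]
    }
  }
  out
}

# Manifest rows for one DCA block: analytic cost bookkeeping.
# scale_in/scale_out are resolution divisors relative to the network input.
dca_manifest <- function(name, cfg, scale_in, scale_out) {
  C <- cfg$in_channels
  E <- cfg$expansion_factor * C
  hc <- E %/% 2L
  rows <- list(
    list(name = paste0(name, ".expand"), kind = "conv", k = 1L,
         cin = C, cout = E, scale = scale_in),
    list(name = paste0(name, ".dw.small.v"), kind = "dw",
         k = cfg$kernel_small, cin = hc, cout = hc, scale = scale_out),
    list(name = paste0(name, ".dw.small.h"), kind = "dw",
         k = cfg$kernel_small, cin = hc, cout = hc, scale = scale_out),
    list(name = paste0(name, ".dw.large.v"), kind = "dw",
         k = cfg$kernel_N %||% cfg$kernel_large, cin = hc, cout = hc,
         scale = scale_out),
    list(name = paste0(name, ".dw.large.h"), kind = "dw",
         k = cfg$kernel_N %||% cfg$kernel_large, cin = hc, cout = hc,
         scale = scale_out),
    list(name = paste0(name, ".proj"), kind = "conv", k = 1L,
         cin = E, cout = C, scale = scale_out)
  )
  if (cfg$use_attention && cfg$mode == "A") {
    r <- max(1L, C %/% 4L)
    rows <- c(rows, list(
      list(name = paste0(name, ".se.fc1"), kind = "dense", k = 1L,
           cin = C, cout = r, scale = NA_real_),
      list(name = paste0(name, ".se.fc2"), kind = "dense", k = 1L,
           cin = r, cout = C, scale = NA_real_)
    ))
  }
  rows
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a DCSAnet model
#'
#' Instantiates the encoder (stem + three DCA stages), the decoder variant
#' named in the configuration, and the classifier head, with seeded
#' He-initialised weights.
#'
#' @param config a [dcsa_config()].
#' @param seed integer seed for weight initialisation.
#' @return an object of class `dcsanet`: the configuration, a flat named list
#'   of weight arrays, running normalization statistics, and a layer manifest
#'   used for analytic cost accounting.
#' @export
dcsanet <- function(config = dcsa_config(), seed = 1L) {
  stopifnot(inherits(config, "dcsa_config"))
  S <- config$stem_channels
  W1 <- config$stage_widths[1]
  W2 <- config$stage_widths[2]
  W3 <- config$stage_widths[3]
  d <- config$decoder_widths
  K <- config$num_classes
  kN <- config$kernel_N
  ks <- config$kernel_small

  blk_cfg <- function(C, mode, attn = FALSE) {
    dca_block_config(C, mode, kernel_small = ks, kernel_large = kN,
                     use_shuffle = config$use_shuffle, use_attention = attn)
  }
  # encoder plan: name, block config, input scale, output scale
  enc <- list(
    list("s1.b1", blk_cfg(S,      "B"), 2L, 4L),
    list("s1.b2", blk_cfg(W1,     "A"), 4L, 4L),
    list("s2.b1", blk_cfg(W1,     "B"), 4L, 8L),
    list("s2.b2", blk_cfg(W2,     "A"), 8L, 8L),
    list("s3.b1", blk_cfg(W2,     "B"), 8L, 16L),
    list("s3.b2", blk_cfg(2L * W2, "A"), 16L, 16L),
    list("s3.b3", blk_cfg(2L * W2, "A"), 16L, 16L),
    list("s3.b4", blk_cfg(2L * W2, "A"), 16L, 16L),
    list("s3.b5", blk_cfg(2L * W2, "B"), 16L, 32L),
    list("s3.b6", blk_cfg(W3,     "A", config$use_attention), 32L, 32L),
    list("s3.b7", blk_cfg(W3,     "A", config$use_attention), 32L, 32L),
    list("s3.b8", blk_cfg(W3,     "A", config$use_attention), 32L, 32L)
  )

  guided <- config$decoder_variant != "plain"
  wg <- if (grepl("feat3", config$decoder_variant)) W3 else W2

  params <- with_seed(seed, {
    p <- list()
    p$stem.w <- he_mat(9L * 3L, S, 9L * 3L)
    p$stem.bn.g <- rep(1, S)
    p$stem.bn.b <- rep(0, S)
    for (b in enc) {
      p <- c(p, flatten_params(dca_block_params(b[[2]]), b[[1]]))
    }
    add_conv <- function(p, name, k, cin, cout, bn = TRUE) {
      p[[paste0(name, ".w")]] <- he_mat(k * k * cin, cout, k * k * cin)
      if (bn) {
        p[[paste0(name, ".bn.g")]] <- rep(1, cout)
        p[[paste0(name, ".bn.b")]] <- rep(0, cout)
      }
      p
    }
    p <- add_conv(p, "dec.squeeze", 1L, W3, d[1])
    p <- add_conv(p, "dec.f2", 3L, d[1] + W2, d[2])
    p <- add_conv(p, "dec.f1", 3L, d[2] + W1, d[3])
    p <- add_conv(p, "dec.r2", 3L, d[3], d[4])
    p <- add_conv(p, "dec.r1", 3L, d[4], d[5])
    p[["dec.cls.w"]] <- he_mat(d[5], K, d[5])
    p[["dec.cls.b"]] <- rep(0, K)
    if (guided) {
      p <- add_conv(p, "gag.t1", 3L, wg, wg)
      p <- add_conv(p, "gag.t2", 3L, wg, W1)
    }
    p
  })

  rows <- list(list(name = "stem", kind = "conv", k = 9L, cin = 3L,
                    cout = S, scale = 2L))
  for (b in enc) rows <- c(rows, dca_manifest(b[[1]], b[[2]], b[[3]], b[[4]]))
  rows <- c(rows, list(
    list(name = "dec.squeeze", kind = "conv", k = 1L, cin = W3, cout = d[1],
         scale = 16L),
    list(name = "dec.f2", kind = "conv", k = 9L, cin = d[1] + W2,
         cout = d[2], scale = 8L),
    list(name = "dec.f1", kind = "conv", k = 9L, cin = d[2] + W1,
         cout = d[3], scale = 4L),
    list(name = "dec.r2", kind = "conv", k = 9L, cin = d[3], cout = d[4],
         scale = 2L),
    list(name = "dec.r1", kind = "conv", k = 9L, cin = d[4], cout = d[5],
         scale = 1L),
    list(name = "dec.cls", kind = "conv", k = 1L, cin = d[5], cout = K,
         scale = 1L)
  ))
  if (guided) {
    rows <- c(rows, list(
      list(name = "gag.t1", kind = "conv", k = 9L, cin = wg, cout = wg,
           scale = 8L),
      list(name = "gag.t2", kind = "conv", k = 9L, cin = wg, cout = W1,
           scale = 4L)
    ))
  }
  manifest <- do.call(rbind, lapply(rows, function(r) {
    data.frame(name = r$name, kind = r$kind, k = r$k, cin = r$cin,
               cout = r$cout, scale = r$scale, stringsAsFactors = FALSE)
  }))

  structure(list(config = config, params = params,
                 stats = new.env(parent = emptyenv()),
                 manifest = manifest, seed = seed,
                 enc_plan = enc, history = NULL),
            class = "dcsanet")
}

# ---- forward pass ------------------------------------------------------------

check_input_size <- function(model, H, W) {
  dv <- model$config$input_divisor
  if (H %% dv != 0 || W %% dv != 0) {
    stop("input spatial dimensions (", H, "x", W,
         ") must be divisible by ", dv)
  }
}

# Full tape-level forward. X is a (B*H*W) x 3 matrix; returns handles.
fw_dcsanet <- function(model, tape, X, dim, training = FALSE,
                       upto = c("logits", "encoder")) {
  upto <- match.arg(upto)
  cfg <- model$config
  check_input_size(model, dim[2], dim[3])
  P <- function(name) ag_param(tape, name, model$params[[name]])
  Pblk <- function(prefix) function(name) P(paste0(prefix, ".", name))
  st <- model$stats

  h <- ag_input(tape, X, dim)
  h <- nn_conv(tape, h, P("stem.w"), 3L, 3L, stride = 2L)
  h <- nn_bn(tape, h, P("stem.bn.g"), P("stem.bn.b"), st, "stem", training)
  h <- nn_relu(tape, h)

  feats <- list()
  for (b in model$enc_plan) {
    h <- tl_dca(tape, h, b[[2]], Pblk(b[[1]]), st, b[[1]], training)
    if (b[[1]] == "s1.b2") feats$feat1 <- h
    if (b[[1]] == "s2.b2") feats$feat2 <- h
    if (b[[1]] == "s3.b8") feats$feat3 <- h
  }
  if (upto == "encoder") return(feats)

  conv_bn_relu <- function(x, name, k, relu = TRUE) {
    y <- nn_conv(tape, x, P(paste0(name, ".w")), k, k)
    y <- nn_bn(tape, y, P(paste0(name, ".bn.g")), P(paste0(name, ".bn.b")),
               st, name, training)
    if (relu) nn_relu(tape, y) else y
  }

  f1 <- feats$feat1
  variant <- cfg$decoder_variant
  if (variant != "plain") {
    guide <- if (grepl("feat3", variant)) {
      nn_upsample(tape, feats$feat3, 4L) # 1/32 -> 1/8
    } else {
      feats$feat2
    }
    t1 <- conv_bn_relu(guide, "gag.t1", 3L)
    t1 <- nn_upsample(tape, t1, 2L) # 1/8 -> 1/4
    t2 <- conv_bn_relu(t1, "gag.t2", 3L, relu = FALSE)
    f1 <- nn_mul(tape, feats$feat1, t2)
    if (grepl("residual", variant)) f1 <- nn_add(tape, f1, feats$feat1)
  }

  u <- nn_upsample(tape, feats$feat3, 2L)              # 1/32 -> 1/16
  u <- conv_bn_relu(u, "dec.squeeze", 1L)
  u <- nn_upsample(tape, u, 2L)                        # -> 1/8
  u <- conv_bn_relu(nn_concat(tape, list(u, feats$feat2)), "dec.f2", 3L)
  u <- nn_upsample(tape, u, 2L)                        # -> 1/4
  u <- conv_bn_relu(nn_concat(tape, list(u, f1)), "dec.f1", 3L)
  u <- nn_upsample(tape, u, 2L)                        # -> 1/2
  u <- conv_bn_relu(u, "dec.r2", 3L)
  u <- nn_upsample(tape, u, 2L)                        # -> 1/1
  u <- conv_bn_relu(u, "dec.r1", 3L)
  u <- nn_conv(tape, u, P("dec.cls.w"), 1L, 1L)
  nn_add_bias(tape, u, P("dec.cls.b"))
}

# Stack a list of H x W x 3 arrays into the internal batch matrix.
stack_images <- function(images) {
  d <- dim(images[[1]])
  for (im in images) {
    if (!identical(dim(im), d)) stop("all images in a batch must share a size")
  }
  X <- do.call(rbind, lapply(images, function(im) matrix(im, d[1] * d[2], 3L)))
  list(X = X, dim = c(length(images), d[1], d[2], 3L))
}

#' Run the DCSAnet encoder
#'
#' @param model a [dcsanet()] model.
#' @param image an `H x W x 3` array with `H`, `W` divisible by 32.
#' @return list with `feat1`, `feat2`, `feat3`: arrays at 1/4, 1/8 and 1/32 of
#'   the input resolution with the configured stage widths.
#' @export
forward_encoder <- function(model, image) {
  stopifnot(inherits(model, "dcsanet"))
  fm <- fmap_from_array(image)
  check_input_size(model, fm$dim[2], fm$dim[3])
  tape <- ag_tape()
  feats <- fw_dcsanet(model, tape, fm$mat, fm$dim, training = FALSE,
                      upto = "encoder")
  lapply(feats, function(h) fmap_to_array(ag_val(tape, h), h$dim))
}

#' Guided aggregation of a shallow feature map by a deep one
#'
#' The semantically rich guide is refined by a 3x3 convolution at the
#' decoder's intermediate (1/8) resolution, upsampled to the target's scale,
#' channel-matched by a second 3x3 convolution, and combined with the target
#' by elementwise multiplication; with `residual = TRUE` the original target
#' is added back.
#'
#' @param target shallow feature map (`H x W x C` array, 1/4 scale).
#' @param guide deep feature map (`H/8 x W/8 x Cg` for a 1/32-scale guide or
#'   `H/2 x W/2 x Cg` for a 1/8-scale guide).
#' @param residual add the untouched target back after the product.
#' @param weights optional list with `t1.w`, `t1.bn.g`, `t1.bn.b`, `t2.w`,
#'   `t2.bn.g`, `t2.bn.b`; freshly initialised when omitted.
#' @return array with the target's shape.
#' @export
guided_aggregation <- function(target, guide, residual = TRUE,
                               weights = NULL) {
  dt <- dim(target)
  dg <- dim(guide)
  up1 <- dt[1] / 2L / dg[1] # factor taking the guide to 1/8 scale
  if (!up1 %in% c(1, 2, 4)) {
    stop("guide scale is incompatible with the target (expected the guide ",
         "at 1/2 or 1/8 of the target resolution)")
  }
  cg <- dg[3]
  if (is.null(weights)) {
    weights <- list(
      t1.w = he_mat(9L * cg, cg, 9L * cg), t1.bn.g = rep(1, cg),
      t1.bn.b = rep(0, cg),
      t2.w = he_mat(9L * cg, dt[3], 9L * cg), t2.bn.g = rep(1, dt[3]),
      t2.bn.b = rep(0, dt[3])
    )
  }
  fm_t <- fmap_from_array(target)
  fm_g <- fmap_from_array(guide)
  tape <- ag_tape()
  st <- new.env(parent = emptyenv())
  ht <- ag_input(tape, fm_t$mat, fm_t$dim)
  hg <- ag_input(tape, fm_g$mat, fm_g$dim)
  P <- function(name) ag_param(tape, name, resolve_param(weights, name))
  if (up1 > 1) hg <- nn_upsample(tape, hg, as.integer(up1))
  t1 <- nn_conv(tape, hg, P("t1.w"), 3L, 3L)
  t1 <- nn_bn(tape, t1, P("t1.bn.g"), P("t1.bn.b"), st, "t1", FALSE)
  t1 <- nn_relu(tape, t1)
  t1 <- nn_upsample(tape, t1, 2L)
  t2 <- nn_conv(tape, t1, P("t2.w"), 3L, 3L)
  t2 <- nn_bn(tape, t2, P("t2.bn.g"), P("t2.bn.b"), st, "t2", FALSE)
  out <- nn_mul(tape, ht, t2)
  if (residual) out <- nn_add(tape, out, ht)
  fmap_to_array(ag_val(tape, out), out$dim)
}

# ---- analytic cost report ----------------------------------------------------

#' Parameter and FLOP summary of a model
#'
#' Parameters are counted by exhaustive enumeration of the weight arrays.
#' FLOPs are computed analytically from the layer manifest using the
#' closed-form convolution costs (see [conv_flops()]) at the stated input
#' size, under the convention FLOPs = 2 x multiply-accumulates, counting
#' convolution and dense layers only.
#'
#' @param model a [dcsanet()] model.
#' @param input_size input resolution in pixels (square; divisible by 32).
#' @return object of class `dcsa_cost` with fields `params_millions`,
#'   `flops_billions`, `input_size`, raw counts, and the per-layer table.
#' @export
model_summary <- function(model, input_size = 512L) {
  stopifnot(inherits(model, "dcsanet"))
  if (input_size %% model$config$input_divisor != 0) {
    stop("input_size must be divisible by ", model$config$input_divisor)
  }
  m <- model$manifest
  px <- ifelse(is.na(m$scale), 1, (input_size / m$scale)^2)
  macs <- ifelse(m$kind == "dw",
                 px * m$k * m$cout,
                 px * m$k * m$cin * m$cout)
  m$macs <- macs
  n_params <- count_params(model)
  flops <- 2 * sum(macs)
  structure(list(params = n_params,
                 flops = flops,
                 params_millions = n_params / 1e6,
                 flops_billions = flops / 1e9,
                 input_size = as.integer(input_size),
                 layers = m),
            class = "dcsa_cost")
}

#' @export
print.dcsa_cost <- function(x, ...) {
  cat(sprintf("DCSAnet cost report (input %dx%d)\n",
              x$input_size, x$input_size))
  cat(sprintf("  parameters: %s  (%.4f M)\n",
              format(x$params, big.mark = ","), x$params_millions))
  cat(sprintf("  FLOPs:      %.3f G  (2 x MACs, conv/dense layers)\n",
              x$flops_billions))
  invisible(x)
}

#' @export
format.dcsa_cost <- function(x, ...) {
  sprintf("%.4f M params, %.3f GFLOPs @ %d", x$params_millions,
          x$flops_billions, x$input_size)
}
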