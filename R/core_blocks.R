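# DCA building blocks: channel shuffle, asymmetric depthwise-separable
# convolution, the DCA-A (in-stage) and DCA-B (downsampling) inverted-residual
# blocks, squeeze-and-excitation channel attention, and analytic convolution
# cost accounting.
#
# The user-facing functions in this file operate on plain H x W x C arrays
# with freshly initialised (or supplied) weights and identity normalization,
# so each block can be exercised and tested in isolation; the network builder
# in network.R drives the same tape-level implementations.

# ---- channel shuffle --------------------------------------------------------

#' Channel shuffle permutation
#'
#' Computes the group-interleaving permutation used after grouped or split
#' convolutions: channels are reshaped to `groups x n`, transposed, and
#' flattened, so output channel `o * g + r` (0-based) is input channel
#' `r * n + o`, with `n = C / g`.
#'
#' @param channels total channel count.
#' @param groups number of groups `g`; must divide `channels`.
#' @return integer vector `p` of length `channels` such that shuffled channel
#'   `k` is input channel `p[k]` (1-based).
#' @export
shuffle_permutation <- function(channels, groups) {
  if (channels %% groups != 0) {
    stop("channels (", channels, ") not divisible by groups (", groups, ")")
  }
  n <- channels %/% groups
  p <- seq_len(channels) - 1L
  (p %% groups) * n + (p %/% groups) + 1L
}

#' Shuffle the channels of a feature map
#'
#' @param x feature map, an `H x W x C` array (or a matrix treated as columns
#'   of channels).
#' @param groups group count `g`; `C` must be divisible by `g`.
#' @return object of the same shape with channels permuted; pixel values
#'   within a channel are untouched.
#' @examples
#' x <- array(seq_len(2 * 2 * 6), c(2, 2, 6))
#' y <- channel_shuffle(x, 2) # channel order 1,4,2,5,3,6
#' @export
channel_shuffle <- function(x, groups) {
  if (is.matrix(x)) {
    return(x[, shuffle_permutation(ncol(x), groups), drop = FALSE])
  }
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x[, , shuffle_permutation(dim(x)[3], groups), drop = FALSE]
}

# ---- convolution cost accounting -------------------------------------------

#' Convolution cost description
#'
#' Shape bundle for analytic cost accounting: square-equivalent kernel length
#' `N`, input/output channels `C1`/`C2`, and output spatial size `H x W`.
#'
#' @param kernel_length odd kernel length `N`.
#' @param in_channels,out_channels channel counts `C1`, `C2`.
#' @param out_height,out_width output spatial size.
#' @return an object of class `conv_cost`.
#' @export
conv_cost <- function(kernel_length, in_channels, out_channels,
                      out_height, out_width) {
  v <- c(kernel_length, in_channels, out_channels, out_height, out_width)
  if (any(v < 1) || any(v != round(v))) {
    stop("all conv_cost fields must be positive integers")
  }
  if (kernel_length %% 2 == 0) stop("kernel_length must be odd")
  structure(list(N = kernel_length, C1 = in_channels, C2 = out_channels,
                 H = out_height, W = out_width),
            class = "conv_cost")
}

#' Analytic multiply-accumulate count of a convolution
#'
#' Evaluates the closed-form cost of a convolution over an output feature map
#' of size `H x W`:
#' standard `H*W*N^2*C1*C2`; depthwise-separable `H*W*N^2*C1 + H*W*C1*C2`
#' (per-channel spatial filter plus pointwise projection); asymmetric
#' `2*H*W*N*C1*C2` (consecutive `N x 1` and `1 x N` kernels, a `2/N` fraction
#' of the standard cost).
#'
#' Counts are multiply-accumulate operations; [model_summary()] reports FLOPs
#' as twice this quantity.
#'
#' @param cost a [conv_cost()] object.
#' @param kind one of `"standard"`, `"depthwise_separable"`, `"asymmetric"`.
#' @return the operation count (double).
#' @export
conv_flops <- function(cost, kind = c("standard", "depthwise_separable",
                                      "asymmetric")) {
  stopifnot(inherits(cost, "conv_cost"))
  kind <- match.arg(kind)
  px <- cost$H * cost$W
  switch(kind,
    standard = px * cost$N^2 * cost$C1 * cost$C2,
    depthwise_separable = px * cost$N^2 * cost$C1 + px * cost$C1 * cost$C2,
    asymmetric = 2 * px * cost$N * cost$C1 * cost$C2)
}

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution weights, biases, and
#' normalization affine terms) in a model, a block parameter list, or any
#' nested list of numeric arrays.
#'
#' @param object a `dcsanet` model, a parameter list from
#'   [dca_block_params()], or a nested list of numeric arrays.
#' @return total number of scalars (double).
#' @export
count_params <- function(object) {
  if (inherits(object, "dcsanet")) object <- object$params
  if (is.numeric(object)) return(length(object))
  if (!is.list(object)) stop("cannot count parameters of a ", class(object)[1])
  sum(vapply(object, count_params, numeric(1)))
}

# ---- weight initialisation --------------------------------------------------

he_mat <- function(nin, nout, fan) matrix(stats::rnorm(nin * nout, 0, sqrt(2 / fan)), nin, nout)

# Parameters for one asymmetric depthwise pair (N x 1 then 1 x N) on C channels.
asym_dw_params <- function(N, C) {
  list(v = he_mat(N, C, N), h = he_mat(N, C, N))
}

# ---- block configuration -----------------------------------------------------

#' Configuration of a DCA block
#'
#' DCA blocks are inverted-residual bottlenecks: a 1x1 convolution expands the
#' channels fourfold, the expanded map is split channelwise into two halves
#' that pass through asymmetric depthwise convolutions with different kernel
#' lengths (a small and a large receptive field), the halves are concatenated
#' and projected back by a 1x1 convolution. Mode `"A"` (stride 1) adds the
#' block input back elementwise; mode `"B"` (stride 2) instead concatenates
#' the projected map with a max-pooled copy of the input, halving the spatial
#' size and doubling the channel count. A channel shuffle mixes the branch
#' halves afterwards.
#'
#' @param in_channels input channel count `C`; `4 * C` must be even.
#' @param mode `"A"` (shape-preserving) or `"B"` (downsampling).
#' @param kernel_small,kernel_large odd kernel lengths of the two branches.
#' @param use_shuffle apply the channel shuffle at the block output.
#' @param use_attention apply squeeze-and-excitation channel attention to the
#'   projected map (mode `"A"` only).
#' @param expansion_factor channel expansion multiplier (4).
#' @return an object of class `dca_block_config`.
#' @export
dca_block_config <- function(in_channels, mode = c("A", "B"),
                             kernel_small = 3, kernel_large = 7,
                             use_shuffle = TRUE, use_attention = FALSE,
                             expansion_factor = 4) {
  mode <- match.arg(mode)
  if (in_channels < 1) stop("in_channels must be >= 1")
  if ((expansion_factor * in_channels) %% 2 != 0) {
    stop("expanded channel count must be even for the half/half split")
  }
  if (kernel_small %% 2 == 0 || kernel_large %% 2 == 0) {
    stop("branch kernel lengths must be odd")
  }
  structure(list(in_channels = as.integer(in_channels), mode = mode,
                 kernel_small = as.integer(kernel_small),
                 kernel_large = as.integer(kernel_large),
                 use_shuffle = isTRUE(use_shuffle),
                 use_attention = isTRUE(use_attention),
                 expansion_factor = as.integer(expansion_factor)),
            class = "dca_block_config")
}

#' Initialise the weights of one DCA block
#'
#' @param cfg a [dca_block_config()].
#' @param seed optional integer seed for reproducible initialisation.
#' @return named list of weight arrays (He-initialised convolutions, unit
#'   normalization gains, zero shifts).
#' @export
dca_block_params <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "dca_block_config"))
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old))
    set.seed(seed)
  }
  C <- cfg$in_channels
  E <- cfg$expansion_factor * C
  hc <- E %/% 2L
  p <- list(
    expand.w = he_mat(C, E, C),
    expand.bn.g = rep(1, E), expand.bn.b = rep(0, E),
    dw.small = asym_dw_params(cfg$kernel_small, hc),
    dw.large = asym_dw_params(cfg$kernel_large, hc),
    dw.bn.g = rep(1, E), dw.bn.b = rep(0, E),
    proj.w = he_mat(E, C, E),
    proj.bn.g = rep(1, C), proj.bn.b = rep(0, C)
  )
  if (cfg$use_attention && cfg$mode == "A") {
    r <- max(1L, C %/% 4L)
    p$se <- list(w1 = he_mat(C, r, C), b1 = rep(0, r),
                 w2 = he_mat(r, C, r), b2 = rep(0, C))
  }
  p
}

# ---- tape-level implementations ---------------------------------------------

# Asymmetric depthwise pair as a tape op; stride applies to the first (N x 1)
# convolution in both spatial directions, the second (1 x N) runs at stride 1.
tl_asym_dw <- function(tape, x, wv, wh, N, stride) {
  h <- nn_dwconv(tape, x, wv, kh = N, kw = 1L, stride = stride)
  nn_dwconv(tape, h, wh, kh = 1L, kw = N, stride = 1L)
}

# Squeeze-and-excitation gate on the projected map.
tl_se <- function(tape, x, w1, b1, w2, b2) {
  s <- nn_gap(tape, x)
  s <- nn_relu(tape, nn_dense(tape, s, w1, b1))
  g <- nn_sigmoid(tape, nn_dense(tape, s, w2, b2))
  nn_gate(tape, x, g)
}

# One DCA block on the tape. `P` is a function(name) -> param handle resolving
# names relative to the block; `stats`/`training` configure normalization.
tl_dca <- function(tape, x, cfg, P, stats, key, training) {
  C <- x$dim[4]
  stopifnot(C == cfg$in_channels)
  stride <- if (cfg$mode == "B") 2L else 1L
  if (cfg$mode == "B" && (x$dim[2] %% 2L != 0L || x$dim[3] %% 2L != 0L)) {
    stop("DCA-B requires even spatial dimensions, got ",
         x$dim[2], "x", x$dim[3])
  }
  E <- cfg$expansion_factor * C
  hc <- E %/% 2L

  e <- nn_conv(tape, x, P("expand.w"), 1L, 1L)
  e <- nn_bn(tape, e, P("expand.bn.g"), P("expand.bn.b"), stats,
             paste0(key, ".expand"), training)
  e <- nn_relu(tape, e)

  x1 <- nn_cols(tape, e, seq_len(hc))
  x2 <- nn_cols(tape, e, hc + seq_len(hc))
  h1 <- tl_asym_dw(tape, x1, P("dw.small.v"), P("dw.small.h"),
                   cfg$kernel_small, stride)
  h2 <- tl_asym_dw(tape, x2, P("dw.large.v"), P("dw.large.h"),
                   cfg$kernel_large, stride)
  hcat <- nn_concat(tape, list(h1, h2))
  hcat <- nn_bn(tape, hcat, P("dw.bn.g"), P("dw.bn.b"), stats,
                paste0(key, ".dw"), training)
  hcat <- nn_relu(tape, hcat)

  p <- nn_conv(tape, hcat, P("proj.w"), 1L, 1L)
  p <- nn_bn(tape, p, P("proj.bn.g"), P("proj.bn.b"), stats,
             paste0(key, ".proj"), training)

  if (cfg$mode == "A") {
    if (cfg$use_attention) {
      p <- tl_se(tape, p, P("se.w1"), P("se.b1"), P("se.w2"), P("se.b2"))
    }
    out <- nn_add(tape, p, x)
  } else {
    pooled <- nn_maxpool2(tape, x)
    out <- nn_concat(tape, list(p, pooled))
  }
  if (cfg$use_shuffle) {
    out <- nn_cols(tape, out, shuffle_permutation(out$dim[4], 2L))
  }
  out
}

# ---- standalone array-level wrappers ----------------------------------------

# Convert an H x W x C array to the internal (H*W) x C single-sample matrix.
fmap_from_array <- function(x) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  d <- dim(x)
  list(mat = matrix(x, d[1] * d[2], d[3]), dim = c(1L, d[1], d[2], d[3]))
}

fmap_to_array <- function(mat, dim) array(mat, c(dim[2], dim[3], dim[4]))

# Run a tape-level op on a plain array with supplied parameters (eval mode:
# identity normalization statistics).
run_standalone <- function(x, params, fn) {
  fm <- fmap_from_array(x)
  tape <- ag_tape()
  h <- ag_input(tape, fm$mat, fm$dim)
  P <- function(name) ag_param(tape, name, resolve_param(params, name))
  out <- fn(tape, h, P)
  fmap_to_array(ag_val(tape, out), out$dim)
}

# Resolve "a.b.c" against nested lists whose names may themselves contain dots.
resolve_param <- function(params, name) {
  if (!is.null(params[[name]])) return(params[[name]])
  parts <- strsplit(name, ".", fixed = TRUE)[[1]]
  for (split_at in rev(seq_len(length(parts) - 1L))) {
    head <- paste(parts[seq_len(split_at)], collapse = ".")
    rest <- paste(parts[-seq_len(split_at)], collapse = ".")
    if (!is.null(params[[head]])) {
      return(resolve_param(params[[head]], rest))
    }
  }
  stop("unknown parameter: ", name)
}

#' Asymmetric depthwise-separable convolution
#'
#' Applies a depthwise `N x 1` convolution followed by a depthwise `1 x N`
#' convolution (same padding). The spatial stride is applied once, on the
#' first convolution; channel count is preserved.
#'
#' @param x `H x W x C` array.
#' @param N odd kernel length.
#' @param stride 1 or 2.
#' @param weights optional list with `v` and `h`, each an `N x C` matrix of
#'   per-channel taps; freshly initialised when omitted.
#' @return `H/stride x W/stride x C` array.
#' @export
asymmetric_dw_conv <- function(x, N, stride = 1L, weights = NULL) {
  if (N %% 2 == 0) stop("kernel length N must be odd")
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2")
  C <- dim(x)[3]
  if (is.null(weights)) weights <- asym_dw_params(N, C)
  run_standalone(x, weights, function(tape, h, P) {
    tl_asym_dw(tape, h, P("v"), P("h"), as.integer(N), as.integer(stride))
  })
}

#' Apply one DCA block to a feature map
#'
#' `dca_a_block()` preserves the input shape (in-stage feature extraction);
#' `dca_b_block()` halves the spatial size and doubles the channel count
#' (downsampling). See [dca_block_config()] for the internal structure.
#' Normalization runs in inference mode with identity statistics, so with
#' all-zero convolution weights `dca_a_block()` reduces to a channel shuffle
#' of its input.
#'
#' @param x `H x W x C` array with `C == cfg$in_channels`.
#' @param cfg a [dca_block_config()] with the matching mode.
#' @param params optional [dca_block_params()] list; freshly initialised when
#'   omitted.
#' @return the transformed feature map array.
#' @export
dca_a_block <- function(x, cfg, params = NULL) {
  stopifnot(inherits(cfg, "dca_block_config"))
  if (cfg$mode != "A") stop("cfg$mode must be \"A\" for dca_a_block()")
  if (is.null(params)) params <- dca_block_params(cfg)
  run_standalone(x, params, function(tape, h, P) {
    tl_dca(tape, h, cfg, P, new.env(parent = emptyenv()), "blk", FALSE)
  })
}

#' @rdname dca_a_block
#' @export
dca_b_block <- function(x, cfg, params = NULL) {
  stopifnot(inherits(cfg, "dca_block_config"))
  if (cfg$mode != "B") stop("cfg$mode must be \"B\" for dca_b_block()")
  if (is.null(params)) params <- dca_block_params(cfg)
  run_standalone(x, params, function(tape, h, P) {
    tl_dca(tape, h, cfg, P, new.env(parent = emptyenv()), "blk", FALSE)
  })
}

#' Squeeze-and-excitation channel attention
#'
#' Rescales every channel by a gate in `[0, 1]` computed from the globally
#' average-pooled channel statistics through a two-layer bottleneck
#' (`C -> C/reduction -> C`) with a sigmoid output.
#'
#' @param x `H x W x C` array.
#' @param reduction bottleneck divisor; must not exceed `C` and must divide it.
#' @param weights optional list `w1` (`C x C/r`), `b1`, `w2` (`C/r x C`), `b2`.
#' @return array of the same shape.
#' @export
channel_attention <- function(x, reduction = 4L, weights = NULL) {
  C <- dim(x)[3]
  if (reduction > C) stop("reduction (", reduction, ") exceeds channels (", C, ")")
  if (C %% reduction != 0) stop("channels not divisible by reduction")
  r <- C %/% reduction
  if (is.null(weights)) {
    weights <- list(w1 = he_mat(C, r, C), b1 = rep(0, r),
                    w2 = he_mat(r, C, r), b2 = rep(0, C))
  }
  run_standalone(x, weights, function(tape, h, P) {
    tl_se(tape, h, P("w1"), P("b1"), P("w2"), P("b2"))
  })
}

# ---- RNG helpers -------------------------------------------------------------

get_rng_state <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Evaluate an expression under a temporary seed without disturbing the
# caller's RNG state (the promise is forced after set.seed, in the caller's
# frame).
with_seed <- function(seed, code) {
  old <- get_rng_state()
  on.exit(set_rng_state(old))
  set.seed(seed)
  code
}
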