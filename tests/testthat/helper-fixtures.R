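# Shared fixtures: tiny models and synthetic inputs built in code.

tiny_config <- function(variant = "feat3_guided_residual") {
  dcsa_config(stem_channels = 2L, decoder_widths = c(8L, 8L, 8L, 8L, 8L),
              decoder_variant = variant)
}

tiny_model_cache <- new.env(parent = emptyenv())

tiny_model <- function(variant = "feat3_guided_residual", seed = 2L) {
  key <- paste(variant, seed)
  if (is.null(tiny_model_cache[[key]])) {
    tiny_model_cache[[key]] <- dcsanet(tiny_config(variant), seed = seed)
  }
  tiny_model_cache[[key]]
}

random_fmap <- function(h, w, c, seed = 1L) {
  set.seed(seed)
  array(stats::rnorm(h * w * c), c(h, w, c))
}

# Random image/mask pair (synthetic input for pipeline tests).
random_sample <- function(size = 32L, seed = 1L, n_classes = 4L) {
  set.seed(seed)
  seg_sample(array(round(stats::runif(size * size * 3) * 255) / 255,
                   c(size, size, 3L)),
             matrix(sample(0:(n_classes - 1L), size * size, replace = TRUE),
                    size, size))
}

# Brute-force channel shuffle oracle: reshape the channel indices row-major to
# (g, n), transpose, flatten row-major. In column-major R, the row-major
# flatten of t(M) is the column-major flatten of M.
shuffle_oracle <- function(channels, groups) {
  m <- matrix(seq_len(channels), nrow = groups, byrow = TRUE)
  as.vector(m)
}

# Enumeration oracles for convolution costs: count every multiply performed
# by a naive loop implementation.
count_macs_standard <- function(H, W, N, C1, C2) {
  macs <- 0
  for (y in seq_len(H)) for (x in seq_len(W)) for (co in seq_len(C2)) {
    macs <- macs + N * N * C1
  }
  macs
}

count_macs_dw_separable <- function(H, W, N, C1, C2) {
  macs <- 0
  for (y in seq_len(H)) for (x in seq_len(W)) {
    macs <- macs + N * N * C1  # depthwise: one N x N filter per channel
    macs <- macs + C1 * C2     # pointwise 1x1
  }
  macs
}

count_macs_asymmetric <- function(H, W, N, C1, C2) {
  macs <- 0
  for (y in seq_len(H)) for (x in seq_len(W)) for (co in seq_len(C2)) {
    macs <- macs + N * C1  # N x 1 pass
    macs <- macs + N * C1  # 1 x N pass
  }
  macs
}
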