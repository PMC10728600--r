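# Channel shuffle, asymmetric depthwise convolution, DCA blocks, channel
# attention, and analytic cost accounting.

test_that("channel shuffle matches the reshape/transpose/flatten oracle", {
  # trivial cases: one group, and one channel per group
  expect_equal(shuffle_permutation(6, 1), 1:6)
  expect_equal(shuffle_permutation(6, 6), 1:6)
  # g = 2 over 6 channels interleaves the halves: c0,c3,c1,c4,c2,c5 (0-based)
  expect_equal(shuffle_permutation(6, 2), c(1L, 4L, 2L, 5L, 3L, 6L))
  set.seed(41)
  for (i in 1:25) {
    g <- sample(1:8, 1)
    C <- g * sample(1:8, 1)
    expect_identical(shuffle_permutation(C, g), shuffle_oracle(C, g))
  }
})

test_that("channel shuffle is a permutation and self-inverts with g then n", {
  set.seed(7)
  for (i in 1:10) {
    g <- sample(2:6, 1)
    C <- g * sample(2:6, 1)
    x <- random_fmap(4, 5, C, seed = i)
    y <- channel_shuffle(x, g)
    expect_identical(sort(shuffle_permutation(C, g)), 1:C)
    # values within a channel untouched
    expect_equal(y[, , 1], x[, , shuffle_permutation(C, g)[1]])
    # applying the shuffle with n = C/g channels per group restores the input
    expect_identical(channel_shuffle(y, C %/% g), x)
  }
  expect_error(channel_shuffle(random_fmap(2, 2, 6), 4), "divisible")
})

test_that("asymmetric depthwise conv keeps channels and scales space by stride", {
  x <- random_fmap(16, 16, 5, seed = 3)
  expect_equal(dim(asymmetric_dw_conv(x, N = 7, stride = 1)), c(16, 16, 5))
  expect_equal(dim(asymmetric_dw_conv(x, N = 7, stride = 2)), c(8, 8, 5))
  expect_error(asymmetric_dw_conv(x, N = 4), "odd")
  expect_error(asymmetric_dw_conv(x, N = 3, stride = 3), "stride")
})

test_that("asymmetric pair halves the weight count of a square depthwise kernel", {
  # N = 7, C = 32: the pair holds C*(N + N) weights against C*N^2 square ones
  C <- 32L
  N <- 7L
  w <- list(v = matrix(0, N, C), h = matrix(0, N, C))
  expect_equal(count_params(w), C * (N + N))
  square <- matrix(0, N * N, C)
  expect_equal(count_params(list(square)), C * N^2)
})

test_that("DCA-A preserves shape and reduces to a shuffle with zero weights", {
  for (C in c(4L, 6L)) {
    cfg <- dca_block_config(C, "A")
    x <- random_fmap(8, 10, C, seed = C)
    expect_equal(dim(dca_a_block(x, cfg)), dim(x))
  }
  # all conv weights zero + identity normalization: out = shuffle(x + 0)
  cfg <- dca_block_config(6L, "A")
  p <- dca_block_params(cfg, seed = 1)
  p$expand.w[] <- 0
  p$dw.small$v[] <- 0; p$dw.small$h[] <- 0
  p$dw.large$v[] <- 0; p$dw.large$h[] <- 0
  p$proj.w[] <- 0
  x <- random_fmap(6, 6, 6, seed = 9)
  expect_equal(dca_a_block(x, cfg, p), channel_shuffle(x, 2), tolerance = 1e-12)
  # with the shuffle disabled the residual sum keeps the input channel order
  cfg2 <- dca_block_config(6L, "A", use_shuffle = FALSE)
  expect_equal(dca_a_block(x, cfg2, p), x, tolerance = 1e-12)
  expect_error(dca_a_block(x, dca_block_config(6L, "B")), "mode")
})

test_that("DCA-B halves space, doubles channels, and pools constants", {
  cases <- list(c(16L, 16L, 8L), c(32L, 32L, 4L), c(12L, 20L, 6L))
  for (d in cases) {
    cfg <- dca_block_config(d[3], "B")
    x <- random_fmap(d[1], d[2], d[3], seed = d[1])
    y <- dca_b_block(x, cfg)
    expect_equal(dim(y), c(d[1] %/% 2L, d[2] %/% 2L, 2L * d[3]))
  }
  # odd spatial size is an error, not silent padding
  cfg <- dca_block_config(4L, "B")
  expect_error(dca_b_block(random_fmap(9, 8, 4), cfg), "even spatial")
  # pooled branch of an all-constant input is all-constant at half resolution
  p <- dca_block_params(cfg, seed = 2)
  xc <- array(0.7, c(8, 8, 4))
  y <- dca_b_block(xc, cfg, p)
  pooled_channels <- which(apply(y, 3, function(ch) all(abs(ch - 0.7) < 1e-12)))
  expect_length(pooled_channels, 4L) # the 4 max-pooled input channels survive
})

test_that("DCA blocks are deterministic at inference", {
  cfg <- dca_block_config(4L, "A")
  p <- dca_block_params(cfg, seed = 5)
  x <- random_fmap(8, 8, 4, seed = 5)
  expect_identical(dca_a_block(x, cfg, p), dca_a_block(x, cfg, p))
})

test_that("channel attention gates channels between identity and zero", {
  x <- random_fmap(6, 6, 8, seed = 4)
  r <- 2L
  w <- list(w1 = matrix(0, 8, 8 %/% r), b1 = rep(0, 8 %/% r),
            w2 = matrix(0, 8 %/% r, 8), b2 = rep(100, 8))
  expect_equal(channel_attention(x, r, w), x, tolerance = 1e-12) # gate = 1
  w$b2 <- rep(-100, 8)
  expect_equal(max(abs(channel_attention(x, r, w))), 0) # gate = 0
  # an all-zero channel has zero pooled statistic, so it stays zero
  x[, , 1] <- 0
  y <- channel_attention(x, r)
  expect_equal(max(abs(y[, , 1])), 0)
  expect_error(channel_attention(x, reduction = 16), "exceeds")
})

test_that("conv cost formulas match the printed closed forms", {
  cc <- conv_cost(3, 8, 16, 16, 16)
  expect_equal(conv_flops(cc, "standard"), 294912)
  # depthwise-separable / standard = 1/C2 + 1/N^2
  expect_equal(conv_flops(cc, "depthwise_separable") / conv_flops(cc, "standard"),
               1 / 16 + 1 / 9)
  # asymmetric / standard = 2/N
  cc7 <- conv_cost(7, 8, 16, 16, 16)
  expect_equal(conv_flops(cc7, "asymmetric") / conv_flops(cc7, "standard"),
               2 / 7)
  expect_error(conv_flops(cc, "winograd"))
  expect_error(conv_cost(4, 8, 16, 16, 16), "odd")
  expect_error(conv_cost(3, 0, 16, 16, 16), "positive")
})

test_that("conv cost formulas agree with the naive enumeration oracle", {
  set.seed(13)
  for (i in 1:8) {
    H <- sample(1:4, 1); W <- sample(1:4, 1)
    N <- sample(c(1, 3), 1)
    C1 <- sample(1:3, 1); C2 <- sample(1:4, 1)
    cc <- conv_cost(N, C1, C2, H, W)
    expect_equal(conv_flops(cc, "standard"),
                 count_macs_standard(H, W, N, C1, C2))
    expect_equal(conv_flops(cc, "depthwise_separable"),
                 count_macs_dw_separable(H, W, N, C1, C2))
    expect_equal(conv_flops(cc, "asymmetric"),
                 count_macs_asymmetric(H, W, N, C1, C2))
  }
})

test_that("standard/depthwise ratio identity holds for random costs", {
  set.seed(23)
  for (i in 1:20) {
    cc <- conv_cost(sample(c(3, 5, 7, 9), 1), sample(1:64, 1),
                    sample(1:64, 1), sample(1:32, 1), sample(1:32, 1))
    expect_equal(conv_flops(cc, "standard") /
                   conv_flops(cc, "depthwise_separable"),
                 1 / (1 / cc$C2 + 1 / cc$N^2))
  }
})

test_that("count_params matches closed forms and block enumeration", {
  # single 3x3 conv, 3 -> 16 channels, with bias
  expect_equal(count_params(list(w = matrix(0, 27, 16), b = rep(0, 16))), 448)
  # depthwise 7x1, 32 channels, no bias
  expect_equal(count_params(list(matrix(0, 7, 32))), 224)
  # DCA block: closed form 8C^2 + 4CN + 12C kernel-small + BN terms
  for (C in c(4L, 8L)) {
    for (N in c(5L, 7L, 9L)) {
      cfg <- dca_block_config(C, "A", kernel_large = N)
      expected <- 4 * C^2 + 8 * C +              # expand + its BN
        2 * C * 2 * 3 + 2 * C * 2 * N + 8 * C +  # dw pairs + BN
        4 * C^2 + 2 * C                           # project + its BN
      expect_equal(count_params(dca_block_params(cfg)), expected)
    }
  }
  # attention adds the SE bottleneck: C^2/2 + 5C/4
  C <- 8L
  base <- count_params(dca_block_params(dca_block_config(C, "A")))
  attn <- count_params(dca_block_params(dca_block_config(C, "A",
                                                         use_attention = TRUE)))
  expect_equal(attn - base, C^2 / 2 + 5 * C / 4)
})
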