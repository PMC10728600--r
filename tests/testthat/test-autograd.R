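# Gradient correctness of the tensor ops against central finite differences.

fd_check <- function(build, params, h = 1e-5, tol = 1e-4) {
  # build(params) must return a scalar loss and its gradients
  r <- build(params)
  for (nm in names(params)) {
    g <- r$grads[[nm]]
    expect_false(is.null(g), label = paste("gradient for", nm))
    for (i in sample(length(params[[nm]]), min(3, length(params[[nm]])))) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + h
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - h
      num <- (build(up)$loss - build(dn)$loss) / (2 * h)
      expect_equal(unname(g[i]), num, tolerance = tol,
                   label = paste0("d loss / d ", nm, "[", i, "]"))
    }
  }
}

# Loss wrapper: sum(out * probe) gives a generic scalar objective.
op_loss <- function(fn, x_dim, params, probe_seed = 99, input_seed = 42) {
  set.seed(input_seed)
  X <- matrix(rnorm(prod(x_dim[1:3]) * x_dim[4]), prod(x_dim[1:3]), x_dim[4])
  function(p) {
    tape <- dcsanet:::ag_tape()
    hx <- dcsanet:::ag_input(tape, X, x_dim)
    hp <- lapply(names(p), function(nm) dcsanet:::ag_param(tape, nm, p[[nm]]))
    names(hp) <- names(p)
    out <- fn(tape, hx, hp)
    set.seed(probe_seed)
    probe <- matrix(rnorm(length(dcsanet:::ag_val(tape, out))),
                    nrow(dcsanet:::ag_val(tape, out)))
    v <- dcsanet:::ag_val(tape, out)
    loss_node <- dcsanet:::ag_node(tape, sum(v * probe), NULL, out$id,
                                   function(g) list(g * probe))
    loss <- dcsanet:::ag_val(tape, loss_node)
    grads <- dcsanet:::ag_backward(tape, loss_node)
    list(loss = loss, grads = grads)
  }
}

test_that("standard convolution gradients match finite differences", {
  set.seed(1)
  for (stride in c(1L, 2L)) {
    p <- list(w = matrix(rnorm(9 * 3 * 4, 0, 0.5), 27, 4))
    fd_check(op_loss(function(tape, x, hp) {
      dcsanet:::nn_conv(tape, x, hp$w, 3L, 3L, stride = stride)
    }, c(2L, 6L, 6L, 3L), p), p)
  }
})

test_that("depthwise convolution gradients match finite differences", {
  set.seed(2)
  for (stride in c(1L, 2L)) {
    p <- list(w = matrix(rnorm(5 * 3, 0, 0.5), 5, 3))
    fd_check(op_loss(function(tape, x, hp) {
      dcsanet:::nn_dwconv(tape, x, hp$w, 5L, 1L, stride = stride)
    }, c(1L, 6L, 6L, 3L), p), p)
  }
})

test_that("batchnorm gradients match finite differences in training mode", {
  set.seed(3)
  p <- list(g = runif(3, 0.5, 1.5), b = rnorm(3))
  fd_check(op_loss(function(tape, x, hp) {
    dcsanet:::nn_bn(tape, x, hp$g, hp$b, new.env(), "k", TRUE)
  }, c(2L, 4L, 4L, 3L), p), p, tol = 1e-3)
})

test_that("dense + sigmoid + gate gradients match finite differences", {
  set.seed(4)
  p <- list(w1 = matrix(rnorm(3 * 2, 0, 0.5), 3, 2), b1 = rnorm(2),
            w2 = matrix(rnorm(2 * 3, 0, 0.5), 2, 3), b2 = rnorm(3))
  fd_check(op_loss(function(tape, x, hp) {
    dcsanet:::tl_se(tape, x, hp$w1, hp$b1, hp$w2, hp$b2)
  }, c(2L, 3L, 3L, 3L), p), p)
})

test_that("softmax cross-entropy gradient matches finite differences", {
  set.seed(5)
  labels <- sample(0:2, 8, replace = TRUE)
  p <- list(w = matrix(rnorm(2 * 3, 0, 0.5), 2, 3))
  X <- matrix(rnorm(16), 8, 2)
  build <- function(pp) {
    tape <- dcsanet:::ag_tape()
    hx <- dcsanet:::ag_input(tape, X, c(1L, 2L, 4L, 2L))
    hw <- dcsanet:::ag_param(tape, "w", pp$w)
    lg <- dcsanet:::nn_conv(tape, hx, hw, 1L, 1L)
    l <- dcsanet:::nn_softmax_ce(tape, lg, labels)
    list(loss = dcsanet:::ag_val(tape, l),
         grads = dcsanet:::ag_backward(tape, l))
  }
  fd_check(build, p)
})

test_that("maxpool routes gradient to the maximum entry only", {
  X <- matrix(c(1, 4, 2, 3), 4, 1) # one 2x2 plane, max is 4 at (2,1)
  tape <- dcsanet:::ag_tape()
  hx <- dcsanet:::ag_input(tape, X, c(1L, 2L, 2L, 1L))
  y <- dcsanet:::nn_maxpool2(tape, hx)
  expect_equal(dcsanet:::ag_val(tape, y), matrix(4, 1, 1))
  l <- dcsanet:::ag_node(tape, sum(dcsanet:::ag_val(tape, y)), NULL, y$id,
                         function(g) list(matrix(g, 1, 1)))
  grads <- dcsanet:::ag_backward(tape, l)
  # route check through an input parameter is covered below; check the
  # backward wiring by differentiating the pooled value w.r.t. the input
  tape2 <- dcsanet:::ag_tape()
  hp <- dcsanet:::ag_param(tape2, "x", X)
  hp$dim <- c(1L, 2L, 2L, 1L)
  y2 <- dcsanet:::nn_maxpool2(tape2, hp)
  l2 <- dcsanet:::ag_node(tape2, sum(dcsanet:::ag_val(tape2, y2)), NULL,
                          y2$id, function(g) list(matrix(g, 1, 1)))
  g <- dcsanet:::ag_backward(tape2, l2)$x
  expect_equal(as.vector(g), c(0, 1, 0, 0))
})

test_that("bilinear upsampling is a partition of unity and differentiable", {
  U <- dcsanet:::bilinear_op(3, 4, 2)
  expect_equal(as.vector(Matrix::rowSums(U)), rep(1, 6 * 8))
  # constant fields stay constant under upsampling
  x <- random_fmap(4, 4, 2, seed = 8)
  x[, , 1] <- 0.37
  tape <- dcsanet:::ag_tape()
  fm <- dcsanet:::fmap_from_array(x)
  h <- dcsanet:::ag_input(tape, fm$mat, fm$dim)
  y <- dcsanet:::nn_upsample(tape, h, 2L)
  Y <- dcsanet:::ag_val(tape, y)
  expect_equal(max(abs(Y[, 1] - 0.37)), 0, tolerance = 1e-12)
  expect_equal(y$dim, c(1L, 8L, 8L, 2L))
})

test_that("whole-network gradients flow to every parameter", {
  # input large enough that feat3 is 2x2: batchnorm over a single pixel is
  # degenerate (constant output) and would legitimately zero deep gradients
  m <- tiny_model()
  set.seed(10)
  img <- array(runif(64 * 64 * 3), c(64, 64, 3))
  labels <- sample(0:3, 64 * 64, replace = TRUE)
  st <- dcsanet:::stack_images(list(img))
  tape <- dcsanet:::ag_tape()
  lg <- dcsanet:::fw_dcsanet(m, tape, st$X, st$dim, training = TRUE)
  l <- dcsanet:::nn_softmax_ce(tape, lg, labels)
  grads <- dcsanet:::ag_backward(tape, l)
  expect_setequal(names(grads), names(m$params))
  for (nm in names(grads)) {
    expect_false(is.null(grads[[nm]]), label = paste("grad of", nm))
    expect_true(any(grads[[nm]] != 0), label = paste("nonzero grad of", nm))
  }
})
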