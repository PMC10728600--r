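# Differentiable tensor operations used by the DCA blocks and the decoder.
# All ops take and return tape handles (see autograd.R). Convolutions are
# computed as per-tap gathers followed by GEMM (standard convs) or broadcast
# products (depthwise convs); the gather index tables and the sparse bilinear
# interpolation operators are cached per shape.

.op_cache <- new.env(parent = emptyenv())

cache_get <- function(key, make) {
  v <- .op_cache[[key]]
  if (is.null(v)) {
    v <- make()
    assign(key, v, envir = .op_cache)
  }
  v
}

# Index table for a kh x kw window, stride s, explicit zero padding (ph, pw).
# Returns list(ix = (B*Ho*Wo) x (kh*kw) integer matrix, 0 marks a padded tap,
# Ho, Wo). Tap order is row offset fastest, matching the weight layout.
conv_taps <- function(B, H, W, kh, kw, stride, ph, pw) {
  key <- paste("tap", B, H, W, kh, kw, stride, ph, pw, sep = ":")
  cache_get(key, function() {
    Ho <- (H + 2L * ph - kh) %/% stride + 1L
    Wo <- (W + 2L * pw - kw) %/% stride + 1L
    ix <- matrix(0L, B * Ho * Wo, kh * kw)
    boff <- (seq_len(B) - 1L) * H * W
    t <- 0L
    for (tw in seq_len(kw)) {
      ws <- stride * (seq_len(Wo) - 1L) + tw - pw
      wok <- ws >= 1L & ws <= W
      for (th in seq_len(kh)) {
        t <- t + 1L
        hs <- stride * (seq_len(Ho) - 1L) + th - ph
        hok <- hs >= 1L & hs <= H
        hw <- outer(ifelse(hok, hs, NA_integer_),
                    ifelse(wok, (ws - 1L) * H, NA_integer_), `+`)
        full <- as.vector(outer(as.vector(hw), boff, `+`))
        full[is.na(full)] <- 0L
        ix[, t] <- as.integer(full)
      }
    }
    list(ix = ix, Ho = Ho, Wo = Wo)
  })
}

pad_rows <- function(X) rbind(matrix(0, 1L, ncol(X)), X)

# Standard convolution. W is a ((kh*kw)*Cin) x Cout matrix, tap-major rows.
nn_conv <- function(tape, x, w, kh, kw, stride = 1L,
                    ph = (kh - 1L) %/% 2L, pw = (kw - 1L) %/% 2L) {
  d <- x$dim
  X <- ag_val(tape, x)
  Wm <- ag_val(tape, w)
  cin <- d[4]
  cout <- ncol(Wm)
  if (kh == 1L && kw == 1L && stride == 1L) {
    Y <- X %*% Wm
    bw <- function(g) list(g %*% t(Wm), crossprod(X, g))
    return(ag_node(tape, Y, c(d[1], d[2], d[3], cout), c(x$id, w$id), bw))
  }
  tp <- conv_taps(d[1], d[2], d[3], kh, kw, stride, ph, pw)
  nt <- kh * kw
  Xp <- pad_rows(X)
  Y <- matrix(0, nrow(tp$ix), cout)
  for (t in seq_len(nt)) {
    rows <- ((t - 1L) * cin + 1L):(t * cin)
    Y <- Y + Xp[tp$ix[, t] + 1L, , drop = FALSE] %*% Wm[rows, , drop = FALSE]
  }
  bw <- function(g) {
    dW <- matrix(0, nt * cin, cout)
    dXp <- matrix(0, nrow(Xp), cin)
    for (t in seq_len(nt)) {
      rows <- ((t - 1L) * cin + 1L):(t * cin)
      ixt <- tp$ix[, t] + 1L
      G <- Xp[ixt, , drop = FALSE]
      dW[rows, ] <- crossprod(G, g)
      D <- g %*% t(Wm[rows, , drop = FALSE])
      dXp[ixt, ] <- dXp[ixt, ] + D # duplicate writes only hit the pad row
    }
    list(dXp[-1L, , drop = FALSE], dW)
  }
  ag_node(tape, Y, c(d[1], tp$Ho, tp$Wo, cout), c(x$id, w$id), bw)
}

# Depthwise convolution. W is a (kh*kw) x C matrix of per-channel taps.
nn_dwconv <- function(tape, x, w, kh, kw, stride = 1L,
                      ph = (kh - 1L) %/% 2L, pw = (kw - 1L) %/% 2L) {
  d <- x$dim
  X <- ag_val(tape, x)
  Wm <- ag_val(tape, w)
  C <- d[4]
  tp <- conv_taps(d[1], d[2], d[3], kh, kw, stride, ph, pw)
  nt <- kh * kw
  n <- nrow(tp$ix)
  Xp <- pad_rows(X)
  Y <- matrix(0, n, C)
  for (t in seq_len(nt)) {
    Y <- Y + Xp[tp$ix[, t] + 1L, , drop = FALSE] * rep(Wm[t, ], each = n)
  }
  bw <- function(g) {
    dW <- matrix(0, nt, C)
    dXp <- matrix(0, nrow(Xp), C)
    for (t in seq_len(nt)) {
      ixt <- tp$ix[, t] + 1L
      G <- Xp[ixt, , drop = FALSE]
      dW[t, ] <- colSums(G * g)
      D <- g * rep(Wm[t, ], each = n)
      dXp[ixt, ] <- dXp[ixt, ] + D
    }
    list(dXp[-1L, , drop = FALSE], dW)
  }
  ag_node(tape, Y, c(d[1], tp$Ho, tp$Wo, C), c(x$id, w$id), bw)
}

# Batch normalization over all pixels of the batch, per channel. `stats` is an
# environment holding running moments under `key`; `training` selects batch
# statistics (and updates the running ones) versus the stored moments.
nn_bn <- function(tape, x, gamma, beta, stats, key, training,
                  momentum = 0.1, eps = 1e-5) {
  X <- ag_val(tape, x)
  ga <- ag_val(tape, gamma)
  be <- ag_val(tape, beta)
  n <- nrow(X)
  if (training) {
    m <- colMeans(X)
    xc <- X - rep(m, each = n)
    v <- colMeans(xc * xc)
    s <- stats[[key]]
    if (is.null(s)) s <- list(mean = m * 0, var = m * 0 + 1)
    stats[[key]] <- list(mean = (1 - momentum) * s$mean + momentum * m,
                         var  = (1 - momentum) * s$var  + momentum * v)
  } else {
    s <- stats[[key]]
    if (is.null(s)) s <- list(mean = numeric(ncol(X)), var = rep(1, ncol(X)))
    m <- s$mean
    v <- s$var
    xc <- X - rep(m, each = n)
  }
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * rep(inv, each = n)
  Y <- xhat * rep(ga, each = n) + rep(be, each = n)
  bw <- function(g) {
    dbe <- colSums(g)
    dga <- colSums(g * xhat)
    dxh <- g * rep(ga, each = n)
    if (training) {
      dX <- rep(inv, each = n) *
        (dxh - rep(colMeans(dxh), each = n) -
           xhat * rep(colMeans(dxh * xhat), each = n))
    } else {
      dX <- dxh * rep(inv, each = n)
    }
    list(dX, dga, dbe)
  }
  ag_node(tape, Y, x$dim, c(x$id, gamma$id, beta$id), bw)
}

nn_relu <- function(tape, x) {
  X <- ag_val(tape, x)
  M <- X > 0
  ag_node(tape, X * M, x$dim, x$id, function(g) list(g * M))
}

nn_sigmoid <- function(tape, x) {
  Y <- 1 / (1 + exp(-ag_val(tape, x)))
  ag_node(tape, Y, x$dim, x$id, function(g) list(g * Y * (1 - Y)))
}

nn_add <- function(tape, a, b) {
  ag_node(tape, ag_val(tape, a) + ag_val(tape, b), a$dim, c(a$id, b$id),
          function(g) list(g, g))
}

nn_mul <- function(tape, a, b) {
  A <- ag_val(tape, a)
  B <- ag_val(tape, b)
  ag_node(tape, A * B, a$dim, c(a$id, b$id), function(g) list(g * B, g * A))
}

# Channel concatenation.
nn_concat <- function(tape, xs) {
  vals <- lapply(xs, function(h) ag_val(tape, h))
  ncols <- vapply(vals, ncol, 1L)
  d <- xs[[1]]$dim
  bw <- function(g) {
    out <- vector("list", length(xs))
    at <- 0L
    for (k in seq_along(xs)) {
      out[[k]] <- g[, (at + 1L):(at + ncols[k]), drop = FALSE]
      at <- at + ncols[k]
    }
    out
  }
  ag_node(tape, do.call(cbind, vals), c(d[1], d[2], d[3], sum(ncols)),
          vapply(xs, function(h) h$id, 1L), bw)
}

# Column (channel) selection; idx must have no duplicates.
nn_cols <- function(tape, x, idx) {
  X <- ag_val(tape, x)
  d <- x$dim
  bw <- function(g) {
    dX <- matrix(0, nrow(X), ncol(X))
    dX[, idx] <- g
    list(dX)
  }
  ag_node(tape, X[, idx, drop = FALSE], c(d[1], d[2], d[3], length(idx)),
          x$id, bw)
}

# 2x2 max pooling, stride 2 (even spatial dims required by callers).
nn_maxpool2 <- function(tape, x) {
  d <- x$dim
  X <- ag_val(tape, x)
  tp <- conv_taps(d[1], d[2], d[3], 2L, 2L, 2L, 0L, 0L)
  Xp <- pad_rows(X)
  G <- lapply(1:4, function(t) Xp[tp$ix[, t] + 1L, , drop = FALSE])
  Y <- pmax(G[[1]], G[[2]], G[[3]], G[[4]])
  bw <- function(g) {
    dXp <- matrix(0, nrow(Xp), ncol(X))
    claimed <- matrix(FALSE, nrow(Y), ncol(Y))
    for (t in 1:4) {
      m <- (G[[t]] == Y) & !claimed
      claimed <- claimed | m
      ixt <- tp$ix[, t] + 1L
      dXp[ixt, ] <- dXp[ixt, ] + g * m
    }
    list(dXp[-1L, , drop = FALSE])
  }
  ag_node(tape, Y, c(d[1], tp$Ho, tp$Wo, ncol(X)), x$id, bw)
}

# Sparse operator for bilinear x`f` upsampling of one H x W image plane
# (half-pixel center alignment, edge clamped).
bilinear_op <- function(H, W, f) {
  axis <- function(n, no) {
    s <- (seq_len(no) - 0.5) / f - 0.5
    i0 <- floor(s)
    tfr <- s - i0
    i0c <- pmin(pmax(i0, 0), n - 1)
    i1c <- pmin(pmax(i0 + 1, 0), n - 1)
    list(i0 = i0c + 1, i1 = i1c + 1, w1 = 1 - tfr, w2 = tfr)
  }
  ay <- axis(H, H * f)
  ax <- axis(W, W * f)
  Ho <- H * f
  Wo <- W * f
  rows <- rep(seq_len(Ho * Wo), 4L)
  ry <- rep(seq_len(Ho), Wo)
  rx <- rep(seq_len(Wo), each = Ho)
  cix <- function(iy, ix) iy[ry] + (ix[rx] - 1) * H
  cols <- c(cix(ay$i0, ax$i0), cix(ay$i1, ax$i0),
            cix(ay$i0, ax$i1), cix(ay$i1, ax$i1))
  wts <- c(ay$w1[ry] * ax$w1[rx], ay$w2[ry] * ax$w1[rx],
           ay$w1[ry] * ax$w2[rx], ay$w2[ry] * ax$w2[rx])
  Matrix::sparseMatrix(i = rows, j = cols, x = wts, dims = c(Ho * Wo, H * W))
}

nn_upsample <- function(tape, x, f) {
  d <- x$dim
  key <- paste("bil", d[1], d[2], d[3], f, sep = ":")
  U <- cache_get(key, function() {
    U1 <- bilinear_op(d[2], d[3], f)
    if (d[1] == 1L) U1 else Matrix::bdiag(rep(list(U1), d[1]))
  })
  Y <- as.matrix(U %*% ag_val(tape, x))
  bw <- function(g) list(as.matrix(Matrix::crossprod(U, g)))
  ag_node(tape, Y, c(d[1], d[2] * f, d[3] * f, d[4]), x$id, bw)
}

# Global average pooling to a B x C matrix.
nn_gap <- function(tape, x) {
  d <- x$dim
  grp <- rep(seq_len(d[1]), each = d[2] * d[3])
  Y <- rowsum(ag_val(tape, x), grp) / (d[2] * d[3])
  bw <- function(g) list(g[grp, , drop = FALSE] / (d[2] * d[3]))
  ag_node(tape, Y, NULL, x$id, bw)
}

# Per-sample channel gate: multiply feature map x by gate (B x C).
nn_gate <- function(tape, x, gate) {
  d <- x$dim
  grp <- rep(seq_len(d[1]), each = d[2] * d[3])
  X <- ag_val(tape, x)
  G <- ag_val(tape, gate)
  Y <- X * G[grp, , drop = FALSE]
  bw <- function(g) list(g * G[grp, , drop = FALSE],
                         rowsum(g * X, grp))
  ag_node(tape, Y, d, c(x$id, gate$id), bw)
}

# Dense layer on B x C inputs (used by the squeeze-and-excitation gate).
nn_dense <- function(tape, x, w, b) {
  X <- ag_val(tape, x)
  Wm <- ag_val(tape, w)
  bv <- ag_val(tape, b)
  Y <- X %*% Wm + rep(bv, each = nrow(X))
  bw <- function(g) list(g %*% t(Wm), crossprod(X, g), colSums(g))
  ag_node(tape, Y, NULL, c(x$id, w$id, b$id), bw)
}

nn_add_bias <- function(tape, x, b) {
  bv <- ag_val(tape, b)
  n <- nrow(ag_val(tape, x))
  ag_node(tape, ag_val(tape, x) + rep(bv, each = n), x$dim, c(x$id, b$id),
          function(g) list(g, colSums(g)))
}

# Mean pixelwise softmax cross-entropy against integer labels in 0..K-1.
nn_softmax_ce <- function(tape, logits, labels) {
  L <- ag_val(tape, logits)
  n <- nrow(L)
  mx <- do.call(pmax, lapply(seq_len(ncol(L)), function(j) L[, j]))
  lse <- mx + log(rowSums(exp(L - mx)))
  pick <- cbind(seq_len(n), as.integer(labels) + 1L)
  loss <- sum(lse - L[pick]) / n
  bw <- function(g) {
    P <- exp(L - lse)
    P[pick] <- P[pick] - 1
    list(P * (g / n))
  }
  ag_node(tape, loss, NULL, logits$id, bw)
}
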