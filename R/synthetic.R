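# Synthetic field-scene generator: noise-textured soil background, clustered
# elliptical soybean leaflets, thin curved graminoid strokes, and broad lobed
# broadleaf shapes, with exact ground-truth masks. The generator emulates the
# geometry of nadir field photographs (object shapes, class imbalance, mutual
# occlusion); it makes no attempt at photorealism. Graminoid strokes share the
# soybean hue deliberately, so distinguishing the two requires shape, not a
# colour lookup.

CLASS_NAMES <- c("background", "soybean", "graminoid_weed", "broadleaf_weed")

#' Segmentation sample
#'
#' @param image `H x W x 3` array of RGB values in `[0, 1]` (8-bit levels).
#' @param mask `H x W` integer matrix with values in `0..3`
#'   (0 background, 1 soybean, 2 graminoid weed, 3 broadleaf weed).
#' @return object of class `seg_sample`.
#' @export
seg_sample <- function(image, mask) {
  stopifnot(is.array(image), length(dim(image)) == 3L, dim(image)[3] == 3L)
  mask <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  if (!identical(dim(image)[1:2], dim(mask))) {
    stop("image and mask shapes differ")
  }
  if (any(mask < 0L | mask > 3L)) stop("mask values must lie in 0..3")
  if (any(image < 0 | image > 1)) stop("image values must lie in [0, 1]")
  structure(list(image = image, mask = mask), class = "seg_sample")
}

#' Synthetic scene specification
#'
#' @param size square scene size in pixels, divisible by 32.
#' @param target_fractions named per-class pixel-fraction goals in `[0, 1]`
#'   for soybean, graminoid and broadleaf cover; their sum must not exceed 1.
#' @param occlusion_rate fraction of objects deliberately placed overlapping
#'   an already-drawn object (the later-drawn class owns the overlap).
#' @param seed integer seed; the same spec yields a bitwise-identical scene.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(size = 512L,
                       target_fractions = c(soybean = 0.20,
                                            graminoid = 0.08,
                                            broadleaf = 0.10),
                       occlusion_rate = 0.2,
                       seed = 1L) {
  if (size %% 32 != 0) stop("size must be divisible by 32")
  tf <- target_fractions
  need <- c("soybean", "graminoid", "broadleaf")
  if (is.null(names(tf))) names(tf) <- need[seq_along(tf)]
  missing <- setdiff(need, names(tf))
  tf[missing] <- 0
  tf <- tf[need]
  if (any(tf < 0) || any(tf > 1)) stop("target fractions must lie in [0, 1]")
  if (sum(tf) > 1) stop("target fractions sum to more than 1 (infeasible)")
  if (occlusion_rate < 0 || occlusion_rate > 1) {
    stop("occlusion_rate must lie in [0, 1]")
  }
  structure(list(size = as.integer(size), target_fractions = tf,
                 occlusion_rate = occlusion_rate, seed = as.integer(seed)),
            class = "scene_spec")
}

# Paint `region` (logical matrix over the full scene or index vector) on the
# scene environment with class `cls` and colour `col` (+ per-pixel jitter).
paint <- function(sc, idx, cls, col, jitter = 0.04) {
  if (length(idx) == 0L) return(invisible(NULL))
  sc$mask[idx] <- cls
  n <- length(idx)
  for (ch in 1:3) {
    sc$img[idx + (ch - 1L) * sc$npx] <-
      pmin(1, pmax(0, col[ch] + stats::rnorm(n, 0, jitter)))
  }
  invisible(NULL)
}

# Index vector of pixels inside an ellipse (axes a, b, rotation theta).
ellipse_idx <- function(size, cx, cy, a, b, theta) {
  r0 <- max(1L, floor(cy - a - b)); r1 <- min(size, ceiling(cy + a + b))
  c0 <- max(1L, floor(cx - a - b)); c1 <- min(size, ceiling(cx + a + b))
  if (r0 > r1 || c0 > c1) return(integer())
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  u <- dx * ct + dy * st
  v <- -dx * st + dy * ct
  inside <- (u / a)^2 + (v / b)^2 <= 1
  which_in <- which(inside)
  if (length(which_in) == 0L) return(integer())
  rr <- rows[(which_in - 1L) %% length(rows) + 1L]
  cc <- cols[(which_in - 1L) %/% length(rows) + 1L]
  rr + (cc - 1L) * size
}

# Index vector of pixels inside a lobed blob r(theta) = R (1 + depth sin(k t + phi)).
lobed_idx <- function(size, cx, cy, R, k, phi, depth = 0.35) {
  ext <- R * (1 + depth)
  r0 <- max(1L, floor(cy - ext)); r1 <- min(size, ceiling(cy + ext))
  c0 <- max(1L, floor(cx - ext)); c1 <- min(size, ceiling(cx + ext))
  if (r0 > r1 || c0 > c1) return(integer())
  rows <- r0:r1; cols <- c0:c1
  dy <- matrix(rows - cy, length(rows), length(cols))
  dx <- matrix(cols - cx, length(rows), length(cols), byrow = TRUE)
  dist <- sqrt(dx^2 + dy^2)
  ang <- atan2(dy, dx)
  inside <- dist <= R * (1 + depth * sin(k * ang + phi))
  w <- which(inside)
  if (length(w) == 0L) return(integer())
  rr <- rows[(w - 1L) %% length(rows) + 1L]
  cc <- cols[(w - 1L) %/% length(rows) + 1L]
  rr + (cc - 1L) * size
}

# Index vector of pixels within width/2 of a quadratic Bezier stroke.
stroke_idx <- function(size, p0, p1, p2, width) {
  tseq <- seq(0, 1, length.out = max(16L, 3L * size %/% 2L))
  pts <- outer((1 - tseq)^2, p0) + outer(2 * tseq * (1 - tseq), p1) +
    outer(tseq^2, p2)
  rad <- width / 2
  off <- expand.grid(dr = -ceiling(rad):ceiling(rad),
                     dc = -ceiling(rad):ceiling(rad))
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 0.25, , drop = FALSE]
  rr <- rep(round(pts[, 2]), each = nrow(off)) + off$dr
  cc <- rep(round(pts[, 1]), each = nrow(off)) + off$dc
  ok <- rr >= 1 & rr <= size & cc >= 1 & cc <= size
  unique(rr[ok] + (cc[ok] - 1L) * size)
}

# Pick an object centre, optionally biased onto an existing object.
pick_center <- function(sc, size, occl) {
  if (length(sc$centers) > 0 && stats::runif(1) < occl) {
    base <- sc$centers[[sample.int(length(sc$centers), 1L)]]
    pmin(pmax(base + stats::rnorm(2, 0, size / 16), 1), size)
  } else {
    stats::runif(2, 1, size)
  }
}

#' Generate one synthetic field scene
#'
#' Draws a soil background, then soybean leaflet clusters, broadleaf lobed
#' blobs and graminoid strokes (in that order; later classes overwrite
#' earlier ones where they overlap), adding objects of each class until its
#' target pixel fraction is reached.
#'
#' @param spec a [scene_spec()].
#' @return a [seg_sample()] with the exact generator geometry as mask.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, {
    size <- spec$size
    sc <- new.env(parent = emptyenv())
    sc$npx <- size * size
    sc$mask <- matrix(0L, size, size)
    sc$centers <- list()

    # soil: brown base, low-frequency brightness blotches, fine noise
    base <- c(120, 90, 60) / 255
    rows <- seq_len(size)
    shade <- matrix(0, size, size)
    for (i in 1:4) {
      cx <- stats::runif(1, 1, size); cy <- stats::runif(1, 1, size)
      sg <- stats::runif(1, size / 6, size / 2)
      amp <- stats::runif(1, -0.08, 0.08)
      shade <- shade + amp * exp(-(outer((rows - cy)^2, (rows - cx)^2, "+")) /
                                   (2 * sg^2))
    }
    sc$img <- array(0, c(size, size, 3L))
    for (ch in 1:3) {
      sc$img[, , ch] <- pmin(1, pmax(0, base[ch] + shade +
                                       stats::rnorm(sc$npx, 0, 8 / 255)))
    }

    frac <- function(cls) sum(sc$mask == cls) / sc$npx
    tf <- spec$target_fractions
    occl <- spec$occlusion_rate

    # soybean: trifoliate leaflet clusters (class 1)
    soy_col <- c(0.26, 0.55, 0.22)
    tries <- 0L
    while (tf["soybean"] > 0 && frac(1L) < tf["soybean"] && tries < 400L) {
      ctr <- pick_center(sc, size, occl)
      phi <- stats::runif(1, 0, 2 * pi)
      a <- stats::runif(1, size / 20, size / 12)
      for (leaf in 0:2) {
        ang <- phi + leaf * 2 * pi / 3
        lc <- ctr + 0.9 * a * c(cos(ang), sin(ang))
        idx <- ellipse_idx(size, lc[1], lc[2], a, a / 2.2, ang + pi / 2)
        paint(sc, idx, 1L, soy_col * stats::runif(1, 0.85, 1.15))
      }
      sc$centers <- c(sc$centers, list(ctr))
      tries <- tries + 1L
    }

    # broadleaf: lobed blobs, darker blue-green (class 3)
    bl_col <- c(0.16, 0.42, 0.33)
    tries <- 0L
    while (tf["broadleaf"] > 0 && frac(3L) < tf["broadleaf"] && tries < 400L) {
      ctr <- pick_center(sc, size, occl)
      idx <- lobed_idx(size, ctr[1], ctr[2],
                       R = stats::runif(1, size / 18, size / 9),
                       k = sample(4:6, 1L), phi = stats::runif(1, 0, 2 * pi))
      paint(sc, idx, 3L, bl_col * stats::runif(1, 0.85, 1.15))
      sc$centers <- c(sc$centers, list(ctr))
      tries <- tries + 1L
    }

    # graminoid: thin curved strokes sharing the soybean hue (class 2)
    tries <- 0L
    while (tf["graminoid"] > 0 && frac(2L) < tf["graminoid"] && tries < 600L) {
      p0 <- pick_center(sc, size, occl)
      dir <- stats::runif(1, 0, 2 * pi)
      len <- stats::runif(1, size / 4, size / 1.8)
      p2 <- p0 + len * c(cos(dir), sin(dir))
      p1 <- (p0 + p2) / 2 +
        stats::rnorm(2, 0, size / 10) # curvature
      idx <- stroke_idx(size, p0, p1, p2, width = stats::runif(1, 2, 5))
      paint(sc, idx, 2L, soy_col * stats::runif(1, 0.9, 1.1))
      sc$centers <- c(sc$centers, list(p0))
      tries <- tries + 1L
    }

    img <- round(sc$img * 255) / 255 # quantize to 8-bit levels
    seg_sample(img, sc$mask)
  })
}

#' Generate a synthetic dataset
#'
#' Scene seeds are drawn from one master stream, so every scene is an
#' independent reproducible draw; the per-scene seeds and achieved class
#' fractions are recorded in the `manifest` attribute.
#'
#' @param n number of scenes (>= 1).
#' @param spec a [scene_spec()] template (its seed field is ignored).
#' @param seed master seed.
#' @return list of `n` [seg_sample()]s with a `manifest` data frame attribute.
#' @export
generate_dataset <- function(n, spec = scene_spec(), seed = 1L) {
  stopifnot(n >= 1)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, n))
  samples <- vector("list", n)
  man <- vector("list", n)
  for (i in seq_len(n)) {
    sp <- spec
    sp$seed <- seeds[i]
    samples[[i]] <- generate_scene(sp)
    fr <- vapply(0:3, function(k) mean(samples[[i]]$mask == k), numeric(1))
    man[[i]] <- data.frame(scene = i, seed = seeds[i],
                           frac_background = fr[1], frac_soybean = fr[2],
                           frac_graminoid = fr[3], frac_broadleaf = fr[4])
  }
  attr(samples, "manifest") <- do.call(rbind, man)
  samples
}
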