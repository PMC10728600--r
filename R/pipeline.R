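# Preprocessing pipeline: LabelMe polygon annotations to 4-class index masks,
# random 512x512 cropping, five-fold augmentation (rotation, flip, Gaussian
# noise, contrast), and the 6:3:1 random split.

LABEL_CLASSES <- c(soybean = 1L, graminoid_weed = 2L, broadleaf_weed = 3L)

#' Annotation record
#'
#' @param image_path path of the annotated image.
#' @param polygons list of polygons, each a list with `class` (one of
#'   `"soybean"`, `"graminoid_weed"`, `"broadleaf_weed"`) and `points`, an
#'   `n x 2` matrix of (x, y) pixel coordinates (LabelMe convention: x is the
#'   column, y is the row, origin at the top-left corner), `n >= 3`.
#' @return object of class `annotation_record`.
#' @export
annotation_record <- function(image_path, polygons) {
  for (i in seq_along(polygons)) {
    p <- polygons[[i]]
    if (is.null(p$points) || nrow(p$points) < 3L) {
      stop("polygon ", i, " has fewer than 3 vertices")
    }
  }
  structure(list(image_path = image_path, polygons = polygons),
            class = "annotation_record")
}

#' Read a LabelMe JSON annotation
#'
#' Accepts the LabelMe dialect: top-level `imagePath` and `shapes`, each shape
#' carrying `label` and `points`.
#'
#' @param path JSON file path.
#' @return an [annotation_record()].
#' @export
read_labelme <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  polys <- lapply(j$shapes, function(s) {
    pts <- do.call(rbind, lapply(s$points, function(p) c(p[[1]], p[[2]])))
    list(class = s$label, points = pts)
  })
  annotation_record(j$imagePath %||% path, polys)
}

#' Rasterize polygon annotations to an index mask
#'
#' Fills polygon interiors (pixel-center containment) with the class index;
#' background is 0; later polygons overwrite earlier ones. Vertices outside
#' the image are clipped to its bounds.
#'
#' @param rec an [annotation_record()].
#' @param height,width output mask size in pixels.
#' @return `height x width` integer mask with values in `0..3`.
#' @export
rasterize_annotation <- function(rec, height, width) {
  stopifnot(inherits(rec, "annotation_record"))
  mask <- matrix(0L, height, width)
  for (i in seq_along(rec$polygons)) {
    poly <- rec$polygons[[i]]
    cls <- LABEL_CLASSES[poly$class]
    if (is.na(cls)) {
      stop("polygon ", i, " has unknown class \"", poly$class,
           "\" (expected one of: ", paste(names(LABEL_CLASSES),
                                          collapse = ", "), ")")
    }
    pts <- poly$points
    pts[, 1] <- pmin(pmax(pts[, 1], 0), width)
    pts[, 2] <- pmin(pmax(pts[, 2], 0), height)
    # pixel (r, c) has center (c - 0.5, r - 0.5) in LabelMe coordinates
    c0 <- max(1L, floor(min(pts[, 1]) + 0.5))
    c1 <- min(width, ceiling(max(pts[, 1]) + 0.5))
    r0 <- max(1L, floor(min(pts[, 2]) + 0.5))
    r1 <- min(height, ceiling(max(pts[, 2]) + 0.5))
    if (r0 > r1 || c0 > c1) next
    grid <- as.matrix(expand.grid(x = (c0:c1) - 0.5, y = (r0:r1) - 0.5))
    inside <- mgcv::in.out(rbind(pts, pts[1, ]), grid)
    if (!any(inside)) next
    sub <- matrix(inside, nrow = length(c0:c1)) # x fastest in expand.grid
    idx <- which(t(sub)) # transpose to row-fastest
    rr <- (r0:r1)[(idx - 1L) %% (r1 - r0 + 1L) + 1L]
    cc <- (c0:c1)[(idx - 1L) %/% (r1 - r0 + 1L) + 1L]
    mask[cbind(rr, cc)] <- cls
  }
  mask
}

#' Random square crop of an image/mask pair
#'
#' The crop window is drawn uniformly over all valid positions (using the
#' current RNG state) and applied identically to image and mask.
#'
#' @param sample a [seg_sample()].
#' @param size crop side length; source dimensions must be at least `size`.
#' @return a [seg_sample()] of size `size x size`.
#' @export
random_crop <- function(sample, size) {
  d <- dim(sample$mask)
  if (d[1] < size || d[2] < size) {
    stop("source (", d[1], "x", d[2], ") is smaller than the crop size ", size)
  }
  r <- if (d[1] == size) 1L else sample.int(d[1] - size + 1L, 1L)
  c <- if (d[2] == size) 1L else sample.int(d[2] - size + 1L, 1L)
  seg_sample(sample$image[r:(r + size - 1L), c:(c + size - 1L), , drop = FALSE],
             sample$mask[r:(r + size - 1L), c:(c + size - 1L)])
}

rot_sample <- function(s, quarter_turns) {
  rot90 <- function(m) t(m)[, nrow(m):1, drop = FALSE] # counter-clockwise
  img <- s$image
  msk <- s$mask
  for (i in seq_len(quarter_turns)) {
    msk <- rot90(msk)
    img <- array(c(rot90(img[, , 1]), rot90(img[, , 2]), rot90(img[, , 3])),
                 c(dim(msk), 3L))
  }
  seg_sample(img, msk)
}

flip_sample <- function(s, horizontal) {
  if (horizontal) {
    seg_sample(s$image[, dim(s$mask)[2]:1, , drop = FALSE],
               s$mask[, dim(s$mask)[2]:1, drop = FALSE])
  } else {
    seg_sample(s$image[dim(s$mask)[1]:1, , , drop = FALSE],
               s$mask[dim(s$mask)[1]:1, , drop = FALSE])
  }
}

noise_sample <- function(s, sd = 10 / 255) {
  img <- s$image + stats::rnorm(length(s$image), 0, sd)
  img <- pmin(pmax(img, 0), 1) # array first so dims survive
  seg_sample(round(img * 255) / 255, s$mask)
}

contrast_sample <- function(s, gain) {
  img <- pmin(pmax((s$image - 0.5) * gain + 0.5, 0), 1)
  seg_sample(round(img * 255) / 255, s$mask)
}

#' Five-fold dataset augmentation
#'
#' Every input sample yields itself plus four derived samples: a random
#' right-angle rotation (90/180/270 degrees), a random flip (horizontal or
#' vertical), Gaussian pixel noise (sigma 10 on the 8-bit scale), and a
#' contrast increase (gain uniform in 1.1..1.5). Geometric transforms are
#' applied identically to the mask; photometric ones leave it untouched.
#' Uses the current RNG state.
#'
#' @param samples nonempty list of [seg_sample()]s.
#' @return list of `5 * length(samples)` samples, with a `provenance`
#'   character attribute naming each sample's transform.
#' @export
augment_dataset <- function(samples) {
  if (length(samples) == 0L) stop("empty input")
  out <- vector("list", 5L * length(samples))
  prov <- character(5L * length(samples))
  for (i in seq_along(samples)) {
    s <- samples[[i]]
    at <- (i - 1L) * 5L
    out[[at + 1L]] <- s
    out[[at + 2L]] <- rot_sample(s, sample(1:3, 1L))
    out[[at + 3L]] <- flip_sample(s, stats::runif(1) < 0.5)
    out[[at + 4L]] <- noise_sample(s)
    out[[at + 5L]] <- contrast_sample(s, stats::runif(1, 1.1, 1.5))
    prov[at + 1:5] <- c("original", "rotation", "flip", "noise", "contrast")
  }
  attr(out, "provenance") <- prov
  out
}

#' Random 6:3:1 dataset split
#'
#' Samples are permuted under `seed`; the first `floor(0.6 n)` go to the
#' training set, the next `floor(0.3 n)` to validation, and the remainder to
#' test.
#'
#' @param samples list of at least 10 samples.
#' @param ratios three nonnegative weights (default `c(6, 3, 1)`).
#' @param seed integer permutation seed.
#' @return object of class `dataset_split`: lists `train`, `val`, `test`, the
#'   seed, and the index assignment.
#' @export
split_dataset <- function(samples, ratios = c(6, 3, 1), seed = 1L) {
  n <- length(samples)
  if (n < 10L) stop("need at least 10 samples to split, got ", n)
  w <- ratios / sum(ratios)
  perm <- with_seed(seed, sample.int(n))
  n_train <- floor(w[1] * n)
  n_val <- floor(w[2] * n)
  idx <- list(train = perm[seq_len(n_train)],
              val = perm[n_train + seq_len(n_val)],
              test = perm[(n_train + n_val + 1L):n])
  structure(list(train = samples[idx$train], val = samples[idx$val],
                 test = samples[idx$test], seed = as.integer(seed),
                 indices = idx),
            class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset split (seed %d): %d train / %d val / %d test\n",
              x$seed, length(x$train), length(x$val), length(x$test)))
  invisible(x)
}

# ---- disk I/O -----------------------------------------------------------------

#' Write and read a segmentation sample as PNG files
#'
#' Images are written as RGB PNG; masks as single-channel PNG holding the raw
#' class indices 0..3.
#'
#' @param sample a [seg_sample()].
#' @param image_path,mask_path output paths.
#' @export
write_sample <- function(sample, image_path, mask_path) {
  png::writePNG(sample$image, image_path)
  png::writePNG(sample$mask / 255, mask_path)
  invisible(c(image_path, mask_path))
}

#' @rdname write_sample
#' @export
read_sample <- function(image_path, mask_path) {
  img <- png::readPNG(image_path)
  msk <- round(png::readPNG(mask_path) * 255)
  seg_sample(img, matrix(as.integer(msk), nrow(msk), ncol(msk)))
}
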