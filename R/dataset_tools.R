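# Dataset bookkeeping: the 70/20/10 train/validation/test partition and the
# augmentation expansion applied to training images only.

#' Partition sizes for a train/validation/test split
#'
#' Train and validation counts are floored; the test set receives the
#' remainder, so the three counts always sum to `n_total` exactly. For
#' 4306 images at 70/20/10 this yields 3014 / 861 / 431.
#'
#' @param n_total Number of images (>= 0).
#' @param ratios Numeric `(train, val, test)` fractions, non-negative and
#'   summing to 1 (default `c(0.7, 0.2, 0.1)`).
#' @return Named integer vector `c(train = , val = , test = )`.
#' @export
split_counts <- function(n_total, ratios = c(0.7, 0.2, 0.1)) {
  check_ratios(ratios)
  if (n_total < 0L) lt_value_error("n_total must be >= 0")
  n_train <- floor(n_total * ratios[1])
  n_val <- floor(n_total * ratios[2])
  c(train = as.integer(n_train), val = as.integer(n_val),
    test = as.integer(n_total - n_train - n_val))
}

check_ratios <- function(ratios) {
  if (!is.numeric(ratios) || length(ratios) != 3L || any(ratios < 0) ||
      abs(sum(ratios) - 1) > 1e-9) {
    lt_value_error("ratios must be three non-negative numbers summing to 1")
  }
  invisible(TRUE)
}

#' Deterministically assign ids to the three splits
#'
#' Shuffles the ids with the given seed and partitions them by
#' [split_counts()]. The three parts are disjoint and exhaustive; the same
#' seed always produces the same partition.
#'
#' @param ids Vector of unique identifiers.
#' @param ratios As in [split_counts()].
#' @param seed Integer RNG seed.
#' @return A list with elements `train`, `val`, `test`.
#' @export
assign_split <- function(ids, ratios = c(0.7, 0.2, 0.1), seed = 1L) {
  if (anyDuplicated(ids)) lt_value_error("ids must be unique")
  check_ratios(ratios)
  n <- length(ids)
  counts <- split_counts(n, ratios)
  shuffled <- with_seed(seed, ids[sample.int(n)])
  list(train = shuffled[seq_len(counts["train"])],
       val = shuffled[seq_len(counts["val"]) + counts["train"]],
       test = shuffled[seq_len(counts["test"]) + counts["train"] + counts["val"]])
}

#' Dataset size after augmenting the training set
#'
#' Augmented variants are added alongside the originals, so the dataset
#' grows by `copies_per_image` new images per training image:
#' `n_full + n_train * copies_per_image`. Two copies per training image
#' takes 4306 images (3014 in training) to 10334.
#'
#' @param n_full Total images before augmentation.
#' @param n_train Training-set size (<= n_full).
#' @param copies_per_image Augmented copies generated per training image.
#' @return Integer total after augmentation.
#' @export
augmented_total <- function(n_full, n_train, copies_per_image) {
  if (n_train > n_full) lt_value_error("n_train cannot exceed n_full")
  if (copies_per_image < 0L) lt_value_error("copies_per_image must be >= 0")
  as.integer(n_full + n_train * copies_per_image)
}

#' Augmentation parameters
#'
#' Jitter magnitudes default to the protocol's maxima: saturation,
#' brightness and exposure within +/-10%, blur up to 1 pixel, and noise on
#' up to 1% of pixels.
#'
#' @param saturation_jitter,brightness_jitter,exposure_jitter Maximum
#'   absolute fractional jitter (default 0.10 each).
#' @param blur_px Maximum Gaussian blur radius in pixels (default 1).
#' @param noise_frac Maximum fraction of pixels receiving salt-and-pepper
#'   noise (default 0.01).
#' @param copies_per_image Copies generated per training image (default 2).
#' @param seed Integer RNG seed.
#' @return An object of class `lt_augment_params`.
#' @export
augment_params <- function(saturation_jitter = 0.10, brightness_jitter = 0.10,
                           exposure_jitter = 0.10, blur_px = 1,
                           noise_frac = 0.01, copies_per_image = 2L,
                           seed = 1L) {
  if (any(c(saturation_jitter, brightness_jitter, exposure_jitter,
            blur_px, noise_frac) < 0)) {
    lt_value_error("augmentation magnitudes must be >= 0")
  }
  if (copies_per_image < 0L) lt_value_error("copies_per_image must be >= 0")
  structure(list(saturation_jitter = saturation_jitter,
                 brightness_jitter = brightness_jitter,
                 exposure_jitter = exposure_jitter,
                 blur_px = blur_px, noise_frac = noise_frac,
                 copies_per_image = as.integer(copies_per_image),
                 seed = as.integer(seed)),
            class = "lt_augment_params")
}

#' Produce one augmented variant of an image
#'
#' Applies, in order: luma-preserving saturation scaling, multiplicative
#' brightness, gamma-style exposure adjustment, Gaussian blur, and
#' salt-and-pepper noise. Each jitter is drawn uniformly within its
#' +/-bound; blur radius and noise fraction are drawn uniformly in
#' `[0, max]`. With all parameters zero the image is returned bit-identical;
#' a fixed seed gives identical output on repeat calls. The RGB-space
#' formulation keeps the zero-parameter identity exact.
#'
#' @param img Integer `h x w x 3` image.
#' @param params An [augment_params()].
#' @return The augmented image, same shape, 8-bit.
#' @export
augment_image <- function(img, params = augment_params()) {
  with_seed(params$seed, {
    js <- stats::runif(1, -params$saturation_jitter, params$saturation_jitter)
    jb <- stats::runif(1, -params$brightness_jitter, params$brightness_jitter)
    je <- stats::runif(1, -params$exposure_jitter, params$exposure_jitter)
    radius <- stats::runif(1, 0, params$blur_px)
    frac <- stats::runif(1, 0, params$noise_frac)

    out <- img * 1.0
    if (js != 0) {
      g <- 0.299 * out[, , 1] + 0.587 * out[, , 2] + 0.114 * out[, , 3]
      for (ch in 1:3) out[, , ch] <- g + (1 + js) * (out[, , ch] - g)
    }
    if (jb != 0) out <- out * (1 + jb)
    if (je != 0) {
      out <- pmin(pmax(out, 0), 255)
      out <- 255 * (out / 255)^(1 / (1 + je))
    }
    if (radius > 0) out <- gaussian_blur(out, radius)
    out <- round_half_up(pmin(pmax(out, 0), 255))
    storage.mode(out) <- "integer"

    n_noise <- floor(frac * prod(dim(img)[1:2]))
    if (n_noise >= 1L) {
      flat <- sample.int(prod(dim(img)[1:2]), n_noise)
      vals <- sample(c(0L, 255L), n_noise, replace = TRUE)
      for (ch in 1:3) {
        plane <- out[, , ch]
        plane[flat] <- vals
        out[, , ch] <- plane
      }
    }
    out
  })
}

# separable Gaussian blur with replicate padding; kernel spans +/-ceil(2*sigma)
gaussian_blur <- function(img, sigma) {
  half <- max(1L, as.integer(ceiling(2 * sigma)))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_axis <- function(m, along_rows) {
    if (along_rows) m <- t(m)
    n <- ncol(m)
    idx <- function(j) pmin(pmax(j, 1L), n)
    acc <- matrix(0, nrow(m), n)
    for (o in seq(-half, half)) {
      acc <- acc + k[o + half + 1L] * m[, idx(seq_len(n) + o), drop = FALSE]
    }
    if (along_rows) t(acc) else acc
  }
  for (ch in 1:3) {
    img[, , ch] <- blur_axis(blur_axis(img[, , ch], FALSE), TRUE)
  }
  img
}

#' Resize an image by nearest-neighbour sampling
#'
#' Dataset preparation helper; detector training pipelines expect square
#' inputs (640 x 640 by default).
#'
#' @param img Integer `h x w x 3` image.
#' @param width,height Target size in pixels (default 640 each).
#' @return The resized image.
#' @export
resize_image <- function(img, width = 640L, height = 640L) {
  d <- dim(img)
  src_r <- pmin(d[1], floor((seq_len(height) - 0.5) * d[1] / height) + 1L)
  src_c <- pmin(d[2], floor((seq_len(width) - 0.5) * d[2] / width) + 1L)
  img[src_r, src_c, , drop = FALSE]
}
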