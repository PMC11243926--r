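# Independent reference implementations used to cross-check the package.
# These are deliberately naive (per-pixel loops, exhaustive search, numeric
# integration) and share no code with the functions they validate.

fixed_clock <- function(t = "2024-05-01 10:00:00") {
  function() as.POSIXct(t, tz = "UTC")
}

# uniform gray test image, h x w x 3
gray_image <- function(h, w, value = 128L) {
  array(as.integer(value), dim = c(h, w, 3L))
}

# image with distinct pixel values for identity/round-trip checks
ramp_image <- function(h, w) {
  base <- matrix(seq_len(h * w) %% 256L, h, w)
  arr <- array(0L, dim = c(h, w, 3L))
  for (ch in 1:3) arr[, , ch] <- (base + 37L * ch) %% 256L
  arr
}

# exhaustive nearest-white scan in the stated tie-break order (y, then x)
brute_representative <- function(mask, box) {
  cx <- box$x + box$width %/% 2L
  cy <- box$y + box$height %/% 2L
  if (mask[cy + 1L, cx + 1L] == 255L) return(c(cx, cy))
  best <- NULL
  bestd <- Inf
  for (yy in box$y:(box$y + box$height - 1L)) {
    for (xx in box$x:(box$x + box$width - 1L)) {
      if (mask[yy + 1L, xx + 1L] == 255L) {
        d <- (xx - cx)^2 + (yy - cy)^2
        if (d < bestd) {
          bestd <- d
          best <- c(xx, yy)
        }
      }
    }
  }
  best
}

# per-pixel threshold loop for mask refinement
brute_white_count <- function(roi, box, threshold) {
  count <- 0L
  for (yy in box$y:(box$y + box$height - 1L)) {
    for (xx in box$x:(box$x + box$width - 1L)) {
      px <- as.numeric(roi[yy + 1L, xx + 1L, ])
      g <- floor(0.299 * px[1] + 0.587 * px[2] + 0.114 * px[3] + 0.5)
      if (g <= threshold) count <- count + 1L
    }
  }
  count
}

# rasterised IoU: count pixels on a grid
brute_iou <- function(a, b) {
  gw <- max(a$x + a$width, b$x + b$width)
  gh <- max(a$y + a$height, b$y + b$height)
  ga <- matrix(FALSE, gh, gw)
  gb <- matrix(FALSE, gh, gw)
  ga[(a$y + 1):(a$y + a$height), (a$x + 1):(a$x + a$width)] <- TRUE
  gb[(b$y + 1):(b$y + b$height), (b$x + 1):(b$x + b$width)] <- TRUE
  sum(ga & gb) / sum(ga | gb)
}

# fine-grid numeric integration of the monotone precision envelope
ap_grid_oracle <- function(points, n = 20000L) {
  grid <- (seq_len(n) - 0.5) / n
  env <- numeric(n)
  for (i in seq_len(nrow(points))) {
    env <- pmax(env, ifelse(points$recall[i] >= grid, points$precision[i], 0))
  }
  mean(env)
}

# exhaustive maximal matching: maximum number of pred-gt pairs with same
# class and IoU >= threshold, over all injective assignments
brute_max_matches <- function(preds, gts, thr) {
  np <- nrow(preds)
  ng <- nrow(gts)
  ok <- matrix(FALSE, np, ng)
  for (i in seq_len(np)) {
    for (j in seq_len(ng)) {
      if (preds$label[i] == gts$label[j]) {
        ok[i, j] <- iou(rect(preds$x[i], preds$y[i], preds$width[i], preds$height[i]),
                        rect(gts$x[j], gts$y[j], gts$width[j], gts$height[j])) >= thr
      }
    }
  }
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (np - i + 1L) <= best) return()
    if (i > np) {
      best <<- max(best, count)
      return()
    }
    recurse(i + 1L, used, count)
    for (j in seq_len(ng)) {
      if (ok[i, j] && !used[j]) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, logical(ng), 0L)
  best
}

# 9-parameter DLT homography fit via SVD null space — an independent
# algorithm from the package's 8-unknown solve
svd_homography <- function(src, dst) {
  A <- NULL
  for (i in 1:4) {
    x <- src[i, 1]; y <- src[i, 2]; X <- dst[i, 1]; Y <- dst[i, 2]
    A <- rbind(A,
               c(-x, -y, -1, 0, 0, 0, x * X, y * X, X),
               c(0, 0, 0, -x, -y, -1, x * Y, y * Y, Y))
  }
  v <- svd(A, nv = 9)$v[, 9]
  m <- matrix(v, 3, 3, byrow = TRUE)
  m / m[3, 3]
}

# random axis-aligned rectangle correspondence; destination scale kept in
# [0.5, 2] of the source, the regime of same-scene dual-camera panels (a
# sub-half-scale destination would amplify its integer rounding past one
# source pixel on the return trip)
random_rect_corr <- function() {
  sx <- runif(1, 0, 50); sy <- runif(1, 0, 50)
  sw <- runif(1, 40, 200); sh <- runif(1, 40, 200)
  dx <- runif(1, 0, 50); dy <- runif(1, 0, 50)
  dw <- sw * runif(1, 0.5, 2); dh <- sh * runif(1, 0.5, 2)
  quad_correspondence(
    rbind(c(sx, sy), c(sx + sw, sy), c(sx + sw, sy + sh), c(sx, sy + sh)),
    rbind(c(dx, dy), c(dx + dw, dy), c(dx + dw, dy + dh), c(dx, dy + dh)))
}

# random PR curve with achievable (recall, precision) points
random_pr_points <- function(n = 10L) {
  data.frame(recall = sort(runif(n)), precision = runif(n),
             threshold = sort(runif(n), decreasing = TRUE))
}

random_mask <- function(h = 15L, w = 15L, p_white = 0.3) {
  matrix(ifelse(runif(h * w) < p_white, 255L, 0L), h, w)
}
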