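unit_square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))

test_that("fit_homography recovers identity and pure scaling", {
  h_id <- fit_homography(quad_correspondence(unit_square, unit_square))
  expect_equal(h_id$m, diag(3), tolerance = 1e-9)

  h_sc <- fit_homography(quad_correspondence(unit_square, unit_square * 2))
  expect_equal(h_sc$m, diag(c(2, 2, 1)), tolerance = 1e-9)
})

test_that("degenerate quads raise a singularity error", {
  collinear <- rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 1))
  expect_error(quad_correspondence(collinear, unit_square),
               class = "lizardtherm_singularity_error")
  expect_error(quad_correspondence(unit_square, collinear),
               class = "lizardtherm_singularity_error")
})

test_that("random general quads reproduce all corners and match the SVD fit", {
  set.seed(21)
  for (k in 1:40) {
    # jitter rectangle corners into a general convex-ish quad
    src <- unit_square * 100 + matrix(runif(8, -15, 15), 4, 2)
    dst <- unit_square * 80 + 20 + matrix(runif(8, -12, 12), 4, 2)
    corr <- tryCatch(quad_correspondence(src, dst),
                     lizardtherm_singularity_error = function(e) NULL)
    if (is.null(corr)) next
    h <- fit_homography(corr)
    for (i in 1:4) {
      v <- h$m %*% c(src[i, ], 1)
      expect_lt(max(abs(v[1:2] / v[3] - dst[i, ])), 1e-6)
    }
    expect_equal(h$m, svd_homography(src, dst), tolerance = 1e-6)
  }
})

test_that("map_point follows the floor(v + 0.5) rounding rule", {
  h_id <- homography(diag(3))
  p <- map_point(h_id, pixel_coord(5, 7))
  expect_identical(c(p$x, p$y), c(5L, 7L))

  h_half <- homography(diag(c(0.5, 0.5, 1)))
  p2 <- map_point(h_half, pixel_coord(5, 0))
  expect_identical(c(p2$x, p2$y), c(3L, 0L))   # 2.5 rounds up
})

test_that("map_point agrees with a direct homogeneous-product oracle", {
  set.seed(22)
  for (k in 1:40) {
    corr <- random_rect_corr()
    h <- fit_homography(corr)
    x <- runif(1, corr$src[1, 1], corr$src[2, 1])
    y <- runif(1, corr$src[1, 2], corr$src[4, 2])
    p <- pixel_coord(round(x), round(y))
    v <- c(h$m[1, 1] * p$x + h$m[1, 2] * p$y + h$m[1, 3],
           h$m[2, 1] * p$x + h$m[2, 2] * p$y + h$m[2, 3],
           h$m[3, 1] * p$x + h$m[3, 2] * p$y + h$m[3, 3])
    want <- floor(v[1:2] / v[3] + 0.5)
    got <- map_point(h, p)
    expect_identical(c(got$x, got$y), as.integer(want))
  }
})

test_that("rectangle correspondences reduce to per-axis linear interpolation", {
  set.seed(23)
  for (k in 1:20) {
    corr <- random_rect_corr()
    h <- fit_homography(corr)
    sx0 <- corr$src[1, 1]; sy0 <- corr$src[1, 2]
    sw <- corr$src[2, 1] - sx0; sh <- corr$src[4, 2] - sy0
    dx0 <- corr$dst[1, 1]; dy0 <- corr$dst[1, 2]
    dw <- corr$dst[2, 1] - dx0; dh <- corr$dst[4, 2] - dy0
    for (j in 1:10) {
      px <- round(runif(1, sx0, sx0 + sw))
      py <- round(runif(1, sy0, sy0 + sh))
      want_x <- floor(dx0 + (px - sx0) / sw * dw + 0.5)
      want_y <- floor(dy0 + (py - sy0) / sh * dh + 0.5)
      got <- map_point(h, pixel_coord(px, py))
      expect_identical(c(got$x, got$y), as.integer(c(want_x, want_y)))
    }
  }
})

test_that("forward-then-inverse mapping returns within one pixel", {
  set.seed(24)
  for (k in 1:30) {
    corr <- random_rect_corr()
    fwd <- fit_homography(corr)
    bwd <- fit_homography(quad_correspondence(corr$dst, corr$src))
    px <- round(runif(1, corr$src[1, 1] + 1, corr$src[2, 1] - 1))
    py <- round(runif(1, corr$src[1, 2] + 1, corr$src[4, 2] - 1))
    mid <- map_point(fwd, pixel_coord(px, py))
    back <- map_point(bwd, mid)
    # after two integer roundings the worst case is one pixel
    expect_lte(max(abs(c(back$x - px, back$y - py))), 1L)
  }
})

test_that("degenerate mappings raise the dedicated conditions", {
  # third row sends (1, 1) to infinity
  h <- homography(matrix(c(1, 0, 0, 0, 1, 0, -0.5, -0.5, 1), 3, 3, byrow = TRUE))
  expect_error(map_point(h, pixel_coord(1, 1)),
               class = "lizardtherm_mapping_error")

  # negative normalised coordinates are out-of-panel, not rounded
  shift <- homography(matrix(c(1, 0, -10, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE))
  err <- tryCatch(map_point(shift, pixel_coord(2, 5)),
                  lizardtherm_out_of_panel_error = function(e) e)
  expect_s3_class(err, "lizardtherm_out_of_panel_error")
  expect_equal(unname(err$raw["x"]), -8)

  # rounded coordinates beyond the panel are out-of-panel too
  expect_error(map_point(homography(diag(3)), pixel_coord(30, 5),
                         panel = c(20, 20, 3)),
               class = "lizardtherm_out_of_panel_error")
})

test_that("homography text files round-trip at full precision", {
  tmp <- withr::local_tempfile(fileext = ".txt")
  h <- fit_homography(random_rect_corr())
  write_homography(h, tmp)
  expect_equal(read_homography(tmp)$m, h$m, tolerance = 1e-15)
  writeLines(c("1", "2"), tmp)
  expect_error(read_homography(tmp), class = "lizardtherm_input_error")
})
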