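# renders a bar onto a blank thermal panel using a given colourmap
render_bar_panel <- function(bar, cmap, h = 160L, w = 120L) {
  panel <- gray_image(h, w, 0L)
  cols <- (bar$x_med - bar$bar_width %/% 2L):(bar$x_med + (bar$bar_width - 1L) %/% 2L)
  rows <- bar$y_min:bar$y_max
  for (ch in 1:3) {
    panel[rows + 1L, cols + 1L, ch] <- matrix(cmap[, ch], length(rows),
                                              length(cols))
  }
  panel
}

test_that("row_to_temperature reproduces the annotated endpoints", {
  bar <- scale_bar(t_min = 29.3, t_max = 50.5, y_min = 40L, y_max = 140L,
                   x_med = 60L)
  expect_equal(row_to_temperature(bar, bar$y_max), 29.3)
  expect_equal(row_to_temperature(bar, bar$y_min), 50.5)
  expect_equal(row_to_temperature(bar, 90L), (29.3 + 50.5) / 2)
  expect_error(row_to_temperature(bar, 141L), class = "lizardtherm_range_error")
  expect_error(row_to_temperature(bar, 39L), class = "lizardtherm_range_error")
})

test_that("row_to_temperature is strictly decreasing in the row index", {
  bar <- scale_bar(20, 45, 10L, 110L, 50L)
  temps <- row_to_temperature(bar, bar$y_min:bar$y_max)
  expect_true(all(diff(temps) < 0))
  expect_true(all(temps >= bar$t_min & temps <= bar$t_max))
})

test_that("scale_bar validates its invariants", {
  expect_error(scale_bar(30, 30, 0L, 10L, 5L), class = "lizardtherm_value_error")
  expect_error(scale_bar(20, 30, 10L, 10L, 5L), class = "lizardtherm_value_error")
  expect_error(scale_bar(20, 30, 0L, 10L, 5L, bar_width = 0L),
               class = "lizardtherm_value_error")
})

test_that("sample_bar averages across the bar width", {
  bar <- scale_bar(25, 40, 10L, 59L, 60L, bar_width = 10L)
  cmap <- make_colourmap(50L)
  panel <- render_bar_panel(bar, cmap)

  # constant-per-row render reads back exactly
  s <- sample_bar(panel, bar)
  expect_identical(s$rows, 10:59)
  expect_identical(unname(s$colours), unname(cmap))

  # width-1 bar: colours read back exactly
  bar1 <- scale_bar(25, 40, 10L, 59L, 60L, bar_width = 1L)
  panel1 <- render_bar_panel(bar1, cmap)
  expect_identical(unname(sample_bar(panel1, bar1)$colours), unname(cmap))

  # horizontal noise: per-row mean equals a brute-force average
  set.seed(31)
  noisy <- panel
  cols <- 56:65   # footprint of x_med = 60, width 10 (0-based 55..64)
  noise <- array(sample(-3:3, 50 * 10 * 3, TRUE), dim = c(50, 10, 3))
  noisy[11:60, cols, ] <- pmin(pmax(noisy[11:60, cols, ] + noise, 0L), 255L)
  s2 <- sample_bar(noisy, bar)
  for (r in c(1, 17, 50)) {
    want <- floor(apply(noisy[10 + r, cols, , drop = FALSE], 3, mean) + 0.5)
    expect_identical(as.integer(s2$colours[r, ]), as.integer(want))
  }

  # footprint leaving the panel is a bounds error
  off <- scale_bar(25, 40, 10L, 59L, 118L, bar_width = 10L)
  expect_error(sample_bar(panel, off), class = "lizardtherm_bounds_error")
})

test_that("colour_to_temperature matches exact bar colours and tolerates small perturbations", {
  bar <- scale_bar(28, 44, 20L, 99L, 60L)
  cmap <- make_colourmap(80L)
  panel <- render_bar_panel(bar, cmap)

  for (r in c(20L, 47L, 99L)) {
    px <- pixel_coord(10L, 5L)
    panel_copy <- panel
    panel_copy[6, 11, ] <- cmap[r - 19L, ]
    expect_equal(colour_to_temperature(panel_copy, bar, px),
                 row_to_temperature(bar, r))
  }

  # +/-1 per-channel perturbation still resolves to the same row
  # (consecutive colourmap steps are >= 4 apart)
  set.seed(32)
  for (k in 1:20) {
    r <- sample(20:99, 1)
    perturbed <- pmin(pmax(cmap[r - 19L, ] + sample(c(-1L, 0L, 1L), 3, TRUE), 0L), 255L)
    panel_copy <- panel
    panel_copy[6, 11, ] <- perturbed
    # brute-force nearest-colour scan as the oracle
    d2 <- rowSums(sweep(cmap, 2, perturbed)^2)
    want_row <- 19L + which.min(d2)
    expect_equal(colour_to_temperature(panel_copy, bar, pixel_coord(10L, 5L)),
                 row_to_temperature(bar, want_row))
    expect_identical(want_row, r)
  }
})

test_that("recovered temperatures stay in range and within the quantisation bound", {
  scene <- make_scene(seed = 41)
  bar <- scene$gt_scalebar
  step <- (bar$t_max - bar$t_min) / (bar$y_max - bar$y_min)
  set.seed(41)
  for (k in 1:50) {
    x <- sample(0:(dim(scene$thermal_panel)[2] - 1L), 1)
    y <- sample(0:(dim(scene$thermal_panel)[1] - 1L), 1)
    t_hat <- colour_to_temperature(scene$thermal_panel, bar, pixel_coord(x, y))
    expect_gte(t_hat, bar$t_min)
    expect_lte(t_hat, bar$t_max)
    expect_lte(abs(t_hat - scene$gt_temperature[y + 1L, x + 1L]), step / 2 + 1e-9)
  }
})
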