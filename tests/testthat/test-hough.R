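p64 <- gielis_params(n_points = 64L)

# rasterized template edge mask at a known pose
raster_template_mask <- function(shape, center, axis_row, axis_col,
                                 p = gielis_params()) {
  fit <- eye_border_fit(center[1], center[2], axis_row, axis_col)
  render_border(fit, p, shape)
}

test_that("accumulator equals the brute-force triple-loop oracle", {
  ext <- ulcerseg:::gielis_extents(p64)
  set.seed(42)
  edges <- matrix(runif(50 * 50) < 0.04, 50, 50)
  edges <- edges | raster_template_mask(c(50, 50), c(25, 26), 10, 16, p64)
  for (sc in list(c(8, 14), c(10, 16), c(12, 18))) {   # coarse 3-cell space
    tm <- gielis_template(p64, scale_row = sc[1] / ext["row"],
                          scale_col = sc[2] / ext["col"])
    off <- ulcerseg:::raster_offsets(tm)
    grid_dim <- c(25L, 25L)
    acc <- hough_accumulate(edges, off, stride = 2L, tol = 1L,
                            grid_dim = grid_dim)
    oracle <- hough_oracle(edges, off, stride = 2L, tol = 1L,
                           grid_dim = grid_dim)
    expect_identical(unname(acc), unname(oracle))
  }
})

test_that("the fit recovers a rasterized template pose", {
  shape <- c(200, 300)
  edges <- raster_template_mask(shape, c(101, 153), 55, 95)
  space <- hough_control(row_scale_range = c(40, 70),
                         col_scale_range = c(80, 110),
                         scale_steps = 7, rotation_steps = 1)
  fit <- hough_fit_eye_border(edges, gielis_params(), space)
  expect_lte(max(abs(fit$center - c(101, 153))), space$center_stride)
  expect_lte(abs(fit$axis_row - 55), 5)   # one scale step
  expect_lte(abs(fit$axis_col - 95), 5)
  expect_gte(fit$vote_fraction, 0.8)
})

test_that("recovery survives 500 uniform noise pixels", {
  shape <- c(400, 600)
  edges <- raster_template_mask(shape, c(201, 305), 90, 170)
  clean_fit <- hough_fit_eye_border(edges, gielis_params(),
    hough_control(row_scale_range = c(70, 110), col_scale_range = c(140, 200),
                  scale_steps = 7, rotation_steps = 1))
  set.seed(9)
  noise_idx <- cbind(sample.int(400, 500, TRUE), sample.int(600, 500, TRUE))
  noisy <- edges
  noisy[noise_idx] <- TRUE
  fit <- hough_fit_eye_border(noisy, gielis_params(),
    hough_control(row_scale_range = c(70, 110), col_scale_range = c(140, 200),
                  scale_steps = 7, rotation_steps = 1))
  expect_lte(max(abs(fit$center - clean_fit$center)), 2)
  expect_equal(fit$axis_row, clean_fit$axis_row, tolerance = 6)
  expect_equal(fit$axis_col, clean_fit$axis_col, tolerance = 9)
})

test_that("insufficient or unrecognizable edges raise informative errors", {
  expect_error(hough_fit_eye_border(matrix(FALSE, 100, 100)),
               "insufficient edge evidence")
  set.seed(1)
  sparse <- matrix(runif(200 * 200) < 0.002, 200, 200)  # ~80 scattered px
  expect_error(
    hough_fit_eye_border(sparse, gielis_params(),
      hough_control(min_vote_fraction = 0.6)),
    "no eye border found")
})

test_that("voting is monotone in edge pixels and deterministic", {
  ext <- ulcerseg:::gielis_extents(p64)
  tm <- gielis_template(p64, scale_row = 12 / ext["row"],
                        scale_col = 18 / ext["col"])
  off <- ulcerseg:::raster_offsets(tm)
  set.seed(5)
  edges <- matrix(runif(60 * 60) < 0.05, 60, 60)
  acc1 <- hough_accumulate(edges, off, stride = 2L, tol = 1L)
  more <- edges
  more[cbind(sample.int(60, 30, TRUE), sample.int(60, 30, TRUE))] <- TRUE
  acc2 <- hough_accumulate(more, off, stride = 2L, tol = 1L)
  expect_true(all(acc2 >= acc1))
  expect_identical(acc1, hough_accumulate(edges, off, stride = 2L, tol = 1L))
})

test_that("translation equivariance on stride multiples", {
  shape <- c(160, 160)
  space <- hough_control(row_scale_range = c(25, 35),
                         col_scale_range = c(40, 50), scale_steps = 3,
                         rotation_steps = 1)
  e1 <- raster_template_mask(shape, c(71, 75), 30, 45)
  f1 <- hough_fit_eye_border(e1, gielis_params(), space)
  e2 <- ulcerseg:::shift_mask(e1, 4L, 6L)
  f2 <- hough_fit_eye_border(e2, gielis_params(), space)
  expect_equal(unname(f2$center - f1$center), c(4, 6))
  expect_equal(f2$axis_row, f1$axis_row)
  expect_equal(f2$axis_col, f1$axis_col)
})

test_that("render/fill are consistent and respect geometry", {
  fit <- eye_border_fit(80, 100, axis_row = 40, axis_col = 70)
  shape <- c(160, 200)
  outline <- render_border(fit, gielis_params(), shape)
  filled <- fill_border(fit, gielis_params(), shape)
  expect_true(all(filled[outline]))           # outline is part of the fill
  expect_true(all(outline[filled & !ulcerseg:::shift_mask(filled, 1, 0) |
                            filled & !ulcerseg:::shift_mask(filled, -1, 0)]))
  # mirror symmetry of the default shape about its center row and column
  expect_mask_equal(outline[1:159, ], outline[159:1, ])    # about row 80
  expect_mask_equal(outline[, 1:199], outline[, 199:1])    # about col 100
  # area matches the quadrature of the polar integral, within 2%
  phi <- seq(0, 2 * pi, length.out = 20001)
  r <- gielis_radius(phi, gielis_params())
  ext <- ulcerseg:::gielis_extents(gielis_params())
  unit_area <- sum(0.5 * r^2) * diff(phi[1:2])
  area <- unit_area * (40 / ext["row"]) * (70 / ext["col"])
  expect_equal(sum(filled), unname(area), tolerance = 0.02)
  # doubling both axes quadruples the area, within rasterization error
  fit2 <- eye_border_fit(80, 100, axis_row = 20, axis_col = 35)
  expect_equal(sum(filled) / sum(fill_border(fit2, gielis_params(), shape)),
               4, tolerance = 0.05)
})

test_that("render then refit is a fixed point", {
  shape <- c(200, 280)
  fit <- eye_border_fit(99, 141, axis_row = 50, axis_col = 90)
  outline <- render_border(fit, gielis_params(), shape)
  space <- hough_control(row_scale_range = c(40, 60),
                         col_scale_range = c(80, 100), scale_steps = 5,
                         rotation_steps = 1)
  refit <- hough_fit_eye_border(outline, gielis_params(), space)
  expect_lte(max(abs(refit$center - fit$center)), 1)
  expect_equal(refit$axis_row, 50, tolerance = 2.6)
  expect_equal(refit$axis_col, 90, tolerance = 2.6)
  # and a second render from the refit encloses essentially the same region
  f1 <- fill_border(fit, gielis_params(), shape)
  f2 <- fill_border(refit, gielis_params(), shape)
  expect_gte(sum(f1 & f2) / sum(f1 | f2), 0.9)
})

test_that("a fit outside the image renders empty with a warning", {
  fit <- eye_border_fit(-500, -500, axis_row = 30, axis_col = 50)
  expect_warning(out <- render_border(fit, gielis_params(), c(100, 100)),
                 "outside")
  expect_false(any(out))
})
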