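cfg <- preprocess_control()

test_that("specular mask excludes a saturated patch and keeps the rest", {
  img <- flat_rgb(64, 64, red = 0.5, green = 0.5, blue = 0.5)
  img[20:24, 30:34, ] <- 1  # saturated white 5x5 patch
  m <- specular_reflection_mask(img, cfg)
  # brute-force Otsu on the squared blue channel flags exactly the patch;
  # closing with a disk cannot shrink it
  thr <- otsu_bruteforce(img[, , 3]^2)
  expect_true(all(img[, , 3][!m]^2 > thr))
  expect_false(any(m[20:24, 30:34]))
  # everything further than the closing radius from the patch survives
  far <- matrix(TRUE, 64, 64)
  far[pmax(20 - 6, 1):pmin(24 + 6, 64), pmax(30 - 6, 1):pmin(34 + 6, 64)] <- FALSE
  expect_true(all(m[far]))
})

test_that("constant blue channel yields an all-true mask with a warning", {
  img <- flat_rgb(64, 64, blue = 0)
  expect_warning(m <- specular_reflection_mask(img, cfg), "constant blue")
  expect_true(all(m))
})

test_that("an implausibly large reflection split is rejected as reflection-free", {
  # bright-blue half-frame: Otsu flags half of the image, far above the cap
  img <- flat_rgb(64, 64, blue = 0.1)
  img[, 33:64, 3] <- 0.9
  expect_warning(m <- specular_reflection_mask(img, cfg), "reflection-free")
  expect_true(all(m))
})

test_that("specular mask attains high recall on generated reflections", {
  sc <- blob_scene(seed = 11)
  m <- specular_reflection_mask(sc$image, cfg)
  recall <- sum(!m & sc$truth_reflections) / sum(sc$truth_reflections)
  expect_gte(recall, 0.95)
})

test_that("masked_green honours identity, zero and impulse cases", {
  img <- flat_rgb(64, 64, green = 0.4)
  all_true <- matrix(TRUE, 64, 64)
  gs <- masked_green(img, all_true, cfg)
  # all-true mask: output is the smoothed green channel itself (flat field)
  expect_equal(gs, matrix(0.4, 64, 64), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(masked_green(img, !all_true, cfg) == 0))

  # impulse: the response is the sampled 2-D Gaussian kernel, truncated at
  # +/- 3 sigma and normalized to unit mass
  imp <- flat_rgb(65, 65, green = 0)
  imp[33, 33, 2] <- 1
  out <- masked_green(imp, matrix(TRUE, 65, 65), cfg)
  rad <- ceiling(3 * cfg$gaussian_sigma)
  d2 <- outer((-rad:rad)^2, (-rad:rad)^2, `+`)
  kern <- exp(-d2 / (2 * cfg$gaussian_sigma^2))
  kern <- kern / sum(kern)
  expect_equal(out[33 + (-rad:rad), 33 + (-rad:rad)], kern,
               tolerance = 1e-5, ignore_attr = TRUE)
  expect_equal(sum(out), 1, tolerance = 1e-6)
  expect_lt(max(out[1:20, ]), 1e-12)
})

test_that("masked_green is linear in the image for a fixed mask", {
  sc <- blob_scene(seed = 3)
  mask <- sc$image[, , 3] < 0.5
  g1 <- masked_green(sc$image, mask, cfg)
  half <- sc$image * 0.5
  g2 <- masked_green(half, mask, cfg)
  expect_equal(g2, 0.5 * g1, tolerance = 1e-12)
})

test_that("masked_green rejects shape mismatches", {
  img <- flat_rgb(64, 64)
  expect_error(masked_green(img, matrix(TRUE, 32, 64), cfg), "dimensions")
})

test_that("square_binarize squares before thresholding", {
  g <- matrix(0.2, 16, 16)
  g[5:8, 5:8] <- 0.9
  fixed <- preprocess_control(threshold_method = "fixed", fixed_threshold = 0.5)
  m <- square_binarize(g, fixed)
  expect_mask_equal(m, g^2 > 0.5)          # 0.81 > 0.5, 0.04 is not
  # fixed threshold t on squared values == threshold sqrt(t) on raw values
  fixed2 <- preprocess_control(threshold_method = "fixed",
                               fixed_threshold = 0.37)
  expect_mask_equal(square_binarize(g, fixed2), g > sqrt(0.37))
})

test_that("square_binarize recovers a bright disk from uniform noise", {
  set.seed(101)
  g <- matrix(runif(96 * 96, 0, 0.55), 96, 96)
  disk <- (row(g) - 48)^2 + (col(g) - 48)^2 <= 20^2
  g[disk] <- 0.95
  m <- square_binarize(g, cfg)
  iou <- sum(m & disk) / sum(m | disk)
  expect_gte(iou, 0.9)
  # and it induces the same mask as the exhaustive-search Otsu threshold
  # (the threshold itself may sit anywhere on a degenerate plateau)
  expect_mask_equal(m, g^2 > otsu_bruteforce(g^2))
})

test_that("square_binarize handles degenerate input", {
  expect_warning(m <- square_binarize(matrix(0.3, 8, 8), cfg), "constant")
  expect_false(any(m))
  m0 <- suppressWarnings(square_binarize(matrix(0, 8, 8), cfg))
  expect_false(any(m0))
})

test_that("ellipse premask recovers an analytic ellipse within a pixel", {
  m <- matrix(FALSE, 120, 160)
  el <- ((row(m) - 60) / 30)^2 + ((col(m) - 80) / 50)^2 <= 1
  cfg1 <- preprocess_control(ellipse_dilation_factor = 1)
  pm <- ellipse_premask(el, cfg1)
  # recovered semi-axes from the rendered mask extents
  expect_equal(sum(range(which(apply(pm, 1, any)))) / 2, 60, tolerance = 1)
  expect_equal(diff(range(which(apply(pm, 1, any)))) / 2, 30, tolerance = 1)
  expect_equal(diff(range(which(apply(pm, 2, any)))) / 2, 50, tolerance = 1)
  iou <- sum(pm & el) / sum(pm | el)
  expect_gte(iou, 0.95)
})

test_that("ellipse premask covers the union of disjoint blobs", {
  m <- matrix(FALSE, 100, 100)
  m[20:30, 20:30] <- TRUE
  m[70:80, 60:70] <- TRUE
  pm <- ellipse_premask(m, cfg)
  or <- moments_bruteforce(m)
  pm_or <- moments_bruteforce(pm)
  # centroid of the premask matches the union's moment centroid
  expect_equal(pm_or$centroid, or$centroid, tolerance = 1.5)
  # axis-aligned rendering: the per-axis extents follow the union's moment
  # semi-axes (the larger eigen-axis on the dominant marginal direction),
  # inflated by the dilation factor
  dom <- if (or$var_row >= or$var_col) 1 else 2
  ext_dom <- diff(range(which(apply(pm, dom, any)))) / 2
  expect_equal(ext_dom, cfg$ellipse_dilation_factor * or$semi_major,
               tolerance = 2)
})

test_that("ellipse premask degenerates to a disk for a single pixel", {
  m <- matrix(FALSE, 64, 64)
  m[32, 40] <- TRUE
  pm <- ellipse_premask(m, cfg)
  d <- disk <- (row(m) - 32)^2 + (col(m) - 40)^2 <= cfg$closing_radius^2
  expect_mask_equal(pm, d)
  expect_error(ellipse_premask(matrix(FALSE, 64, 64), cfg),
               "no fluorescein")
})

test_that("thinning produces thin skeletons inside the input", {
  bar <- matrix(FALSE, 30, 40)
  bar[14:16, 10:29] <- TRUE
  sk <- thin_mask(bar)
  expect_true(all(bar[sk]))                  # skeleton inside input
  expect_true(all(colSums(sk[, 11:28]) <= 1))  # 1 px wide along the bar
  expect_gte(sum(sk), 15)

  disk <- (row(matrix(0, 41, 41)) - 21)^2 + (col(matrix(0, 41, 41)) - 21)^2 <= 100
  skd <- thin_mask(disk)
  idx <- which(skd, arr.ind = TRUE)
  expect_true(all(sqrt((idx[, 1] - 21)^2 + (idx[, 2] - 21)^2) <= 2))

  expect_mask_equal(thin_mask(matrix(FALSE, 10, 10)), matrix(FALSE, 10, 10))
})

test_that("thinning never increases the component count", {
  set.seed(7)
  for (k in 1:5) {
    m <- matrix(runif(60 * 60) < 0.4, 60, 60)
    m <- ulcerseg:::from_ebi(EBImage::closing(ulcerseg:::as_ebi(m),
                                              EBImage::makeBrush(5, "disc"))) > 0.5
    sk <- thin_mask(m)
    expect_true(all(m[sk]))
    expect_lte(max(label_components(sk)), max(label_components(m)))
  }
})

test_that("preprocessing is deterministic", {
  sc <- blob_scene(seed = 5)
  p1 <- preprocess_eye(sc$image, cfg)
  p2 <- preprocess_eye(sc$image, cfg)
  expect_identical(p1, p2)
})
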