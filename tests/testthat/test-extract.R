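test_that("cornea extraction masks the green channel by disk and reflections", {
  img <- flat_rgb(100, 100, green = 0.6)
  fit <- eye_border_fit(50, 50, axis_row = 120, axis_col = 120)
  disk <- cornea_disk_from_fit(fit, "semi_minor")  # covers the whole frame
  all_true <- matrix(TRUE, 100, 100)
  out <- extract_cornea_region(img, disk, all_true)
  expect_equal(unclass(out), img[, , 2], ignore_attr = TRUE)

  small <- cornea_disk_from_fit(eye_border_fit(50, 50, 4, 4), "semi_minor")
  expect_error(extract_cornea_region(img, small, all_true), "cornea too small")

  outside <- cornea_disk_from_fit(eye_border_fit(-300, -300, 20, 20),
                                  "semi_minor")
  expect_error(extract_cornea_region(img, outside, all_true),
               "outside the image")
})

test_that("cornea extraction is confined to the generated cornea", {
  sc <- blob_scene(seed = 31)
  refl <- matrix(TRUE, 240, 320)
  disk <- cornea_disk_from_fit(sc$truth_border, sc$params$cornea_radius_mode)
  out <- extract_cornea_region(sc$image, disk, refl)
  ring <- ulcerseg:::from_ebi(EBImage::dilate(
    ulcerseg:::as_ebi(sc$truth_cornea), EBImage::makeBrush(5, "box"))) > 0.5
  expect_true(all(out[!ring] == 0))
})

test_that("candidate extraction finds blobs and stays empty on uniform corneas", {
  # no fluorescein: uniform dim green inside the support
  g <- matrix(0, 80, 80)
  sup <- ulcerseg:::disk_mask(c(80, 80), c(40, 40), 30)
  g[sup] <- 0.1
  expect_false(any(candidate_ulcer_mask(g, support = sup)))

  # one bright blob -> one component; two blobs -> two components
  g1 <- g
  blob1 <- ulcerseg:::disk_mask(c(80, 80), c(35, 35), 6)
  g1[blob1] <- 0.85
  m1 <- candidate_ulcer_mask(g1, support = sup)
  expect_equal(max(label_components(m1)), 1)
  expect_gte(sum(m1 & blob1) / sum(m1 | blob1), 0.95)

  g2 <- g1
  blob2 <- ulcerseg:::disk_mask(c(80, 80), c(50, 48), 5)
  g2[blob2] <- 0.9
  m2 <- candidate_ulcer_mask(g2, support = sup)
  expect_equal(max(label_components(m2)), 2)
})

test_that("the minimum-contrast guard suppresses noise-only splits", {
  set.seed(77)
  g <- matrix(0, 80, 80)
  sup <- ulcerseg:::disk_mask(c(80, 80), c(40, 40), 30)
  g[sup] <- pmin(pmax(0.1 + rnorm(sum(sup), 0, 0.02), 0), 1)
  expect_false(any(candidate_ulcer_mask(g, support = sup)))
})

test_that("eyelid filtering follows the contact x elongation truth table", {
  shape <- c(120, 160)
  border <- matrix(FALSE, shape[1], shape[2])
  border[10, ] <- TRUE                      # border along row 10
  mk <- function(rows, cols) {
    m <- matrix(FALSE, shape[1], shape[2]); m[rows, cols] <- TRUE; m
  }
  elong_touch <- mk(11:13, 30:80)       # ratio >> 3, touches
  elong_free  <- mk(60:62, 30:80)       # ratio >> 3, far from border
  compact_touch <- mk(11:18, 120:127)   # ratio ~ 1, touches
  compact_free  <- mk(60:67, 120:127)   # ratio ~ 1, free
  cand <- elong_touch | elong_free | compact_touch | compact_free
  res <- filter_eyelid_segments(cand, border, ratio_threshold = 3,
                                border_dilation_px = 2)
  expect_mask_equal(res$mask, elong_free | compact_touch | compact_free)
  expect_equal(nrow(res$rejected), 1)
  expect_true(res$rejected$touches_border)
  expect_gt(res$rejected$axis_ratio, 3)
  # semi-axes agree with the brute-force moment oracle
  or <- moments_bruteforce(elong_touch)
  expect_equal(res$rejected$semi_major, or$semi_major, tolerance = 1e-9)
  expect_equal(res$rejected$semi_minor, or$semi_minor, tolerance = 1e-9)
})

test_that("raising the ratio threshold never removes more segments", {
  sc <- generate_scene(scene_params(eyelid_arc = list(), seed = 13))
  seg <- segment_ulcer(sc$image)
  kept <- lapply(c(2, 3, 4, 5), function(thr) {
    filter_eyelid_segments(seg$candidates, seg$border_mask,
                           ratio_threshold = thr)$mask
  })
  for (k in 1:3) expect_true(all(kept[[k + 1]] >= kept[[k]]))
})

test_that("single-pixel segments get the floored axis ratio", {
  cand <- matrix(FALSE, 70, 70); cand[35, 35] <- TRUE
  res <- filter_eyelid_segments(cand, matrix(FALSE, 70, 70), min_area = 1L)
  expect_equal(res$features$semi_minor, 0.5)
  expect_equal(res$features$axis_ratio, 1)
  expect_false(res$features$rejected)
  # at the default minimum area the speck is treated as noise
  res2 <- filter_eyelid_segments(cand, matrix(FALSE, 70, 70))
  expect_false(any(res2$mask))
  expect_equal(nrow(res2$features), 0)
})

test_that("segment_ulcer recovers a generated ulcer end to end", {
  sc <- blob_scene(seed = 0)
  seg <- segment_ulcer(sc$image)
  m <- compute_metrics(confusion(seg$ulcer_mask, sc$truth_ulcer))
  expect_gte(m$dice, 0.90)
  # the final mask never leaves the cornea disk and never claims reflections
  expect_true(all(seg$cornea_mask[seg$ulcer_mask]))
  expect_mask_equal(seg$ulcer_mask & seg$reflection_mask, seg$ulcer_mask)
})

test_that("segment_ulcer returns an empty mask on a healthy eye", {
  sc <- generate_scene(scene_params(seed = 7))
  seg <- segment_ulcer(sc$image)
  expect_lte(sum(seg$ulcer_mask), 0.01 * sum(seg$cornea_mask))
})

test_that("a lid-stain arc is rejected and recorded, leaving no ulcer", {
  sc <- generate_scene(scene_params(eyelid_arc = list(), seed = 8))
  seg <- segment_ulcer(sc$image)
  expect_equal(sum(seg$ulcer_mask & sc$truth_eyelid), 0)
  expect_lte(sum(seg$ulcer_mask), 0.01 * sum(seg$cornea_mask))
  expect_gte(nrow(seg$rejected_segments), 1)
  # at least one recorded rejection overlaps the true arc
  lab <- label_components(seg$candidates)
  overlap <- vapply(seg$rejected_segments$label, function(k)
    sum(sc$truth_eyelid[lab == k]), integer(1))
  expect_gte(max(overlap), 1)
})

test_that("segment_ulcer is deterministic and attaches stage names to errors", {
  sc <- blob_scene(seed = 2)
  s1 <- segment_ulcer(sc$image)
  s2 <- segment_ulcer(sc$image)
  expect_identical(s1$ulcer_mask, s2$ulcer_mask)
  expect_identical(s1$border_fit, s2$border_fit)
  dark <- flat_rgb(100, 100, red = 0, green = 0, blue = 0)
  expect_error(suppressWarnings(segment_ulcer(dark)), "\\[preprocess\\]")
})

test_that("print, summary and plot methods work", {
  sc <- blob_scene(seed = 2)
  seg <- segment_ulcer(sc$image)
  expect_output(print(seg), "ulcer pixels")
  expect_output(print(summary(seg)), "cornea area")
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf, 320, 240)
  expect_silent(plot(seg))
  grDevices::dev.off()
  expect_true(file.exists(tf))
})
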