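# Preprocessing chain: specular-reflection masking from the blue channel,
# Gaussian-smoothed green channel masking, squaring + binarization, the
# elliptical pre-mask, and thinning. Output feeds the Hough recognizer.

is_constant <- function(x) {
  r <- range(x)
  (r[2L] - r[1L]) < 1e-10
}

# Threshold a [0,1] grayscale matrix of *already squared* intensities.
# Otsu is computed per image via EBImage; fixed mode uses the configured cut.
binarize_gray <- function(gray, cfg) {
  thr <- if (cfg$threshold_method == "otsu")
    EBImage::otsu(as_ebi(gray), range = c(0, 1), levels = 256L)
  else cfg$fixed_threshold
  structure(gray > thr, threshold = thr)
}

disc_brush <- function(radius) {
  EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")
}

#' Specular-reflection mask from the blue channel
#'
#' Saturated highlights from the tear film and light source are bright in the
#' blue channel under cobalt-blue illumination. The blue channel is squared
#' (spreading highlights from the rest of the image), binarized, closed with a
#' disk of `cfg$closing_radius`, and complemented, so the returned mask is
#' TRUE where the image is *not* specular reflection.
#'
#' @param image H x W x 3 RGB array in \[0, 1\].
#' @param cfg a [preprocess_control()] object.
#' @return logical H x W matrix; TRUE = keep (non-reflection).
#' @export
specular_reflection_mask <- function(image, cfg = preprocess_control()) {
  validate_rgb_image(image)
  blue <- image[, , 3L]
  if (is_constant(blue)) {
    warning("constant blue channel: no specular reflections found",
            call. = FALSE)
    return(matrix(TRUE, nrow(blue), ncol(blue)))
  }
  b2 <- blue^2
  bin <- binarize_gray(b2, cfg)
  closed <- from_ebi(EBImage::closing(as_ebi(unclass(bin) & TRUE),
                                      disc_brush(cfg$closing_radius))) > 0.5
  if (mean(closed) > cfg$max_reflection_fraction) {
    # highlights are compact blobs; a split this large is the illuminated
    # eye itself, i.e. the image carries no usable specular evidence
    warning(sprintf(paste0("thresholded reflection region covers %.0f%% of ",
                           "the frame; treating the image as reflection-free"),
                    100 * mean(closed)), call. = FALSE)
    return(matrix(TRUE, nrow(blue), ncol(blue)))
  }
  !closed
}

#' Smoothed green channel under a reflection mask
#'
#' The green channel (the fluorescein signal) is convolved with a Gaussian
#' low-pass kernel of standard deviation `cfg$gaussian_sigma` and multiplied
#' elementwise by the reflection mask.
#'
#' @param image H x W x 3 RGB array.
#' @param reflection_mask logical H x W matrix (TRUE = keep).
#' @param cfg a [preprocess_control()] object.
#' @return H x W numeric matrix in \[0, 1\].
#' @export
masked_green <- function(image, reflection_mask, cfg = preprocess_control()) {
  validate_rgb_image(image)
  check_mask(reflection_mask, ref = image, arg = "reflection_mask")
  g <- image[, , 2L]
  gs <- from_ebi(EBImage::gblur(as_ebi(g), sigma = cfg$gaussian_sigma))
  gs <- pmin(pmax(gs, 0), 1)
  gs * reflection_mask
}

#' Square then binarize a grayscale image
#'
#' Squaring precedes thresholding: it spreads bright fluorescein from the
#' dimmer background and moves the Otsu split point toward the bright mode.
#'
#' @param gray H x W numeric matrix in \[0, 1\].
#' @param cfg a [preprocess_control()] object. In `"fixed"` mode the
#'   threshold applies to the squared values.
#' @return logical H x W matrix, with the threshold used attached as
#'   attribute `"threshold"`.
#' @export
square_binarize <- function(gray, cfg = preprocess_control()) {
  stopifnot(is.matrix(gray), is.numeric(gray))
  if (min(gray) < 0 || max(gray) > 1)
    stop("grayscale values must lie in [0, 1]", call. = FALSE)
  if (is_constant(gray)) {
    warning("constant image: binarization degenerates to an empty mask",
            call. = FALSE)
    return(structure(matrix(FALSE, nrow(gray), ncol(gray)), threshold = NA_real_))
  }
  binarize_gray(gray^2, cfg)
}

#' Elliptical pre-mask from the second moments of a binary image
#'
#' Computes the centroid and moment semi-axes of the union of foreground
#' pixels (semi-axis = twice the standard deviation along the axis, exact for
#' a filled ellipse), inflates both semi-axes by `cfg$ellipse_dilation_factor`
#' and returns the filled axis-aligned ellipse. The general-orientation
#' moment ellipse is computed, but its orientation is zeroed: eyes are
#' horizontal in this imaging protocol, so the semi-major axis is laid along
#' whichever image axis carries the larger marginal variance.
#'
#' @param mask logical H x W matrix with at least one TRUE pixel.
#' @param cfg a [preprocess_control()] object.
#' @return logical H x W matrix: the filled pre-mask ellipse.
#' @export
ellipse_premask <- function(mask, cfg = preprocess_control()) {
  check_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("no fluorescein response detected (empty binary image)", call. = FALSE)
  ctr <- colMeans(idx)
  if (nrow(idx) == 1L) {
    # degenerate: single pixel -> disk of the closing radius
    return(fill_ellipse(dim(mask), ctr, cfg$closing_radius, cfg$closing_radius))
  }
  cv <- stats::cov(idx) * (nrow(idx) - 1L) / nrow(idx)  # population moments
  ev <- eigen(cv, symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  semi <- 2 * sqrt(ev)                                  # major, minor
  if (cv[1L, 1L] >= cv[2L, 2L]) {                       # rows dominate
    semi_row <- semi[1L]; semi_col <- semi[2L]
  } else {
    semi_row <- semi[2L]; semi_col <- semi[1L]
  }
  semi_row <- max(semi_row * cfg$ellipse_dilation_factor, 1)
  semi_col <- max(semi_col * cfg$ellipse_dilation_factor, 1)
  fill_ellipse(dim(mask), ctr, semi_row, semi_col)
}

# Filled axis-aligned ellipse rasterized over an H x W grid.
fill_ellipse <- function(shape, center, semi_row, semi_col) {
  rr <- (seq_len(shape[1L]) - center[1L]) / semi_row
  cc <- (seq_len(shape[2L]) - center[2L]) / semi_col
  outer(rr^2, cc^2, `+`) <= 1
}

#' Morphological thinning
#'
#' Zhang-Suen thinning to a 1-pixel-wide 8-connected skeleton. The number of
#' connected components never increases.
#'
#' @param mask logical H x W matrix.
#' @return logical H x W matrix, the skeleton (a subset of `mask`).
#' @export
thin_mask <- function(mask) {
  check_mask(mask)
  zs_thin(mask)
}

#' Run the full preprocessing chain
#'
#' Produces every intermediate of the preprocessing stage: the
#' specular-reflection (complement) mask, the smoothed masked green channel,
#' its squared binarization, the closed version, the elliptical pre-mask,
#' their conjunction, and the thinned edge image handed to the recognizer.
#'
#' @param image H x W x 3 RGB array.
#' @param cfg a [preprocess_control()] object.
#' @return a list with elements `reflection_mask`, `green_smooth`,
#'   `green_bin`, `green_closed`, `premask`, `pre_edges`, `edges`.
#' @export
preprocess_eye <- function(image, cfg = preprocess_control()) {
  reflection_mask <- specular_reflection_mask(image, cfg)
  green_smooth <- masked_green(image, reflection_mask, cfg)
  green_bin <- square_binarize(green_smooth, cfg)
  green_bin <- unclass(green_bin) & TRUE  # drop threshold attribute
  green_closed <- from_ebi(EBImage::closing(as_ebi(green_bin),
                                            disc_brush(cfg$closing_radius))) > 0.5
  premask <- ellipse_premask(green_bin, cfg)
  pre_edges <- green_closed & premask
  edges <- thin_mask(pre_edges)
  list(reflection_mask = reflection_mask, green_smooth = green_smooth,
       green_bin = green_bin, green_closed = green_closed,
       premask = premask, pre_edges = pre_edges, edges = edges)
}
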