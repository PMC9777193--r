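# Ulcer extraction inside the cornea disk and rejection of eyelid
# fluorescein accumulations, plus the end-to-end segment_ulcer() driver.

# Otsu threshold for an arbitrary sample vector in [0, 1] (EBImage's otsu
# operates on whole images only; the candidate stage thresholds within the
# cornea support). 256-level histogram, maximal between-class variance;
# foreground is values strictly above the returned threshold.
otsu_vec <- function(x, levels = 256L) {
  h <- tabulate(pmin(floor(x * levels) + 1L, levels), nbins = levels)
  w <- cumsum(h)
  mu <- cumsum(h * (seq_len(levels) - 0.5))
  n <- w[levels]; mtot <- mu[levels]
  w0 <- w[-levels]; w1 <- n - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, levels - 1L)
  sb[valid] <- (mtot * w0[valid] - n * mu[-levels][valid])^2 /
    (w0[valid] * w1[valid])
  if (!any(is.finite(sb))) return(NA_real_)
  which.max(sb) / levels
}

#' Label 8-connected components
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background), assigned in
#'   column-major scan order.
#' @export
label_components <- function(mask) {
  check_mask(mask)
  label8_cpp(mask)
}

# Moment features of one component's pixel coordinates (n x 2 row/col).
# Semi-axes are 2 sd along the principal axes; the minor axis is floored at
# 0.5 px so 1-pixel-wide segments get a finite axis ratio.
component_features <- function(idx, label) {
  n <- nrow(idx)
  if (n == 1L) {
    smaj <- 0.5; smin <- 0.5
  } else {
    cv <- stats::cov(idx) * (n - 1L) / n
    ev <- pmax(eigen(cv, symmetric = TRUE, only.values = TRUE)$values, 0)
    smaj <- max(2 * sqrt(ev[1L]), 0.5)
    smin <- max(2 * sqrt(ev[2L]), 0.5)
  }
  data.frame(label = label, area = n,
             centroid_row = mean(idx[, 1L]), centroid_col = mean(idx[, 2L]),
             semi_major = smaj, semi_minor = smin,
             axis_ratio = smaj / smin)
}

#' Extract the cornea region intensities
#'
#' Green channel multiplied by the rasterized cornea disk and the
#' specular-reflection (complement) mask.
#'
#' @param image H x W x 3 RGB array.
#' @param disk a [cornea_disk_from_fit()] object.
#' @param reflection_mask logical H x W matrix (TRUE = keep).
#' @param min_radius disks smaller than this radius (pixels) are rejected.
#' @return H x W numeric matrix, zero outside the cornea support, with the
#'   support mask attached as attribute `"support"`.
#' @export
extract_cornea_region <- function(image, disk, reflection_mask,
                                  min_radius = 5) {
  validate_rgb_image(image)
  check_mask(reflection_mask, ref = image, arg = "reflection_mask")
  if (!inherits(disk, "cornea_disk")) stop("disk must be a cornea_disk")
  if (disk$radius < min_radius)
    stop(sprintf("cornea too small (radius %.1f px < %g px)",
                 disk$radius, min_radius), call. = FALSE)
  dm <- disk_mask(dim(image)[1:2], disk$center, disk$radius)
  if (!any(dm))
    stop("cornea disk lies entirely outside the image", call. = FALSE)
  out <- image[, , 2L] * dm * reflection_mask
  attr(out, "support") <- dm & reflection_mask
  out
}

#' Candidate ulcer mask within the cornea
#'
#' Squares and binarizes the cornea-region green intensities, thresholding
#' over the cornea support only (pixels outside the support never vote for
#' the threshold nor enter the mask). A minimum-contrast guard keeps the mask
#' empty on fluorescein-free corneas: if mean foreground minus mean
#' background intensity over the support falls below `extract$min_contrast`,
#' no candidates are returned. An empty result is a legal healthy-eye
#' outcome.
#'
#' @param cornea_green H x W matrix from [extract_cornea_region()].
#' @param cfg a [preprocess_control()] object (threshold method).
#' @param extract an [extract_control()] object (contrast guard).
#' @param support optional logical matrix; defaults to the `"support"`
#'   attribute of `cornea_green`, else to `cornea_green > 0`.
#' @return logical H x W candidate mask.
#' @export
candidate_ulcer_mask <- function(cornea_green, cfg = preprocess_control(),
                                 extract = extract_control(),
                                 support = NULL) {
  stopifnot(is.matrix(cornea_green))
  if (is.null(support)) support <- attr(cornea_green, "support")
  if (is.null(support)) support <- cornea_green > 0
  check_mask(support, ref = cornea_green, arg = "support")
  empty <- matrix(FALSE, nrow(cornea_green), ncol(cornea_green))
  v <- cornea_green[support]
  if (length(v) == 0L || is_constant(v)) return(empty)
  thr <- if (cfg$threshold_method == "otsu") otsu_vec(v^2)
         else cfg$fixed_threshold
  if (is.na(thr)) return(empty)
  fg <- v^2 > thr
  if (!any(fg) || all(fg)) return(empty)
  if (mean(v[fg]) - mean(v[!fg]) < extract$min_contrast) return(empty)
  out <- empty
  out[support] <- fg
  out
}

#' Reject eyelid fluorescein accumulations
#'
#' For each 8-connected component of the candidate mask, computes the moment
#' semi-axes and tests contact with the rendered eye border (component
#' dilated by `border_dilation_px`, Chebyshev). A component is excluded iff
#' it touches the border AND its semi-major / semi-minor ratio exceeds
#' `ratio_threshold` -- the signature of a fluorescein strip along the eyelid
#' margin rather than a compact ulcer.
#'
#' Components below `min_area` pixels are removed as noise specks before the
#' analysis and appear in neither output table.
#'
#' @param candidates logical H x W candidate mask.
#' @param border logical H x W rendered eye-border outline.
#' @param ratio_threshold elongation cutoff (default 3).
#' @param border_dilation_px contact tolerance, pixels (default 2).
#' @param min_area minimum component area in pixels (default 4).
#' @return a list with `mask` (surviving candidates), `candidates` (the
#'   despeckled input mask the segment labels refer to), `rejected` and
#'   `features` (data frames of per-segment features: label, area, centroid,
#'   semi-axes, `axis_ratio`, `touches_border`, `rejected`).
#' @export
filter_eyelid_segments <- function(candidates, border, ratio_threshold = 3,
                                   border_dilation_px = 2L, min_area = 4L) {
  check_mask(candidates)
  check_mask(border, ref = candidates, arg = "border")
  lab <- label8_cpp(candidates)
  if (min_area > 1L && max(lab) > 0L) {
    sizes <- tabulate(lab[lab > 0L])
    for (k in which(sizes < min_area)) candidates[lab == k] <- FALSE
    lab <- label8_cpp(candidates)
  }
  nseg <- max(lab)
  feats <- NULL
  keep <- candidates
  if (nseg > 0L) {
    # dilating the border once is equivalent to dilating each segment
    border_wide <- if (border_dilation_px > 0L && any(border))
      from_ebi(EBImage::dilate(as_ebi(border),
        EBImage::makeBrush(2L * border_dilation_px + 1L, "box"))) > 0.5
    else border
    idx_all <- which(candidates, arr.ind = TRUE)
    labs <- lab[candidates]
    rows <- split(seq_len(nrow(idx_all)), labs)
    feats <- do.call(rbind, lapply(seq_len(nseg), function(k) {
      idx <- idx_all[rows[[as.character(k)]], , drop = FALSE]
      f <- component_features(idx, k)
      f$touches_border <- any(border_wide[idx])
      f$rejected <- f$touches_border && f$axis_ratio > ratio_threshold
      f
    }))
    for (k in feats$label[feats$rejected]) keep[lab == k] <- FALSE
  } else {
    feats <- data.frame(label = integer(), area = integer(),
                        centroid_row = numeric(), centroid_col = numeric(),
                        semi_major = numeric(), semi_minor = numeric(),
                        axis_ratio = numeric(), touches_border = logical(),
                        rejected = logical())
  }
  list(mask = keep, candidates = candidates,
       rejected = feats[feats$rejected, , drop = FALSE],
       features = feats)
}

with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

#' Segment the corneal ulcer in a fluorescein slit-lamp image
#'
#' Runs the full training-free chain: specular-reflection masking,
#' green-channel preprocessing and thinning, Gielis/Hough eye-border
#' recognition, cornea-disk extraction, candidate binarization inside the
#' cornea, and eyelid-segment rejection. A healthy eye yields an empty ulcer
#' mask (a success, not an error); stage failures propagate with the stage
#' name attached.
#'
#' @param image H x W x 3 RGB array in \[0, 1\], or a file path readable by
#'   [read_eye_image()].
#' @param config a [seg_control()] configuration.
#' @return an object of class `ulcer_seg`: a list with `ulcer_mask`,
#'   `cornea_mask`, `border_fit`, `border_mask`, `reflection_mask`,
#'   `candidates`, `segments`, `rejected_segments`, `overlay`, `edges`,
#'   `config` and the input `image`.
#' @seealso [plot.ulcer_seg()], [summary.ulcer_seg()]
#' @export
segment_ulcer <- function(image, config = seg_control()) {
  if (is.character(image)) image <- read_eye_image(image)
  validate_rgb_image(image)
  stopifnot(inherits(config, "seg_control"))
  shape <- dim(image)[1:2]

  pre <- with_stage("preprocess", preprocess_eye(image, config$preprocess))
  fit <- with_stage("hough",
                    hough_fit_eye_border(pre$edges, config$shape, config$hough))
  disk <- with_stage("cornea",
                     cornea_disk_from_fit(fit, config$cornea$radius_mode))
  cornea_green <- with_stage("extract",
    extract_cornea_region(image, disk, pre$reflection_mask,
                          min_radius = config$cornea$min_radius))
  cand <- with_stage("candidates",
    candidate_ulcer_mask(cornea_green, config$preprocess, config$extract))
  border_mask <- render_border(fit, config$shape, shape)
  filt <- with_stage("filter",
    filter_eyelid_segments(cand, border_mask,
                           ratio_threshold = config$extract$ratio_threshold,
                           border_dilation_px = config$extract$border_dilation_px,
                           min_area = config$extract$min_area))

  overlay <- image * as.numeric(filt$mask)
  structure(list(ulcer_mask = filt$mask,
                 cornea_mask = disk_mask(shape, disk$center, disk$radius),
                 border_fit = fit,
                 border_mask = border_mask,
                 reflection_mask = pre$reflection_mask,
                 candidates = filt$candidates,
                 segments = filt$features,
                 rejected_segments = filt$rejected,
                 overlay = overlay,
                 edges = pre$edges,
                 stages = pre,
                 config = config,
                 image = image),
            class = "ulcer_seg")
}

#' @export
print.ulcer_seg <- function(x, ...) {
  d <- dim(x$image)
  cat(sprintf("Corneal ulcer segmentation (%d x %d image)\n", d[1L], d[2L]))
  print(x$border_fit)
  cat(sprintf("  cornea disk: radius %.1f px (%s)\n",
              x$border_fit$semi_minor *
                ifelse(x$config$cornea$radius_mode == "semi_minor", 1, 0.5),
              x$config$cornea$radius_mode))
  cat(sprintf("  ulcer pixels: %d (%.2f%% of cornea); segments kept %d, rejected %d\n",
              sum(x$ulcer_mask),
              100 * sum(x$ulcer_mask) / max(sum(x$cornea_mask), 1L),
              sum(!x$segments$rejected), nrow(x$rejected_segments)))
  invisible(x)
}

#' Summarize a segmentation result
#'
#' @param object an `ulcer_seg` object.
#' @param ... unused.
#' @return a list with the border fit, pixel areas, and the per-segment
#'   feature table, of class `summary.ulcer_seg`.
#' @export
summary.ulcer_seg <- function(object, ...) {
  structure(list(border_fit = object$border_fit,
                 ulcer_area = sum(object$ulcer_mask),
                 cornea_area = sum(object$cornea_mask),
                 n_reflection_px = sum(!object$reflection_mask),
                 segments = object$segments),
            class = "summary.ulcer_seg")
}

#' @export
print.summary.ulcer_seg <- function(x, ...) {
  print(x$border_fit)
  cat(sprintf("cornea area %d px; ulcer area %d px; reflection pixels %d\n",
              x$cornea_area, x$ulcer_area, x$n_reflection_px))
  if (nrow(x$segments)) {
    cat("segments:\n")
    print(x$segments, row.names = FALSE, digits = 3)
  } else cat("no candidate segments\n")
  invisible(x)
}

#' Plot a segmentation result
#'
#' Shows the original image with the recognized eye border, the cornea-disk
#' outline, and the final ulcer mask painted over it.
#'
#' @param x an `ulcer_seg` object.
#' @param ... passed to [graphics::plot.default()] (e.g. `main`).
#' @export
plot.ulcer_seg <- function(x, ...) {
  img <- x$image
  paint <- function(mask, col) {
    for (ch in 1:3) {
      m <- img[, , ch]
      m[mask] <- col[ch]
      img[, , ch] <<- m
    }
  }
  paint(x$border_mask, c(1, 1, 0))
  wide <- x$ulcer_mask & !shift_mask(x$ulcer_mask, 1L, 0L) |
    x$ulcer_mask & !shift_mask(x$ulcer_mask, 0L, 1L)
  paint(wide, c(1, 0, 0))
  d <- dim(img)
  graphics::plot.default(0, 0, type = "n", xlim = c(0, d[2L]),
                         ylim = c(0, d[1L]), asp = 1, xlab = "col",
                         ylab = "row", yaxs = "i", xaxs = "i", ...)
  graphics::rasterImage(grDevices::as.raster(img), 0, 0, d[2L], d[1L])
  invisible(x)
}
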