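# Nested control objects mirror the pipeline stages. Each *_control()
# validates its own block; seg_control() assembles the full configuration.
# read_config() merges a YAML file over the defaults and rejects unknown keys.

#' Preprocessing parameters
#'
#' @param gaussian_sigma standard deviation, in pixels, of the Gaussian
#'   low-pass filter applied to the green channel before masking. Default 2.
#' @param closing_radius radius, in pixels, of the disk structuring element
#'   used for morphological closing of the specular-reflection mask and of the
#'   binarized green image. Default 5.
#' @param threshold_method `"otsu"` for a per-image Otsu threshold on the
#'   squared intensities, or `"fixed"` to use `fixed_threshold`.
#' @param fixed_threshold threshold on the squared intensities in \[0, 1\],
#'   used only when `threshold_method = "fixed"`.
#' @param ellipse_dilation_factor multiplicative dilation of both semi-axes of
#'   the elliptical pre-mask, in \[1, 2\]. Default 1.15, so the pre-mask does
#'   not clip the true eye border.
#' @param max_reflection_fraction specular highlights are compact; if the
#'   thresholded reflection region covers more than this fraction of the
#'   frame the split is rejected as non-specular (typically the illuminated
#'   eye itself, on a reflection-free image) and an all-true mask is
#'   returned with a warning. Default 0.25.
#' @return a list of class `preprocess_control`.
#' @export
preprocess_control <- function(gaussian_sigma = 2,
                               closing_radius = 5L,
                               threshold_method = c("otsu", "fixed"),
                               fixed_threshold = 0.5,
                               ellipse_dilation_factor = 1.15,
                               max_reflection_fraction = 0.25) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(is.numeric(gaussian_sigma), gaussian_sigma > 0,
            is.numeric(closing_radius), closing_radius >= 1,
            is.numeric(fixed_threshold), fixed_threshold >= 0,
            fixed_threshold <= 1,
            ellipse_dilation_factor >= 1, ellipse_dilation_factor <= 2,
            max_reflection_fraction > 0, max_reflection_fraction <= 1)
  structure(list(gaussian_sigma = gaussian_sigma,
                 closing_radius = as.integer(closing_radius),
                 threshold_method = threshold_method,
                 fixed_threshold = fixed_threshold,
                 ellipse_dilation_factor = ellipse_dilation_factor,
                 max_reflection_fraction = max_reflection_fraction),
            class = "preprocess_control")
}

#' Gielis Superformula shape parameters
#'
#' The polar-curve family
#' \deqn{r(\varphi) = \left[\,|\cos(m\varphi/4)/a|^{n_2} +
#'   |\sin(m\varphi/4)/b|^{n_3}\,\right]^{-1/n_1}}
#' with the defaults `n1 = n2 = n3 = 1`, `m = 2` traces the lens-shaped eye
#' aperture outline used as the Hough template. `a` and `b` are kept at 1;
#' anisotropy is carried by per-axis pixel scales at template generation.
#'
#' @param a,b shape denominators, must be positive. Default 1.
#' @param m rotational symmetry parameter. Default 2 (eye shape).
#' @param n1,n2,n3 exponents; `n1` must be nonzero. Default 1.
#' @param n_points number of samples along the curve when a discrete template
#'   is built; at least 64. Default 192.
#' @return a list of class `gielis_params`.
#' @export
gielis_params <- function(a = 1, b = 1, m = 2, n1 = 1, n2 = 1, n3 = 1,
                          n_points = 192L) {
  stopifnot(a > 0, b > 0, n1 != 0, n_points >= 64)
  structure(list(a = a, b = b, m = m, n1 = n1, n2 = n2, n3 = n3,
                 n_points = as.integer(n_points)),
            class = "gielis_params")
}

#' Hough search-space parameters
#'
#' Pose space for eye-border recognition: candidate centers on a stride grid,
#' semi-axes on regular grids over per-axis ranges, and a small rotation
#' sweep. Ranges given as fractions in (0, 1\] are interpreted relative to
#' half the corresponding image dimension at fit time; values > 1 are taken
#' as pixels.
#'
#' @param row_scale_range length-2 numeric, range of the vertical semi-axis
#'   (semi-minor for a landscape eye). Default `c(0.25, 0.75)` of H/2.
#' @param col_scale_range length-2 numeric, range of the horizontal semi-axis.
#'   Default `c(0.25, 0.75)` of W/2.
#' @param scale_steps grid points per scale axis. Default 12.
#' @param rotation_range length-2 numeric, radians. Default +/- 10 degrees.
#' @param rotation_steps grid points for rotation; 1 reproduces a
#'   rotation-free search. Default 5.
#' @param center_stride accumulator grid stride for the coarse center search,
#'   in pixels; a refinement pass at stride 1 runs around the coarse peak.
#'   Default 2.
#' @param min_vote_fraction recognition-failure cutoff on the winning cell's
#'   matched fraction of template points. Default 0.15.
#' @return a list of class `hough_control`.
#' @export
hough_control <- function(row_scale_range = c(0.25, 0.75),
                          col_scale_range = c(0.25, 0.75),
                          scale_steps = 12L,
                          rotation_range = c(-10, 10) * pi / 180,
                          rotation_steps = 5L,
                          center_stride = 2L,
                          min_vote_fraction = 0.15) {
  stopifnot(length(row_scale_range) == 2L, diff(row_scale_range) >= 0,
            row_scale_range[1L] > 0,
            length(col_scale_range) == 2L, diff(col_scale_range) >= 0,
            col_scale_range[1L] > 0,
            scale_steps >= 1, rotation_steps >= 1, center_stride >= 1,
            length(rotation_range) == 2L, diff(rotation_range) >= 0,
            min_vote_fraction >= 0, min_vote_fraction <= 1)
  structure(list(row_scale_range = as.numeric(row_scale_range),
                 col_scale_range = as.numeric(col_scale_range),
                 scale_steps = as.integer(scale_steps),
                 rotation_range = as.numeric(rotation_range),
                 rotation_steps = as.integer(rotation_steps),
                 center_stride = as.integer(center_stride),
                 min_vote_fraction = min_vote_fraction),
            class = "hough_control")
}

#' Cornea-disk construction parameters
#'
#' @param radius_mode `"half_semi_minor"` takes the disk diameter equal to
#'   the recognized border's semi-minor axis (radius = semi-minor / 2);
#'   `"semi_minor"` takes the radius equal to the semi-minor axis, so the
#'   disk spans the full aperture height, as the cornea does in a typical
#'   slit-lamp framing. The full pipeline defaults to `"semi_minor"`.
#' @param min_radius guard: radii below this many pixels are rejected as
#'   "cornea too small". Default 5.
#' @return a list of class `cornea_control`.
#' @export
cornea_control <- function(radius_mode = c("semi_minor", "half_semi_minor"),
                           min_radius = 5) {
  radius_mode <- match.arg(radius_mode)
  stopifnot(min_radius >= 0)
  structure(list(radius_mode = radius_mode, min_radius = min_radius),
            class = "cornea_control")
}

#' Ulcer-candidate filtering parameters
#'
#' @param ratio_threshold semi-major / semi-minor elongation above which a
#'   border-contacting segment is rejected as eyelid stain. Default 3.
#' @param border_dilation_px dilation, in pixels (Chebyshev), applied to a
#'   segment before testing contact with the rendered eye border; absorbs
#'   rasterization gaps. Default 2.
#' @param min_contrast minimum difference between mean foreground and mean
#'   background green intensity (un-squared scale, within the cornea support)
#'   for the candidate mask to be kept; below it the cornea is considered
#'   fluorescein-free and the mask is empty. Default 0.10.
#' @param min_area candidate components smaller than this many pixels are
#'   dropped as sensor-noise specks before feature analysis. Default 4.
#' @return a list of class `extract_control`.
#' @export
extract_control <- function(ratio_threshold = 3,
                            border_dilation_px = 2L,
                            min_contrast = 0.10,
                            min_area = 4L) {
  stopifnot(ratio_threshold >= 1, border_dilation_px >= 0,
            min_contrast >= 0, min_contrast <= 1, min_area >= 1)
  structure(list(ratio_threshold = ratio_threshold,
                 border_dilation_px = as.integer(border_dilation_px),
                 min_contrast = min_contrast,
                 min_area = as.integer(min_area)),
            class = "extract_control")
}

#' Full pipeline configuration
#'
#' Assembles the per-stage control blocks used by [segment_ulcer()] and the
#' batch runners.
#'
#' @param preprocess,shape,hough,cornea,extract stage control objects; see
#'   [preprocess_control()], [gielis_params()], [hough_control()],
#'   [cornea_control()], [extract_control()].
#' @return a list of class `seg_control`.
#' @export
seg_control <- function(preprocess = preprocess_control(),
                        shape = gielis_params(),
                        hough = hough_control(),
                        cornea = cornea_control(),
                        extract = extract_control()) {
  stopifnot(inherits(preprocess, "preprocess_control"),
            inherits(shape, "gielis_params"),
            inherits(hough, "hough_control"),
            inherits(cornea, "cornea_control"),
            inherits(extract, "extract_control"))
  structure(list(preprocess = preprocess, shape = shape, hough = hough,
                 cornea = cornea, extract = extract),
            class = "seg_control")
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain any subset of the blocks `preprocess`, `shape`,
#' `hough`, `cornea`, `extract`; given fields override the defaults and every
#' unknown block or field is an error (fail-fast validation). `rotation_range`
#' may be given in degrees under the key `rotation_range_deg`.
#'
#' @param path YAML file path.
#' @return a validated `seg_control` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  builders <- list(preprocess = preprocess_control,
                   shape = gielis_params,
                   hough = hough_control,
                   cornea = cornea_control,
                   extract = extract_control)
  unknown <- setdiff(names(raw), names(builders))
  if (length(unknown))
    stop("unknown config block(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  blocks <- list()
  for (nm in names(builders)) {
    args <- raw[[nm]]
    if (is.null(args)) args <- list()
    if (nm == "hough" && !is.null(args$rotation_range_deg)) {
      args$rotation_range <- as.numeric(args$rotation_range_deg) * pi / 180
      args$rotation_range_deg <- NULL
    }
    allowed <- names(formals(builders[[nm]]))
    bad <- setdiff(names(args), allowed)
    if (length(bad))
      stop(sprintf("unknown field(s) in config block '%s': %s",
                   nm, paste(bad, collapse = ", ")), call. = FALSE)
    blocks[[nm]] <- do.call(builders[[nm]], args)
  }
  seg_control(preprocess = blocks$preprocess, shape = blocks$shape,
              hough = blocks$hough, cornea = blocks$cornea,
              extract = blocks$extract)
}
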