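#' @useDynLib ulcerseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Images are plain base-R structures throughout the package:
#   * an RGB image is an H x W x 3 double array, values in [0, 1],
#     channels ordered red, green, blue;
#   * a grayscale image is an H x W double matrix in [0, 1];
#   * a mask is an H x W logical matrix (TRUE = foreground).
# Pixel coordinates are (row, col), 1-based as usual in R; all geometry
# below is written against pixel centers at integer coordinates.

MIN_IMAGE_DIM <- 64L

#' Validate an RGB ocular-surface image
#'
#' Checks that `x` is an H x W x 3 numeric array with values in \[0, 1\] and
#' both spatial dimensions at least 64 pixels. Returns the (unmodified) array
#' invisibly so it can be used in pipelines; signals an error otherwise.
#'
#' @param x object to validate.
#' @return `x`, invisibly.
#' @export
validate_rgb_image <- function(x) {
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3L] != 3L)
    stop("expected an H x W x 3 RGB array", call. = FALSE)
  if (!is.numeric(x))
    stop("RGB image must be numeric", call. = FALSE)
  d <- dim(x)
  if (d[1L] < MIN_IMAGE_DIM || d[2L] < MIN_IMAGE_DIM)
    stop(sprintf("image too small (%d x %d); need at least %d x %d",
                 d[1L], d[2L], MIN_IMAGE_DIM, MIN_IMAGE_DIM), call. = FALSE)
  rng <- range(x)
  if (is.na(rng[1L]) || rng[1L] < 0 || rng[2L] > 1)
    stop("RGB intensities must lie in [0, 1] with no missing values",
         call. = FALSE)
  invisible(x)
}

check_mask <- function(mask, ref = NULL, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("%s must be a logical matrix", arg), call. = FALSE)
  if (!is.null(ref)) {
    rd <- if (is.matrix(ref)) dim(ref) else dim(ref)[1:2]
    if (!identical(dim(mask), rd))
      stop(sprintf("%s dimensions (%d x %d) do not match image (%d x %d)",
                   arg, nrow(mask), ncol(mask), rd[1L], rd[2L]), call. = FALSE)
  }
  invisible(mask)
}

# EBImage stores images transposed (x = column, y = row); these two helpers
# confine the convention flip to one place.
as_ebi <- function(m) EBImage::Image(t(m))
from_ebi <- function(im) t(EBImage::imageData(im))

#' Read an eye photograph as a normalized RGB array
#'
#' Reads PNG, JPEG or TIFF and returns an H x W x 3 double array in \[0, 1\].
#' 8-bit inputs are divided by 255 by the decoders; grayscale inputs are
#' replicated across channels; an alpha channel, if present, is dropped.
#'
#' @param path file path; format inferred from the extension.
#' @return H x W x 3 numeric array, validated.
#' @export
read_eye_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png  = png::readPNG(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    tif  = ,
    tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop("the 'tiff' package is required to read TIFF files", call. = FALSE)
      tiff::readTIFF(path)
    },
    stop("unsupported image format: .", ext, call. = FALSE)
  )
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (dim(x)[3L] > 3L) x <- x[, , 1:3, drop = FALSE]
  x[] <- pmin(pmax(x, 0), 1)
  validate_rgb_image(x)
  x
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground pixels are written as 255, background as 0.
#'
#' @param mask logical matrix.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  check_mask(mask)
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' Pixels at intensity > 0.5 become TRUE. Multi-channel PNGs are reduced by
#' their first channel.
#'
#' @param path PNG file path.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L) x <- x[, , 1L]
  x > 0.5
}

#' Write an RGB array as PNG
#'
#' @param image H x W x 3 array in \[0, 1\].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rgb <- function(image, path) {
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}
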