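# Gielis Superformula shape model. The polar curve
#   r(phi) = [ |cos(m phi/4)/a|^n2 + |sin(m phi/4)/b|^n3 ]^(-1/n1)
# with n1 = n2 = n3 = 1, m = 2 traces a lens-shaped outline with sharp
# lateral corners -- the eye-aperture template used by the recognizer.

#' Superformula radial distance
#'
#' Evaluates the Gielis Superformula radius at polar angle(s) `phi`.
#'
#' @param phi polar angle(s), radians.
#' @param p a [gielis_params()] object.
#' @return numeric vector of radii, strictly positive for valid parameters.
#' @export
gielis_radius <- function(phi, p = gielis_params()) {
  t1 <- abs(cos(p$m * phi / 4) / p$a)^p$n2
  t2 <- abs(sin(p$m * phi / 4) / p$b)^p$n3
  s <- t1 + t2
  if (any(s == 0))
    stop("undefined radius: both Superformula terms vanish", call. = FALSE)
  s^(-1 / p$n1)
}

# Angular span after which the Cartesian curve closes: the smallest multiple
# of 2*pi that is also a multiple of the radial period 4*pi/m, i.e. 2*pi*k
# with k the smallest positive integer making k*m/2 an integer.
gielis_period <- function(p) {
  for (k in 1:64) if (abs(k * p$m / 2 - round(k * p$m / 2)) < 1e-9)
    return(2 * pi * k)
  2 * pi * 64
}

# Maximum |col| and |row| extent of the unit-scale curve, found numerically.
gielis_extents <- function(p) {
  phi <- seq(0, gielis_period(p), length.out = 4096L)
  r <- gielis_radius(phi, p)
  c(row = max(abs(r * sin(phi))), col = max(abs(r * cos(phi))))
}

#' Discretized Superformula template
#'
#' Samples `phi` uniformly over one full closure period of the curve, maps to
#' Cartesian offsets `(row, col) = (r sin(phi) * scale_row,
#' r cos(phi) * scale_col)`, rotates by `rotation`, and recenters the point
#' set to zero mean. The independent row/column scaling realizes the
#' semi-minor/semi-major anisotropy of the eye aperture.
#'
#' @param p a [gielis_params()] object (`p$n_points` curve samples).
#' @param scale_row,scale_col per-axis pixel scales.
#' @param rotation rotation angle, radians.
#' @return a list of class `shape_template` with elements `points`
#'   (n x 2 matrix of `(row, col)` offsets) and `n_points`.
#' @export
gielis_template <- function(p = gielis_params(), scale_row = 1, scale_col = 1,
                            rotation = 0) {
  stopifnot(scale_row > 0, scale_col > 0)
  phi <- seq(0, gielis_period(p), length.out = p$n_points + 1L)[-(p$n_points + 1L)]
  r <- gielis_radius(phi, p)
  col <- r * cos(phi) * scale_col
  row <- r * sin(phi) * scale_row
  if (rotation != 0) {
    cs <- cos(rotation); sn <- sin(rotation)
    col2 <- col * cs - row * sn
    row2 <- col * sn + row * cs
    col <- col2; row <- row2
  }
  pts <- cbind(row = row - mean(row), col = col - mean(col))
  structure(list(points = pts, n_points = p$n_points),
            class = "shape_template")
}

#' Recognized eye-border pose
#'
#' Constructor for the pose of a recognized (or ground-truth) eye border:
#' center, per-axis semi-axes, rotation and vote statistics. `semi_major` and
#' `semi_minor` are the larger and smaller of the two semi-axes; by
#' convention the column (horizontal) axis carries the semi-major for an
#' unrotated eye.
#'
#' @param center_row,center_col border center, pixels.
#' @param axis_row,axis_col vertical and horizontal semi-axes, pixels (> 0).
#' @param rotation rotation, radians. Default 0.
#' @param votes accumulator votes behind the fit (NA for ground truth).
#' @param n_template number of rasterized template points voted with.
#' @return a list of class `eye_border_fit` with fields `center`,
#'   `axis_row`, `axis_col`, `semi_major`, `semi_minor`, `rotation`,
#'   `votes`, `vote_fraction`.
#' @export
eye_border_fit <- function(center_row, center_col, axis_row, axis_col,
                           rotation = 0, votes = NA_real_,
                           n_template = NA_real_) {
  stopifnot(axis_row > 0, axis_col > 0)
  vf <- if (is.na(votes) || is.na(n_template)) NA_real_
        else min(1, votes / n_template)
  structure(list(center = c(row = center_row, col = center_col),
                 axis_row = axis_row, axis_col = axis_col,
                 semi_major = max(axis_row, axis_col),
                 semi_minor = min(axis_row, axis_col),
                 rotation = rotation, votes = votes, vote_fraction = vf),
            class = "eye_border_fit")
}

#' @export
print.eye_border_fit <- function(x, ...) {
  cat(sprintf(paste0("Eye border fit: center (%.1f, %.1f), semi-axes ",
                     "%.1f x %.1f px, rotation %.1f deg"),
              x$center[1L], x$center[2L], x$semi_minor, x$semi_major,
              x$rotation * 180 / pi))
  if (!is.na(x$vote_fraction))
    cat(sprintf(", vote fraction %.2f", x$vote_fraction))
  cat("\n")
  invisible(x)
}

#' Cornea disk from a recognized eye border
#'
#' The cornea sits directly in front of the iris and pupil; its disk is
#' centered on the recognized border's center. In `"half_semi_minor"` mode
#' the disk *diameter* equals the border's semi-minor axis (radius =
#' semi-minor / 2); in `"semi_minor"` mode the *radius* equals the semi-minor
#' axis, so the disk spans the full aperture height.
#'
#' @param fit an [eye_border_fit()] with `semi_minor > 0`.
#' @param radius_mode `"half_semi_minor"` (default) or `"semi_minor"`.
#' @return a list of class `cornea_disk` with `center` and `radius` (pixels).
#' @export
cornea_disk_from_fit <- function(fit,
                                 radius_mode = c("half_semi_minor",
                                                 "semi_minor")) {
  radius_mode <- match.arg(radius_mode)
  if (!inherits(fit, "eye_border_fit")) stop("fit must be an eye_border_fit")
  if (!isTRUE(fit$semi_minor > 0))
    stop("invalid fit: semi_minor must be positive", call. = FALSE)
  r <- switch(radius_mode,
              half_semi_minor = fit$semi_minor / 2,
              semi_minor = fit$semi_minor)
  structure(list(center = fit$center, radius = r, mode = radius_mode),
            class = "cornea_disk")
}

# Filled disk rasterized over an H x W grid.
disk_mask <- function(shape, center, radius) {
  rr <- (seq_len(shape[1L]) - center[1L])^2
  cc <- (seq_len(shape[2L]) - center[2L])^2
  outer(rr, cc, `+`) <= radius^2
}
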