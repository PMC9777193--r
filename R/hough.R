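# Eye-border recognition: a generalized Hough transform over Gielis
# templates. Edge pixels vote for candidate centers through the inverted
# template (dual-template voting); the accumulator maximum over all
# (scale_row, scale_col, rotation) cells defines the fit, followed by a
# stride-1 center refinement around the coarse peak.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Integer template offsets, rasterized with unit thickness (rounded and
# deduplicated). Returns a 2-column integer matrix.
raster_offsets <- function(template) {
  pts <- round(template$points)
  uniq <- !duplicated(pts)
  matrix(as.integer(pts[uniq, , drop = FALSE]), ncol = 2L,
         dimnames = list(NULL, c("row", "col")))
}

#' Hough vote accumulator for one pose cell
#'
#' Low-level voting: each edge pixel votes, through each rasterized template
#' offset, for every accumulator cell whose center lies within `tol` pixels
#' (Chebyshev) of the candidate center `edge - offset`. Cells sit on a
#' `stride`-spaced grid anchored at pixel (1, 1). Exposed so the voting rule
#' can be checked against independent implementations.
#'
#' @param edges logical H x W edge mask.
#' @param offsets integer n x 2 matrix of template `(row, col)` offsets.
#' @param stride accumulator grid stride, pixels.
#' @param tol vote tolerance band, pixels.
#' @param origin length-2 integer, grid anchor (default `c(1, 1)`).
#' @param grid_dim optional length-2 integer, number of grid cells per axis;
#'   defaults to covering the image.
#' @return integer matrix of vote counts over the center grid.
#' @export
hough_accumulate <- function(edges, offsets, stride = 1L, tol = 1L,
                             origin = c(1L, 1L), grid_dim = NULL) {
  check_mask(edges)
  idx <- which(edges, arr.ind = TRUE)
  if (is.null(grid_dim))
    grid_dim <- c(floor((nrow(edges) - origin[1L]) / stride) + 1L,
                  floor((ncol(edges) - origin[2L]) / stride) + 1L)
  hough_vote_cpp(as.integer(idx[, 1L]), as.integer(idx[, 2L]),
                 as.integer(offsets[, 1L]), as.integer(offsets[, 2L]),
                 as.integer(origin[1L]), as.integer(origin[2L]),
                 as.integer(stride), as.integer(grid_dim[1L]),
                 as.integer(grid_dim[2L]), as.integer(tol))
}

# First maximum of an accumulator under the documented tie-break:
# lowest row, then lowest col. Returns list(votes, row_idx, col_idx).
acc_peak <- function(acc) {
  m <- max(acc)
  hits <- which(acc == m, arr.ind = TRUE)
  o <- order(hits[, 1L], hits[, 2L])[1L]
  list(votes = m, i = hits[o, 1L], j = hits[o, 2L])
}

resolve_range <- function(rng, dim_px) {
  if (max(rng) <= 1) rng * dim_px / 2 else rng
}

grid_seq <- function(rng, steps) {
  if (steps == 1L) mean(rng) else seq(rng[1L], rng[2L], length.out = steps)
}

#' Recognize the eye border by generalized Hough transform
#'
#' Searches center x semi-axes x rotation for the Gielis template pose best
#' supported by the edge image: a coarse pass on a `center_stride` grid over
#' all scale/rotation cells, then a stride-1 center refinement around the
#' coarse peak. Ties are broken deterministically (lowest row, then lowest
#' col, then smallest scale, in iteration order).
#'
#' @param edges logical H x W edge mask with at least 50 TRUE pixels.
#' @param p a [gielis_params()] object.
#' @param space a [hough_control()] object.
#' @return an [eye_border_fit()] carrying votes and vote fraction.
#' @export
hough_fit_eye_border <- function(edges, p = gielis_params(),
                                 space = hough_control()) {
  check_mask(edges)
  n_edge <- sum(edges)
  if (n_edge < 50L)
    stop(sprintf("insufficient edge evidence (%d edge pixels, need >= 50)",
                 n_edge), call. = FALSE)
  H <- nrow(edges); W <- ncol(edges)
  ext <- gielis_extents(p)
  row_axes <- grid_seq(resolve_range(space$row_scale_range, H),
                       space$scale_steps)
  col_axes <- grid_seq(resolve_range(space$col_scale_range, W),
                       space$scale_steps)
  rots <- grid_seq(space$rotation_range, space$rotation_steps)
  stride <- space$center_stride

  best <- NULL
  # iteration order fixes the scale/rotation tie-break: smaller scales and
  # rotations earlier, replacement only on strictly more votes
  for (rot in rots) for (ar in row_axes) for (ac in col_axes) {
    tmpl <- gielis_template(p, scale_row = ar / ext["row"],
                            scale_col = ac / ext["col"], rotation = rot)
    off <- raster_offsets(tmpl)
    acc <- hough_accumulate(edges, off, stride = stride, tol = 1L)
    pk <- acc_peak(acc)
    if (is.null(best) || pk$votes > best$votes) {
      best <- list(votes = pk$votes,
                   center = c(1L + (pk$i - 1L) * stride,
                              1L + (pk$j - 1L) * stride),
                   axis_row = ar, axis_col = ac, rotation = rot,
                   offsets = off)
    }
  }

  # refinement: stride-1 center search in a small window around the coarse
  # peak, jointly with half-grid-step scale perturbations of the winning
  # scale/rotation cell
  step_r <- if (length(row_axes) > 1L) diff(row_axes[1:2]) else 0
  step_c <- if (length(col_axes) > 1L) diff(col_axes[1:2]) else 0
  org <- pmax(best$center - (stride + 1L), 1L)
  n_ref <- pmin(best$center + stride + 1L, c(H, W)) - org + 1L
  for (dar in c(-0.5, 0, 0.5) * step_r) for (dac in c(-0.5, 0, 0.5) * step_c) {
    ar <- best$axis_row + dar
    ac <- best$axis_col + dac
    if (ar <= 0 || ac <= 0) next
    off <- if (dar == 0 && dac == 0) best$offsets else
      raster_offsets(gielis_template(p, scale_row = ar / ext["row"],
                                     scale_col = ac / ext["col"],
                                     rotation = best$rotation))
    acc <- hough_accumulate(edges, off, stride = 1L, tol = 1L,
                            origin = org, grid_dim = n_ref)
    pk <- acc_peak(acc)
    if (pk$votes > best$refined_votes %||% -1) {
      best$refined_votes <- pk$votes
      best$refined <- list(center = c(org[1L] + pk$i - 1L,
                                      org[2L] + pk$j - 1L),
                           axis_row = ar, axis_col = ac, offsets = off)
    }
  }
  best$votes <- best$refined_votes
  best$center <- best$refined$center
  best$axis_row <- best$refined$axis_row
  best$axis_col <- best$refined$axis_col
  best$offsets <- best$refined$offsets

  n_tmpl <- nrow(best$offsets)
  fit <- eye_border_fit(best$center[1L], best$center[2L],
                        axis_row = best$axis_row, axis_col = best$axis_col,
                        rotation = best$rotation, votes = best$votes,
                        n_template = n_tmpl)
  if (fit$vote_fraction < space$min_vote_fraction)
    stop(sprintf("no eye border found (vote fraction %.3f < %.3f)",
                 fit$vote_fraction, space$min_vote_fraction), call. = FALSE)
  fit
}

# Pixels strictly inside the fitted closed curve. The Gielis curves used
# here are star-shaped about their center, so a pixel is inside iff its
# radius in unit-curve coordinates does not exceed r(phi).
fill_border_impl <- function(fit, p, shape) {
  ext <- gielis_extents(p)
  sr <- fit$axis_row / ext["row"]
  sc <- fit$axis_col / ext["col"]
  H <- shape[1L]; W <- shape[2L]
  dr <- seq_len(H) - fit$center[1L]
  dc <- seq_len(W) - fit$center[2L]
  rowm <- matrix(dr, H, W)
  colm <- matrix(dc, H, W, byrow = TRUE)
  if (fit$rotation != 0) {
    cs <- cos(-fit$rotation); sn <- sin(-fit$rotation)
    colr <- colm * cs - rowm * sn
    rowr <- colm * sn + rowm * cs
    colm <- colr; rowm <- rowr
  }
  qr <- rowm / sr
  qc <- colm / sc
  rho <- sqrt(qr^2 + qc^2)
  phi <- atan2(qr, qc)
  rho <= gielis_radius(phi, p)
}

shift_mask <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  out <- matrix(FALSE, H, W)
  rs <- max(1, 1 + dr):min(H, H + dr)
  cs <- max(1, 1 + dc):min(W, W + dc)
  out[rs, cs] <- m[rs - dr, cs - dc]
  out
}

#' Fill the recognized eye border
#'
#' Rasterizes the filled interior of the fitted closed Gielis curve, clipped
#' to the image bounds.
#'
#' @param fit an [eye_border_fit()].
#' @param p a [gielis_params()] object.
#' @param shape length-2 integer `(H, W)`.
#' @return logical H x W mask of the filled region.
#' @export
fill_border <- function(fit, p = gielis_params(), shape) {
  stopifnot(inherits(fit, "eye_border_fit"), length(shape) == 2L)
  fill_border_impl(fit, p, shape)
}

#' Render the recognized eye border outline
#'
#' 1-pixel-thick closed outline of the fitted shape: the filled region minus
#' its 4-neighbor erosion (an 8-connected boundary), clipped to bounds.
#'
#' @inheritParams fill_border
#' @return logical H x W mask of the outline.
#' @export
render_border <- function(fit, p = gielis_params(), shape) {
  f <- fill_border(fit, p, shape)
  if (!any(f)) {
    warning("fitted border lies entirely outside the image", call. = FALSE)
    return(f)
  }
  inner <- f & shift_mask(f, 1L, 0L) & shift_mask(f, -1L, 0L) &
    shift_mask(f, 0L, 1L) & shift_mask(f, 0L, -1L)
  f & !inner
}
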