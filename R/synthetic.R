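# Seeded synthetic fluorescein-eye scenes with exhaustive ground truth.
# A scene emulates the salient structure of a cobalt-blue slit-lamp
# photograph: a dark background; a lens-shaped (Gielis) eye aperture with a
# blue-dominant sclera/illumination field; a darker cornea/iris disk spanning
# the aperture height; a green tear-film strip along the lid margins (the
# fluorescein meniscus that outlines the aperture); bright-green ulcer blobs
# inside the cornea; saturated specular highlights; optionally an elongated
# lid-margin stain arc; additive Gaussian sensor noise.

SCENE_COLORS <- list(background = c(0.02, 0.03, 0.03),
                     sclera     = c(0.10, 0.15, 0.18),
                     iris       = c(0.06, 0.08, 0.15),
                     tear_band  = c(0.12, 0.65, 0.18),
                     eyelid     = c(0.15, 0.80, 0.18),
                     reflection = c(1.00, 1.00, 1.00))

# Run code under a fixed seed, restoring the caller's RNG state.
local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Synthetic scene parameters
#'
#' Fully describes one synthetic fluorescein-eye scene. All geometry is in
#' pixels, intensities in \[0, 1\]. Ulcer blobs are validated to lie inside
#' the ground-truth cornea disk (with their edge ramp).
#'
#' @param image_size `(H, W)`. Default `c(240, 320)`.
#' @param center eye-border center `(row, col)`; default image center.
#' @param semi_major,semi_minor eye-border semi-axes. Defaults 100 and 60.
#' @param rotation border rotation, radians. Default 0.
#' @param ulcer_blobs list of blobs, each `list(center = c(row, col),
#'   semi_axes = c(sr, sc), peak = green peak)`. Empty list = healthy eye.
#' @param n_reflections number of specular highlight disks. Default 2.
#' @param reflection_radius_range radius range, pixels. Default `c(2, 4)`.
#' @param eyelid_arc `NULL`, or `list(thickness, extent, intensity,
#'   position)`: a lid-margin stain strip of the given radial thickness (px),
#'   angular extent (radians) and green intensity, centered at polar position
#'   `position` (radians) on the border.
#' @param tear_band_px radial thickness of the tear-film strip along the
#'   whole lid margin; 0 disables it. Default 6.
#' @param tear_band_green green intensity of the tear-film strip. Default 0.75.
#' @param blob_ramp_px spatial half-width of the cosine edge ramp of ulcer
#'   blobs; the ground-truth mask is the half-peak level set. Default 2.
#' @param noise_sigma additive Gaussian noise standard deviation. Default 0.01.
#' @param cornea_radius_mode `"semi_minor"` (disk spans the aperture height;
#'   default) or `"half_semi_minor"`.
#' @param min_contrast asserted minimum difference between mean green inside
#'   the ulcer and in the rest of the cornea. Default 0.2.
#' @param seed integer seed driving reflection placement and noise.
#' @return a list of class `scene_params`.
#' @export
scene_params <- function(image_size = c(240L, 320L),
                         center = image_size / 2,
                         semi_major = 100, semi_minor = 60,
                         rotation = 0,
                         ulcer_blobs = list(),
                         n_reflections = 2L,
                         reflection_radius_range = c(2, 4),
                         eyelid_arc = NULL,
                         tear_band_px = 6,
                         tear_band_green = 0.75,
                         blob_ramp_px = 2,
                         noise_sigma = 0.01,
                         cornea_radius_mode = c("semi_minor",
                                                "half_semi_minor"),
                         min_contrast = 0.2,
                         seed = 0L) {
  cornea_radius_mode <- match.arg(cornea_radius_mode)
  stopifnot(length(image_size) == 2L, all(image_size >= 64L),
            semi_major > 0, semi_minor > 0, semi_major >= semi_minor,
            n_reflections >= 0, noise_sigma >= 0, tear_band_px >= 0,
            blob_ramp_px >= 0, min_contrast >= 0)
  cornea_r <- switch(cornea_radius_mode, semi_minor = semi_minor,
                     half_semi_minor = semi_minor / 2)
  for (b in ulcer_blobs) {
    stopifnot(length(b$center) == 2L, length(b$semi_axes) == 2L,
              all(b$semi_axes > 0), b$peak > 0, b$peak <= 1)
    reach <- sqrt(sum((b$center - center)^2)) + max(b$semi_axes) + blob_ramp_px
    if (reach > cornea_r)
      stop(sprintf(paste0("ulcer blob at (%.0f, %.0f) extends outside the ",
                          "cornea disk (reach %.1f px > radius %.1f px)"),
                   b$center[1L], b$center[2L], reach, cornea_r), call. = FALSE)
  }
  if (!is.null(eyelid_arc)) {
    defaults <- list(thickness = 9, extent = 1.2, intensity = 0.8,
                     position = pi / 2)
    eyelid_arc <- utils::modifyList(defaults, eyelid_arc)
    stopifnot(eyelid_arc$thickness > 0, eyelid_arc$extent > 0,
              eyelid_arc$intensity > 0, eyelid_arc$intensity <= 1)
  }
  border <- eye_border_fit(center[1L], center[2L], axis_row = semi_minor,
                           axis_col = semi_major, rotation = rotation)
  structure(list(image_size = as.integer(image_size), border = border,
                 cornea_radius = cornea_r,
                 cornea_radius_mode = cornea_radius_mode,
                 ulcer_blobs = ulcer_blobs,
                 n_reflections = as.integer(n_reflections),
                 reflection_radius_range = reflection_radius_range,
                 eyelid_arc = eyelid_arc, tear_band_px = tear_band_px,
                 tear_band_green = tear_band_green,
                 blob_ramp_px = blob_ramp_px, noise_sigma = noise_sigma,
                 min_contrast = min_contrast, seed = as.integer(seed)),
            class = "scene_params")
}

shrunk_fit <- function(fit, by) {
  eye_border_fit(fit$center[1L], fit$center[2L],
                 axis_row = max(fit$axis_row - by, 1),
                 axis_col = max(fit$axis_col - by, 1),
                 rotation = fit$rotation)
}

# Polar angle of every pixel in the border's unit-curve frame.
border_phi <- function(fit, p, shape) {
  ext <- gielis_extents(p)
  dr <- seq_len(shape[1L]) - fit$center[1L]
  dc <- seq_len(shape[2L]) - fit$center[2L]
  rowm <- matrix(dr, shape[1L], shape[2L])
  colm <- matrix(dc, shape[1L], shape[2L], byrow = TRUE)
  if (fit$rotation != 0) {
    cs <- cos(-fit$rotation); sn <- sin(-fit$rotation)
    colr <- colm * cs - rowm * sn
    rowr <- colm * sn + rowm * cs
    colm <- colr; rowm <- rowr
  }
  atan2(rowm / (fit$axis_row / ext["row"]), colm / (fit$axis_col / ext["col"]))
}

#' Render a synthetic fluorescein-eye scene
#'
#' Deterministic given `params` (including `params$seed`, which drives
#' specular-highlight placement and sensor noise). Returns the image and
#' every ground-truth mask.
#'
#' @param params a [scene_params()] object.
#' @return a list of class `synthetic_scene` with `image` (H x W x 3),
#'   `truth_ulcer`, `truth_cornea`, `truth_reflections`, `truth_eyelid`
#'   (logical masks), `truth_border` (an [eye_border_fit()]), and `params`.
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  shape <- params$image_size
  H <- shape[1L]; W <- shape[2L]
  p <- gielis_params()
  fit <- params$border
  col <- SCENE_COLORS

  fill <- fill_border_impl(fit, p, shape)
  band <- if (params$tear_band_px > 0)
    fill & !fill_border_impl(shrunk_fit(fit, params$tear_band_px), p, shape)
  else matrix(FALSE, H, W)
  cornea_disk_m <- disk_mask(shape, fit$center, params$cornea_radius)
  truth_cornea <- cornea_disk_m & fill

  # eyelid stain arc: a thicker strip over an angular window of the margin
  truth_eyelid <- matrix(FALSE, H, W)
  if (!is.null(params$eyelid_arc)) {
    arc <- params$eyelid_arc
    strip <- fill & !fill_border_impl(shrunk_fit(fit, arc$thickness), p, shape)
    phi <- border_phi(fit, p, shape)
    dphi <- (phi - arc$position + pi) %% (2 * pi) - pi
    truth_eyelid <- strip & abs(dphi) <= arc$extent / 2
  }

  # ulcer blobs: plateau + cosine edge ramp; truth is the half-peak level set
  blob_field <- matrix(0, H, W)
  truth_ulcer <- matrix(FALSE, H, W)
  rows <- matrix(seq_len(H), H, W)
  cols <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (b in params$ulcer_blobs) {
    d <- sqrt(((rows - b$center[1L]) / b$semi_axes[1L])^2 +
              ((cols - b$center[2L]) / b$semi_axes[2L])^2)
    wn <- params$blob_ramp_px / sqrt(prod(b$semi_axes))
    s <- ifelse(d <= 1 - wn, 1,
                ifelse(d >= 1 + wn, 0, 0.5 - 0.5 * sin((d - 1) * pi / (2 * wn))))
    blob_field <- pmax(blob_field, s * b$peak)
    truth_ulcer <- truth_ulcer | d <= 1
  }

  local_seed(params$seed, {
    # specular highlights: compact saturated disks on the sclera, clear of
    # the cornea so reflections and ulcer truth never overlap
    truth_refl <- matrix(FALSE, H, W)
    if (params$n_reflections > 0L) {
      rmax <- max(params$reflection_radius_range)
      margin <- rmax + params$tear_band_px + 2
      elig <- fill_border_impl(shrunk_fit(fit, margin), p, shape) &
        !disk_mask(shape, fit$center, params$cornea_radius + rmax + 2)
      pool <- which(elig)
      for (i in seq_len(params$n_reflections)) {
        if (!length(pool)) break
        ctr_idx <- pool[sample.int(length(pool), 1L)]
        ctr <- c((ctr_idx - 1L) %% H + 1L, (ctr_idx - 1L) %/% H + 1L)
        rad <- stats::runif(1, params$reflection_radius_range[1L],
                            params$reflection_radius_range[2L])
        truth_refl <- truth_refl | disk_mask(shape, ctr, rad)
      }
    }

    img <- array(0, dim = c(H, W, 3L))
    for (k in 1:3) {
      ch <- matrix(col$background[k], H, W)
      ch[fill] <- col$sclera[k]
      ch[truth_cornea] <- col$iris[k]
      ch[band] <- col$tear_band[k]
      if (k == 2L) ch[band] <- params$tear_band_green
      if (any(truth_eyelid)) {
        ch[truth_eyelid] <- col$eyelid[k]
        if (k == 2L) ch[truth_eyelid] <- params$eyelid_arc$intensity
      }
      if (k == 2L) ch <- pmax(ch, col$iris[2L] +
                                blob_field * (1 - col$iris[2L]))
      if (k == 1L) ch <- pmax(ch, 0.08 * (blob_field > 0.5))
      ch[truth_refl] <- col$reflection[k]
      img[, , k] <- ch
    }
    if (params$noise_sigma > 0)
      img <- img + array(stats::rnorm(length(img), 0, params$noise_sigma),
                         dim = dim(img))
    img <- pmin(pmax(img, 0), 1)

    if (any(truth_ulcer) && params$min_contrast > 0) {
      inside <- mean(img[, , 2L][truth_ulcer])
      rest <- truth_cornea & !truth_ulcer
      outside <- mean(img[, , 2L][rest])
      stopifnot("ulcer/cornea green contrast below the configured minimum" =
                  inside - outside >= params$min_contrast)
    }

    structure(list(image = img, truth_ulcer = truth_ulcer,
                   truth_cornea = truth_cornea, truth_border = fit,
                   truth_reflections = truth_refl,
                   truth_eyelid = truth_eyelid, params = params),
              class = "synthetic_scene")
  })
}

#' Generate a suite of synthetic scenes
#'
#' Samples scene parameters from difficulty-dependent distributions and
#' renders each scene. About 10% of the scenes (at least one for n >= 2) are
#' healthy eyes with no ulcer blobs.
#'
#' * `easy`: one high-contrast blob, 1-2 reflections, no lid-stain arc,
#'   noise 0.01;
#' * `medium`: 1-3 blobs, 2-4 reflections, a lid-stain arc with probability
#'   0.5, noise 0.02;
#' * `hard`: 1-3 dimmer blobs, 3-5 reflections, an arc always, small border
#'   rotation, noise 0.05.
#'
#' @param n number of scenes (>= 1).
#' @param difficulty `"easy"`, `"medium"` or `"hard"`.
#' @param seed integer master seed; per-scene seeds are drawn from it.
#' @return a list of `synthetic_scene` objects.
#' @export
generate_suite <- function(n, difficulty = c("easy", "medium", "hard"),
                           seed = 0L) {
  difficulty <- match.arg(difficulty)
  stopifnot(n >= 1)
  local_seed(seed, {
    n_healthy <- if (n >= 2L) max(1L, round(0.1 * n)) else 0L
    healthy <- rep(FALSE, n)
    if (n_healthy > 0L) healthy[sample.int(n, n_healthy)] <- TRUE
    lapply(seq_len(n), function(i) {
      H <- 240L; W <- 320L
      center <- c(H, W) / 2 + stats::runif(2, -8, 8)
      semi_major <- stats::runif(1, 85, 115)
      semi_minor <- stats::runif(1, 50, 70)
      rotation <- if (difficulty == "hard")
        stats::runif(1, -5, 5) * pi / 180 else 0
      cornea_r <- semi_minor
      n_blobs <- if (healthy[i]) 0L else switch(difficulty,
        easy = 1L, medium = sample(1:3, 1L), hard = sample(1:3, 1L))
      axes_rng <- switch(difficulty, easy = c(12, 20), medium = c(8, 18),
                         hard = c(6, 16))
      peak_rng <- switch(difficulty, easy = c(0.80, 0.90),
                         medium = c(0.70, 0.90), hard = c(0.55, 0.80))
      has_arc <- switch(difficulty, easy = FALSE,
                        medium = stats::runif(1) < 0.5, hard = TRUE)
      arc <- if (has_arc)
        list(thickness = stats::runif(1, 8, 11),
             extent = stats::runif(1, 0.8, 1.5),
             intensity = stats::runif(1, 0.7, 0.9),
             position = sample(c(pi / 2, -pi / 2), 1L))
      blobs <- lapply(seq_len(n_blobs), function(j) {
        ax <- sort(stats::runif(2, axes_rng[1L], axes_rng[2L]))
        offmax <- max(0, cornea_r - max(ax) - 2 - 6)
        # keep ulcers angularly clear of a lid-stain arc so the two stay
        # separate connected components
        repeat {
          ang <- stats::runif(1, 0, 2 * pi)
          if (is.null(arc)) break
          d <- abs((ang - arc$position + pi) %% (2 * pi) - pi)
          if (d > arc$extent / 2 + 0.8) break
        }
        off <- sqrt(stats::runif(1)) * offmax
        list(center = center + off * c(sin(ang), cos(ang)),
             semi_axes = c(ax[1L], ax[2L]),
             peak = stats::runif(1, peak_rng[1L], peak_rng[2L]))
      })
      n_refl <- switch(difficulty, easy = sample(1:2, 1L),
                       medium = sample(2:4, 1L), hard = sample(3:5, 1L))
      noise <- switch(difficulty, easy = 0.01, medium = 0.02, hard = 0.05)
      params <- scene_params(image_size = c(H, W), center = center,
                             semi_major = semi_major, semi_minor = semi_minor,
                             rotation = rotation, ulcer_blobs = blobs,
                             n_reflections = n_refl, eyelid_arc = arc,
                             noise_sigma = noise,
                             seed = sample.int(.Machine$integer.max, 1L))
      generate_scene(params)
    })
  })
}

#' Write a synthetic scene to disk
#'
#' Writes the image under `dir/images/<stem>.png` and the ground-truth masks
#' under `dir/truth/<stem>_{ulcer,cornea,reflections,eyelid}.png`.
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if needed).
#' @param stem file stem.
#' @return a manifest entry (list) with file paths and border pose, invisibly.
#' @export
write_scene <- function(scene, dir, stem) {
  stopifnot(inherits(scene, "synthetic_scene"))
  img_dir <- file.path(dir, "images"); truth_dir <- file.path(dir, "truth")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
  write_rgb(scene$image, file.path(img_dir, paste0(stem, ".png")))
  for (m in c("ulcer", "cornea", "reflections", "eyelid"))
    write_mask(scene[[paste0("truth_", m)]],
               file.path(truth_dir, paste0(stem, "_", m, ".png")))
  fit <- scene$truth_border
  invisible(list(stem = stem, image = file.path("images", paste0(stem, ".png")),
                 center = unname(fit$center), semi_major = fit$semi_major,
                 semi_minor = fit$semi_minor, rotation = fit$rotation,
                 n_blobs = length(scene$params$ulcer_blobs),
                 seed = scene$params$seed))
}
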