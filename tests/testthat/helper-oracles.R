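# Independent brute-force oracles used to freeze expected values. These are
# deliberately naive re-derivations (explicit loops, closed forms) that never
# call the code paths they check.

# Eq.-style Superformula evaluation, written out directly.
gielis_direct <- function(phi, a = 1, b = 1, m = 2, n1 = 1, n2 = 1, n3 = 1) {
  (abs(cos(m * phi / 4) / a)^n2 + abs(sin(m * phi / 4) / b)^n3)^(-1 / n1)
}

# Otsu's threshold by exhaustive search over 256 histogram cuts.
otsu_bruteforce <- function(x, levels = 256L) {
  bins <- pmin(floor(x * levels) + 1L, levels)
  best <- -Inf; best_t <- NA_real_
  for (t in 1:(levels - 1L)) {
    lo <- x[bins <= t]; hi <- x[bins > t]
    if (!length(lo) || !length(hi)) next
    v <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (v > best) { best <- v; best_t <- t / levels }
  }
  best_t
}

# Per-pixel confusion tally with an explicit double loop.
confusion_loop <- function(pred, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred))) {
    if (pred[i, j] && truth[i, j]) tp <- tp + 1L
    else if (pred[i, j] && !truth[i, j]) fp <- fp + 1L
    else if (!pred[i, j] && truth[i, j]) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, TN = tn, FP = fp, FN = fn)
}

# Moment centroid and semi-axes (2 sd along principal axes) by explicit sums.
moments_bruteforce <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  n <- nrow(idx)
  mr <- sum(idx[, 1]) / n; mc <- sum(idx[, 2]) / n
  srr <- sum((idx[, 1] - mr)^2) / n
  scc <- sum((idx[, 2] - mc)^2) / n
  src <- sum((idx[, 1] - mr) * (idx[, 2] - mc)) / n
  tr <- srr + scc; det <- srr * scc - src^2
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
  l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det, 0))
  list(centroid = c(mr, mc), semi_major = 2 * sqrt(max(l1, 0)),
       semi_minor = 2 * sqrt(max(l2, 0)), var_row = srr, var_col = scc)
}

# Generalized-Hough accumulator by triple loop: a cell gains one vote per
# template offset that has at least one edge pixel within `tol` (Chebyshev)
# of cell + offset.
hough_oracle <- function(edges, offsets, stride, tol,
                         origin = c(1L, 1L), grid_dim) {
  eidx <- which(edges, arr.ind = TRUE)
  acc <- matrix(0L, grid_dim[1], grid_dim[2])
  for (i in seq_len(grid_dim[1])) {
    cr <- origin[1] + (i - 1L) * stride
    for (j in seq_len(grid_dim[2])) {
      cc <- origin[2] + (j - 1L) * stride
      v <- 0L
      for (t in seq_len(nrow(offsets))) {
        pr <- cr + offsets[t, 1]; pc <- cc + offsets[t, 2]
        hit <- any(abs(eidx[, 1] - pr) <= tol & abs(eidx[, 2] - pc) <= tol)
        if (hit) v <- v + 1L
      }
      acc[i, j] <- v
    }
  }
  acc
}

# A flat mid-gray RGB image with given green/blue planes substituted.
flat_rgb <- function(h = 64L, w = 64L, red = 0.5, green = 0.5, blue = 0.5) {
  img <- array(0, dim = c(h, w, 3L))
  img[, , 1] <- red; img[, , 2] <- green; img[, , 3] <- blue
  img
}

# Default single-blob test scene used across files.
blob_scene <- function(seed = 1, noise = 0.01, ...) {
  generate_scene(scene_params(
    ulcer_blobs = list(list(center = c(115, 150), semi_axes = c(14, 16),
                            peak = 0.85)),
    noise_sigma = noise, seed = seed, ...))
}

expect_mask_equal <- function(a, b) expect_identical(unclass(a) & TRUE,
                                                     unclass(b) & TRUE)
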