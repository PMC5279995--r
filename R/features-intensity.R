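#' Intensity histogram features
#'
#' First-order statistics of the voxel intensities inside the mask.
#' Skewness and kurtosis are the standardized third and fourth central
#' moments (kurtosis is not excess kurtosis: a normal sample gives ~3);
#' for a constant region they are undefined and reported as `NA`.
#' Energy and entropy are computed from the intensity histogram at
#' `bin_width` HU; a constant region has entropy 0 and energy 1.
#'
#' @param volume an [image_volume()] (or bare 3D array).
#' @param mask 3D logical array on the same grid, nonempty.
#' @param bin_width histogram bin width, HU.
#' @return named numeric vector.
#' @export
intensity_features <- function(volume, mask, bin_width = 25) {
  a <- if (inherits(volume, "image_volume")) volume$data else volume
  stopifnot_mask(mask)
  v <- a[mask]
  rng <- range(v)
  p <- if (rng[2] > rng[1]) {
    breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                  ceiling(rng[2] / bin_width) * bin_width + bin_width,
                  by = bin_width)
    tab <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                                 all.inside = TRUE), length(breaks) - 1L)
    tab / sum(tab)
  } else 1
  p <- p[p > 0]
  c(int_mean = mean(v),
    int_median = stats::median(v),
    int_sd = stats::sd(v),
    int_min = rng[1],
    int_max = rng[2],
    int_skewness = skewness_pop(v),
    int_kurtosis = kurtosis_pop(v),
    int_energy = sum(p^2),
    int_entropy = -sum(p * log2(p)))
}

#' Parenchyma ring mask around a nodule
#'
#' All voxels outside the nodule within a distance of the nodule's maximum
#' radius (surface-voxel distance to the centroid) of the nodule boundary,
#' clipped to the volume. Disjoint from the nodule by construction.
#'
#' @param mask 3D logical nodule mask, nonempty.
#' @param spacing mm triple.
#' @return 3D logical ring mask.
#' @export
parenchyma_mask <- function(mask, spacing) {
  stopifnot_mask(mask)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx)
  surf <- which(surface_voxels(mask), arr.ind = TRUE)
  radii_mm <- sqrt(rowSums(sweep(sweep(surf, 2, centroid), 2, spacing, `*`)^2))
  r_vox <- max(radii_mm) / min(spacing)
  ring <- dilate_ball(mask, r_vox) & !mask
  if (!any(ring))
    stop("parenchyma ring is empty (nodule fills the volume)", call. = FALSE)
  ring
}

# central-difference gradient magnitude in mm^-1 units
#' @noRd
gradient_magnitude <- function(a, spacing) {
  gx <- (shift1(a, 1, -1L, 0) - shift1(a, 1, 1L, 0)) / (2 * spacing[1])
  gy <- (shift1(a, 2, -1L, 0) - shift1(a, 2, 1L, 0)) / (2 * spacing[2])
  gz <- (shift1(a, 3, -1L, 0) - shift1(a, 3, 1L, 0)) / (2 * spacing[3])
  sqrt(gx^2 + gy^2 + gz^2)
}

# Deterministic quasi-uniform selection of n surface points: surface
# voxels ordered by (polar angle, azimuth) about the centroid, strided.
#' @noRd
pick_surface_points <- function(mask, n) {
  surf <- which(surface_voxels(mask), arr.ind = TRUE)
  centroid <- colMeans(which(mask, arr.ind = TRUE))
  d <- sweep(surf, 2, centroid)
  r <- sqrt(rowSums(d^2))
  theta <- acos(pmin(pmax(d[, 3] / pmax(r, 1e-9), -1), 1))
  phi <- atan2(d[, 2], d[, 1])
  ord <- order(theta, phi)
  surf <- surf[ord, , drop = FALSE]
  if (nrow(surf) > n)
    surf <- surf[round(seq(1, nrow(surf), length.out = n)), , drop = FALSE]
  surf
}

# Fit I(t) = b + h * (1 - plogis(t / w)) to every profile (rows of P,
# sampled at mm offsets t) by a grid search over the shared width w with
# per-width linear least squares for (b, h). Returns per-profile width,
# height, and R^2.
#' @noRd
fit_sigmoid_profiles <- function(P, t, widths = exp(seq(log(0.05), log(10),
                                                        length.out = 30))) {
  n <- nrow(P)
  tot <- rowSums(sweep(P, 1, rowMeans(P))^2)
  best_rss <- rep(Inf, n); best_w <- rep(NA_real_, n)
  best_h <- rep(NA_real_, n); best_b <- rep(NA_real_, n)
  for (w in widths) {
    X <- cbind(1, 1 - stats::plogis(t / w))
    fit <- .lm.fit(X, t(P))
    rss <- colSums(fit$residuals^2)
    better <- rss < best_rss
    if (any(better)) {
      best_rss[better] <- rss[better]
      best_w[better] <- w
      best_b[better] <- fit$coefficients[1, better]
      best_h[better] <- fit$coefficients[2, better]
    }
  }
  r2 <- ifelse(tot > 0, 1 - best_rss / tot, 0)
  data.frame(width = best_w, height = best_h, offset = best_b, r2 = r2)
}

#' Margin (boundary sharpness) features
#'
#' At `n_normals` quasi-uniform surface points, the intensity profile along
#' the outward surface normal (estimated from the smoothed occupancy
#' gradient) is sampled over +/- `profile_halflength` mm and fit with a
#' logistic edge model `b + h * (1 - plogis(t / w))` (`t` positive
#' outward), so the fitted height `h` is the inside-minus-outside contrast
#' and `w > 0` the transition width. Widths are found by grid search over
#' (0.05, 10] mm with closed-form height/offset per candidate width;
#' profiles with non-finite fits are dropped and counted, and the sigmoid
#' features are reported missing when more than half drop. Also reports
#' gradient-magnitude statistics at the boundary surface and on the
#' one-voxel inner and outer shells, plus intensity statistics of the
#' surrounding parenchyma ring.
#'
#' @param volume an [image_volume()].
#' @param mask 3D logical array, nonempty, same grid.
#' @param n_normals number of surface sampling locations (default 800).
#' @param profile_halflength half-length of the sampled profile, mm.
#' @param ring optional precomputed [parenchyma_mask()] (on the same grid).
#' @return named numeric vector.
#' @export
margin_features <- function(volume, mask, n_normals = 800,
                            profile_halflength = 5, ring = NULL) {
  stopifnot(inherits(volume, "image_volume"))
  stopifnot_mask(mask)
  a <- volume$data; sp <- volume$spacing
  u <- smooth_gauss(mask * 1.0, 1 / sp)  # ~1 mm occupancy smoothing
  surf <- pick_surface_points(mask, n_normals)
  # outward normal = -grad(occupancy), central differences in mm
  gx <- (shift1(u, 1, -1L, 0) - shift1(u, 1, 1L, 0)) / (2 * sp[1])
  gy <- (shift1(u, 2, -1L, 0) - shift1(u, 2, 1L, 0)) / (2 * sp[2])
  gz <- (shift1(u, 3, -1L, 0) - shift1(u, 3, 1L, 0)) / (2 * sp[3])
  nrm <- cbind(-gx[surf], -gy[surf], -gz[surf])
  len <- sqrt(rowSums(nrm^2))
  keep <- len > 1e-9
  surf <- surf[keep, , drop = FALSE]
  nrm <- nrm[keep, , drop = FALSE] / len[keep]
  t_mm <- seq(-profile_halflength, profile_halflength, by = 0.5)
  # profile sample positions in continuous voxel coordinates
  P <- matrix(NA_real_, nrow(surf), length(t_mm))
  for (j in seq_along(t_mm)) {
    pos <- cbind(surf[, 1] + t_mm[j] * nrm[, 1] / sp[1],
                 surf[, 2] + t_mm[j] * nrm[, 2] / sp[2],
                 surf[, 3] + t_mm[j] * nrm[, 3] / sp[3])
    P[, j] <- interp_trilinear(a, pos)
  }
  fits <- fit_sigmoid_profiles(P, t_mm)
  ok <- is.finite(fits$width) & is.finite(fits$height)
  n_dropped <- sum(!ok)
  if (n_dropped > 0.5 * nrow(fits)) {
    sig <- c(NA_real_, NA_real_, NA_real_, NA_real_)
  } else {
    sig <- c(mean(fits$width[ok]), stats::sd(fits$width[ok]),
             mean(fits$height[ok]), stats::sd(fits$height[ok]))
  }
  # boundary gradient on a mildly smoothed image (noise-robust edge
  # strength); shell statistics on the raw gradient
  gm_smooth <- gradient_magnitude(smooth_gauss(a, 1 / sp), sp)
  gm <- gradient_magnitude(a, sp)
  bsurf <- surface_voxels(mask)
  shell_in <- bsurf
  shell_out <- dilate1(mask, "cross") & !mask
  if (is.null(ring)) {
    ring <- tryCatch(parenchyma_mask(mask, sp), error = function(e) NULL)
  }
  ring_stats <- if (!is.null(ring) && any(ring)) {
    rv <- a[ring]
    c(mean(rv), stats::sd(rv), hist_entropy(rv, bin_width = 25))
  } else c(NA_real_, NA_real_, NA_real_)
  out <- c(mar_sigmoid_width_mean_mm = sig[1],
           mar_sigmoid_width_sd_mm = sig[2],
           mar_sigmoid_height_mean_hu = sig[3],
           mar_sigmoid_height_sd_hu = sig[4],
           mar_grad_boundary_mean = mean(gm_smooth[bsurf]),
           mar_grad_boundary_sd = stats::sd(gm_smooth[bsurf]),
           mar_grad_shell_in_mean = mean(gm[shell_in]),
           mar_grad_shell_in_sd = stats::sd(gm[shell_in]),
           mar_grad_shell_out_mean = mean(gm[shell_out]),
           mar_grad_shell_out_sd = stats::sd(gm[shell_out]),
           mar_parenchyma_mean_hu = ring_stats[1],
           mar_parenchyma_sd_hu = ring_stats[2],
           mar_parenchyma_entropy = ring_stats[3])
  attr(out, "n_dropped_fits") <- n_dropped
  out
}
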