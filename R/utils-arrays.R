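# Internal 3D array helpers shared by the generator and the feature code.
# All arrays are dense base-R arrays indexed [x, y, z]; spacings are mm.

#' @noRd
stopifnot_mask <- function(mask) {
  if (!is.array(mask) || length(dim(mask)) != 3L)
    stop("mask must be a 3D array", call. = FALSE)
  if (!any(mask)) stop("mask is empty", call. = FALSE)
  invisible(TRUE)
}

# Derive a per-record random seed from a master seed and small integer ids.
# Keeps results reproducible under partial regeneration of a cohort.
#' @noRd
derive_seed <- function(master, ...) {
  ids <- c(...)
  s <- as.double(master %% 2147483647L)
  for (k in ids) {
    s <- (s * 48271 + as.double(k) * 8191 + 1) %% 2147483647
  }
  as.integer(s)
}

# Shift a 3D array by one voxel along an axis, filling with `fill`.
#' @noRd
shift1 <- function(a, axis, s, fill = FALSE) {
  d <- dim(a)
  out <- array(fill, d)
  n <- d[axis]
  if (abs(s) >= n) return(out)
  src <- vector("list", 3L); dst <- vector("list", 3L)
  for (ax in 1:3) { src[[ax]] <- seq_len(d[ax]); dst[[ax]] <- seq_len(d[ax]) }
  if (s >= 0) { dst[[axis]] <- (s + 1L):n; src[[axis]] <- 1L:(n - s) }
  else        { dst[[axis]] <- 1L:(n + s); src[[axis]] <- (1L - s):n }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

# One-voxel morphological dilation. kind "box" uses the 26-neighbourhood
# (separable max filter), kind "cross" the 6-neighbourhood.
#' @noRd
dilate1 <- function(mask, kind = c("box", "cross")) {
  kind <- match.arg(kind)
  if (kind == "box") {
    out <- mask
    for (ax in 1:3)
      out <- out | shift1(out, ax, 1L) | shift1(out, ax, -1L)
    out
  } else {
    out <- mask
    for (ax in 1:3)
      out <- out | shift1(mask, ax, 1L) | shift1(mask, ax, -1L)
    out
  }
}

# One-voxel erosion; voxels outside the grid count as background, so
# mask voxels on the grid border are always eroded.
#' @noRd
erode1 <- function(mask, kind = c("box", "cross")) {
  kind <- match.arg(kind)
  out <- mask
  if (kind == "box") {
    for (ax in 1:3)
      out <- out & shift1(out, ax, 1L) & shift1(out, ax, -1L)
  } else {
    for (ax in 1:3)
      out <- out & shift1(mask, ax, 1L) & shift1(mask, ax, -1L)
  }
  out
}

# Approximate Euclidean dilation by radius r (voxels): alternate 6- and
# 26-neighbourhood steps, which approximates a Euclidean ball by an
# octagonal-metric ball (worst-case radial error below 10%).
#' @noRd
dilate_ball <- function(mask, r) {
  r <- max(0, r)
  n <- floor(r)
  out <- mask
  if (n >= 1) {
    for (k in seq_len(n)) {
      kind <- if (k %% 2L == 1L) "cross" else "box"
      out <- dilate1(out, kind)
    }
  }
  out
}

# Surface voxels: in the mask but with at least one 6-neighbour outside.
#' @noRd
surface_voxels <- function(mask) {
  mask & !erode1(mask, "cross")
}

# Extract the largest 26-connected component (flood fill by repeated
# dilation restricted to the mask, on the mask's bounding box).
#' @noRd
largest_component <- function(mask) {
  if (!any(mask)) return(mask)
  bb <- mask_bbox(mask)
  sub <- mask[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2], drop = FALSE]
  remaining <- sub
  best <- NULL; best_n <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(remaining))
    seed[which(remaining)[1L]] <- TRUE
    repeat {
      grown <- dilate1(seed, "box") & remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    n <- sum(seed)
    if (n > best_n) { best <- seed; best_n <- n }
    remaining <- remaining & !seed
  }
  out <- array(FALSE, dim(mask))
  out[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2]] <- best
  out
}

#' @noRd
n_components <- function(mask) {
  if (!any(mask)) return(0L)
  bb <- mask_bbox(mask)
  remaining <- mask[bb[1, 1]:bb[1, 2], bb[2, 1]:bb[2, 2], bb[3, 1]:bb[3, 2], drop = FALSE]
  count <- 0L
  while (any(remaining)) {
    seed <- array(FALSE, dim(remaining))
    seed[which(remaining)[1L]] <- TRUE
    repeat {
      grown <- dilate1(seed, "box") & remaining
      if (sum(grown) == sum(seed)) break
      seed <- grown
    }
    count <- count + 1L
    remaining <- remaining & !seed
  }
  count
}

# Voxel-index bounding box of a mask: 3x2 matrix (min, max per axis).
#' @noRd
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  t(apply(idx, 2, range))
}

# --- separable filtering -----------------------------------------------------

# n x n operator matrix applying a 1D kernel with reflective boundaries.
#' @noRd
kernel_op <- function(n, kernel) {
  h <- (length(kernel) - 1L) %/% 2L
  M <- matrix(0, n, n)
  i <- seq_len(n)
  for (o in -h:h) {
    j <- i + o
    # reflect (and clamp, for kernels wider than the axis)
    j <- ifelse(j < 1L, 2L - j, j)
    j <- ifelse(j > n, 2L * n - j, j)
    j <- pmin(pmax(j, 1L), n)
    M[cbind(i, j)] <- M[cbind(i, j)] + kernel[o + h + 1L]
  }
  M
}

# Apply 1D kernels (a list of length 3, NULL = identity) separably.
#' @noRd
conv_sep <- function(a, kernels) {
  d <- dim(a)
  if (!is.null(kernels[[1L]]) && length(kernels[[1L]]) > 1L) {
    a <- array(kernel_op(d[1], kernels[[1L]]) %*% matrix(a, d[1]), d)
  }
  if (!is.null(kernels[[2L]]) && length(kernels[[2L]]) > 1L) {
    a <- aperm(a, c(2, 1, 3))
    a <- array(kernel_op(d[2], kernels[[2L]]) %*% matrix(a, d[2]), d[c(2, 1, 3)])
    a <- aperm(a, c(2, 1, 3))
  }
  if (!is.null(kernels[[3L]]) && length(kernels[[3L]]) > 1L) {
    a <- aperm(a, c(3, 2, 1))
    a <- array(kernel_op(d[3], kernels[[3L]]) %*% matrix(a, d[3]), d[c(3, 2, 1)])
    a <- aperm(a, c(3, 2, 1))
  }
  a
}

#' @noRd
gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  h <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-h:h, sd = sigma)
  k / sum(k)
}

# Gaussian smoothing with per-axis sigma in voxels.
#' @noRd
smooth_gauss <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  conv_sep(a, lapply(sigma_vox, gauss_kernel))
}

# Box (moving-average) filter of odd width w voxels along every axis.
#' @noRd
box_filter <- function(a, w) {
  k <- rep(1 / w, w)
  conv_sep(a, list(k, k, k))
}

# --- interpolation and resampling -------------------------------------------

# Trilinear interpolation of a at continuous 1-based voxel coordinates
# (columns x, y, z of pts). Coordinates are clamped to the grid.
#' @noRd
interp_trilinear <- function(a, pts) {
  d <- dim(a)
  x <- pmin(pmax(pts[, 1], 1), d[1])
  y <- pmin(pmax(pts[, 2], 1), d[2])
  z <- pmin(pmax(pts[, 3], 1), d[3])
  x0 <- pmin(floor(x), d[1] - 1L); y0 <- pmin(floor(y), d[2] - 1L)
  z0 <- pmin(floor(z), d[3] - 1L)
  x0 <- pmax(x0, 1); y0 <- pmax(y0, 1); z0 <- pmax(z0, 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  n1 <- d[1]; n12 <- d[1] * d[2]
  base <- x0 + n1 * (y0 - 1) + n12 * (z0 - 1)
  v000 <- a[base];            v100 <- a[base + 1]
  v010 <- a[base + n1];       v110 <- a[base + n1 + 1]
  v001 <- a[base + n12];      v101 <- a[base + n12 + 1]
  v011 <- a[base + n1 + n12]; v111 <- a[base + n1 + n12 + 1]
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
  (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
  (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
  (v011 * (1 - fx) + v111 * fx) * fy * fz
}

# Nearest-neighbour lookup at continuous 1-based voxel coordinates.
# Ties round half-up so that integer-ratio resampling assigns every source
# voxel the same number of target samples (keeps mask volume unbiased).
#' @noRd
interp_nearest <- function(a, pts) {
  d <- dim(a)
  x <- pmin(pmax(floor(pts[, 1] + 0.5), 1), d[1])
  y <- pmin(pmax(floor(pts[, 2] + 0.5), 1), d[2])
  z <- pmin(pmax(floor(pts[, 3] + 0.5), 1), d[3])
  a[cbind(x, y, z)]
}

# mm coordinates of voxel centers along one axis.
#' @noRd
axis_mm <- function(n, spacing, origin = 0) {
  origin + (seq_len(n) - 1) * spacing
}

#' @noRd
grid_coords_mm <- function(dim3, spacing, origin = c(0, 0, 0)) {
  list(x = axis_mm(dim3[1], spacing[1], origin[1]),
       y = axis_mm(dim3[2], spacing[2], origin[2]),
       z = axis_mm(dim3[3], spacing[3], origin[3]))
}

# Quantize values (within a mask) to L levels by min-max scaling.
# Constant regions map to level 1.
#' @noRd
quantize_minmax <- function(v, levels) {
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(rep(1L, length(v)))
  q <- floor((v - lo) / (hi - lo) * levels) + 1L
  pmin(q, as.integer(levels))
}

# Sample statistics used across feature families (population moments).
#' @noRd
skewness_pop <- function(v) {
  n <- length(v); m <- mean(v); s2 <- mean((v - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((v - m)^3) / s2^1.5
}

#' @noRd
kurtosis_pop <- function(v) {
  m <- mean(v); s2 <- mean((v - m)^2)
  if (s2 <= 0) return(NA_real_)
  mean((v - m)^4) / s2^2
}

# Shannon entropy (bits) of a histogram of v with fixed bin width or count.
#' @noRd
hist_entropy <- function(v, bin_width = NULL, n_bins = NULL) {
  if (length(v) == 0L) return(NA_real_)
  rng <- range(v)
  if (rng[2] <= rng[1]) return(0)
  if (!is.null(bin_width)) {
    breaks <- seq(floor(rng[1] / bin_width) * bin_width,
                  ceiling(rng[2] / bin_width) * bin_width + bin_width,
                  by = bin_width)
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  }
  p <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE,
                             all.inside = TRUE), length(breaks) - 1L)
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}
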