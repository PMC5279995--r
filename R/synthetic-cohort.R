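#' Study design for a repeated-segmentation nodule cohort
#'
#' Describes a cohort in which every nodule is segmented several times:
#' by `n_algorithms` distinct segmentation algorithms, each run with
#' `n_inits_per_algorithm` different initializations. The default design
#' emulates a multi-institution lung-nodule robustness study: 52 nodules,
#' 3 algorithms x 3 initializations, i.e. 9 segmentations per nodule and
#' 468 segmentation records in total.
#'
#' @param n_nodules number of nodules in the cohort.
#' @param n_algorithms number of distinct segmentation algorithms emulated.
#' @param n_inits_per_algorithm number of initializations per algorithm.
#' @param volume_shape integer triple, voxels per axis of each CT volume.
#' @param spacing mm triple, voxel spacing (anisotropic by default so that
#'   downstream isotropic resampling is exercised).
#' @param noise_sd additive Gaussian image noise, HU.
#' @param nodule_size_range mm pair, range of nodule diameters drawn.
#' @param background background (lung parenchyma) intensity, HU.
#' @param seed master seed; every per-record random stream is derived from it.
#' @return An object of class `study_design`.
#' @examples
#' d <- study_design(n_nodules = 2, volume_shape = c(48, 48, 48))
#' d$n_nodules * d$n_algorithms * d$n_inits_per_algorithm
#' @export
study_design <- function(n_nodules = 52L,
                         n_algorithms = 3L,
                         n_inits_per_algorithm = 3L,
                         volume_shape = c(96L, 96L, 96L),
                         spacing = c(0.7, 0.7, 1.25),
                         noise_sd = 20,
                         nodule_size_range = c(6, 14),
                         background = -800,
                         seed = 1L) {
  stopifnot(n_nodules >= 1, n_algorithms >= 1, n_inits_per_algorithm >= 1,
            length(volume_shape) == 3, all(volume_shape >= 8),
            length(spacing) == 3, all(spacing > 0),
            noise_sd >= 0, length(nodule_size_range) == 2,
            nodule_size_range[1] > 0,
            nodule_size_range[2] >= nodule_size_range[1])
  fov <- volume_shape * spacing
  if (nodule_size_range[2] > min(fov))
    stop("nodule_size_range exceeds the field of view (",
         paste(round(fov, 1), collapse = " x "), " mm)", call. = FALSE)
  structure(list(
    n_nodules = as.integer(n_nodules),
    n_algorithms = as.integer(n_algorithms),
    n_inits_per_algorithm = as.integer(n_inits_per_algorithm),
    volume_shape = as.integer(volume_shape),
    spacing = as.numeric(spacing),
    noise_sd = noise_sd,
    nodule_size_range = as.numeric(nodule_size_range),
    background = background,
    seed = as.integer(seed)
  ), class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat("Repeated-segmentation study design\n")
  cat(sprintf("  %d nodules x %d algorithms x %d initializations = %d segmentations\n",
              x$n_nodules, x$n_algorithms, x$n_inits_per_algorithm,
              x$n_nodules * x$n_algorithms * x$n_inits_per_algorithm))
  cat(sprintf("  volume %s voxels at %s mm, noise sd %g HU, nodules %g-%g mm\n",
              paste(x$volume_shape, collapse = "x"),
              paste(x$spacing, collapse = "x"),
              x$noise_sd, x$nodule_size_range[1], x$nodule_size_range[2]))
  invisible(x)
}

#' Geometric and intensity description of one synthetic nodule
#'
#' A nodule is a smoothly lobulated ellipsoid: an ellipsoid with semi-axes
#' `semi_axes` (mm), rotated by Euler angles `orientation`, whose radius is
#' modulated by a low-order angular perturbation of relative amplitude
#' `lobulation_amplitude`. Its intensity ramps from the background value to
#' `mean_intensity` over a 10-90% transition width of `margin_sharpness` mm,
#' and correlated noise texture of standard deviation `texture_amplitude` HU
#' (correlation length `texture_correlation_length` mm) is added inside.
#'
#' @param center mm triple, nodule center in volume coordinates.
#' @param semi_axes mm triple, ellipsoid semi-axes (all > 0).
#' @param orientation Euler angles (radians), rotation applied to the axes.
#' @param mean_intensity nodule core intensity, HU.
#' @param texture_amplitude internal texture standard deviation, HU.
#' @param texture_correlation_length texture correlation length, mm.
#' @param margin_sharpness 10-90% intensity transition width, mm (> 0).
#' @param lobulation_amplitude relative radial modulation (dimensionless).
#' @return An object of class `nodule_spec`.
#' @export
nodule_spec <- function(center, semi_axes,
                        orientation = c(0, 0, 0),
                        mean_intensity = 0,
                        texture_amplitude = 40,
                        texture_correlation_length = 2,
                        margin_sharpness = 1,
                        lobulation_amplitude = 0.1) {
  stopifnot(length(center) == 3, length(semi_axes) == 3, all(semi_axes > 0),
            margin_sharpness > 0, lobulation_amplitude >= 0)
  structure(list(center = as.numeric(center),
                 semi_axes = as.numeric(semi_axes),
                 orientation = as.numeric(orientation),
                 mean_intensity = mean_intensity,
                 texture_amplitude = texture_amplitude,
                 texture_correlation_length = texture_correlation_length,
                 margin_sharpness = margin_sharpness,
                 lobulation_amplitude = lobulation_amplitude),
            class = "nodule_spec")
}

#' Construct an image volume
#'
#' A 3D scalar grid with voxel spacing (mm) and origin: the mm coordinate of
#' the center of voxel (1, 1, 1).
#'
#' @param data 3D numeric array, HU-like intensities.
#' @param spacing mm triple (> 0).
#' @param origin mm triple.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(spacing) == 3, all(spacing > 0), all(is.finite(data)))
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat(sprintf("image_volume %s voxels at %s mm (range %.1f..%.1f HU)\n",
              paste(dim(x$data), collapse = "x"),
              paste(signif(x$spacing, 3), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

# rotation matrix from Euler angles (z-y-x convention)
#' @noRd
euler_rotation <- function(ang) {
  cz <- cos(ang[1]); sz <- sin(ang[1])
  cy <- cos(ang[2]); sy <- sin(ang[2])
  cx <- cos(ang[3]); sx <- sin(ang[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3)
  Rz %*% Ry %*% Rx
}

# Signed radial distance (mm, positive inside) from every voxel of a local
# box to the lobulated ellipsoid surface, plus the box index ranges.
# The lobulation is a fixed smooth function of direction with coefficients
# derived deterministically from the nodule geometry.
#' @noRd
nodule_signed_distance <- function(design, nodule) {
  shp <- design$volume_shape; sp <- design$spacing
  ext <- max(nodule$semi_axes) * (1 + nodule$lobulation_amplitude) +
    3 * nodule$margin_sharpness + 4
  co <- grid_coords_mm(shp, sp)
  rx <- which(abs(co$x - nodule$center[1]) <= ext)
  ry <- which(abs(co$y - nodule$center[2]) <= ext)
  rz <- which(abs(co$z - nodule$center[3]) <= ext)
  R <- euler_rotation(nodule$orientation)
  g <- as.matrix(expand.grid(x = co$x[rx], y = co$y[ry], z = co$z[rz]))
  u <- sweep(g, 2, nodule$center) %*% R
  r <- sqrt(rowSums(u^2))
  f <- sqrt((u[, 1] / nodule$semi_axes[1])^2 +
            (u[, 2] / nodule$semi_axes[2])^2 +
            (u[, 3] / nodule$semi_axes[3])^2)
  if (nodule$lobulation_amplitude > 0) {
    dirs <- u / pmax(r, 1e-9)
    # three fixed oblique wave vectors; phases tied to the nodule geometry
    ph <- sum(nodule$semi_axes) + sum(nodule$center)
    w1 <- cos(3 * dirs[, 1] + 2 * dirs[, 2] + ph)
    w2 <- cos(2 * dirs[, 2] - 3 * dirs[, 3] + 1.7 * ph)
    w3 <- cos(3 * dirs[, 3] + 2 * dirs[, 1] - 0.6 * ph)
    f <- f / (1 + nodule$lobulation_amplitude * (w1 + w2 + w3) / 3)
  }
  d <- ifelse(f > 1e-9, r * (1 - f) / pmax(f, 1e-9), max(nodule$semi_axes))
  list(d = array(d, c(length(rx), length(ry), length(rz))),
       rx = rx, ry = ry, rz = rz)
}

#' Generate one synthetic CT volume containing a nodule
#'
#' Renders the nodule of `nodule` into a background of lung-parenchyma
#' intensity (`design$background`, default -800 HU) with additive Gaussian
#' noise of sd `design$noise_sd`. The nodule intensity transitions from
#' background to `mean_intensity` over `margin_sharpness` mm (logistic
#' profile in the signed distance to the nodule surface), and correlated
#' noise texture is added inside. Deterministic given `seed`.
#'
#' @param design a [study_design()].
#' @param nodule a [nodule_spec()]; must fit inside the field of view.
#' @param seed integer seed for the volume's noise streams.
#' @return An [image_volume()].
#' @export
generate_volume <- function(design, nodule, seed = design$seed) {
  shp <- design$volume_shape; sp <- design$spacing
  fov <- shp * sp
  half <- max(nodule$semi_axes) * (1 + nodule$lobulation_amplitude)
  for (ax in 1:3) {
    if (nodule$center[ax] - half < 0 || nodule$center[ax] + half > fov[ax])
      stop(sprintf("nodule extends outside the field of view along axis %d (%s)",
                   ax, c("x", "y", "z")[ax]), call. = FALSE)
  }
  set.seed(derive_seed(seed, 11L))
  vol <- array(design$background, shp)
  if (design$noise_sd > 0)
    vol <- vol + array(stats::rnorm(prod(shp), sd = design$noise_sd), shp)
  sd3 <- nodule_signed_distance(design, nodule)
  # logistic weight: 10-90% rise over margin_sharpness mm
  s <- nodule$margin_sharpness / (2 * log(9))
  w <- stats::plogis(sd3$d / s)
  box <- vol[sd3$rx, sd3$ry, sd3$rz, drop = FALSE]
  box <- box + w * (nodule$mean_intensity - design$background)
  if (nodule$texture_amplitude > 0) {
    set.seed(derive_seed(seed, 13L))
    tex <- array(stats::rnorm(length(w)), dim(w))
    tex <- smooth_gauss(tex, nodule$texture_correlation_length / sp)
    tsd <- stats::sd(as.vector(tex))
    if (tsd > 0) tex <- tex / tsd * nodule$texture_amplitude
    box <- box + w * tex
  }
  vol[sd3$rx, sd3$ry, sd3$rz] <- box
  image_volume(vol, sp)
}

#' Noise-free reference (truth) mask of a nodule
#'
#' The voxel-center indicator of the lobulated ellipsoid: a voxel belongs to
#' the mask iff its center lies inside the nodule surface.
#'
#' @inheritParams generate_volume
#' @return 3D logical array of the design's volume shape.
#' @export
truth_mask <- function(design, nodule) {
  sd3 <- nodule_signed_distance(design, nodule)
  mask <- array(FALSE, design$volume_shape)
  mask[sd3$rx, sd3$ry, sd3$rz] <- sd3$d >= 0
  largest_component(mask)
}

#' Draw the nodule specifications of a cohort
#'
#' Samples one [nodule_spec()] per nodule: diameters uniform over the
#' design's size range with mild per-axis anisotropy, random orientation,
#' core intensity uniform in -50..50 HU, margin transition width uniform in
#' 0.5..3 mm, and a small fixed lobulation. Deterministic given the design
#' seed.
#'
#' @param design a [study_design()].
#' @return list of `nodule_spec` objects of length `design$n_nodules`.
#' @export
sample_nodules <- function(design) {
  fov <- design$volume_shape * design$spacing
  lapply(seq_len(design$n_nodules), function(i) {
    set.seed(derive_seed(design$seed, 7L, i))
    diam <- stats::runif(1, design$nodule_size_range[1], design$nodule_size_range[2])
    aspect <- stats::runif(3, 0.85, 1.2)
    aspect <- aspect / prod(aspect)^(1 / 3)
    semi <- diam / 2 * aspect
    center <- fov / 2 + stats::runif(3, -0.05, 0.05) * fov
    nodule_spec(center = center,
                semi_axes = semi,
                orientation = stats::runif(3, 0, pi),
                mean_intensity = stats::runif(1, -50, 50),
                texture_amplitude = 40,
                texture_correlation_length = 2,
                margin_sharpness = stats::runif(1, 0.5, 3),
                lobulation_amplitude = 0.1)
  })
}

#' Segmentation record
#'
#' One of the repeated segmentations of a nodule: a binary mask on the same
#' grid as its volume plus (nodule, algorithm, initialization) identifiers.
#'
#' @param mask 3D logical array, nonempty, single 26-connected component.
#' @param spacing mm triple.
#' @param nodule_id,algorithm_id,init_id integer identifiers.
#' @return An object of class `seg_record`.
#' @export
seg_record <- function(mask, spacing, nodule_id, algorithm_id, init_id) {
  stopifnot_mask(mask)
  structure(list(mask = mask, spacing = as.numeric(spacing),
                 nodule_id = as.integer(nodule_id),
                 algorithm_id = as.integer(algorithm_id),
                 init_id = as.integer(init_id)),
            class = "seg_record")
}

#' @export
print.seg_record <- function(x, ...) {
  cat(sprintf("seg_record nodule %d, algorithm %d, init %d: %d voxels\n",
              x$nodule_id, x$algorithm_id, x$init_id, sum(x$mask)))
  invisible(x)
}

#' Generate the repeated segmentations of one nodule
#'
#' Emulates segmentation variability with two components:
#' \itemize{
#'  \item an algorithm-specific systematic perturbation: a signed
#'    morphological boundary offset (-1, 0, +1 voxel across the algorithms)
#'    together with algorithm-specific Gaussian boundary smoothing;
#'  \item an initialization-specific random low-frequency boundary jitter
#'    of amplitude `jitter_amplitude` voxels, smaller than the one-voxel
#'    inter-algorithm offset.
#' }
#' The construction makes repeated runs of the same algorithm agree more
#' than runs of different algorithms (repeatability above reproducibility).
#' Each (nodule, algorithm, init) triple uses its own random stream derived
#' from `seed`, so any record can be regenerated in isolation.
#'
#' @param truth 3D logical truth mask (see [truth_mask()]).
#' @param design a [study_design()].
#' @param nodule_id integer identifier stored in the records.
#' @param seed master seed (defaults to the design seed).
#' @param offsets signed boundary offsets in voxels, one per algorithm.
#' @param smooth_sigmas boundary smoothing sigma in voxels, one per algorithm.
#' @param jitter_amplitude initialization jitter amplitude, voxels.
#' @param max_retries bounded number of jitter redraws if a perturbation
#'   empties the mask.
#' @return list of [seg_record()]s of length
#'   `n_algorithms * n_inits_per_algorithm`.
#' @export
generate_segmentations <- function(truth, design, nodule_id,
                                   seed = design$seed,
                                   offsets = NULL,
                                   smooth_sigmas = NULL,
                                   jitter_amplitude = 0.3,
                                   max_retries = 5L) {
  stopifnot_mask(truth)
  na <- design$n_algorithms; ni <- design$n_inits_per_algorithm
  if (is.null(offsets))
    offsets <- seq(-1, 1, length.out = na)
  if (is.null(smooth_sigmas))
    smooth_sigmas <- seq(0.8, 1.6, length.out = na)
  stopifnot(length(offsets) == na, length(smooth_sigmas) == na)

  # work on a padded bounding box for speed
  bb <- mask_bbox(truth)
  pad <- 8L
  d <- dim(truth)
  lo <- pmax(bb[, 1] - pad, 1L); hi <- pmin(bb[, 2] + pad, d)
  sub <- truth[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]

  records <- vector("list", na * ni)
  k <- 0L
  for (a in seq_len(na)) {
    # systematic algorithm bias: signed morphological boundary offset
    base <- sub
    noff <- round(offsets[a])
    if (noff >= 1) for (r in seq_len(noff)) base <- dilate1(base, "cross")
    if (noff <= -1) for (r in seq_len(-noff)) base <- erode1(base, "cross")
    if (!any(base)) base <- sub  # offset would empty the mask; fall back
    u <- smooth_gauss(base * 1.0, smooth_sigmas[a])
    # level shift per voxel of boundary displacement at the 0.5 crossing
    slope <- stats::dnorm(0, sd = smooth_sigmas[a])
    for (i in seq_len(ni)) {
      k <- k + 1L
      mask_sub <- NULL
      for (try in 0:max_retries) {
        set.seed(derive_seed(seed, nodule_id, a, i, try))
        jit <- array(stats::rnorm(length(sub)), dim(sub))
        jit <- smooth_gauss(jit, 4)
        jsd <- stats::sd(as.vector(jit))
        if (jsd > 0) jit <- jit / jsd
        # clamp: the level shift only means boundary displacement near the
        # 0.5 crossing; unbounded shifts would admit far-field components
        level <- pmin(pmax(0.5 - slope * jitter_amplitude * jit, 0.15), 0.85)
        cand <- u >= level
        if (any(cand)) {
          mask_sub <- largest_component(cand)
          break
        }
      }
      if (is.null(mask_sub))
        stop(sprintf("perturbation emptied the mask for nodule %d, algorithm %d, init %d",
                     nodule_id, a, i), call. = FALSE)
      mask <- array(FALSE, d)
      mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- mask_sub
      records[[k]] <- seg_record(mask, design$spacing, nodule_id, a, i)
    }
  }
  records
}

#' Simulate one nodule of the cohort: volume, truth mask and segmentations
#'
#' @param design a [study_design()].
#' @param i nodule index in 1..n_nodules.
#' @param nodules optional precomputed [sample_nodules()] list.
#' @return list with elements `volume`, `truth`, `segmentations`, `nodule`.
#' @export
simulate_nodule <- function(design, i, nodules = NULL) {
  if (is.null(nodules)) nodules <- sample_nodules(design)
  nod <- nodules[[i]]
  vol <- generate_volume(design, nod, seed = derive_seed(design$seed, 3L, i))
  tm <- truth_mask(design, nod)
  segs <- generate_segmentations(tm, design, nodule_id = i, seed = design$seed)
  list(volume = vol, truth = tm, segmentations = segs, nodule = nod)
}

#' Simulate a whole cohort
#'
#' Convenience wrapper returning every segmentation record of the design.
#' Memory scales with `n_nodules * prod(volume_shape)`; for large designs
#' prefer streaming nodule-by-nodule via [simulate_nodule()] (as
#' [run_pipeline()] does).
#'
#' @param design a [study_design()].
#' @param keep_volumes keep the generated volumes in the result.
#' @return list with `records` (list of [seg_record()]), `nodules`, and
#'   optionally `volumes`.
#' @export
simulate_cohort <- function(design, keep_volumes = FALSE) {
  nodules <- sample_nodules(design)
  records <- list()
  volumes <- if (keep_volumes) vector("list", design$n_nodules) else NULL
  for (i in seq_len(design$n_nodules)) {
    sim <- simulate_nodule(design, i, nodules)
    records <- c(records, sim$segmentations)
    if (keep_volumes) volumes[[i]] <- sim$volume
  }
  out <- list(records = records, nodules = nodules)
  if (keep_volumes) out$volumes <- volumes
  out
}

#' Dice overlap coefficient between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; 1 for identical nonempty masks, 0 for disjoint
#' masks. Both masks empty is an error (the coefficient is undefined).
#'
#' @param a,b 3D logical arrays of identical shape.
#' @return proportion in `[0, 1]`.
#' @examples
#' m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
#' dice(m, m)
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("mask shapes differ", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0L) stop("both masks are empty", call. = FALSE)
  2 * sum(a & b) / (sa + sb)
}
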