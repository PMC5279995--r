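#' Texture configuration
#'
#' Parameters of the texture feature families, with the common site
#' presets as defaults: 32 min-max quantization levels, co-occurrence
#' distance 1 voxel, the 13 symmetric 3D offsets (26-connectivity modulo
#' symmetry), 8 in-plane directions for 2D analysis, GLCM recomputed at
#' 1, 2 and 3 mm isotropic scales, and Laplacian-of-Gaussian sigmas of
#' 0.5, 1.5 and 2.5 mm.
#'
#' @param glcm_levels quantization levels for co-occurrence matrices (>= 2).
#' @param glcm_distance voxel distance between co-occurring voxels.
#' @param glcm_scales mm isotropic scales at which GLCM features are
#'   recomputed.
#' @param rl_levels quantization levels for run-length matrices.
#' @param rl_scale mm isotropic grid on which run-length (and Law's)
#'   features are computed.
#' @param log_sigmas mm sigmas of the Laplacian-of-Gaussian filters.
#' @param wavelet_levels decomposition levels of the 3D Haar transform.
#' @param laws_triples character vector of 3D Law's kernel triples, each a
#'   concatenation of three of L5, E5, S5, R5, W5.
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(glcm_levels = 32L,
                           glcm_distance = 1L,
                           glcm_scales = c(1, 2, 3),
                           rl_levels = 16L,
                           rl_scale = 1,
                           log_sigmas = c(0.5, 1.5, 2.5),
                           wavelet_levels = 1L,
                           laws_triples = c("E5L5L5", "S5L5L5", "R5L5L5",
                                            "W5L5L5", "E5E5E5")) {
  stopifnot(glcm_levels >= 2, glcm_distance >= 1, all(glcm_scales > 0),
            rl_levels >= 2, rl_scale > 0, all(log_sigmas > 0),
            wavelet_levels >= 1)
  structure(list(glcm_levels = as.integer(glcm_levels),
                 glcm_distance = as.integer(glcm_distance),
                 offsets_3d = 13L, directions_2d = 8L,
                 glcm_scales = glcm_scales,
                 rl_levels = as.integer(rl_levels), rl_scale = rl_scale,
                 log_sigmas = log_sigmas,
                 wavelet_levels = as.integer(wavelet_levels),
                 laws_triples = laws_triples),
            class = "texture_config")
}

# The 13 symmetric offsets of the 3D 26-neighbourhood (26 / 2).
#' @noRd
offsets_3d_13 <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

# The 4 symmetric in-plane offsets (8 directions / 2).
#' @noRd
offsets_2d_4 <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))
}

# Co-occurrence pairs for one offset: integer levels at p and p + d, both
# inside the mask. q is the level array with 0 outside the mask.
#' @noRd
glcm_pairs <- function(q, d) {
  dims <- dim(q)
  lo <- pmax(1, 1 - d); hi <- pmin(dims, dims - d)
  if (any(hi < lo)) return(NULL)
  rx <- lo[1]:hi[1]; ry <- lo[2]:hi[2]; rz <- lo[3]:hi[3]
  A <- q[rx, ry, rz]
  B <- q[rx + d[1], ry + d[2], rz + d[3]]
  keep <- A > 0L & B > 0L
  if (!any(keep)) return(NULL)
  cbind(A[keep], B[keep])
}

# Haralick measures of one normalized symmetric co-occurrence matrix.
#' @noRd
glcm_measures <- function(Pm) {
  L <- nrow(Pm)
  i <- row(Pm); j <- col(Pm)
  p <- Pm
  nz <- p > 0
  c(contrast = sum(p * (i - j)^2),
    dissimilarity = sum(p * abs(i - j)),
    homogeneity = sum(p / (1 + (i - j)^2)),
    energy = sum(p^2),
    entropy = -sum(p[nz] * log2(p[nz])))
}

# GLCM measures at one scale: per-offset measures, then mean and range.
#' @noRd
glcm_at_scale <- function(vals, mask, offs, levels, distance) {
  q <- array(0L, dim(mask))
  q[mask] <- quantize_minmax(vals, levels)
  meas <- NULL
  for (k in seq_len(nrow(offs))) {
    pr <- glcm_pairs(q, offs[k, ] * distance)
    if (is.null(pr)) next
    M <- matrix(tabulate(pr[, 1] + levels * (pr[, 2] - 1L), levels * levels),
                levels, levels)
    M <- M + t(M)
    M <- M / sum(M)
    meas <- rbind(meas, glcm_measures(M))
  }
  if (is.null(meas)) return(NULL)
  list(mean = colMeans(meas),
       range = apply(meas, 2, function(x) max(x) - min(x)))
}

#' Gray-level co-occurrence (Haralick) texture features
#'
#' Intensities inside the mask are min-max quantized to `glcm_levels`;
#' co-occurrence matrices are accumulated over the 13 symmetric 3D offsets
#' at `glcm_distance`, restricted to voxel pairs both inside the mask,
#' symmetrized and normalized to sum 1. Contrast, dissimilarity,
#' homogeneity, energy (angular second moment) and entropy are computed
#' per offset and aggregated as the mean and range (max - min) over
#' offsets. The multi-scale variant resamples (volume, mask) to each of
#' `glcm_scales` mm before recomputing; the 2D variant uses the
#' maximal-diameter axial slice with the 4 symmetric in-plane offsets
#' (8 directions).
#'
#' @param volume an [image_volume()].
#' @param mask 3D logical array, nonempty, same grid (>= 2 voxels).
#' @param cfg a [texture_config()].
#' @param scales override `cfg$glcm_scales`; `NULL` computes on the input
#'   grid only (feature names then carry no scale tag).
#' @return named numeric vector; all-NA for offsets that admit no valid
#'   voxel pair.
#' @export
glcm_features <- function(volume, mask, cfg = texture_config(), scales = cfg$glcm_scales) {
  stopifnot(inherits(volume, "image_volume"))
  stopifnot_mask(mask)
  offs <- offsets_3d_13()
  measures <- c("contrast", "dissimilarity", "homogeneity", "energy", "entropy")
  if (is.null(scales)) {
    res <- glcm_at_scale(volume$data[mask], mask, offs, cfg$glcm_levels,
                         cfg$glcm_distance)
    out <- c(if (is.null(res)) rep(NA_real_, 10) else c(res$mean, res$range))
    names(out) <- c(sprintf("tex_glcm3d_%s_mean", measures),
                    sprintf("tex_glcm3d_%s_range", measures))
    return(out)
  }
  out <- numeric(0)
  for (s in scales) {
    rs <- resample_for_texture(volume, mask, s)
    res <- if (sum(rs$mask) >= 2)
      glcm_at_scale(rs$volume$data[rs$mask], rs$mask, offs, cfg$glcm_levels,
                    cfg$glcm_distance) else NULL
    v <- if (is.null(res)) rep(NA_real_, 10) else c(res$mean, res$range)
    names(v) <- c(sprintf("tex_glcm3d_s%gmm_%s_mean", s, measures),
                  sprintf("tex_glcm3d_s%gmm_%s_range", s, measures))
    out <- c(out, v)
  }
  out
}

#' 2D GLCM features on the maximal-diameter axial slice
#'
#' @inheritParams glcm_features
#' @return named numeric vector (per-measure means over the 4 symmetric
#'   in-plane offsets).
#' @export
glcm_features_2d <- function(volume, mask, cfg = texture_config()) {
  stopifnot(inherits(volume, "image_volume"))
  stopifnot_mask(mask)
  z <- select_max_slice(mask, volume$spacing)
  m2 <- mask[, , z, drop = FALSE]
  measures <- c("contrast", "dissimilarity", "homogeneity", "energy", "entropy")
  res <- if (sum(m2) >= 2)
    glcm_at_scale(volume$data[, , z, drop = FALSE][m2], m2, offsets_2d_4(),
                  cfg$glcm_levels, cfg$glcm_distance) else NULL
  out <- if (is.null(res)) rep(NA_real_, 5) else res$mean
  names(out) <- sprintf("tex_glcm2d_%s_mean", measures)
  out
}

# resample helper reused by the texture families; margin_mm pads the
# mask bounding box (clipped to the volume) for families that need
# context beyond the mask
#' @noRd
resample_for_texture <- function(volume, mask, spacing_mm, margin_mm = 0) {
  bb <- mask_bbox(mask)
  lo <- volume$origin + (bb[, 1] - 1) * volume$spacing - margin_mm
  hi <- volume$origin + (bb[, 2] - 1) * volume$spacing + margin_mm
  lo <- pmax(lo, volume$origin)
  hi <- pmin(hi, volume$origin + (dim(volume$data) - 1) * volume$spacing)
  resample_iso(volume, mask, cbind(lo, hi), spacing_mm)
}

# --- run-length --------------------------------------------------------------

# Run-length matrix accumulation over the 13 symmetric 3D directions.
# Returns a list of data frames (level, length, count) per direction.
# Runs are maximal sequences of equal level along a direction, truncated
# at the mask boundary.
#' @noRd
runlength_runs <- function(q, mask, dirs) {
  dims <- dim(mask)
  idx <- which(mask, arr.ind = TRUE)
  lev <- q[mask]
  out <- vector("list", nrow(dirs))
  for (k in seq_len(nrow(dirs))) {
    d <- dirs[k, ]
    # line invariants: two independent cross-products with d
    l1 <- d[2] * idx[, 1] - d[1] * idx[, 2]
    l2 <- d[3] * idx[, 1] - d[1] * idx[, 3]
    l3 <- d[3] * idx[, 2] - d[2] * idx[, 3]
    pos <- idx[, 1] * d[1] + idx[, 2] * d[2] + idx[, 3] * d[3]
    step <- sum(d^2)
    key <- paste(l1, l2, l3)
    o <- order(key, pos)
    kk <- key[o]; pp <- pos[o]; ll <- lev[o]
    n <- length(o)
    if (n == 0L) { out[[k]] <- NULL; next }
    newline <- c(TRUE, kk[-1] != kk[-n])
    gap <- c(TRUE, pp[-1] != pp[-n] + step)
    chg <- c(TRUE, ll[-1] != ll[-n])
    brk <- newline | gap | chg
    run_id <- cumsum(brk)
    out[[k]] <- data.frame(level = ll[brk],
                           length = tabulate(run_id, max(run_id)))
  }
  out
}

# standard run-length statistics from a (level, length, count) table
#' @noRd
rl_stats <- function(runs, n_vox) {
  l <- runs$length; g <- runs$level
  Nr <- nrow(runs)
  c(sre = sum(1 / l^2) / Nr,
    lre = sum(l^2) / Nr,
    gln = sum(tapply(rep(1, Nr), g, sum)^2) / Nr,
    rln = sum(tapply(rep(1, Nr), l, sum)^2) / Nr,
    rp = Nr / n_vox,
    lgre = sum(1 / g^2) / Nr,
    hgre = sum(g^2) / Nr)
}

#' Run-length texture features
#'
#' Gray-level run-length statistics from min-max quantized intensities
#' (`rl_levels`), computed along each of the 13 symmetric 3D directions
#' with runs truncated at the mask boundary, then averaged over
#' directions. Computed directly in the (resampled) mask region. Reports
#' short/long-run emphasis, gray-level and run-length non-uniformity, run
#' percentage and low/high gray-level run emphasis.
#'
#' @inheritParams glcm_features
#' @param resample resample to `cfg$rl_scale` mm first (set `FALSE` to
#'   compute on the input grid, e.g. for oracle comparisons).
#' @return named numeric vector.
#' @export
runlength_features <- function(volume, mask, cfg = texture_config(),
                               resample = TRUE) {
  stopifnot(inherits(volume, "image_volume"))
  stopifnot_mask(mask)
  if (resample) {
    rs <- resample_for_texture(volume, mask, cfg$rl_scale)
    volume <- rs$volume; mask <- rs$mask
  }
  if (sum(mask) < 2) {
    out <- rep(NA_real_, 7)
    names(out) <- sprintf("tex_rl_%s", c("sre", "lre", "gln", "rln", "rp",
                                         "lgre", "hgre"))
    return(out)
  }
  q <- array(0L, dim(mask))
  q[mask] <- quantize_minmax(volume$data[mask], cfg$rl_levels)
  runs <- runlength_runs(q, mask, offsets_3d_13())
  n_vox <- sum(mask)
  stats_mat <- t(vapply(runs, rl_stats, numeric(7), n_vox = n_vox))
  out <- colMeans(stats_mat)
  names(out) <- sprintf("tex_rl_%s", names(out))
  out
}

# --- Law's texture energy ----------------------------------------------------

#' @noRd
laws_kernels_1d <- function() {
  list(L5 = c(1, 4, 6, 4, 1),
       E5 = c(-1, -2, 0, 2, 1),
       S5 = c(-1, 0, 2, 0, -1),
       R5 = c(1, -4, 6, -4, 1),
       W5 = c(-1, 2, 0, -2, 1))
}

# distinct axis-permutations of a kernel triple (as 3-row name matrix)
#' @noRd
triple_permutations <- function(triple) {
  names3 <- substring(triple, c(1, 3, 5), c(2, 4, 6))
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  assigned <- apply(perms, 1, function(p) paste(names3[p], collapse = ""))
  unique_idx <- !duplicated(assigned)
  lapply(which(unique_idx), function(r) names3[perms[r, ]])
}

#' Rotation-invariant 3D Law's texture energy features
#'
#' Each feature derives from a 3D filter formed as the outer product of
#' three 1D Law's kernels (L5 level, E5 edge, S5 spot, R5 ripple, W5
#' wave). The local energy map is the 5-voxel moving average of the
#' absolute filter response; rotation invariance is obtained by averaging
#' the energy maps over all distinct axis-permutations of the kernel
#' triple (combined with the absolute value, this makes the summaries
#' exactly invariant under 90-degree axis rotations and flips). The map is
#' summarized inside the mask by mean, sd, skewness and kurtosis.
#' Filtering uses reflective padding; masks thinner than the kernel
#' support are still computed but flagged via the `"thin_mask"` attribute.
#'
#' @inheritParams runlength_features
#' @return named numeric vector.
#' @export
laws_features <- function(volume, mask, cfg = texture_config(),
                          resample = TRUE) {
  stopifnot(inherits(volume, "image_volume"))
  stopifnot_mask(mask)
  if (resample) {
    rs <- resample_for_texture(volume, mask, cfg$rl_scale)
    volume <- rs$volume; mask <- rs$mask
    if (!any(mask)) mask <- array(TRUE, dim(volume$data))
  }
  a <- volume$data
  k1 <- laws_kernels_1d()
  out <- numeric(0)
  thin <- any(mask_bbox(mask)[, 2] - mask_bbox(mask)[, 1] + 1 < 5)
  for (triple in cfg$laws_triples) {
    perms <- triple_permutations(triple)
    emap <- 0
    for (p in perms) {
      resp <- conv_sep(a, list(k1[[p[1]]], k1[[p[2]]], k1[[p[3]]]))
      emap <- emap + box_filter(abs(resp), 5L)
    }
    emap <- emap / length(perms)
    v <- emap[mask]
    s <- c(mean = mean(v), sd = stats::sd(v),
           skewness = skewness_pop(v), kurtosis = kurtosis_pop(v))
    names(s) <- sprintf("tex_laws_%s_%s", triple, names(s))
    out <- c(out, s)
  }
  attr(out, "thin_mask") <- thin
  out
}

# --- Laplacian of Gaussian ---------------------------------------------------

#' Laplacian-of-Gaussian texture features
#'
#' Scale-normalized LoG response (`sigma^2` times the Laplacian of the
#' Gaussian-smoothed image, derivatives in mm) at each configured sigma;
#' reports the mean and sd of the response inside the mask per sigma. The
#' scale normalization makes the center response to an isolated blob of
#' radius `r` peak near `sigma = r / sqrt(3)`. Sigmas below half the voxel
#' size are computed with a warning (the discrete grid undersamples the
#' kernel).
#'
#' @inheritParams glcm_features
#' @return named numeric vector.
#' @export
log_features <- function(volume, mask, cfg = texture_config()) {
  stopifnot(inherits(volume, "image_volume"))
  stopifnot_mask(mask)
  a <- volume$data; sp <- volume$spacing
  out <- numeric(0)
  for (s in cfg$log_sigmas) {
    if (s < min(sp) / 2)
      warning(sprintf("LoG sigma %.2f mm below half the voxel size", s))
    u <- smooth_gauss(a, s / sp)
    lap <- (shift1(u, 1, -1L, 0) - 2 * u + shift1(u, 1, 1L, 0)) / sp[1]^2 +
           (shift1(u, 2, -1L, 0) - 2 * u + shift1(u, 2, 1L, 0)) / sp[2]^2 +
           (shift1(u, 3, -1L, 0) - 2 * u + shift1(u, 3, 1L, 0)) / sp[3]^2
    # replicate edges to avoid boundary artefacts from zero fill
    resp <- s^2 * lap
    v <- resp[mask]
    seg <- c(mean = mean(v), sd = stats::sd(v))
    names(seg) <- sprintf("tex_log_s%gmm_%s", s, names(seg))
    out <- c(out, seg)
  }
  out
}

# --- wavelet -----------------------------------------------------------------

# One-level 3D orthonormal Haar transform of an array with even dims.
# Returns the 8 sub-bands as a named list (lll ... hhh).
#' @noRd
haar3d <- function(a) {
  d <- dim(a)
  stopifnot(all(d %% 2 == 0))
  s <- 1 / sqrt(2)
  along <- function(x, axis) {
    dd <- dim(x)
    n <- dd[axis]
    i1 <- seq(1L, n, by = 2L); i2 <- seq(2L, n, by = 2L)
    idx1 <- idx2 <- rep(list(quote(expr = )), 3)
    pick <- function(ii) {
      args <- list(x)
      for (ax in 1:3) args[[ax + 1]] <- if (ax == axis) ii else seq_len(dd[ax])
      args$drop <- FALSE
      do.call(`[`, args)
    }
    lo <- (pick(i1) + pick(i2)) * s
    hi <- (pick(i1) - pick(i2)) * s
    list(lo = lo, hi = hi)
  }
  x <- along(a, 1)
  bands1 <- list(l = x$lo, h = x$hi)
  bands2 <- list()
  for (nm in names(bands1)) {
    y <- along(bands1[[nm]], 2)
    bands2[[paste0(nm, "l")]] <- y$lo
    bands2[[paste0(nm, "h")]] <- y$hi
  }
  bands3 <- list()
  for (nm in names(bands2)) {
    z <- along(bands2[[nm]], 3)
    bands3[[paste0(nm, "l")]] <- z$lo
    bands3[[paste0(nm, "h")]] <- z$hi
  }
  bands3
}

#' Wavelet sub-band texture features
#'
#' One-level separable orthonormal 3D Haar transform of the cropped
#' volume (odd dimensions are trimmed by one voxel). Per sub-band, the
#' energy (mean squared coefficient) and the entropy of the coefficient
#' histogram (32 bins) restricted to the downsampled mask (a low-resolution
#' voxel is in-mask if any of its 8 children is).
#'
#' @inheritParams glcm_features
#' @return named numeric vector (16 values: 8 sub-bands x energy, entropy).
#' @export
wavelet_features <- function(volume, mask, cfg = texture_config()) {
  stopifnot(inherits(volume, "image_volume"))
  stopifnot_mask(mask)
  a <- volume$data
  d <- dim(a)
  d2 <- d - d %% 2L
  if (any(d2 < 2L)) {
    bn <- apply(expand.grid(c("l", "h"), c("l", "h"), c("l", "h")), 1, paste0,
                collapse = "")
    out <- rep(NA_real_, 16)
    names(out) <- as.vector(vapply(bn, function(b)
      sprintf("tex_wav_%s_%s", b, c("energy", "entropy")), character(2)))
    return(out)
  }
  a <- a[seq_len(d2[1]), seq_len(d2[2]), seq_len(d2[3]), drop = FALSE]
  m <- mask[seq_len(d2[1]), seq_len(d2[2]), seq_len(d2[3]), drop = FALSE]
  bands <- haar3d(a)
  # downsampled mask: any-of-8 pooling
  md <- m[seq(1, d2[1], 2), seq(1, d2[2], 2), seq(1, d2[3], 2), drop = FALSE]
  for (sx in 0:1) for (sy in 0:1) for (sz in 0:1) {
    md <- md | m[seq(1 + sx, d2[1], 2), seq(1 + sy, d2[2], 2),
                 seq(1 + sz, d2[3], 2), drop = FALSE]
  }
  out <- numeric(0)
  for (nm in names(bands)) {
    v <- bands[[nm]][md]
    seg <- c(energy = mean(v^2), entropy = hist_entropy(v, n_bins = 32))
    names(seg) <- sprintf("tex_wav_%s_%s", nm, names(seg))
    out <- c(out, seg)
  }
  out
}
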