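test_that("GLCM measures are exact on constant and checkerboard patterns", {
  n <- 12L
  m <- array(FALSE, c(n, n, n)); m[3:10, 3:10, 3:10] <- TRUE
  vc <- image_volume(array(7, c(n, n, n)), c(1, 1, 1))
  f <- glcm_features(vc, m, scales = NULL)
  expect_equal(unname(f["tex_glcm3d_contrast_mean"]), 0)
  expect_equal(unname(f["tex_glcm3d_dissimilarity_mean"]), 0)
  expect_equal(unname(f["tex_glcm3d_homogeneity_mean"]), 1)
  expect_equal(unname(f["tex_glcm3d_energy_mean"]), 1)
  expect_equal(unname(f["tex_glcm3d_entropy_mean"]), 0)
  expect_true(all(f[grep("range", names(f))] == 0))

  # 4x4 checkerboard, two levels, distance 1: axis offsets have contrast 1
  # (every pair differs by one level), diagonal in-plane offsets 0, so the
  # mean over the 4 valid offsets is 0.5 and the range is 1
  chk <- array((row(matrix(0, 4, 4)) + col(matrix(0, 4, 4))) %% 2, c(4, 4, 1))
  f2 <- glcm_features(image_volume(chk, c(1, 1, 1)), array(TRUE, c(4, 4, 1)),
                      texture_config(glcm_levels = 2), scales = NULL)
  expect_equal(unname(f2["tex_glcm3d_contrast_mean"]), 0.5)
  expect_equal(unname(f2["tex_glcm3d_contrast_range"]), 1)
})

test_that("GLCM features are invariant to monotone affine rescaling", {
  set.seed(4)
  n <- 10L
  a <- array(rnorm(n^3), c(n, n, n))
  m <- array(FALSE, c(n, n, n)); m[2:9, 2:9, 2:9] <- TRUE
  f1 <- glcm_features(image_volume(a, c(1, 1, 1)), m, scales = NULL)
  f2 <- glcm_features(image_volume(3 * a + 100, c(1, 1, 1)), m, scales = NULL)
  expect_equal(f1, f2)
})

test_that("GLCM matrices match brute-force pair counting on random regions", {
  # independent oracle: count in-mask pairs directly, voxel by voxel
  for (seed in 1:5) {
    set.seed(seed)
    a <- array(sample(1:4, 125, replace = TRUE), c(5, 5, 5))
    m <- array(runif(125) > 0.3, c(5, 5, 5))
    if (sum(m) < 2) next
    q <- array(0L, c(5, 5, 5))
    q[m] <- radstab:::quantize_minmax(a[m], 4)
    offs <- radstab:::offsets_3d_13()
    for (k in seq_len(nrow(offs))) {
      d <- offs[k, ]
      # oracle
      M0 <- matrix(0, 4, 4)
      for (x in 1:5) for (y in 1:5) for (z in 1:5) {
        p2 <- c(x, y, z) + d
        if (any(p2 < 1) || any(p2 > 5)) next
        if (!m[x, y, z] || !m[p2[1], p2[2], p2[3]]) next
        i <- q[x, y, z]; j <- q[p2[1], p2[2], p2[3]]
        M0[i, j] <- M0[i, j] + 1
      }
      M0 <- M0 + t(M0)
      pr <- radstab:::glcm_pairs(q, d)
      M1 <- matrix(0, 4, 4)
      if (!is.null(pr))
        M1 <- matrix(tabulate(pr[, 1] + 4 * (pr[, 2] - 1L), 16), 4, 4)
      M1 <- M1 + t(M1)
      expect_equal(M0, M1, ignore_attr = FALSE, tolerance = 0)
    }
  }
})

test_that("run-length statistics agree with direct enumeration", {
  # constant region, single direction along a row of length L: one run,
  # run percentage 1/L
  q <- array(1L, c(6, 1, 1)); m <- array(TRUE, c(6, 1, 1))
  runs <- radstab:::runlength_runs(q, m, rbind(c(1, 0, 0)))
  expect_identical(nrow(runs[[1]]), 1L)
  expect_identical(runs[[1]]$length, 6L)
  expect_equal(unname(radstab:::rl_stats(runs[[1]], 6)["rp"]), 1 / 6)

  # strictly alternating line: all runs length 1, SRE = LRE = 1
  va <- image_volume(array(rep(c(1, 2), 3), c(6, 1, 1)), c(1, 1, 1))
  f <- runlength_features(va, m, resample = FALSE)
  expect_equal(unname(f["tex_rl_sre"]), 1)
  expect_equal(unname(f["tex_rl_lre"]), 1)

  # brute-force oracle on random 6^3 masks, 20 seeds, all 13 directions
  dirs <- radstab:::offsets_3d_13()
  for (seed in 1:20) {
    set.seed(seed)
    a <- array(sample(1:3, 216, replace = TRUE), c(6, 6, 6))
    mk <- array(runif(216) > 0.35, c(6, 6, 6))
    if (!any(mk)) next
    q <- array(0L, c(6, 6, 6)); q[mk] <- a[mk]
    fast <- radstab:::runlength_runs(q, mk, dirs)
    slow <- brute_force_runs(q, mk, dirs)
    for (k in seq_len(nrow(dirs))) {
      ftab <- table(fast[[k]]$level, fast[[k]]$length)
      stab <- table(slow[[k]][, "level"], slow[[k]][, "length"])
      expect_identical(as.vector(ftab), as.vector(stab))
      expect_identical(dimnames(ftab), dimnames(stab))
    }
  }
})

test_that("Law's energies are rotation-invariant and detect gradients", {
  # constant region with the pure smoothing kernel: energy = |c| * 16^3
  n <- 12L
  m <- array(FALSE, c(n, n, n)); m[4:9, 4:9, 4:9] <- TRUE
  vc <- image_volume(array(5, c(n, n, n)), c(1, 1, 1))
  f <- laws_features(vc, m, texture_config(laws_triples = "L5L5L5"),
                     resample = FALSE)
  expect_equal(unname(f["tex_laws_L5L5L5_mean"]), 5 * 16^3)
  expect_equal(unname(f["tex_laws_L5L5L5_sd"]), 0)

  # 90-degree rotation about z: features identical to machine precision
  set.seed(6)
  a <- array(rnorm(n^3), c(n, n, n))
  rot <- function(x) aperm(x[, dim(x)[2]:1, , drop = FALSE], c(2, 1, 3))
  cfg <- texture_config(laws_triples = c("E5L5L5", "S5L5L5", "E5E5E5"))
  f1 <- laws_features(image_volume(a, c(1, 1, 1)), m, cfg, resample = FALSE)
  f2 <- laws_features(image_volume(rot(a), c(1, 1, 1)), rot(m), cfg,
                      resample = FALSE)
  expect_equal(unname(f1), unname(f2), tolerance = 1e-10)

  # edge-kernel energy is larger on a sharp texture than its smoothed copy
  sharp <- array(sample(c(-50, 50), n^3, replace = TRUE), c(n, n, n))
  smooth <- radstab:::smooth_gauss(sharp, 2)
  cfgE <- texture_config(laws_triples = "E5L5L5")
  fe_sharp <- laws_features(image_volume(sharp, c(1, 1, 1)), m, cfgE,
                            resample = FALSE)
  fe_smooth <- laws_features(image_volume(smooth, c(1, 1, 1)), m, cfgE,
                             resample = FALSE)
  expect_gt(fe_sharp["tex_laws_E5L5L5_mean"], fe_smooth["tex_laws_E5L5L5_mean"])
})

test_that("LoG responses vanish on affine images and select blob scale", {
  n <- 24L
  m <- array(FALSE, c(n, n, n)); m[9:16, 9:16, 9:16] <- TRUE
  vc <- image_volume(array(3, c(n, n, n)), c(1, 1, 1))
  f <- log_features(vc, m)
  expect_true(all(abs(f) < 1e-10))

  # linear ramp: the Laplacian annihilates affine functions away from the
  # filter boundary
  ramp <- image_volume(array(rep(seq_len(n), n * n), c(n, n, n)), c(1, 1, 1))
  fr <- log_features(ramp, m, texture_config(log_sigmas = c(1, 2)))
  expect_true(all(abs(fr[grep("mean", names(fr))]) < 1e-6))

  # bright blob of radius 6: center response magnitude peaks at the sigma
  # nearest r/sqrt(3) ~ 3.46
  nb <- 48L; cb <- 24.5
  g <- expand.grid(x = seq_len(nb), y = seq_len(nb), z = seq_len(nb))
  rb <- sqrt((g$x - cb)^2 + (g$y - cb)^2 + (g$z - cb)^2)
  vb <- image_volume(array(ifelse(rb <= 6, 100, 0), c(nb, nb, nb)), c(1, 1, 1))
  cm <- array(FALSE, c(nb, nb, nb)); cm[24:25, 24:25, 24:25] <- TRUE
  fb <- log_features(vb, cm, texture_config(log_sigmas = c(2, 3.46, 5)))
  means <- abs(fb[grep("mean", names(fb))])
  expect_identical(unname(which.max(means)), 2L)
})

test_that("Haar sub-bands satisfy Parseval and detect axis stripes", {
  n <- 16L
  full <- array(TRUE, c(n, n, n))
  vc <- image_volume(array(4, c(n, n, n)), c(1, 1, 1))
  f <- wavelet_features(vc, full)
  details <- f[grep("energy", names(f))]
  details <- details[names(details) != "tex_wav_lll_energy"]
  expect_true(all(details == 0))
  # orthonormal approximation gain: coefficient = c * 2^(3/2)
  expect_equal(unname(f["tex_wav_lll_energy"]), (4 * 2^1.5)^2)

  # Parseval: sum over bands of sum of squared coefficients equals the
  # input sum of squares
  set.seed(1)
  a <- array(rnorm(n^3), c(n, n, n))
  bands <- radstab:::haar3d(a)
  tot <- sum(vapply(bands, function(b) sum(b^2), numeric(1)))
  expect_equal(tot, sum(a^2), tolerance = 1e-6)

  # pure-z stripe pattern: z-detail energy dominates x and y details
  stripe <- array(rep(rep(c(-1, 1), each = 1, length.out = n), each = n * n),
                  c(n, n, n))
  fs <- wavelet_features(image_volume(stripe, c(1, 1, 1)), full)
  expect_gt(fs["tex_wav_llh_energy"],
            10 * max(fs["tex_wav_hll_energy"], fs["tex_wav_lhl_energy"]))
})

test_that("feature extraction is deterministic and dictionary-driven", {
  d <- small_design(n_nodules = 1, seed = 31)
  sim <- cached("sim31", simulate_nodule(d, 1))
  dict <- default_dictionary()
  size_dict <- feature_dictionary(dict[dict$feature_class == "Size", ])
  fv <- extract_all(sim$volume, sim$segmentations[[1]], size_dict)
  expect_identical(names(fv), size_dict$name)
  expect_true(all(is.finite(fv)))

  fv2 <- extract_all(sim$volume, sim$segmentations[[1]], size_dict)
  expect_identical(as.numeric(fv), as.numeric(fv2))
})

test_that("segmentation-insensitive features barely vary across the 9 masks", {
  # homogeneous nodule: mean intensity nearly identical over segmentations
  d <- study_design(n_nodules = 1, volume_shape = c(48, 48, 48),
                    spacing = c(1, 1, 1), noise_sd = 2,
                    nodule_size_range = c(12, 12), seed = 17)
  nod <- nodule_spec(center = c(24, 24, 24), semi_axes = c(6, 6, 6),
                     mean_intensity = 50, texture_amplitude = 0,
                     margin_sharpness = 0.3, lobulation_amplitude = 0)
  vol <- generate_volume(d, nod, seed = 2)
  tm <- truth_mask(d, nod)
  # inward-only perturbations keep every variant inside the homogeneous
  # core, the regime in which intensity features are segmentation-blind
  segs <- generate_segmentations(tm, d, nodule_id = 1, seed = 4,
                                 offsets = c(-4, -3, -2))
  dict <- default_dictionary()
  int_dict <- feature_dictionary(dict[dict$name == "int_mean", ])
  means <- vapply(segs, function(s)
    unname(extract_all(vol, s, int_dict)["int_mean"]), numeric(1))
  expect_lt(diff(range(means)) / abs(mean(means)), 0.01)
})
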