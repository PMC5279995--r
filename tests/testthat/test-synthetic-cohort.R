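test_that("generated volumes honour the noise and margin contracts", {
  d <- study_design(n_nodules = 1, volume_shape = c(48, 48, 48),
                    spacing = c(1, 1, 1), noise_sd = 0,
                    nodule_size_range = c(10, 10), seed = 7)
  nod <- nodule_spec(center = c(24, 24, 24), semi_axes = c(5, 5, 5),
                     mean_intensity = 30, texture_amplitude = 0,
                     margin_sharpness = 0.1, lobulation_amplitude = 0)
  v <- generate_volume(d, nod, seed = 1)
  # voxels well inside the nodule equal the core intensity exactly
  core <- v$data[23:25, 23:25, 23:25]
  expect_true(all(core == 30))
  # far corner is pure background
  expect_true(all(v$data[1:5, 1:5, 1:5] == -800))

  # determinism: same (design, nodule, seed) -> bit-identical volumes
  d2 <- study_design(n_nodules = 1, volume_shape = c(48, 48, 48),
                     spacing = c(1, 1, 1), noise_sd = 20,
                     nodule_size_range = c(10, 10), seed = 7)
  v1 <- generate_volume(d2, nod, seed = 3)
  v2 <- generate_volume(d2, nod, seed = 3)
  expect_identical(v1$data, v2$data)

  # sample SD of a 10^3 background region within 10% of noise_sd = 20
  bg <- v1$data[1:10, 1:10, 1:10]
  expect_lt(abs(sd(as.vector(bg)) - 20) / 20, 0.10)

  # nodule outside the field of view errors naming the axis
  far <- nodule_spec(center = c(46, 24, 24), semi_axes = c(5, 5, 5))
  expect_error(generate_volume(d2, far), "axis 1")
})

test_that("segmentation perturbations preserve the mask invariants", {
  d <- small_design(n_nodules = 1, seed = 9)
  nod <- sample_nodules(d)[[1]]
  tm <- truth_mask(d, nod)
  segs <- generate_segmentations(tm, d, nodule_id = 1)
  expect_length(segs, 9L)
  for (s in segs) {
    expect_gt(sum(s$mask), 0)
    expect_identical(radstab:::n_components(s$mask), 1L)
  }
  # identity perturbation: zero offsets and zero jitter reproduce nearly
  # the truth after smoothing-free thresholding
  segs0 <- generate_segmentations(tm, d, nodule_id = 1, offsets = c(0, 0, 0),
                                  smooth_sigmas = rep(1e-6, 3),
                                  jitter_amplitude = 0)
  for (s in segs0) expect_identical(s$mask, tm)

  # determinism, record-wise
  segs2 <- generate_segmentations(tm, d, nodule_id = 1)
  expect_identical(lapply(segs, `[[`, "mask"), lapply(segs2, `[[`, "mask"))
})

test_that("cohort size is exactly nodules x algorithms x initializations", {
  d <- small_design(n_nodules = 4, seed = 3)
  cohort <- cached("cohort4", simulate_cohort(d))
  expect_length(cohort$records, 4L * 3L * 3L)
  ids <- t(vapply(cohort$records,
                  function(r) c(r$nodule_id, r$algorithm_id, r$init_id),
                  integer(3)))
  expect_false(anyDuplicated(as.data.frame(ids)) > 0)
})

test_that("repeatability exceeds reproducibility in mask overlap", {
  # intra-algorithm Dice above inter-algorithm Dice, per nodule
  d <- small_design(n_nodules = 5, seed = 21)
  nods <- sample_nodules(d)
  intra <- c(); inter <- c()
  for (i in seq_len(d$n_nodules)) {
    tm <- truth_mask(d, nods[[i]])
    segs <- generate_segmentations(tm, d, nodule_id = i)
    alg <- vapply(segs, `[[`, integer(1), "algorithm_id")
    for (a in 1:8) for (b in (a + 1):9) {
      dc <- dice(segs[[a]]$mask, segs[[b]]$mask)
      if (alg[a] == alg[b]) intra <- c(intra, dc) else inter <- c(inter, dc)
    }
  }
  expect_gt(mean(intra), mean(inter))
})

test_that("dice matches its closed form and rejects degenerate input", {
  m <- array(FALSE, c(4, 4, 4)); m[2:3, 2:3, 2:3] <- TRUE
  expect_equal(dice(m, m), 1.0)
  m2 <- array(FALSE, c(4, 4, 4)); m2[1, 1, 1] <- TRUE
  expect_equal(dice(m, m2), 0.0)
  # |A| = |B| = 8, |A n B| = 4 -> 0.5
  a <- array(FALSE, c(4, 4, 4)); a[1:2, 1:2, 1:2] <- TRUE
  b <- array(FALSE, c(4, 4, 4)); b[1:2, 1:2, 2:3] <- TRUE
  expect_equal(dice(a, b), 0.5)
  expect_error(dice(a, array(FALSE, c(3, 3, 3))), "shape")
  e <- array(FALSE, c(4, 4, 4))
  expect_error(dice(e, e), "empty")
})
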