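test_that("intensity statistics handle constant and symmetric regions", {
  m <- array(FALSE, c(8, 8, 8)); m[2:7, 2:7, 2:7] <- TRUE
  v <- image_volume(array(42, c(8, 8, 8)), c(1, 1, 1))
  f <- intensity_features(v, m)
  expect_equal(unname(f[c("int_mean", "int_median", "int_min", "int_max")]),
               rep(42, 4))
  expect_equal(unname(f["int_sd"]), 0)
  expect_equal(unname(f["int_entropy"]), 0)
  expect_equal(unname(f["int_energy"]), 1)
  # skewness/kurtosis undefined for a constant region -> NA, not NaN storm
  expect_true(is.na(f["int_skewness"]) && is.na(f["int_kurtosis"]))

  # symmetric two-value region -> zero skewness
  a <- array(rep(c(10, 20), 108), c(6, 6, 6))
  f2 <- intensity_features(image_volume(a, c(1, 1, 1)),
                           array(TRUE, c(6, 6, 6)))
  expect_equal(unname(f2["int_skewness"]), 0)
})

test_that("kurtosis of a large normal sample is near 3", {
  set.seed(11)
  n <- 22L  # 10648 > 10^4 samples
  a <- array(rnorm(n^3), c(n, n, n))
  f <- intensity_features(image_volume(a * 50, c(1, 1, 1)),
                          array(TRUE, c(n, n, n)))
  expect_equal(unname(f["int_kurtosis"]), 3, tolerance = 0.15 / 3)
})

test_that("parenchyma ring surrounds the nodule and stays disjoint", {
  # centered sphere r = 5 in a large volume: ring reaches ~2r from center
  m <- digital_sphere(5, n = 41)
  ring <- parenchyma_mask(m, c(1, 1, 1))
  expect_false(any(ring & m))
  idx <- which(ring, arr.ind = TRUE)
  d <- sqrt(rowSums(sweep(idx, 2, c(21, 21, 21))^2))
  expect_equal(max(d), 10, tolerance = 0.1)  # outer radius ~ 2r (+-1 voxel)

  # nodule touching the volume edge: ring clipped but nonempty, disjoint
  edge <- digital_sphere(5, n = 21, center = c(5, 11, 11))
  ring2 <- parenchyma_mask(edge, c(1, 1, 1))
  expect_gt(sum(ring2), 0)
  expect_false(any(ring2 & edge))
})

test_that("sigmoid margin fits recover edge contrast and track sharpness", {
  # noise-free step-edge sphere: fitted height ~ inside-outside contrast
  n <- 40L; c0 <- 20.5
  g <- expand.grid(x = seq_len(n), y = seq_len(n), z = seq_len(n))
  r <- sqrt((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2)
  mask <- array(r <= 10, c(n, n, n))
  vol <- image_volume(array(ifelse(r <= 10, 100, -100), c(n, n, n)), c(1, 1, 1))
  mf <- margin_features(vol, mask, n_normals = 200)
  expect_equal(unname(mf["mar_sigmoid_height_mean_hu"]), 200, tolerance = 0.10)

  # generator nodules: wider margin -> larger fitted sigmoid width
  d <- study_design(n_nodules = 1, volume_shape = c(64, 64, 64),
                    spacing = c(1, 1, 1), noise_sd = 5,
                    nodule_size_range = c(12, 12), seed = 3)
  widths <- vapply(c(0.5, 3.0), function(ms) {
    nod <- nodule_spec(center = c(32, 32, 32), semi_axes = c(6, 6, 6),
                       mean_intensity = 0, texture_amplitude = 0,
                       margin_sharpness = ms, lobulation_amplitude = 0)
    v <- generate_volume(d, nod, seed = 9)
    m <- margin_features(v, truth_mask(d, nod), n_normals = 200)
    unname(m["mar_sigmoid_width_mean_mm"])
  }, numeric(1))
  expect_gt(widths[2], widths[1])

  # zero-contrast nodule: no edge, height ~ 0 and boundary gradient at the
  # noise floor
  nod0 <- nodule_spec(center = c(32, 32, 32), semi_axes = c(6, 6, 6),
                      mean_intensity = -800, texture_amplitude = 0,
                      margin_sharpness = 1, lobulation_amplitude = 0)
  v0 <- generate_volume(d, nod0, seed = 5)
  m0 <- margin_features(v0, truth_mask(d, nod0), n_normals = 100)
  h <- m0["mar_sigmoid_height_mean_hu"]
  expect_true(is.na(h) || abs(h) < 15)  # well under any real contrast
  expect_lt(m0["mar_grad_boundary_mean"], 15)
})
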