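test_that("pairwise CCC matches hand-derived values and conventions", {
  # s_xy = s_x^2 = s_y^2 = 2/3, mean shift 1 -> (4/3) / (7/3) = 4/7
  expect_equal(pairwise_ccc(c(1, 2, 3), c(2, 3, 4)), 4 / 7)
  expect_equal(pairwise_ccc(c(1, 5, 2, 7), c(1, 5, 2, 7)), 1)
  # degenerate conventions
  expect_equal(pairwise_ccc(c(2, 2, 2), c(2, 2, 2)), 1)
  expect_equal(pairwise_ccc(c(2, 2, 2), c(5, 5, 5)), 0)
  expect_true(is.na(pairwise_ccc(c(1, 2), c(1, 2))))
  # anti-concordant: y = -x + 2 mean(x)
  x <- c(1, 2, 3, 4)
  y <- -x + 2 * mean(x)
  expect_lte(pairwise_ccc(x, y), 0)
})

test_that("CCC is symmetric, bounded, affine-invariant and below Pearson", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(3:30, 1)
    x <- rnorm(n); y <- rnorm(n) + runif(1, -2, 2)
    cc <- pairwise_ccc(x, y)
    expect_equal(cc, pairwise_ccc(y, x))
    expect_lte(abs(cc), 1)
    expect_lte(abs(cc), abs(cor(x, y)) + 1e-12)
  }
  # same positive affine map on both arguments leaves CCC unchanged
  set.seed(5)
  x <- rnorm(20); y <- x + rnorm(20, 0, 0.3)
  expect_equal(pairwise_ccc(2.5 * x + 7, 2.5 * y + 7), pairwise_ccc(x, y))
})

test_that("repeated-measures CCC separates the three replicate strata", {
  # segmentation-invariant feature -> all modes exactly 1
  tb1 <- simulate_feature_table(n_nodules = 20, sd_nodule = 1,
                                sd_algorithm = 0, sd_init = 0, seed = 2)
  for (m in c("overall", "inter", "intra"))
    expect_equal(repeated_measures_ccc(tb1, "feature", m)$ccc, 1)

  # independent noise, no nodule effect: overall CCC within 0.1 of 0
  tb0 <- simulate_feature_table(n_nodules = 200, sd_nodule = 0,
                                sd_algorithm = 0, sd_init = 1, seed = 8)
  expect_lt(abs(repeated_measures_ccc(tb0, "feature")$ccc), 0.1)

  # algorithm offsets depress inter more than intra
  tb <- simulate_feature_table(n_nodules = 52, sd_nodule = 1,
                               sd_algorithm = 0.3, sd_init = 0.1, seed = 4)
  intra <- repeated_measures_ccc(tb, "feature", "intra")$ccc
  inter <- repeated_measures_ccc(tb, "feature", "inter")$ccc
  overall <- repeated_measures_ccc(tb, "feature", "overall")$ccc
  expect_gt(intra, inter)
  # overall is a pair-count weighted mean of the two strata
  expect_equal(overall, (9 * intra + 27 * inter) / 36)
  expect_gte(overall, min(intra, inter))
  expect_lte(overall, max(intra, inter))
})

test_that("increasing init noise monotonically lowers intra CCC", {
  for (seed in 1:3) {
    cccs <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(s) {
      tb <- simulate_feature_table(n_nodules = 80, sd_nodule = 1,
                                   sd_algorithm = 0.2, sd_init = s,
                                   seed = seed)
      repeated_measures_ccc(tb, "feature", "intra")$ccc
    }, numeric(1))
    expect_true(all(diff(cccs) < 0))
  }
})

test_that("CCC modes are invariant to a common affine rescaling of a feature", {
  tb <- simulate_feature_table(n_nodules = 30, seed = 12)
  tb2 <- tb; tb2$feature <- 3 * tb2$feature + 100
  for (m in c("overall", "inter", "intra"))
    expect_equal(repeated_measures_ccc(tb2, "feature", m)$ccc,
                 repeated_measures_ccc(tb, "feature", m)$ccc)
})

test_that("missing results carry a reason instead of a value", {
  tb <- simulate_feature_table(n_nodules = 2, seed = 1)
  res <- repeated_measures_ccc(tb, "feature")
  expect_true(is.na(res$ccc))
  expect_match(res$reason, "usable")
})

test_that("stability summary counts fractions and quartiles per class", {
  st <- data.frame(feature = c("a1", "a2", "a3"),
                   ccc_overall = c(0.5, 0.8, 1.0),
                   ccc_inter = NA_real_, ccc_intra = NA_real_,
                   n_nodules_used = 10L)
  class(st) <- c("feature_stability", "data.frame")
  dict <- feature_dictionary(data.frame(name = st$feature,
                                        feature_class = "Size"))
  s <- stability_summary(st, dict, thresholds = 0.75)
  expect_equal(unname(s$overall_fractions), 100 * 2 / 3)
  expect_equal(s$per_class$median, 0.8)

  # all CCC = 1 -> every fraction 100%
  st2 <- st; st2$ccc_overall <- 1
  s2 <- stability_summary(st2, dict, thresholds = c(0.75, 0.95))
  expect_equal(unname(s2$overall_fractions), c(100, 100))

  # a feature absent from the dictionary is an error
  dict_short <- feature_dictionary(data.frame(name = c("a1", "a2"),
                                              feature_class = "Size"))
  expect_error(stability_summary(st, dict_short), "without dictionary")
})

test_that("class ANOVA reproduces hand-computed F statistics", {
  mk <- function(vals, classes) {
    st <- data.frame(feature = sprintf("f%d", seq_along(vals)),
                     ccc_overall = vals, ccc_inter = NA_real_,
                     ccc_intra = NA_real_)
    class(st) <- c("feature_stability", "data.frame")
    dict <- feature_dictionary(data.frame(name = st$feature,
                                          feature_class = classes))
    class_anova(st, dict, "overall")
  }
  # groups {1,2,3} and {2,3,4}: between SS 1.5 (df 1), within SS 4 (df 4)
  a <- mk(c(1, 2, 3, 2, 3, 4), rep(c("Size", "GSD"), each = 3))
  expect_equal(a$F, 1.5)
  expect_equal(a$df, c(1, 4))

  # identical groups -> F ~ 0, p ~ 1
  b <- mk(c(0.1, 0.5, 0.9, 0.1, 0.5, 0.9), rep(c("Size", "GSD"), each = 3))
  expect_lt(b$F, 1e-10)
  expect_gt(b$p_value, 0.999)

  # complete separation -> tiny p
  set.seed(3)
  cc <- mk(c(0, 0, 0, 1, 1, 1) + rnorm(6, 0, 1e-3),
           rep(c("Size", "GSD"), each = 3))
  expect_lt(cc$p_value, 1e-6)
})
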