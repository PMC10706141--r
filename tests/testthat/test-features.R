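test_that("histogram features match hand-computed moments and entropy", {
  # constant ROI: degenerate convention
  expect_equal(histogram_features(uniform_slice(200), full_mask()),
               c(mean = 200, sd = 0, skewness = 0, kurtosis = 0, entropy = 0))

  # 16-pixel ROI, half 0 HU and half 100 HU: two-point distribution
  sl <- ct_slice(matrix(rep(c(0, 100), 32), 8, 8))  # alternating 0/100 HU
  m16 <- roi_mask(matrix(c(rep(TRUE, 16), rep(FALSE, 48)), 8, 8))
  f <- histogram_features(sl, m16)
  expect_equal(unname(f["mean"]), 50)
  expect_equal(unname(f["sd"]), sqrt(16 * 2500 / 15))  # sample sd, ddof = 1
  expect_equal(unname(f["skewness"]), 0)
  expect_equal(unname(f["kurtosis"]), 6.25e6 / (16 * 2500 / 15)^2)
  expect_equal(unname(f["entropy"]), 1)  # two occupied bins, p = 1/2 each

  expect_error(histogram_features(sl, roi_mask(matrix(FALSE, 8, 8))),
               class = "bonetex_roi_too_small")
})

test_that("histogram features are translation covariant", {
  withr::local_seed(1)
  sl <- ct_slice(matrix(rnorm(256, 100, 40), 16, 16))
  shifted <- ct_slice(sl$hu + 75)
  f0 <- histogram_features(sl, full_mask())
  f1 <- histogram_features(shifted, full_mask())
  expect_equal(unname(f1["mean"] - f0["mean"]), 75)
  expect_equal(f1[c("sd", "skewness", "kurtosis", "entropy")],
               f0[c("sd", "skewness", "kurtosis", "entropy")])
})

test_that("quantization uses half-open equal-width bins with a closed top edge", {
  hu <- matrix(0, 8, 8)
  hu[1, 1:4] <- c(0, 49, 50, 100)
  q <- quantize_roi(ct_slice(hu), full_mask(8), n = 2)
  expect_identical(q$levels[1, 1:4], c(1L, 1L, 2L, 2L))

  qc <- quantize_roi(uniform_slice(37), full_mask(), n = 64)
  expect_true(all(qc$levels == 1L))

  withr::local_seed(2)
  sl <- ct_slice(matrix(rnorm(256), 16, 16))
  q128 <- quantize_roi(sl, full_mask(), n = 128)
  expect_true(all(q128$levels >= 1 & q128$levels <= 128))
  expect_identical(max(q128$levels), 128L)  # max maps to n
  expect_error(quantize_roi(sl, full_mask(), n = 1), "n")
})

test_that("the worked 4x4 co-occurrence example is reproduced exactly", {
  g <- compute_glcm(quantized(checker_image(), 2), "horizontal")
  expect_identical(g$counts, rbind(c(4L, 2L), c(2L, 4L)))
  expect_equal(g$probs, rbind(c(1/3, 1/6), c(1/6, 1/3)))

  s <- glcm_statistics(g)
  expect_equal(unname(s["contrast"]), 1/3)
  expect_equal(unname(s["correlation"]), 1/3)
  expect_equal(unname(s["energy"]), 5/18)
  expect_equal(unname(s["homogeneity"]), 5/6)
  expect_equal(unname(s["variance"]), 1/4)
})

test_that("co-occurrence counting matches a brute-force oracle on random images", {
  withr::local_seed(99)
  for (i in 1:250) {
    nr <- sample(2:6, 1); nc <- sample(2:6, 1); n <- sample(2:4, 1)
    lv <- matrix(sample.int(n, nr * nc, replace = TRUE), nr, nc)
    lv[matrix(runif(nr * nc) < 0.2, nr, nc)] <- NA  # fragmented ROI
    for (dir in c("horizontal", "vertical")) {
      expected <- brute_force_glcm_counts(lv, n, dir)
      if (sum(expected) == 0) {
        expect_error(compute_glcm(quantized(lv, n), dir), "fragmented")
      } else {
        g <- compute_glcm(quantized(lv, n), dir)
        expect_identical(g$counts, expected + 0L)
        expect_equal(sum(g$probs), 1, tolerance = 1e-12)
      }
    }
  }
})

test_that("horizontal GLCM of an image equals vertical GLCM of its transpose", {
  withr::local_seed(5)
  lv <- matrix(sample.int(3, 36, replace = TRUE), 6, 6)
  h <- compute_glcm(quantized(lv, 3), "horizontal")
  v <- compute_glcm(quantized(t(lv), 3), "vertical")
  expect_identical(h$counts, v$counts)
})

test_that("degenerate and bounded behavior of the Haralick statistics", {
  const <- compute_glcm(quantized(matrix(1L, 4, 4), 2), "horizontal")
  expect_equal(unname(const$probs[1, 1]), 1)
  s <- glcm_statistics(const)
  expect_equal(unname(s), c(0, 0, 1, 1, 0))

  withr::local_seed(12)
  for (i in 1:50) {
    n <- sample(2:5, 1)
    lv <- matrix(sample.int(n, 49, replace = TRUE), 7, 7)
    s <- glcm_statistics(compute_glcm(quantized(lv, n), "vertical"))
    expect_lte(s[["energy"]], 1)
    expect_gte(s[["contrast"]], 0)
    expect_gt(s[["homogeneity"]], 0)
    expect_lte(s[["homogeneity"]], 1)
    expect_lte(abs(s[["correlation"]]), 1 + 1e-12)
  }
})

test_that("the feature index is the documented bijection onto 1..45", {
  expect_identical(feature_index("histogram", k = 1), 1L)
  expect_identical(feature_index("histogram", k = 5), 5L)
  expect_identical(feature_index("glcm", l = 1, m = 1, n = 1), 6L)
  expect_identical(feature_index("glcm", l = 2, m = 4, n = 5), 45L)

  all_j <- c(
    vapply(1:5, function(k) feature_index("histogram", k = k), integer(1)),
    unlist(lapply(1:2, function(l) lapply(1:4, function(m) lapply(1:5,
      function(n) feature_index("glcm", l = l, m = m, n = n)))))
  )
  expect_identical(sort(all_j), 1:45)  # bijective onto 1..45
  expect_error(feature_index("glcm", l = 3, m = 1, n = 1), "l")

  map <- feature_index_map()
  expect_identical(nrow(map), 45L)
  expect_identical(map$j, 1:45)
})

test_that("the full signature has 45 entries and composes its parts correctly", {
  vol <- withr::with_seed(8, render_slice_stack(15, sim_config()))
  sel <- select_roi(vol)
  fv <- extract_feature_vector(sel$slice, sel$roi)
  expect_length(fv, 45)
  expect_true(all(is.finite(fv)))
  expect_identical(names(fv), paste0("j", 1:45))

  # constant ROI: histogram degenerates to (c, 0, 0, 0, 0) and every GLCM
  # block to (contrast 0, correlation 0, energy 1, homogeneity 1, variance 0)
  fc <- extract_feature_vector(uniform_slice(123), full_mask())
  expect_equal(as.numeric(fc), c(123, 0, 0, 0, 0, rep(c(0, 0, 1, 1, 0), 8)))
})

test_that("GLCM features are invariant to a constant HU shift", {
  vol <- withr::with_seed(9, render_slice_stack(15, sim_config()))
  sel <- select_roi(vol)
  fv0 <- extract_feature_vector(sel$slice, sel$roi)
  shifted <- ct_slice(sel$slice$hu + 40, spacing = sel$slice$spacing)
  fv1 <- extract_feature_vector(shifted, sel$roi)
  expect_equal(unname(fv1[6:45]), unname(fv0[6:45]))
  expect_equal(unname(fv1[1]), unname(fv0[1]) + 40)
})

test_that("the change design concatenates timepoints and differences targets", {
  fv1 <- stats::setNames(rnorm(45), paste0("j", 1:45))
  fv2 <- stats::setNames(rnorm(45), paste0("j", 1:45))
  d <- build_change_design(fv1, fv2, y1 = 15, y2 = 14.2)
  expect_length(d$values, 90)
  expect_equal(unname(d$values), c(unname(fv1), unname(fv2)))
  expect_equal(d$target, -0.8)

  same <- build_change_design(fv1, fv1, 10, 10)
  expect_equal(same$target, 0)
  expect_equal(unname(same$values[1:45]), unname(same$values[46:90]))

  swapped <- build_change_design(fv2, fv1, 14.2, 15)
  expect_equal(swapped$target, -d$target)

  expect_error(build_change_design(fv1[1:44], fv2, 1, 2), "45")
})

test_that("texture features separate low- from normal-BMC phantoms", {
  # Homogeneity of a two-phase texture is symmetric under phase exchange, so
  # arms symmetric about bone fraction 0.5 are indistinguishable by design;
  # an osteoporotic (10 g) vs average (15 g) contrast is the relevant one.
  cfg <- sim_config(n_slices = 1)
  homog <- function(bmc, seed) {
    vol <- withr::with_seed(seed, render_slice_stack(bmc, cfg))
    sel <- select_roi(vol)
    q <- quantize_roi(sel$slice, sel$roi, 16)
    glcm_statistics(compute_glcm(q, "horizontal"))[["homogeneity"]]
  }
  lo <- vapply(1:100, function(s) homog(10, s), numeric(1))
  hi <- vapply(1:100, function(s) homog(15, 5000 + s), numeric(1))
  expect_lt(t.test(lo, hi)$p.value, 0.01)
})

test_that("cohort feature tables have one row and 45 features per scan", {
  co <- generate_cohort(sim_config(n_subjects = 4, n_slices = 1, seed = 21))
  ft <- extract_cohort_features(co)
  expect_identical(nrow(ft), 8L)
  expect_true(all(paste0("j", 1:45) %in% names(ft)))

  ch <- build_change_table(ft)
  expect_identical(nrow(ch), 4L)
  expect_true(all(paste0("x", 1:90) %in% names(ch)))
  # x_{j+45} is the timepoint-2 value of the same feature j
  t2 <- ft[ft$timepoint == 2, ]
  expect_equal(ch$x46, t2$j1[order(t2$subject_id)])
  expect_equal(ch$d_bmc,
               ft$bmc_true[ft$timepoint == 2] - ft$bmc_true[ft$timepoint == 1])
})
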