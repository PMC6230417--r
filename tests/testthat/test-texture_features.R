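test_that("quantization clips to the window and bins uniformly", {
  expect_identical(quantize(-100, 32, c(-100, 300)), 0L)
  expect_identical(quantize(-500, 32, c(-100, 300)), 0L)
  expect_identical(quantize(300, 32, c(-100, 300)), 31L)
  expect_identical(quantize(1000, 32, c(-100, 300)), 31L)
  expect_identical(quantize(100, 32, c(-100, 300)), 16L)

  x <- sort(runif(100, -200, 400))
  q <- quantize(x, 32, c(-100, 300))
  expect_true(all(diff(q) >= 0)) # monotone in HU
  expect_identical(unique(as.vector(quantize(array(42, c(3, 3, 3))))), 11L)

  expect_error(quantize(1, levels = 1), class = "ctb_contract_error")
  expect_error(quantize(1, hu_window = c(10, 10)), class = "ctb_contract_error")
})

test_that("GLCM of simple patches matches hand enumeration", {
  # constant patch: all mass on one diagonal cell
  g <- glcm_3d(array(3L, c(3, 3, 3)), levels = 8)
  expect_equal(g$p[4, 4], 1)
  expect_equal(sum(g$p), 1)

  # alternating strip, offset along the strip: pure off-diagonal
  strip <- array(c(0L, 1L, 0L, 1L, 0L, 1L), c(1, 1, 6))
  g <- glcm_3d(strip, offsets = matrix(c(0L, 0L, 1L), 1), symmetric = TRUE,
               levels = 2)
  expect_equal(g$p, matrix(c(0, .5, .5, 0), 2))
})

test_that("GLCM equals a brute-force pair-enumeration oracle on random patches", {
  set.seed(77)
  for (i in 1:6) {
    d <- sample(3:6, 3, replace = TRUE)
    L <- sample(3:6, 1)
    patch <- array(sample(0:(L - 1), prod(d), replace = TRUE), d)
    off <- glcm_offsets_3d()
    g <- glcm_3d(patch, off, symmetric = TRUE, levels = L)
    expect_equal(g$p, oracle_glcm(patch, off, TRUE, L), tolerance = 1e-12)
    # invariants: normalized, non-negative, symmetric
    expect_equal(sum(g$p), 1, tolerance = 1e-9)
    expect_true(all(g$p >= 0))
    expect_equal(g$p, t(g$p))
  }
})

test_that("offset order is irrelevant and reversed offsets reproduce symmetry", {
  set.seed(3)
  patch <- array(sample(0:3, 64, replace = TRUE), c(4, 4, 4))
  off <- glcm_offsets_3d()
  g1 <- glcm_3d(patch, off, symmetric = TRUE, levels = 4)
  g2 <- glcm_3d(patch, off[sample(nrow(off)), ], symmetric = TRUE, levels = 4)
  expect_equal(g1$p, g2$p)
  # asymmetric count over +/- offsets equals the symmetric count
  g3 <- glcm_3d(patch, rbind(off, -off), symmetric = FALSE, levels = 4)
  expect_equal(g1$p, g3$p, tolerance = 1e-12)
})

test_that("GLCM rejects zero and oversized offsets", {
  patch <- array(0:1, c(2, 2, 2))
  expect_error(glcm_3d(patch, matrix(0L, 1, 3), levels = 2),
               class = "ctb_contract_error")
  expect_error(glcm_3d(patch, matrix(c(2L, 0L, 0L), 1), levels = 2),
               class = "ctb_contract_error")
})

test_that("Haralick features match closed forms and the naive oracle", {
  # point mass: maximal order
  g1 <- glcm_3d(array(2L, c(2, 2, 2)), levels = 4)
  f1 <- haralick_features(g1)
  expect_equal(unname(f1[c("contrast", "entropy", "correlation")]),
               c(0, 0, 0))
  expect_equal(unname(f1["energy"]), 1)

  # checkerboard 2x2: P(0,1) = P(1,0) = 1/2
  strip <- array(c(0L, 1L, 0L, 1L, 0L, 1L), c(1, 1, 6))
  f2 <- haralick_features(glcm_3d(strip, matrix(c(0L, 0L, 1L), 1),
                                  levels = 2))
  expect_equal(unname(f2["contrast"]), 1)
  expect_equal(unname(f2["correlation"]), -1)
  expect_equal(unname(f2["entropy"]), 1)
  expect_equal(unname(f2["energy"]), 0.5)
  expect_equal(unname(f2["homogeneity"]), 0.5)

  set.seed(13)
  for (i in 1:5) {
    L <- sample(3:8, 1)
    patch <- array(sample(0:(L - 1), 125, replace = TRUE), c(5, 5, 5))
    g <- glcm_3d(patch, levels = L)
    expect_equal(haralick_features(g), oracle_haralick(g$p),
                 tolerance = 1e-12)
  }
})

test_that("feature_map agrees with per-voxel naive recomputation", {
  set.seed(29)
  d <- c(16, 16, 16)
  v <- ct_volume(array(rnorm(prod(d), 60, 40), d))
  roi_arr <- array(FALSE, d)
  # sampled interior and border voxels, including the grid corner
  picks <- rbind(cbind(sample(3:14, 10, TRUE), sample(3:14, 10, TRUE),
                       sample(3:14, 10, TRUE)),
                 c(1, 1, 1), c(16, 16, 16), c(1, 8, 16))
  roi_arr[picks] <- TRUE
  roi <- ct_mask(roi_arr, spacing = v$spacing)
  win <- 5L
  fm <- feature_map(v, roi, window = win)
  q <- quantize(v$data)
  h <- (win - 1L) / 2L
  for (r in seq_len(nrow(fm))) {
    at <- c(fm$z[r], fm$y[r], fm$x[r])
    lo <- pmax(at - h, 1); hi <- pmin(at + h, d)
    patch_hu <- v$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    patch_q <- q[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    expect_equal(unlist(fm[r, c("mean", "sd", "skewness", "kurtosis",
                                "median")]),
                 stat_features(as.vector(patch_hu)), tolerance = 1e-10)
    g <- glcm_3d(patch_q, levels = 32)
    expect_equal(unlist(fm[r, c("contrast", "correlation", "entropy",
                                "energy", "homogeneity")]),
                 haralick_features(g), tolerance = 1e-10)
  }
})

test_that("constant volumes give degenerate features without error", {
  d <- c(8, 8, 8)
  v <- ct_volume(array(75, d))
  roi <- ct_mask(array(TRUE, d), spacing = v$spacing)
  fm <- feature_map(v, roi, window = 3)
  expect_true(all(fm$mean == 75))
  expect_true(all(fm$sd == 0))
  expect_true(all(fm$energy == 1))
  expect_true(all(fm$correlation == 0)) # zero-variance convention
  expect_error(feature_map(v, roi, window = 4), class = "ctb_contract_error")
})

test_that("HU shifts move statistical means but not GLCM features", {
  set.seed(9)
  d <- c(10, 10, 10)
  base <- array(rnorm(prod(d), 100, 30), d)
  v1 <- ct_volume(base)
  v2 <- ct_volume(base + 50)
  roi_arr <- array(FALSE, d); roi_arr[5, 5, 5] <- TRUE
  roi <- ct_mask(roi_arr)
  f1 <- feature_map(v1, roi, window = 5, hu_window = c(-100, 300))
  f2 <- feature_map(v2, roi, window = 5, hu_window = c(-50, 350))
  expect_equal(f2$mean, f1$mean + 50, tolerance = 1e-9)
  for (g in c("contrast", "correlation", "entropy", "energy", "homogeneity")) {
    expect_equal(f2[[g]], f1[[g]], tolerance = 1e-9)
  }
})
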