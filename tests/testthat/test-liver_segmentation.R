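test_that("EM recovers the generative parameters of a bimodal HU mixture", {
  set.seed(41)
  x <- c(rnorm(5000, -70, 15), rnorm(5000, 100, 12))
  fit <- fit_gmm_em(x)
  ord <- order(fit$means)
  expect_lt(abs(fit$means[ord[1]] - (-70)), 2)
  expect_lt(abs(fit$means[ord[2]] - 100), 2)
  expect_lt(max(abs(fit$weights - 0.5)), 0.03)
})

test_that("EM agrees with an independent mixture fitter on separated data", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(7)
  x <- c(rnorm(3000, -70, 15), rnorm(3000, 100, 12))
  fit <- fit_gmm_em(x)
  ref <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$means), sort(as.numeric(ref$parameters$mean)),
               tolerance = 0.02)
})

test_that("EM handles separated point masses and enforces its contract", {
  expect_warning(fit <- fit_gmm_em(c(0, 0, 0, 100, 100, 100)), "clamped")
  expect_equal(sort(fit$means), c(0, 100), tolerance = 1e-6)
  expect_equal(fit$weights, c(0.5, 0.5), tolerance = 1e-6)

  expect_error(fit_gmm_em(rep(5, 10)), class = "ctb_degenerate_data_error")
  expect_error(fit_gmm_em(c(1, 2), max_iter = 0), class = "ctb_contract_error")
})

test_that("the EM log-likelihood trace is non-decreasing on random inputs", {
  set.seed(11)
  iters <- integer(0)
  for (i in 1:8) {
    # overlapping components force several EM iterations
    x <- c(rnorm(300, runif(1, -20, 0), runif(1, 10, 25)),
           rnorm(300, runif(1, 10, 40), runif(1, 10, 25)))
    fit <- fit_gmm_em(x)
    tr <- fit$log_likelihood_trace
    expect_true(all(diff(tr) >= -1e-9))
    iters <- c(iters, fit$n_iter)
  }
  expect_gt(max(iters), 1) # the monotonicity check actually saw a trajectory
})

test_that("the liver HU range follows mu_L +/- k sigma_L of the nearer component", {
  m <- structure(list(weights = c(.5, .5), means = c(-70, 100),
                      variances = c(225, 144)), class = "gmm2")
  r <- estimate_liver_range(m, seed_mask_mean = 95, k = 2.5)
  expect_equal(c(r$lo, r$hi), c(70, 130))
  expect_identical(r$liver_component, 2L)

  expect_error(estimate_liver_range(m, 95, k = 0),
               class = "ctb_contract_error")
  expect_warning(r2 <- estimate_liver_range(m, 15, k = 1), "equidistant")
  expect_identical(r2$liver_component, 1L)
})

test_that("the thresholded mask is invariant under component relabeling", {
  m <- structure(list(weights = c(.4, .6), means = c(-70, 100),
                      variances = c(225, 144)), class = "gmm2")
  swapped <- structure(list(weights = rev(m$weights), means = rev(m$means),
                            variances = rev(m$variances)), class = "gmm2")
  r1 <- estimate_liver_range(m, 95)
  r2 <- estimate_liver_range(swapped, 95)
  expect_equal(c(r1$lo, r1$hi), c(r2$lo, r2$hi))
})

test_that("liver segmentation recovers the phantom liver with Dice >= 0.95", {
  ph <- make_phantom(small_config(21, noise_sd = 8))
  sd2 <- phantom_seed_slice(ph)
  liver <- segment_liver(ph$pre, sd2$slice, sd2$mask)
  expect_gte(dice(liver, ph$truth$liver_mask), 0.95)
  g <- attr(liver, "gmm")
  # liver-component mean is near 100 HU despite tumor voxels on the slice
  expect_lt(abs(sort(g$means)[2] - 100), 5)
})

test_that("a volume entirely in the liver range segments to the whole grid", {
  set.seed(5)
  arr <- array(rnorm(20 * 20 * 20, 100, 5), c(20, 20, 20))
  # a dark strip on the seed slice gives the 2-component fit both classes
  arr[10, 1:6, ] <- rnorm(6 * 20, -70, 5)
  v <- ct_volume(arr)
  seed_mask <- matrix(FALSE, 20, 20); seed_mask[10:16, 10:16] <- TRUE
  m <- segment_liver(v, 10, seed_mask, k = 6, closing_radius_vox = 2)
  # everything at ~100 HU is one component; after closing the grid is full
  # except the deliberately dark strip region
  expect_gt(mean(m$data), 0.95)
})

test_that("only the largest liver-intensity component survives", {
  arr <- array(-70, c(24, 24, 24))
  arr[4:18, 4:18, 4:18] <- 100     # big blob
  arr[21:22, 21:22, 21:22] <- 100  # small distractor
  arr <- arr + array(rnorm(length(arr), 0, 2), dim(arr))
  v <- ct_volume(arr)
  seed_mask <- matrix(FALSE, 24, 24); seed_mask[6:16, 6:16] <- TRUE
  m <- segment_liver(v, 10, seed_mask, closing_radius_vox = 0)
  expect_gt(mean(m$data[6:16, 6:16, 6:16]), 0.95)
  expect_false(any(m$data[21:22, 21:22, 21:22]))
  lab <- label_components(m$data)
  expect_identical(attr(lab, "n_components"), 1L)
})

test_that("EM parameter recovery holds across seeded phantom draws", {
  errs <- vapply(1:8, function(s) {
    ph <- make_phantom(small_config(100 + s))
    sd2 <- phantom_seed_slice(ph)
    fit <- fit_gmm_em(as.vector(ph$pre$data[sd2$slice, , ]))
    abs(sort(fit$means)[2] - 100)
  }, numeric(1))
  expect_lte(median(errs), 2)
})
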