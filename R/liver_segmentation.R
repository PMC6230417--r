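#' Fit a two-component 1-D Gaussian mixture by expectation-maximization
#'
#' Models the HU histogram of an axial CT slice as a mixture of a liver and
#' a non-liver component. Initialization is deterministic: samples are split
#' at their median and each half contributes the initial moments of one
#' component, which is robust for bimodal HU data. The E-step computes
#' responsibilities under the current parameters; the M-step updates
#' weights, means and variances; iteration stops when the relative
#' log-likelihood improvement falls below `tol` or after `max_iter` steps.
#'
#' @param samples numeric vector of HU values (at least two distinct).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol relative log-likelihood convergence tolerance (default 1e-6).
#' @param var_floor variance floor in HU^2 (default 1e-3); a component whose
#'   variance collapses below it is clamped with a warning.
#' @param seed accepted for interface symmetry with stochastic initializers;
#'   the default median-split initialization is deterministic and ignores it.
#' @return An object of class `gmm2`: list with `weights`, `means`,
#'   `variances`, `log_likelihood_trace`, `n_iter`, `converged`.
#' @examples
#' x <- c(rnorm(500, -70, 15), rnorm(500, 100, 12))
#' fit <- fit_gmm_em(x)
#' sort(fit$means)
#' @export
fit_gmm_em <- function(samples, max_iter = 500L, tol = 1e-6,
                       var_floor = 1e-3, seed = NULL) {
  x <- as.numeric(samples)
  x <- x[is.finite(x)]
  if (length(unique(x)) < 2L) {
    stop_ctb("fit_gmm_em: need at least two distinct finite samples",
             class = "ctb_degenerate_data_error")
  }
  if (max_iter < 1L) {
    stop_ctb("fit_gmm_em: max_iter must be >= 1", class = "ctb_contract_error")
  }
  n <- length(x)

  med <- median(x)
  lower <- x[x <= med]
  upper <- x[x > med]
  if (length(upper) == 0L) { # heavy ties at the median
    upper <- x[x >= med]
    lower <- x[x < med]
  }
  mom <- function(v) {
    m <- mean(v)
    s2 <- max(mean((v - m)^2), var_floor)
    c(m, s2)
  }
  ml <- mom(lower); mu <- mom(upper)
  w <- c(length(lower), length(upper)) / n
  means <- c(ml[1], mu[1])
  vars <- c(ml[2], mu[2])

  loglik <- function(w, means, vars) {
    dens <- w[1] * dnorm(x, means[1], sqrt(vars[1])) +
            w[2] * dnorm(x, means[2], sqrt(vars[2]))
    sum(log(pmax(dens, .Machine$double.xmin)))
  }

  trace <- numeric(0)
  clamped <- FALSE
  ll_old <- loglik(w, means, vars)
  it <- 0L
  converged <- FALSE
  while (it < max_iter) {
    it <- it + 1L
    # E-step: responsibilities of component 1 and 2 for each sample
    d1 <- w[1] * dnorm(x, means[1], sqrt(vars[1]))
    d2 <- w[2] * dnorm(x, means[2], sqrt(vars[2]))
    tot <- pmax(d1 + d2, .Machine$double.xmin)
    r1 <- d1 / tot
    r2 <- 1 - r1
    # M-step
    n1 <- sum(r1); n2 <- n - n1
    w <- c(n1, n2) / n
    means <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    vars <- c(sum(r1 * (x - means[1])^2) / n1,
              sum(r2 * (x - means[2])^2) / n2)
    if (any(vars < var_floor)) {
      vars <- pmax(vars, var_floor)
      clamped <- TRUE
    }
    ll <- loglik(w, means, vars)
    trace <- c(trace, ll)
    if (abs(ll - ll_old) <= tol * abs(ll_old)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  if (clamped) {
    warning("fit_gmm_em: a component variance collapsed and was clamped to ",
            var_floor, " HU^2")
  }
  structure(list(weights = w, means = means, variances = vars,
                 log_likelihood_trace = trace, n_iter = it,
                 converged = converged),
            class = "gmm2")
}

#' @export
print.gmm2 <- function(x, ...) {
  cat(sprintf(
    "<gmm2> w = (%.3f, %.3f), mu = (%.1f, %.1f) HU, sigma = (%.1f, %.1f) HU, %d EM iterations\n",
    x$weights[1], x$weights[2], x$means[1], x$means[2],
    sqrt(x$variances[1]), sqrt(x$variances[2]), x$n_iter))
  invisible(x)
}

#' Estimate the liver HU range from a fitted mixture
#'
#' The liver component is the mixture component whose mean is nearer the
#' mean HU of the radiologist's seed region; the thresholding interval is
#' `mu_L +/- k * sigma_L`.
#'
#' @param model a fitted [fit_gmm_em()] object.
#' @param seed_mask_mean mean HU inside the manual seed region.
#' @param k spread multiplier (> 0, default 2.5).
#' @return List of class `intensity_range`: `lo`, `hi`,
#'   `liver_component` (1 or 2).
#' @examples
#' m <- structure(list(weights = c(.5, .5), means = c(-70, 100),
#'                     variances = c(225, 144)), class = "gmm2")
#' estimate_liver_range(m, seed_mask_mean = 95, k = 2.5)
#' @export
estimate_liver_range <- function(model, seed_mask_mean, k = 2.5) {
  stopifnot(inherits(model, "gmm2"))
  if (!is.numeric(k) || length(k) != 1L || k <= 0) {
    stop_ctb("estimate_liver_range: k must be > 0",
             class = "ctb_contract_error")
  }
  d <- abs(model$means - seed_mask_mean)
  if (d[1] == d[2]) {
    warning("seed mean equidistant from both component means; ",
            "choosing component 1")
    comp <- 1L
  } else {
    comp <- which.min(d)
  }
  s <- sqrt(model$variances[comp])
  structure(list(lo = model$means[comp] - k * s,
                 hi = model$means[comp] + k * s,
                 liver_component = comp),
            class = "intensity_range")
}

#' Segment the liver by GMM thresholding
#'
#' Implements the intensity-analysis liver segmentation: a two-component
#' Gaussian mixture is fitted by EM to all HU values of a radiologist-chosen
#' axial seed slice; the manual seed region's mean HU identifies which
#' component is liver; the whole volume is thresholded to
#' `mu_L +/- k sigma_L`; the largest 26-connected component is retained
#' (discarding other organs of similar attenuation); and a morphological
#' closing with a ball structuring element fills small holes.
#'
#' The mixture is fitted on the full seed slice, not only inside the manual
#' region: both classes must be represented for a two-component model to
#' separate them. The manual region is used solely to label the liver
#' component.
#'
#' @param volume a [ct_volume()].
#' @param seed_slice_index axial index of the manually seeded slice.
#' @param seed_mask_2d logical matrix (same in-plane shape as a slice),
#'   non-empty, marking liver on the seed slice.
#' @param k spread multiplier for the HU range (default 2.5).
#' @param closing_radius_vox ball radius in voxels for the closing
#'   (default 2; 0 disables).
#' @param connectivity connectivity for the largest-component step
#'   (6, 18 or 26; default 26).
#' @return A [ct_mask()] with attributes `gmm` (the fitted `gmm2`) and
#'   `range` (the `intensity_range` used).
#' @export
segment_liver <- function(volume, seed_slice_index, seed_mask_2d, k = 2.5,
                          closing_radius_vox = 2L, connectivity = 26L) {
  stopifnot(inherits(volume, "ct_volume"))
  d <- dim(volume$data)
  if (seed_slice_index < 1L || seed_slice_index > d[1]) {
    stop_ctb("segment_liver: seed slice index out of range",
             class = "ctb_contract_error")
  }
  seed_mask_2d <- seed_mask_2d != 0
  if (!identical(dim(seed_mask_2d), d[2:3])) {
    stop_ctb("segment_liver: seed mask shape does not match a slice",
             class = "ctb_contract_error")
  }
  if (!any(seed_mask_2d)) {
    stop_ctb("segment_liver: seed mask is empty", class = "ctb_contract_error")
  }
  slice <- volume$data[seed_slice_index, , ]
  model <- fit_gmm_em(as.vector(slice))
  rng <- estimate_liver_range(model, mean(slice[seed_mask_2d]), k = k)

  inside <- volume$data >= rng$lo & volume$data <= rng$hi
  if (!any(inside)) {
    stop_ctb(sprintf(
      "segment_liver: no voxel falls in the liver HU range [%.1f, %.1f]",
      rng$lo, rng$hi), class = "ctb_empty_segmentation_error")
  }
  lab <- label_components(inside, connectivity = connectivity)
  sizes <- tabulate(lab[lab > 0L])
  keep <- array(lab == which.max(sizes), dim = d)
  if (closing_radius_vox > 0L) {
    keep <- binary_close(keep, closing_radius_vox)
  }
  out <- ct_mask(keep, spacing = volume$spacing)
  attr(out, "gmm") <- model
  attr(out, "range") <- rng
  out
}
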