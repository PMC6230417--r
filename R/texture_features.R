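#' Quantize HU values into gray levels
#'
#' Clips HU to a window and bins it uniformly into `levels` discrete gray
#' levels (0-based), as required by co-occurrence analysis. The mapping is
#' monotone in HU; values at or below the window floor map to level 0 and
#' values at or above the ceiling map to `levels - 1`.
#'
#' @param x a [ct_volume()] or numeric array of HU values.
#' @param levels number of gray levels (>= 2, default 32).
#' @param hu_window `(lo, hi)` HU clipping window, default `c(-100, 300)`,
#'   which covers the liver/tumor parenchyma range.
#' @return Integer array of the same shape with values in
#'   `0:(levels - 1)`.
#' @examples
#' quantize(100, levels = 32, hu_window = c(-100, 300)) # level 16
#' @export
quantize <- function(x, levels = 32L, hu_window = c(-100, 300)) {
  if (inherits(x, "ct_volume")) x <- x$data
  levels <- as.integer(levels)
  if (levels < 2L) {
    stop_ctb("quantize: levels must be >= 2", class = "ctb_contract_error")
  }
  lo <- hu_window[1]; hi <- hu_window[2]
  if (!(lo < hi)) {
    stop_ctb("quantize: hu_window must satisfy lo < hi",
             class = "ctb_contract_error")
  }
  q <- floor((pmin(pmax(x, lo), hi) - lo) / (hi - lo) * levels)
  q <- pmin(q, levels - 1L)
  out <- as.integer(q)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}

#' The 13 unique unit offsets of a 3-D neighborhood
#'
#' All displacement vectors in `{-1, 0, 1}^3` up to sign (first non-zero
#' component positive), the standard direction set for a
#' rotation-insensitive pooled 3-D co-occurrence matrix.
#'
#' @return A 13 x 3 integer matrix with columns `(dz, dy, dx)`.
#' @export
glcm_offsets_3d <- function() {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  keep <- apply(g, 1L, function(o) {
    nz <- which(o != 0)
    length(nz) > 0 && o[nz[1]] > 0
  })
  out <- g[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  rownames(out) <- NULL
  out
}

#' Gray-level co-occurrence matrix of a 3-D patch
#'
#' Counts co-occurring gray-level pairs `(g(p), g(p + o))` for every voxel
#' `p` whose partner lies inside the patch, pooled over all supplied
#' offsets, optionally symmetrized by adding the transpose, and normalized
#' to probabilities.
#'
#' @param patch integer array of 0-based gray levels (from [quantize()]).
#' @param offsets integer matrix of displacement rows `(dz, dy, dx)`;
#'   default [glcm_offsets_3d()]. Each offset must be non-zero and smaller
#'   than the patch extent in every dimension.
#' @param symmetric add the transpose before normalizing (default `TRUE`).
#' @param levels number of gray levels; default `max(patch) + 1`.
#' @return Object of class `glcm`: list with probability matrix `p`
#'   (`levels x levels`), `levels`, `offsets`, `symmetric`, and the raw
#'   pair count `n_pairs`.
#' @export
glcm_3d <- function(patch, offsets = glcm_offsets_3d(), symmetric = TRUE,
                    levels = NULL) {
  if (is.null(dim(patch))) dim(patch) <- c(length(patch), 1L, 1L)
  if (length(dim(patch)) == 2L) dim(patch) <- c(dim(patch), 1L)
  d <- dim(patch)
  if (length(d) != 3L || length(patch) == 0L) {
    stop_ctb("glcm_3d: patch must be a non-empty 3-D array",
             class = "ctb_contract_error")
  }
  offsets <- matrix(as.integer(offsets), ncol = 3L)
  if (is.null(levels)) levels <- max(patch) + 1L
  levels <- as.integer(levels)
  if (any(patch < 0L) || any(patch >= levels)) {
    stop_ctb("glcm_3d: patch levels outside [0, levels)",
             class = "ctb_contract_error")
  }
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(offsets))) {
    o <- offsets[r, ]
    if (all(o == 0L)) {
      stop_ctb("glcm_3d: zero offset", class = "ctb_contract_error")
    }
    if (any(abs(o) >= d)) {
      stop_ctb("glcm_3d: offset (", paste(o, collapse = ","),
               ") out of range for patch extent ",
               paste(d, collapse = "x"), class = "ctb_contract_error")
    }
    src <- lapply(1:3, function(k) {
      max(1L, 1L - o[k]):min(d[k], d[k] - o[k])
    })
    a <- patch[src[[1]], src[[2]], src[[3]], drop = FALSE]
    b <- patch[src[[1]] + o[1], src[[2]] + o[2], src[[3]] + o[3],
               drop = FALSE]
    tab <- tabulate(as.vector(a) * levels + as.vector(b) + 1L,
                    nbins = levels * levels)
    counts <- counts + matrix(tab, levels, levels, byrow = TRUE)
  }
  if (symmetric) counts <- counts + t(counts)
  n_pairs <- sum(counts)
  if (n_pairs == 0) {
    stop_ctb("glcm_3d: no co-occurring pairs (patch too small for offsets)",
             class = "ctb_contract_error")
  }
  structure(list(p = counts / n_pairs, levels = levels, offsets = offsets,
                 symmetric = symmetric, n_pairs = n_pairs),
            class = "glcm")
}

#' Haralick features of a co-occurrence matrix
#'
#' With `p(i, j)` the normalized GLCM over 0-based levels:
#' contrast `sum p (i - j)^2`; correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)` (0 when either marginal
#' variance vanishes); entropy `-sum p log2 p` with `0 log 0 = 0`; energy
#' `sum p^2`; homogeneity `sum p / (1 + |i - j|)`.
#'
#' @param glcm a [glcm_3d()] object (normalized).
#' @return Named numeric vector: `contrast`, `correlation`, `entropy`,
#'   `energy`, `homogeneity`.
#' @export
haralick_features <- function(glcm) {
  stopifnot(inherits(glcm, "glcm"))
  p <- glcm$p
  L <- glcm$levels
  i <- matrix(0:(L - 1L), L, L)
  j <- t(i)
  pi_ <- rowSums(p)
  pj_ <- colSums(p)
  mu_i <- sum((0:(L - 1L)) * pi_)
  mu_j <- sum((0:(L - 1L)) * pj_)
  s_i <- sqrt(sum((0:(L - 1L) - mu_i)^2 * pi_))
  s_j <- sqrt(sum((0:(L - 1L) - mu_j)^2 * pj_))
  nz <- p > 0
  c(contrast = sum(p * (i - j)^2),
    correlation = if (s_i * s_j > 0) {
      sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j)
    } else 0,
    entropy = -sum(p[nz] * log2(p[nz])),
    energy = sum(p^2),
    homogeneity = sum(p / (1 + abs(i - j))))
}

#' Neighborhood statistical features
#'
#' Mean, population standard deviation, moment skewness
#' (`m3 / m2^{3/2}`), excess kurtosis (`m4 / m2^2 - 3`) and median of a set
#' of HU values. Zero-variance sets get skewness and kurtosis 0.
#'
#' @param values numeric vector of HU values.
#' @return Named numeric vector `mean`, `sd`, `skewness`, `kurtosis`,
#'   `median`.
#' @export
stat_features <- function(values) {
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  c(mean = m,
    sd = sqrt(m2),
    skewness = if (m2 > 0) mean(d^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(d^4) / m2^2 - 3 else 0,
    median = median(values))
}

#' Per-voxel feature map over a region of interest
#'
#' For every ROI voxel, computes the 10-component feature vector (5
#' statistical + 5 Haralick) of its `window^3` neighborhood, clipped at the
#' volume border (no padding: no HU values are invented). Rows are emitted
#' in the array's column-major scan order of the ROI, i.e. the order of
#' `which(roi$data)`.
#'
#' @param volume a [ct_volume()].
#' @param roi a [ct_mask()] marking the voxels to featurize (e.g. the
#'   segmented liver).
#' @param window odd neighborhood edge length in voxels (default 11).
#' @param levels,hu_window quantization parameters, see [quantize()].
#' @param offsets GLCM offsets, default [glcm_offsets_3d()].
#' @return A `data.frame` with 1-based voxel indices `z, y, x` and columns
#'   `mean, sd, skewness, kurtosis, median, contrast, correlation, entropy,
#'   energy, homogeneity` (this fixed order is the classifier contract).
#' @export
feature_map <- function(volume, roi, window = 11L, levels = 32L,
                        hu_window = c(-100, 300),
                        offsets = glcm_offsets_3d()) {
  stopifnot(inherits(volume, "ct_volume"))
  roi_arr <- mask_data(roi)
  if (!identical(dim(roi_arr), dim(volume$data))) {
    stop_ctb("feature_map: ROI shape does not match the volume",
             class = "ctb_contract_error")
  }
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) {
    stop_ctb("feature_map: window must be odd", class = "ctb_contract_error")
  }
  if (!any(roi_arr)) {
    stop_ctb("feature_map: ROI is empty", class = "ctb_contract_error")
  }
  q <- quantize(volume$data, levels = levels, hu_window = hu_window)
  m <- feature_map_cpp(as.numeric(volume$data), as.integer(q),
                       dim(volume$data), as.logical(roi_arr),
                       window, as.integer(levels),
                       matrix(as.integer(offsets), ncol = 3L))
  colnames(m) <- c("z", "y", "x", feature_names())
  as.data.frame(m)
}

#' Fixed feature order of the voxel classifier contract
#' @return Character vector of the 10 feature names.
#' @export
feature_names <- function() {
  c("mean", "sd", "skewness", "kurtosis", "median",
    "contrast", "correlation", "entropy", "energy", "homogeneity")
}
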