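#' Configuration for a paired pre/post CT phantom
#'
#' The phantom emulates the imaging regime of diffuse hepatic metastases on
#' portal-venous CT: an ellipsoidal liver of ~100 HU on a ~-70 HU
#' background, carrying non-overlapping spherical tumors of distinct HU,
#' with additive Gaussian noise. The post-treatment volume re-renders each
#' tumor with its radius scaled by `volume_scale^(1/3)` and its HU shifted
#' by `hu_shift`, so the aggregate volume and density changes are known
#' analytically.
#'
#' @param dim grid shape `(axial, row, column)`, default `c(96, 128, 128)`.
#' @param spacing voxel spacing `(dz, dy, dx)` mm, default 1.5 isotropic.
#' @param background_hu,background_sd background tissue mean/sd (HU),
#'   default -70 / 15.
#' @param liver_semiaxes_mm liver ellipsoid semi-axes `(z, y, x)` mm,
#'   default `c(55, 75, 75)` (~1300 cm^3, a realistic liver).
#' @param liver_hu,liver_sd liver parenchyma mean/sd, default 100 / 12
#'   (portal-phase enhancement).
#' @param n_tumors number of spherical lesions (default 12; the clinical
#'   regime spans roughly 6-129 per liver).
#' @param tumor_radius_mm radius range `(lo, hi)` mm, default `c(4, 12)`;
#'   the lower bound must be at least 2 voxels.
#' @param tumor_hu,tumor_sd lesion mean/sd, default 60 / 10 (hypodense
#'   metastases; clinical mean densities span ~50-145 HU).
#' @param noise_sd global additive noise sd (HU), default 5.
#' @param volume_scale per-tumor post/pre volume ratio(s), recycled to
#'   `n_tumors`; default 1.
#' @param hu_shift per-tumor post-treatment HU shift(s), recycled; default 0.
#' @param seed RNG seed (default 1); the phantom is deterministic given it.
#' @return A validated list of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(96L, 128L, 128L),
                           spacing = c(1.5, 1.5, 1.5),
                           background_hu = -70, background_sd = 15,
                           liver_semiaxes_mm = c(55, 75, 75),
                           liver_hu = 100, liver_sd = 12,
                           n_tumors = 12L, tumor_radius_mm = c(4, 12),
                           tumor_hu = 60, tumor_sd = 10,
                           noise_sd = 5,
                           volume_scale = 1, hu_shift = 0,
                           seed = 1L) {
  cfg <- list(dim = as.integer(dim), spacing = as.numeric(spacing),
              background_hu = background_hu, background_sd = background_sd,
              liver_semiaxes_mm = liver_semiaxes_mm,
              liver_hu = liver_hu, liver_sd = liver_sd,
              n_tumors = as.integer(n_tumors),
              tumor_radius_mm = tumor_radius_mm,
              tumor_hu = tumor_hu, tumor_sd = tumor_sd,
              noise_sd = noise_sd,
              volume_scale = rep_len(volume_scale, max(n_tumors, 1L)),
              hu_shift = rep_len(hu_shift, max(n_tumors, 1L)),
              seed = as.integer(seed))
  stopifnot(length(cfg$dim) == 3L, all(cfg$dim >= 8L),
            length(cfg$spacing) == 3L, all(cfg$spacing > 0),
            length(cfg$liver_semiaxes_mm) == 3L,
            all(cfg$liver_semiaxes_mm > 0),
            cfg$n_tumors >= 0L,
            all(c(cfg$background_sd, cfg$liver_sd, cfg$tumor_sd,
                  cfg$noise_sd) >= 0),
            all(cfg$volume_scale > 0))
  if (cfg$n_tumors > 0L &&
      cfg$tumor_radius_mm[1] < 2 * max(cfg$spacing)) {
    stop_ctb("phantom_config: minimum tumor radius must be >= 2 voxels (",
             2 * max(cfg$spacing), " mm here)", class = "ctb_contract_error")
  }
  class(cfg) <- "phantom_config"
  cfg
}

# Voxel-center coordinates (mm) along each axis.
.axis_mm <- function(dim, spacing) {
  lapply(1:3, function(k) (seq_len(dim[k]) - 0.5) * spacing[k])
}

# Logical array of an ellipsoid (center/semiaxes in mm).
.ellipsoid_mask <- function(dim, spacing, center, semiaxes) {
  ax <- .axis_mm(dim, spacing)
  ez <- ((ax[[1]] - center[1]) / semiaxes[1])^2
  ey <- ((ax[[2]] - center[2]) / semiaxes[2])^2
  ex <- ((ax[[3]] - center[3]) / semiaxes[3])^2
  array(outer(outer(ez, ey, "+"), ex, "+") <= 1, dim = dim)
}

# Add a voxelized sphere to a logical array (bounding-box local update).
.add_sphere <- function(mask, dim, spacing, center, radius) {
  ax <- .axis_mm(dim, spacing)
  rng <- lapply(1:3, function(k) {
    which(abs(ax[[k]] - center[k]) <= radius)
  })
  if (any(lengths(rng) == 0L)) return(mask)
  dz <- (ax[[1]][rng[[1]]] - center[1])^2
  dy <- (ax[[2]][rng[[2]]] - center[2])^2
  dx <- (ax[[3]][rng[[3]]] - center[3])^2
  sub <- outer(outer(dz, dy, "+"), dx, "+") <= radius^2
  mask[rng[[1]], rng[[2]], rng[[3]]] <-
    mask[rng[[1]], rng[[2]], rng[[3]]] | sub
  mask
}

#' Generate a paired pre/post CT phantom with ground truth
#'
#' Renders the pre- and post-treatment volumes of a [phantom_config()] and
#' returns them together with ground-truth masks and the analytic volume
#' and density changes. Tumor centers are placed by rejection sampling so
#' that every sphere (at its larger of pre/post radius) lies inside the
#' liver and no two spheres overlap; placement failure after bounded
#' retries raises an error suggesting fewer or smaller tumors.
#'
#' @param config a [phantom_config()].
#' @param max_tries placement attempts per tumor (default 500).
#' @return List of class `ct_phantom`: `pre`, `post` ([ct_volume()]s),
#'   `truth` (liver mask, pre/post tumor masks, per-tumor table, analytic
#'   `v_pre_cm3` / `v_post_cm3` / `d_pre_hu` / `d_post_hu` /
#'   `delta_v_pct` / `delta_d_pct`), and `config`.
#' @examples
#' ph <- make_phantom(phantom_config(dim = c(24, 32, 32),
#'   spacing = c(2, 2, 2), liver_semiaxes_mm = c(18, 24, 24),
#'   n_tumors = 2, tumor_radius_mm = c(4, 6), seed = 7))
#' ph$truth$delta_v_pct
#' @export
make_phantom <- function(config, max_tries = 500L) {
  stopifnot(inherits(config, "phantom_config"))
  cfg <- config
  d <- cfg$dim; sp <- cfg$spacing
  extent <- d * sp
  center <- extent / 2
  with_seed(cfg$seed, {
    liver <- .ellipsoid_mask(d, sp, center, cfg$liver_semiaxes_mm)

    # --- tumor placement ---
    n <- cfg$n_tumors
    r_pre <- if (n > 0) runif(n, cfg$tumor_radius_mm[1],
                              cfg$tumor_radius_mm[2]) else numeric(0)
    r_post <- r_pre * cfg$volume_scale^(1 / 3)
    r_eff <- pmax(r_pre, r_post)
    hu_pre <- rep_len(cfg$tumor_hu, max(n, 1L))[seq_len(n)]
    hu_post <- hu_pre + cfg$hu_shift[seq_len(n)]
    centers <- matrix(NA_real_, n, 3L)
    gap <- min(sp)
    for (i in seq_len(n)) {
      inner <- cfg$liver_semiaxes_mm - r_eff[i] - gap
      if (any(inner <= 0)) {
        stop_ctb("make_phantom: tumor ", i, " cannot fit inside the liver",
                 class = "ctb_placement_error")
      }
      placed <- FALSE
      for (try in seq_len(max_tries)) {
        u <- runif(3, -1, 1)
        if (sum(u^2) > 1) next
        cand <- center + u * inner
        if (i > 1L) {
          prev <- seq_len(i - 1L)
          dd <- sqrt(rowSums((centers[prev, , drop = FALSE] -
                              matrix(cand, i - 1L, 3L, byrow = TRUE))^2))
          if (any(dd <= r_eff[prev] + r_eff[i] + gap)) next
        }
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) {
        stop_ctb("make_phantom: could not place tumor ", i, " after ",
                 max_tries, " tries; use fewer or smaller tumors",
                 class = "ctb_placement_error")
      }
    }

    tumor_pre <- array(FALSE, dim = d)
    tumor_post <- array(FALSE, dim = d)
    pre_label <- array(0L, dim = d)
    post_label <- array(0L, dim = d)
    for (i in seq_len(n)) {
      m1 <- .add_sphere(array(FALSE, d), d, sp, centers[i, ], r_pre[i])
      m2 <- .add_sphere(array(FALSE, d), d, sp, centers[i, ], r_post[i])
      tumor_pre <- tumor_pre | m1
      tumor_post <- tumor_post | m2
      pre_label[m1] <- i
      post_label[m2] <- i
    }

    render <- function(tumor_mask, tumor_label, hu_by_tumor) {
      nvox <- prod(d)
      img <- cfg$background_hu + rnorm(nvox, sd = cfg$background_sd)
      dim(img) <- d
      nl <- liver & !tumor_mask
      img[nl] <- cfg$liver_hu + rnorm(sum(nl), sd = cfg$liver_sd)
      for (i in seq_len(n)) {
        sel <- tumor_label == i
        img[sel] <- hu_by_tumor[i] + rnorm(sum(sel), sd = cfg$tumor_sd)
      }
      if (cfg$noise_sd > 0) img <- img + rnorm(nvox, sd = cfg$noise_sd)
      ct_volume(img, spacing = sp)
    }
    pre_vol <- render(tumor_pre, pre_label, hu_pre)
    post_vol <- render(tumor_post, post_label, hu_post)
  })

  sphere_cm3 <- function(r) 4 / 3 * pi * r^3 / 1000
  v_pre <- sum(sphere_cm3(r_pre))
  v_post <- sum(sphere_cm3(r_post))
  d_pre <- if (cfg$n_tumors > 0) sum(r_pre^3 * hu_pre) / sum(r_pre^3)
           else NA_real_
  d_post <- if (cfg$n_tumors > 0) sum(r_post^3 * hu_post) / sum(r_post^3)
            else NA_real_
  truth <- list(
    liver_mask = ct_mask(liver, spacing = sp),
    tumor_mask_pre = ct_mask(tumor_pre, spacing = sp),
    tumor_mask_post = ct_mask(tumor_post, spacing = sp),
    tumors = data.frame(id = seq_len(cfg$n_tumors),
                        center_z_mm = centers[, 1],
                        center_y_mm = centers[, 2],
                        center_x_mm = centers[, 3],
                        radius_pre_mm = r_pre, radius_post_mm = r_post,
                        hu_pre = hu_pre, hu_post = hu_post),
    v_pre_cm3 = v_pre, v_post_cm3 = v_post,
    d_pre_hu = d_pre, d_post_hu = d_post,
    delta_v_pct = if (cfg$n_tumors > 0) 100 * (v_post / v_pre - 1)
                  else NA_real_,
    delta_d_pct = if (cfg$n_tumors > 0) 100 * (d_post / d_pre - 1)
                  else NA_real_)
  structure(list(pre = pre_vol, post = post_vol, truth = truth,
                 config = cfg),
            class = "ct_phantom")
}

#' Ground-truth seed slice for liver segmentation of a phantom
#'
#' Returns the axial slice with the largest liver cross-section and the
#' true liver mask on that slice, standing in for the radiologist's manual
#' seed.
#'
#' @param phantom a [make_phantom()] result.
#' @return List with `slice` (index) and `mask` (logical matrix).
#' @export
phantom_seed_slice <- function(phantom) {
  stopifnot(inherits(phantom, "ct_phantom"))
  liver <- phantom$truth$liver_mask$data
  areas <- apply(liver, 1L, sum)
  s <- which.max(areas)
  list(slice = s, mask = liver[s, , ])
}

#' Train a voxel classifier from phantom ground truth
#'
#' Samples balanced tumor / non-tumor voxels inside the true liver of a
#' (training) phantom, computes their neighborhood features on the
#' pre-treatment volume, and trains the backpropagation classifier.
#'
#' @param phantom a [make_phantom()] result.
#' @param n_per_class voxels sampled per class (default 1500).
#' @param window,levels,hu_window feature parameters, see [feature_map()].
#' @param seed RNG seed for sampling and weight initialization.
#' @param ... further arguments to [train_classifier()].
#' @return A `tumor_classifier`.
#' @export
train_phantom_classifier <- function(phantom, n_per_class = 1500L,
                                     window = 11L, levels = 32L,
                                     hu_window = c(-100, 300), seed = 1L,
                                     ...) {
  stopifnot(inherits(phantom, "ct_phantom"))
  liver <- phantom$truth$liver_mask$data
  tumor <- phantom$truth$tumor_mask_pre$data
  pos <- which(liver & tumor)
  neg <- which(liver & !tumor)
  with_seed(seed, {
    pos <- sample(pos, min(n_per_class, length(pos)))
    neg <- sample(neg, min(n_per_class, length(neg)))
  })
  roi <- array(FALSE, dim = dim(liver))
  roi[c(pos, neg)] <- TRUE
  feats <- feature_map(phantom$pre, ct_mask(roi, phantom$pre$spacing),
                       window = window, levels = levels,
                       hu_window = hu_window)
  idx <- cbind(feats$z, feats$y, feats$x)
  labels <- tumor[idx]
  train_classifier(feats, labels, seed = seed, ...)
}

#' Run the measurement pipeline on a phantom and compare to truth
#'
#' With `masks = "truth"`, the response record is computed from the
#' ground-truth tumor masks (isolating the metric layer from segmentation
#' error, which leaves only voxelization error). With `masks = "pipeline"`
#' the full chain runs: GMM/EM liver segmentation seeded with the true
#' seed slice, texture-feature voxel classification with `model`,
#' morphological clean-up, then measurement.
#'
#' @param phantom a [make_phantom()] result.
#' @param masks `"truth"` or `"pipeline"`.
#' @param model a trained classifier (required for `"pipeline"`), e.g.
#'   from [train_phantom_classifier()] on a different phantom.
#' @param k,closing_radius_vox liver-segmentation parameters.
#' @param window,levels,hu_window,threshold tumor-segmentation parameters.
#' @param connectivity lesion connectivity (default 26).
#' @return List of class `phantom_recovery`: the `record`
#'   ([measure_response()]), signed errors `delta_v_error_pct` /
#'   `delta_d_error_pct` (measured minus configured, absolute percentage
#'   points), and for the pipeline route the liver and tumor Dice scores.
#' @export
recover_metrics <- function(phantom, masks = c("truth", "pipeline"),
                            model = NULL, k = 2.5, closing_radius_vox = 2L,
                            window = 11L, levels = 32L,
                            hu_window = c(-100, 300), threshold = 0.5,
                            connectivity = 26L) {
  stopifnot(inherits(phantom, "ct_phantom"))
  masks <- match.arg(masks)
  truth <- phantom$truth
  if (masks == "truth") {
    rec <- measure_response(truth$tumor_mask_pre, truth$tumor_mask_post,
                            phantom$pre, phantom$post,
                            connectivity = connectivity)
    dice_liver <- NA_real_
    dice_pre <- 1; dice_post <- 1
  } else {
    if (is.null(model)) {
      stop_ctb("recover_metrics: pipeline route needs a trained `model`",
               class = "ctb_contract_error")
    }
    seed2d <- phantom_seed_slice(phantom)
    seg <- function(vol) {
      segment_liver(vol, seed2d$slice, seed2d$mask, k = k,
                    closing_radius_vox = closing_radius_vox)
    }
    liver_pre <- seg(phantom$pre)
    liver_post <- seg(phantom$post)
    tum <- function(vol, liver_mask) {
      segment_tumors(vol, liver_mask, model, window = window,
                     levels = levels, hu_window = hu_window,
                     threshold = threshold)
    }
    pre_mask <- tum(phantom$pre, liver_pre)
    post_mask <- tum(phantom$post, liver_post)
    rec <- measure_response(pre_mask, post_mask, phantom$pre, phantom$post,
                            connectivity = connectivity)
    dice_liver <- dice(liver_pre, truth$liver_mask)
    dice_pre <- dice(pre_mask, truth$tumor_mask_pre)
    dice_post <- dice(post_mask, truth$tumor_mask_post)
  }
  structure(list(record = rec,
                 delta_v_error_pct = rec$delta_volume_pct -
                   truth$delta_v_pct,
                 delta_d_error_pct = rec$delta_density_pct -
                   truth$delta_d_pct,
                 dice_liver = dice_liver,
                 dice_tumor_pre = dice_pre,
                 dice_tumor_post = dice_post,
                 masks = masks),
            class = "phantom_recovery")
}
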