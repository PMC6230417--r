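#' Lesion inventory of a tumor mask
#'
#' Labels connected tumor components and computes the per-lesion and
#' whole-burden measurements: voxel count, volume (cm^3), mean HU, longest
#' axial diameter (cm, in-plane Feret) and lesion centroid (mm), plus the
#' global total tumor volume `V` and the mean volumetric tumor density `D`
#' (the voxel-weighted mean HU over the union of all tumor voxels -- not
#' the mean of per-lesion means).
#'
#' @param mask tumor [ct_mask()], aligned to `volume`.
#' @param volume the [ct_volume()] supplying HU values.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Object of class `lesion_set`: list with `lesions` (data.frame),
#'   `total_volume_cm3`, `mean_density_hu` (`NA` when the mask is empty),
#'   `lesion_count`, `spacing`.
#' @export
label_lesions <- function(mask, volume, connectivity = 26L) {
  stopifnot(inherits(mask, "ct_mask"), inherits(volume, "ct_volume"))
  if (!identical(dim(mask$data), dim(volume$data)) ||
      !isTRUE(all.equal(mask$spacing, volume$spacing))) {
    stop_ctb("label_lesions: mask and volume grids are not aligned",
             class = "ctb_contract_error")
  }
  sp <- volume$spacing
  voxel_cm3 <- prod(sp) / 1000
  lab <- label_components(mask$data, connectivity = connectivity)
  n <- attr(lab, "n_components")
  if (n == 0L) {
    lesions <- data.frame(label = integer(0), n_voxels = integer(0),
                          volume_cm3 = numeric(0), mean_hu = numeric(0),
                          diameter_cm = numeric(0), centroid_z_mm = numeric(0),
                          centroid_y_mm = numeric(0), centroid_x_mm = numeric(0))
    return(structure(list(lesions = lesions, total_volume_cm3 = 0,
                          mean_density_hu = NA_real_, lesion_count = 0L,
                          spacing = sp),
                     class = "lesion_set"))
  }
  idx <- which(lab > 0L)
  lb <- lab[idx]
  coord <- arrayInd(idx, dim(lab))
  hu <- volume$data[idx]
  nv <- tabulate(lb, nbins = n)
  mean_hu <- as.numeric(tapply(hu, lb, mean))
  cz <- as.numeric(tapply(coord[, 1], lb, mean)) * sp[1]
  cy <- as.numeric(tapply(coord[, 2], lb, mean)) * sp[2]
  cx <- as.numeric(tapply(coord[, 3], lb, mean)) * sp[3]
  diam <- vapply(seq_len(n), function(l) {
    longest_axial_diameter(coord[lb == l, , drop = FALSE], sp)
  }, numeric(1))
  lesions <- data.frame(label = seq_len(n), n_voxels = nv,
                        volume_cm3 = nv * voxel_cm3, mean_hu = mean_hu,
                        diameter_cm = diam, centroid_z_mm = cz,
                        centroid_y_mm = cy, centroid_x_mm = cx)
  structure(list(lesions = lesions,
                 total_volume_cm3 = sum(lesions$volume_cm3),
                 mean_density_hu = mean(hu),
                 lesion_count = n, spacing = sp),
            class = "lesion_set")
}

#' @export
print.lesion_set <- function(x, ...) {
  cat(sprintf("<lesion_set> %d lesion(s), V = %.3f cm^3, D = %s HU\n",
              x$lesion_count, x$total_volume_cm3,
              if (is.na(x$mean_density_hu)) "NA" else
                sprintf("%.1f", x$mean_density_hu)))
  invisible(x)
}

#' Total tumor volume (cm^3)
#'
#' Sum of the per-lesion volumes, i.e. tumor voxel count times the voxel
#' volume `dz dy dx / 1000`.
#'
#' @param lesions a [label_lesions()] object.
#' @return Volume in cm^3 (0 for an empty set).
#' @export
total_volume <- function(lesions) {
  stopifnot(inherits(lesions, "lesion_set"))
  lesions$total_volume_cm3
}

#' Mean volumetric tumor density (HU)
#'
#' Arithmetic mean HU over all tumor voxels of all lesions.
#'
#' @param lesions a [label_lesions()] object with at least one tumor voxel.
#' @return Mean HU.
#' @export
mean_density <- function(lesions) {
  stopifnot(inherits(lesions, "lesion_set"))
  if (lesions$lesion_count == 0L) {
    stop_ctb("mean_density: undefined for an empty tumor set",
             class = "ctb_degenerate_data_error")
  }
  lesions$mean_density_hu
}

#' Longest axial diameter of a lesion (cm)
#'
#' The maximum, over axial slices, of the largest in-plane distance between
#' voxel centers (2-D Feret diameter), in cm. A single voxel has diameter 0
#' under this center-to-center convention, which differs from caliper
#' conventions by at most one voxel.
#'
#' @param coords integer matrix of voxel indices, columns `(z, y, x)`.
#' @param spacing `(dz, dy, dx)` in mm.
#' @return Diameter in cm.
#' @export
longest_axial_diameter <- function(coords, spacing) {
  coords <- matrix(as.numeric(coords), ncol = 3L)
  if (nrow(coords) == 0L) {
    stop_ctb("longest_axial_diameter: no voxels",
             class = "ctb_contract_error")
  }
  best <- 0
  for (z in unique(coords[, 1])) {
    pts <- coords[coords[, 1] == z, 2:3, drop = FALSE]
    pts <- unique(pts)
    if (nrow(pts) < 2L) next
    pts_mm <- cbind(pts[, 1] * spacing[2], pts[, 2] * spacing[3])
    if (nrow(pts_mm) > 3L) {
      hull <- grDevices::chull(pts_mm)
      pts_mm <- pts_mm[hull, , drop = FALSE]
    }
    best <- max(best, max(dist(pts_mm)))
  }
  best / 10
}

#' RECIST 1.1 diameter sum (cm)
#'
#' At baseline, the target lesions are the (up to) `max_targets` lesions
#' with the largest longest axial diameter among those meeting the
#' measurability floor (`>= min_diameter_cm`); the result is the sum of
#' their diameters. At follow-up the same lesion identities must be
#' re-measured: pass their labels via `targets` (see [match_lesions()]),
#' in which case no floor is applied.
#'
#' @param lesions a [label_lesions()] object.
#' @param max_targets maximum targets per organ (default 2, the liver
#'   allowance).
#' @param min_diameter_cm baseline measurability floor (default 1.0 cm).
#' @param targets optional lesion labels to re-measure (follow-up call).
#' @return List of class `recist_sum`: `sum_cm`, `target_labels`,
#'   `no_target` (TRUE when no lesion is measurable at baseline).
#' @export
recist_sum <- function(lesions, max_targets = 2L, min_diameter_cm = 1.0,
                       targets = NULL) {
  stopifnot(inherits(lesions, "lesion_set"))
  df <- lesions$lesions
  if (!is.null(targets)) {
    if (!all(targets %in% df$label)) {
      stop_ctb("recist_sum: unknown target label(s)",
               class = "ctb_contract_error")
    }
    sel <- df[match(targets, df$label), ]
    return(structure(list(sum_cm = sum(sel$diameter_cm),
                          target_labels = targets, no_target = FALSE),
                     class = "recist_sum"))
  }
  eligible <- df[df$diameter_cm >= min_diameter_cm, ]
  if (nrow(eligible) == 0L) {
    return(structure(list(sum_cm = NA_real_, target_labels = integer(0),
                          no_target = TRUE),
                     class = "recist_sum"))
  }
  eligible <- eligible[order(-eligible$diameter_cm), ]
  sel <- head(eligible, max_targets)
  structure(list(sum_cm = sum(sel$diameter_cm),
                 target_labels = sel$label, no_target = FALSE),
            class = "recist_sum")
}

#' Match baseline target lesions to follow-up lesions
#'
#' Nearest-centroid assignment: each baseline label is matched to the
#' follow-up lesion whose centroid is closest (greedy, without
#' replacement, largest baseline lesion first).
#'
#' @param baseline,followup [label_lesions()] objects.
#' @param labels baseline labels to match (default: all).
#' @return Integer vector of follow-up labels, named by baseline label;
#'   `NA` where the follow-up has fewer lesions than requested.
#' @export
match_lesions <- function(baseline, followup, labels = NULL) {
  stopifnot(inherits(baseline, "lesion_set"), inherits(followup, "lesion_set"))
  labels <- labels %||% baseline$lesions$label
  bl <- baseline$lesions[match(labels, baseline$lesions$label), ]
  bl <- bl[order(-bl$volume_cm3), ]
  fu <- followup$lesions
  out <- stats::setNames(rep(NA_integer_, nrow(bl)), bl$label)
  avail <- fu$label
  for (i in seq_len(nrow(bl))) {
    if (length(avail) == 0L) break
    cand <- fu[fu$label %in% avail, ]
    d2 <- (cand$centroid_z_mm - bl$centroid_z_mm[i])^2 +
          (cand$centroid_y_mm - bl$centroid_y_mm[i])^2 +
          (cand$centroid_x_mm - bl$centroid_x_mm[i])^2
    pick <- cand$label[which.min(d2)]
    out[as.character(bl$label[i])] <- pick
    avail <- setdiff(avail, pick)
  }
  out[as.character(labels)]
}

#' Percent change from a baseline value
#'
#' `100 (post - pre) / pre`; the baseline must be positive.
#'
#' @param pre baseline value (> 0).
#' @param post follow-up value.
#' @return Percent change.
#' @examples
#' percent_change(57.4, 40.9) # -28.75
#' @export
percent_change <- function(pre, post) {
  if (!is.finite(pre) || pre <= 0) {
    stop_ctb("percent_change: baseline must be a positive finite value",
             class = "ctb_domain_error")
  }
  100 * (post - pre) / pre
}

#' Combined volume-plus-density change
#'
#' The combined response statistic: the signed sum of the percent volume
#' change and the percent density change,
#' `delta(V+D) = deltaV + deltaD`.
#'
#' @param delta_v,delta_d percent changes (finite).
#' @return Percent.
#' @examples
#' combined_change(131.25, -4.7) # 126.55
#' @export
combined_change <- function(delta_v, delta_d) {
  if (!is.finite(delta_v) || !is.finite(delta_d)) {
    stop_ctb("combined_change: inputs must be finite",
             class = "ctb_domain_error")
  }
  delta_v + delta_d
}

#' RECIST 1.1 response category
#'
#' CR: disappearance of all target lesions. PR: at least a 30% decrease of
#' the diameter sum from baseline. PD: at least a 20% increase and an
#' absolute increase of at least 5 mm. SD: neither.
#'
#' @param delta_s percent change of the diameter sum.
#' @param absolute_increase_mm absolute change of the sum in mm.
#' @param all_targets_gone flag for complete disappearance.
#' @return One of `"CR"`, `"PR"`, `"SD"`, `"PD"`.
#' @export
recist_category <- function(delta_s, absolute_increase_mm,
                            all_targets_gone = FALSE) {
  if (isTRUE(all_targets_gone)) return("CR")
  if (delta_s <= -30) return("PR")
  if (delta_s >= 20 && absolute_increase_mm >= 5) return("PD")
  "SD"
}

#' Pre/post response record
#'
#' Runs the full measurement on a pair of tumor masks: lesion inventories,
#' the whole-burden percent changes deltaV (volume) and deltaD (density),
#' the RECIST deltaS (diameter sum over baseline targets re-measured on the
#' matched follow-up lesions), the combined delta(V+D), the RECIST category
#' and the two-group reduction (progression = PD, nonprogression = PR or
#' SD). Both time points must contain tumor for the delta metrics.
#'
#' Note the two metric families deliberately use different lesion sets:
#' V and D include every lesion regardless of size, while deltaS tracks
#' only the (up to two) measurable targets.
#'
#' @param pre_mask,post_mask tumor [ct_mask()]s.
#' @param pre_volume,post_volume matching [ct_volume()]s.
#' @param connectivity lesion connectivity (default 26).
#' @param max_targets,min_diameter_cm RECIST target rules, see
#'   [recist_sum()].
#' @return Object of class `response_record`: list with `delta_volume_pct`,
#'   `delta_density_pct`, `delta_size_pct`, `combined_pct`,
#'   `recist_category`, `progression_group`, the pre/post `lesion_set`s and
#'   the raw V/D/S values.
#' @export
measure_response <- function(pre_mask, post_mask, pre_volume, post_volume,
                             connectivity = 26L, max_targets = 2L,
                             min_diameter_cm = 1.0) {
  pre <- label_lesions(pre_mask, pre_volume, connectivity)
  post <- label_lesions(post_mask, post_volume, connectivity)
  if (pre$lesion_count == 0L || post$lesion_count == 0L) {
    stop_ctb("measure_response: both time points must contain tumor",
             class = "ctb_degenerate_data_error")
  }
  dv <- percent_change(total_volume(pre), total_volume(post))
  dd <- percent_change(mean_density(pre), mean_density(post))

  base_sum <- recist_sum(pre, max_targets, min_diameter_cm)
  if (base_sum$no_target) {
    ds <- NA_real_
    cat_ <- NA_character_
    post_sum <- NA_real_
  } else {
    matched <- match_lesions(pre, post, labels = base_sum$target_labels)
    if (anyNA(matched)) {
      ds <- NA_real_
      cat_ <- NA_character_
      post_sum <- NA_real_
    } else {
      fu <- recist_sum(post, targets = unname(matched))
      post_sum <- fu$sum_cm
      ds <- percent_change(base_sum$sum_cm, post_sum)
      cat_ <- recist_category(ds, (post_sum - base_sum$sum_cm) * 10)
    }
  }
  structure(list(
    delta_volume_pct = dv,
    delta_density_pct = dd,
    delta_size_pct = ds,
    combined_pct = combined_change(dv, dd),
    recist_category = cat_,
    progression_group = if (is.na(cat_)) NA_character_
                        else if (cat_ == "PD") "progression"
                        else "nonprogression",
    pre = pre, post = post,
    values = list(v_pre = total_volume(pre), v_post = total_volume(post),
                  d_pre = mean_density(pre), d_post = mean_density(post),
                  s_pre = base_sum$sum_cm, s_post = post_sum)),
    class = "response_record")
}

#' @export
print.response_record <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%+.2f%%", v)
  cat("<response_record>\n",
      sprintf("  deltaV = %s  deltaD = %s  deltaS = %s  delta(V+D) = %s\n",
              fmt(x$delta_volume_pct), fmt(x$delta_density_pct),
              fmt(x$delta_size_pct), fmt(x$combined_pct)),
      sprintf("  RECIST: %s (%s)\n",
              x$recist_category %||% "NA", x$progression_group %||% "NA"),
      sep = "")
  invisible(x)
}
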