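#' CT volume container
#'
#' A 3-D grid of Hounsfield unit (HU) values plus voxel spacing. The internal
#' axis convention is `(axial, row, column)`: axis 1 indexes axial slices
#' (cranio-caudal), axes 2 and 3 span the axial plane. Spacing is stored as
#' `(dz, dy, dx)` in millimetres, matching the axis order.
#'
#' @param data numeric 3-D array of HU values; must be finite everywhere.
#' @param spacing numeric length-3 vector `(dz, dy, dx)` in mm, all > 0.
#' @param phase contrast phase label, one of `"portal"`, `"arterial"`,
#'   `"unenhanced"`. All measurements in this package assume the portal
#'   venous phase.
#' @return An object of class `ct_volume`: a list with elements `data`,
#'   `spacing` and `phase`.
#' @examples
#' v <- ct_volume(array(0, c(4, 5, 6)), spacing = c(1.8, 1, 1))
#' dim(v$data)
#' @export
ct_volume <- function(data, spacing = c(1, 1, 1),
                      phase = c("portal", "arterial", "unenhanced")) {
  phase <- match.arg(phase)
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_ctb("ct_volume: `data` must be a 3-D array, got ",
             paste(dim(data), collapse = "x"), class = "ctb_shape_error")
  }
  if (any(dim(data) < 1L)) {
    stop_ctb("ct_volume: all dimensions must be >= 1",
             class = "ctb_shape_error")
  }
  storage.mode(data) <- "double"
  if (!all(is.finite(data))) {
    stop_ctb("ct_volume: HU data contains non-finite values",
             class = "ctb_validation_error")
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop_ctb("ct_volume: spacing must be three positive numbers (dz, dy, dx)",
             class = "ctb_header_error")
  }
  structure(list(data = data, spacing = spacing, phase = phase),
            class = "ct_volume")
}

#' Binary mask aligned to a CT volume
#'
#' @param data logical (or 0/1 numeric) 3-D array.
#' @param spacing voxel spacing `(dz, dy, dx)` in mm, inherited from the
#'   reference volume.
#' @param reference optional `ct_volume`; when given, shape and spacing are
#'   checked against it and its spacing is used.
#' @return An object of class `ct_mask` with elements `data` (logical array)
#'   and `spacing`.
#' @export
ct_mask <- function(data, spacing = c(1, 1, 1), reference = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop_ctb("ct_mask: `data` must be a 3-D array",
             class = "ctb_shape_error")
  }
  if (!is.logical(data)) {
    vals <- unique(as.vector(data))
    if (!all(vals %in% c(0, 1))) {
      stop_ctb("ct_mask: values must be 0/1 or logical",
               class = "ctb_validation_error")
    }
    data <- array(data != 0, dim = dim(data))
  }
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "ct_volume"))
    if (!identical(dim(data), dim(reference$data))) {
      stop_ctb("ct_mask: mask shape does not match its reference volume",
               class = "ctb_contract_error")
    }
    spacing <- reference$spacing
  }
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0)) {
    stop_ctb("ct_mask: spacing must be three positive numbers",
             class = "ctb_header_error")
  }
  structure(list(data = data, spacing = spacing), class = "ct_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat(sprintf("<ct_volume> %s voxels @ (%.3g, %.3g, %.3g) mm, %s phase\n",
              paste(dim(x$data), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3], x$phase))
  cat(sprintf("  HU range [%.1f, %.1f]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.ct_mask <- function(x, ...) {
  cat(sprintf("<ct_mask> %s voxels @ (%.3g, %.3g, %.3g) mm, %d foreground\n",
              paste(dim(x$data), collapse = " x "),
              x$spacing[1], x$spacing[2], x$spacing[3], sum(x$data)))
  invisible(x)
}

# NIfTI stores axes fastest-first as (x, y, z); internally we use
# (z, y, x) so axis 1 is the axial slice index.
.to_disk <- function(a) aperm(a, c(3L, 2L, 1L))
.from_disk <- function(a) aperm(a, c(3L, 2L, 1L))

#' Read a CT volume from NIfTI
#'
#' Reads a 3-D NIfTI-1 image (`.nii` or `.nii.gz`), extracts voxel spacing
#' from the header, and normalises the axis order to
#' `(axial, row, column)`.
#'
#' @param path path to an existing NIfTI file.
#' @param phase contrast-phase label recorded on the result.
#' @return A [ct_volume()].
#' @export
read_volume <- function(path, phase = "portal") {
  hdr <- .read_nifti_3d(path)
  ct_volume(.from_disk(hdr$data), spacing = rev(hdr$pixdim), phase = phase)
}

#' Read a binary mask from NIfTI
#'
#' @inheritParams read_volume
#' @param reference optional `ct_volume` the mask must align to.
#' @return A [ct_mask()].
#' @export
read_mask <- function(path, reference = NULL) {
  hdr <- .read_nifti_3d(path)
  ct_mask(.from_disk(hdr$data), spacing = rev(hdr$pixdim),
          reference = reference)
}

.read_nifti_3d <- function(path) {
  if (!file.exists(path)) {
    stop_ctb("file not found: ", path, class = "ctb_io_error")
  }
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) {
    stop_ctb("expected a 3-D image, got ", length(d), "-D: ", path,
             class = "ctb_shape_error")
  }
  pd <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(pd)) || any(pd <= 0)) {
    stop_ctb("non-positive voxel spacing in header of ", path,
             class = "ctb_header_error")
  }
  list(data = array(as.numeric(img), dim = d), pixdim = as.numeric(pd))
}

#' Write a CT volume or mask to NIfTI
#'
#' Volumes are stored as 32-bit float, masks as unsigned 8-bit. The header
#' pixdim carries the voxel spacing so that `write` then `read` is the
#' identity on both data and spacing.
#'
#' @param x a `ct_volume` or `ct_mask`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "ct_mask")) {
    arr <- .to_disk(array(as.integer(x$data), dim = dim(x$data)))
    dtype <- "uint8"
  } else if (inherits(x, "ct_volume")) {
    arr <- .to_disk(x$data)
    dtype <- "float"
  } else {
    stop_ctb("write_volume: need a ct_volume or ct_mask",
             class = "ctb_contract_error")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(x$spacing)
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

#' @rdname write_volume
#' @export
write_mask <- write_volume

#' Read a per-patient cohort response table
#'
#' Reads a CSV with columns `case`, `density_pct`, `volume_pct`, `size_pct`,
#' `combined_pct`, `recist`, `pfs_months`. Missing progression-free survival
#' may be written as an empty field or a dash and is parsed as `NA` (never
#' zero). The combined column is validated against the additivity identity
#' `combined = density + volume` to within 0.01 percentage points; rows
#' violating it trigger a warning naming the cases.
#'
#' @param path CSV file path.
#' @return A `data.frame` of class `cohort_table`.
#' @examples
#' tab <- read_cohort(system.file("extdata", "table2_cohort.csv",
#'                                package = "ctburden"))
#' nrow(tab)
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) {
    stop_ctb("file not found: ", path, class = "ctb_io_error")
  }
  df <- read.csv(path, stringsAsFactors = FALSE,
                 na.strings = c("", "NA", "-", "—"))
  required <- c("case", "density_pct", "volume_pct", "size_pct",
                "combined_pct", "recist", "pfs_months")
  if (nrow(df) == 0L) {
    stop_ctb("cohort table is empty: ", path, class = "ctb_validation_error")
  }
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_ctb("cohort table lacks columns: ",
             paste(missing_cols, collapse = ", "),
             class = "ctb_validation_error")
  }
  df <- df[required]
  for (col in c("density_pct", "volume_pct", "size_pct", "combined_pct",
                "pfs_months")) {
    df[[col]] <- as.numeric(df[[col]])
  }
  if (anyDuplicated(df$case)) {
    stop_ctb("duplicate case numbers: ",
             paste(unique(df$case[duplicated(df$case)]), collapse = ", "),
             class = "ctb_validation_error")
  }
  bad_recist <- !df$recist %in% c("CR", "PR", "SD", "PD")
  if (any(bad_recist)) {
    stop_ctb("invalid RECIST categories in cases: ",
             paste(df$case[bad_recist], collapse = ", "),
             class = "ctb_validation_error")
  }
  dev <- abs(df$combined_pct - (df$density_pct + df$volume_pct))
  if (any(dev > 0.01, na.rm = TRUE)) {
    warning("combined_pct deviates from density_pct + volume_pct by > 0.01 ",
            "in cases: ", paste(df$case[dev > 0.01], collapse = ", "))
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Path to the packaged 25-patient cohort fixture
#'
#' Per-patient percent changes in mean volumetric tumor density, total tumor
#' volume and RECIST diameter sum, the combined change, the RECIST 1.1
#' category and progression-free survival for the 25-patient
#' neuroendocrine-tumor cohort used throughout the examples and tests.
#'
#' @return File path of the CSV shipped with the package.
#' @export
cohort_fixture_path <- function() {
  system.file("extdata", "table2_cohort.csv", package = "ctburden",
              mustWork = TRUE)
}
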