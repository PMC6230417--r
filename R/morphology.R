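# Binary 3-D morphology and connected components (Rcpp backends).

#' Label connected components of a 3-D mask
#'
#' @param mask logical 3-D array or [ct_mask()].
#' @param connectivity 6, 18 or 26 (default 26).
#' @return Integer array of component labels (0 = background) with
#'   attribute `n_components`.
#' @export
label_components <- function(mask, connectivity = 26L) {
  arr <- mask_data(mask)
  lab <- label_components_cpp(as.logical(arr), dim(arr),
                              as.integer(connectivity))
  n <- attr(lab, "n_components")
  dim(lab) <- dim(arr)
  attr(lab, "n_components") <- n
  lab
}

#' Binary morphology with a ball structuring element
#'
#' Dilation, erosion, closing (dilate then erode) and opening (erode then
#' dilate) with a Euclidean ball of the given voxel radius. At the grid
#' border the structuring element is clipped (outside voxels count as
#' background for dilation and foreground for erosion) so that closing is
#' extensive and opening anti-extensive on the bounded grid. Radius 0 is
#' the identity.
#'
#' @param mask logical 3-D array or [ct_mask()].
#' @param radius ball radius in voxels (>= 0).
#' @return Logical array (or `ct_mask` if the input was one).
#' @name morphology
NULL

.morph <- function(mask, radius, ops) {
  arr <- mask_data(mask)
  d <- dim(arr)
  out <- as.logical(arr)
  for (op in ops) out <- binary_morph_cpp(out, d, as.integer(radius), op)
  dim(out) <- d
  if (inherits(mask, "ct_mask")) ct_mask(out, spacing = mask$spacing) else out
}

#' @rdname morphology
#' @export
binary_dilate <- function(mask, radius) .morph(mask, radius, 0L)

#' @rdname morphology
#' @export
binary_erode <- function(mask, radius) .morph(mask, radius, 1L)

#' @rdname morphology
#' @export
binary_close <- function(mask, radius) .morph(mask, radius, c(0L, 1L))

#' @rdname morphology
#' @export
binary_open <- function(mask, radius) .morph(mask, radius, c(1L, 0L))
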