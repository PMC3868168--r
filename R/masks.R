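#' @title Tissue masks and atlas alignment
#' @description Binary tissue masks from posterior-probability maps,
#'   nearest-neighbour alignment of a labeled parcellation to the perfusion
#'   grid, and the masked whole-brain perfusion map.
#' @name masks_atlas
NULL

#' Threshold a tissue-probability map
#'
#' A voxel enters the mask iff its posterior probability is greater than or
#' equal to the threshold ("minimum probability" read inclusively). The
#' default 0.70 minimizes partial-volume contamination of each tissue class.
#'
#' @param prob 3-D array of posterior probabilities in [0, 1].
#' @param threshold Minimum admitted probability, in (0, 1). Default 0.70.
#' @return Binary (0/1) array of the same shape.
#' @export
threshold_probability <- function(prob, threshold = 0.70) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("'threshold' must be a single probability in (0, 1)")
  if (any(prob < 0 | prob > 1, na.rm = TRUE))
    stop("probability map has values outside [0, 1]")
  mask <- array(0L, dim = dim(prob))
  mask[!is.na(prob) & prob >= threshold] <- 1L
  mask
}

#' Assemble gray/white tissue masks
#'
#' Resolves overlap between independently thresholded gray and white masks:
#' a voxel claimed by both is assigned to gray (the analysis target), with a
#' warning. Guarantees the two masks are disjoint so the whole-brain mask
#' sum can never double perfusion.
#'
#' @param gray,white Binary 3-D arrays on a shared grid.
#' @return List of class \code{tissue_masks} with disjoint \code{gray} and
#'   \code{white} binary arrays.
#' @export
tissue_masks <- function(gray, white) {
  if (!identical(dim(gray), dim(white)))
    stop("geometry mismatch: gray and white masks differ in shape")
  overlap <- gray > 0 & white > 0
  if (any(overlap)) {
    warning(sum(overlap),
            " voxel(s) in both tissue masks; assigned to gray")
    white[overlap] <- 0L
  }
  structure(list(gray = (gray > 0) + 0L, white = (white > 0) + 0L),
            class = "tissue_masks")
}

#' Resample an integer label volume to a target grid
#'
#' Nearest-neighbour assignment: each target voxel center is mapped through
#' the target affine to world coordinates and back through the source
#' affine; the nearest source voxel's label is copied. Labels are never
#' interpolated, so every output label exists in the input; target voxels
#' falling outside the source grid get 0 (background).
#'
#' @param labels 3-D integer array of region labels (0 = background).
#' @param src_geometry \code{\link{vol_geometry}} of \code{labels}.
#' @param target_geometry \code{\link{vol_geometry}} of the perfusion grid.
#' @return Integer label array with \code{target_geometry$dim}.
#' @export
resample_labels <- function(labels, src_geometry, target_geometry) {
  stopifnot(inherits(src_geometry, "vol_geometry"),
            inherits(target_geometry, "vol_geometry"))
  if (identical(src_geometry$dim, target_geometry$dim) &&
      isTRUE(all.equal(src_geometry$affine, target_geometry$affine)))
    return(labels)
  inv <- tryCatch(solve(src_geometry$affine),
                  error = function(e) stop("singular source affine"))
  world <- .voxel_world(target_geometry)
  src_idx <- round(inv %*% world)[1:3, , drop = FALSE]
  d <- src_geometry$dim
  inside <- src_idx[1, ] >= 0 & src_idx[1, ] < d[1] &
            src_idx[2, ] >= 0 & src_idx[2, ] < d[2] &
            src_idx[3, ] >= 0 & src_idx[3, ] < d[3]
  out <- integer(ncol(world))
  lin <- 1L + src_idx[1, inside] + d[1] * (src_idx[2, inside] +
           d[2] * src_idx[3, inside])
  out[inside] <- as.integer(labels)[lin]
  array(out, dim = target_geometry$dim)
}

#' Masked whole-brain perfusion map
#'
#' Implements whole-brain perfusion = (binary gray mask + binary white
#' mask) x (perfusion data). The masks are disjoint by construction
#' (\code{\link{tissue_masks}}); if raw overlapping masks are supplied the
#' factor-2 voxels are resolved to 1 with a warning.
#'
#' @param perf 3-D perfusion array.
#' @param masks A \code{\link{tissue_masks}} object or list with binary
#'   \code{gray} and \code{white} arrays.
#' @return Array of the same shape: perfusion inside the union mask,
#'   exactly 0 outside.
#' @export
whole_brain_perfusion <- function(perf, masks) {
  if (!identical(dim(perf), dim(masks$gray)) ||
      !identical(dim(perf), dim(masks$white)))
    stop("geometry mismatch: masks are not on the perfusion grid")
  m <- (masks$gray > 0) + (masks$white > 0)
  if (any(m > 1)) {
    warning("overlapping tissue masks produced mask-sum 2; clamped to 1")
    m <- pmin(m, 1)
  }
  out <- perf * m
  out[m == 0] <- 0
  out
}
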