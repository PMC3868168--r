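#' Voxel-grid geometry
#'
#' Minimal geometry record used by the resampling and simulation code: grid
#' dimensions, voxel sizes and a 4x4 voxel-to-world affine (0-based voxel
#' indices; world coordinates in mm at voxel centers). The default affine
#' places the corner of voxel (0,0,0) at the world origin, so grids of
#' different resolution constructed over the same field of view align.
#'
#' @param dim Integer grid dimensions (length 3).
#' @param voxdim_mm Voxel sizes in mm (length 3).
#' @param affine Optional 4x4 voxel-to-world matrix; computed from
#'   \code{voxdim_mm} when absent.
#' @return A list of class \code{vol_geometry}.
#' @export
vol_geometry <- function(dim, voxdim_mm = c(1, 1, 1), affine = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim > 0L), length(voxdim_mm) == 3L,
            all(voxdim_mm > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxdim_mm, 1))
    affine[1:3, 4] <- voxdim_mm / 2  # center of voxel 0
  }
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  structure(list(dim = dim, voxdim_mm = voxdim_mm, affine = affine),
            class = "vol_geometry")
}

#' Read a NIfTI-1 volume
#'
#' Thin wrapper around \code{RNifti}: returns the voxel array together with
#' the header geometry in the package's \code{\link{vol_geometry}} form.
#' NIfTI qform/sform affines address 0-based voxel indices, matching the
#' package's internal convention.
#'
#' @param path Path to a \code{.nii} or \code{.nii.gz} file.
#' @return List with \code{data} (array) and \code{geometry}.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) {
    pd <- RNifti::pixdim(img)
    geom <- vol_geometry(dim(arr), pd[1:3],
                         affine = unclass(RNifti::xform(img)))
  } else geom <- NULL
  list(data = arr, geometry = geom)
}

#' Write a NIfTI-1 volume
#'
#' @param data 3-D or 4-D array.
#' @param path Output path (\code{.nii} or \code{.nii.gz}).
#' @param voxdim_mm Voxel sizes in mm.
#' @return \code{path}, invisibly.
#' @export
write_volume <- function(data, path, voxdim_mm = c(1, 1, 1)) {
  data <- array(as.numeric(data), dim = dim(data))  # drop attributes; NA-safe
  img <- RNifti::asNifti(data)
  pd <- RNifti::pixdim(img)
  pd[seq_along(voxdim_mm)] <- voxdim_mm
  RNifti::pixdim(img) <- pd
  RNifti::writeNifti(img, path)
  invisible(path)
}

# world coordinates of every voxel center of a geometry, 4 x n
.voxel_world <- function(geom) {
  idx <- as.matrix(expand.grid(i = seq_len(geom$dim[1]) - 1L,
                               j = seq_len(geom$dim[2]) - 1L,
                               k = seq_len(geom$dim[3]) - 1L))
  geom$affine %*% rbind(t(idx), 1)
}
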