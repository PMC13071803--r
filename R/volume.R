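#' Attenuation volumes
#'
#' A `voxel_volume` stores a 3-D array of non-negative linear
#' attenuation values (1/mm) on a regular grid, with the geometric
#' metadata needed to place it in the world: voxel spacing (mm),
#' the world position of the centre of voxel (1,1,1) (`origin`, mm) and
#' a 3x3 orthonormal direction matrix whose columns give the world
#' directions of the three array axes (identity for synthetic volumes).
#'
#' The world position of voxel index `(i, j, k)` (1-based) is
#' `origin + direction %*% (spacing * (c(i,j,k) - 1))`.
#'
#' @param intensities 3-D numeric array, values >= 0.
#' @param spacing length-3 positive voxel spacing (mm).
#' @param origin world position of the first voxel centre (mm).
#' @param direction 3x3 orthonormal matrix.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(intensities, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0), direction = diag(3)) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(length(dim(intensities)) == 3L, length(spacing) == 3L,
            length(origin) == 3L, all(spacing > 0))
  if (any(intensities < 0)) stop("attenuation values must be non-negative")
  direction <- matrix(as.numeric(direction), 3L, 3L)
  if (max(abs(crossprod(direction) - diag(3))) > 1e-9)
    stop("direction must be orthonormal")
  # tight index range of the nonzero support (padded by one voxel for
  # the trilinear fade); rays are clipped to it, so renders of mostly
  # empty grids do not pay for the empty space
  support <- NULL
  nz1 <- which(apply(intensities, 1L, max) > 0)
  if (length(nz1)) {
    nz2 <- which(apply(intensities, 2L, max) > 0)
    nz3 <- which(apply(intensities, 3L, max) > 0)
    d <- dim(intensities)
    support <- list(lo = pmax(c(min(nz1), min(nz2), min(nz3)) - 1L, 1L),
                    hi = pmin(c(max(nz1), max(nz2), max(nz3)) + 1L, d))
  }
  structure(list(intensities = intensities, spacing = as.numeric(spacing),
                 origin = as.numeric(origin), direction = direction,
                 support = support),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("voxel_volume %dx%dx%d, spacing (%g, %g, %g) mm, origin (%g, %g, %g) mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' World coordinates of voxel centres
#'
#' @param volume a `voxel_volume`.
#' @param idx matrix of 1-based voxel indices (rows = voxels) or a
#'   single length-3 index.
#' @return World coordinates in mm, same shape convention as `idx`.
#' @export
voxel_to_world <- function(volume, idx) {
  single <- is.null(dim(idx))
  if (single) idx <- matrix(idx, 1L, 3L)
  w <- sweep((sweep(idx, 2L, c(1, 1, 1), "-") %*%
                diag(volume$spacing)) %*% t(volume$direction),
             2L, volume$origin, "+")
  if (single) as.vector(w) else w
}

#' Axis-aligned world bounding box of a posed volume
#'
#' Transforms the corner voxel centres of the volume's nonzero support
#' (falling back to the full grid) by `pose` and returns the enclosing
#' axis-aligned box, padded by half a voxel so the support of trilinear
#' interpolation is covered.
#'
#' @param volume a `voxel_volume`.
#' @param pose a `rigid_transform` mapping volume world coordinates to
#'   scene world coordinates.
#' @return list with `lo` and `hi` (mm).
#' @export
volume_world_bbox <- function(volume, pose = rt_identity()) {
  s <- volume$support
  if (is.null(s)) {
    d <- dim(volume$intensities)
    s <- list(lo = c(1, 1, 1), hi = d)
  }
  corners <- as.matrix(expand.grid(c(s$lo[1], s$hi[1]),
                                   c(s$lo[2], s$hi[2]),
                                   c(s$lo[3], s$hi[3])))
  w <- rt_apply(pose, voxel_to_world(volume, corners))
  pad <- max(volume$spacing) / 2
  list(lo = apply(w, 2L, min) - pad, hi = apply(w, 2L, max) + pad)
}

#' Read and write attenuation volumes as NIfTI
#'
#' Volumes are stored as NIfTI-1 with the voxel spacing in `pixdim` and
#' the origin/direction in the sform. Only identity-direction volumes
#' are written by the synthetic generator, but arbitrary orthonormal
#' directions round-trip.
#'
#' @param volume a `voxel_volume`.
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume_nifti` returns a `voxel_volume`.
#' @export
write_volume_nifti <- function(volume, path) {
  xform <- diag(4)
  xform[1:3, 1:3] <- volume$direction %*% diag(volume$spacing)
  xform[1:3, 4] <- volume$origin
  img <- RNifti::asNifti(volume$intensities)
  img <- RNifti::`sform<-`(img, structure(xform, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  xform <- RNifti::xform(img)
  A <- xform[1:3, 1:3]
  spacing <- sqrt(colSums(A^2))
  voxel_volume(array(as.numeric(img), dim = dim(img)), spacing = spacing,
               origin = xform[1:3, 4], direction = A %*% diag(1 / spacing))
}
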