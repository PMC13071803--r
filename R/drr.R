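#' Render a digitally reconstructed radiograph (DRR)
#'
#' Casts a ray from the camera source through every pixel centre and
#' integrates the posed attenuation volume along it: fixed-step
#' trilinear ray marching with the step adapted down so an integer
#' number of samples exactly tiles the clipped ray segment (midpoint
#' rule). Rays are clipped to the world-space axis-aligned bounding box
#' of the posed volume, and only pixels inside the projection of that
#' box are marched at all; the remainder are exactly 0, identical to
#' full casting because the box contains the volume's support.
#'
#' @param volume a `voxel_volume`.
#' @param pose a `rigid_transform` placing the volume in the world
#'   (default identity).
#' @param camera a `camera_model`.
#' @param step_mm nominal integration step (mm); default half the
#'   smallest voxel spacing.
#' @return numeric matrix (`camera$image_size`) of line integrals
#'   (dimensionless, attenuation x mm), with attribute `roi` giving the
#'   marched pixel rectangle `c(r0, r1, c0, c1)` (0-based, inclusive)
#'   or `NULL` if the volume projects outside the image.
#' @export
render_drr <- function(volume, pose = rt_identity(), camera,
                       step_mm = min(volume$spacing) / 2) {
  stopifnot(inherits(volume, "voxel_volume"),
            inherits(camera, "camera_model"))
  if (step_mm <= 0) stop("step_mm must be positive")
  roi <- drr_roi(volume, pose, camera)
  nr <- camera$image_size[1]; nc <- camera$image_size[2]
  if (is.null(roi)) {
    out <- matrix(0, nr, nc)
    attr(out, "roi") <- NULL
    return(out)
  }
  bb <- volume_world_bbox(volume, pose)
  Bm <- t(volume$direction) %*% t(pose$rotation)
  c0 <- -as.vector(Bm %*% pose$translation) -
    as.vector(t(volume$direction) %*% volume$origin)
  out <- drr_render_cpp(as.numeric(volume$intensities),
                        dim(volume$intensities), volume$spacing,
                        Bm, c0, camera$source, camera$ray_matrix,
                        nr, nc, as.integer(roi), bb$lo, bb$hi, step_mm)
  attr(out, "roi") <- roi
  out
}

# Pixel rectangle (0-based, inclusive) covering the projection of the
# posed volume's bounding box, padded by one pixel; NULL if empty.
drr_roi <- function(volume, pose, camera) {
  bb <- volume_world_bbox(volume, pose)
  corners <- as.matrix(expand.grid(c(bb$lo[1], bb$hi[1]),
                                   c(bb$lo[2], bb$hi[2]),
                                   c(bb$lo[3], bb$hi[3])))
  uv <- t(apply(corners, 1L, function(p) {
    q <- project_point(camera, p)
    if (isTRUE(attr(q, "behind_camera"))) c(NA_real_, NA_real_) else q
  }))
  if (anyNA(uv)) {
    # part of the box projects behind the source: march everything
    return(c(0L, camera$image_size[1] - 1L, 0L, camera$image_size[2] - 1L))
  }
  r0 <- max(0L, floor(min(uv[, 2])) - 1L)
  r1 <- min(camera$image_size[1] - 1L, ceiling(max(uv[, 2])) + 1L)
  c0 <- max(0L, floor(min(uv[, 1])) - 1L)
  c1 <- min(camera$image_size[2] - 1L, ceiling(max(uv[, 1])) + 1L)
  if (r0 > r1 || c0 > c1) return(NULL)
  as.integer(c(r0, r1, c0, c1))
}
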