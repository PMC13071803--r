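#' Inertial coordinate system of a bone volume
#'
#' Computes the bone-fixed frame used to define pose perturbations: the
#' origin is the intensity-weighted centroid of the volume (its inertial
#' centre, world mm) and the axes are the principal axes of the
#' intensity-weighted inertia tensor about that centroid.
#'
#' Axis conventions, fixed for determinism: columns are ordered by
#' descending principal moment of inertia; each of the first two
#' columns is signed so that its largest-magnitude component is
#' positive; the third column is their cross product, so the axes
#' always form a right-handed frame. If the principal moments are
#' numerically indistinguishable (spherically symmetric intensity, e.g.
#' a single voxel), world-aligned identity axes are returned with a
#' warning.
#'
#' @param volume a `voxel_volume` with strictly positive total
#'   intensity.
#' @param degenerate_rtol relative spread of principal moments below
#'   which the tensor is treated as spherically symmetric.
#' @return An object of class `inertial_frame`: `origin` (world mm) and
#'   `axes` (3x3 orthonormal, det +1, columns = X, Y, Z principal axes).
#' @export
inertial_frame <- function(volume, degenerate_rtol = 1e-9) {
  stopifnot(inherits(volume, "voxel_volume"))
  w <- volume$intensities
  total <- sum(w)
  if (total <= 0) stop("empty volume: total intensity must be positive")
  d <- dim(w)

  # marginal sums give the centroid cheaply in index space
  mi <- apply(w, 1L, sum); mj <- apply(w, 2L, sum); mk <- apply(w, 3L, sum)
  ci <- sum(mi * seq_len(d[1])) / total
  cj <- sum(mj * seq_len(d[2])) / total
  ck <- sum(mk * seq_len(d[3])) / total
  origin <- voxel_to_world(volume, c(ci, cj, ck))

  # inertia tensor about the centroid, in volume axes then world axes
  xi <- (seq_len(d[1]) - ci) * volume$spacing[1]
  yj <- (seq_len(d[2]) - cj) * volume$spacing[2]
  zk <- (seq_len(d[3]) - ck) * volume$spacing[3]
  sxx <- sum(apply(w, 1L, sum) * xi^2)
  syy <- sum(apply(w, 2L, sum) * yj^2)
  szz <- sum(apply(w, 3L, sum) * zk^2)
  sxy <- sum(apply(w, c(1L, 2L), sum) * outer(xi, yj))
  sxz <- sum(apply(w, c(1L, 3L), sum) * outer(xi, zk))
  syz <- sum(apply(w, c(2L, 3L), sum) * outer(yj, zk))
  S <- matrix(c(sxx, sxy, sxz, sxy, syy, syz, sxz, syz, szz), 3L, 3L)
  inertia <- diag(rep(sum(diag(S)), 3L)) - S
  inertia <- volume$direction %*% inertia %*% t(volume$direction)

  e <- eigen(inertia, symmetric = TRUE)
  moments <- e$values  # eigen returns descending order
  scale <- max(abs(moments), 1e-300)
  if ((moments[1] - moments[3]) / scale < degenerate_rtol) {
    warning("degenerate inertia tensor (spherical symmetry): using world-aligned axes")
    return(structure(list(origin = origin, axes = diag(3),
                          moments = moments),
                     class = "inertial_frame"))
  }
  axes <- e$vectors
  for (k in 1:2) {
    if (axes[which.max(abs(axes[, k])), k] < 0) axes[, k] <- -axes[, k]
  }
  axes[, 3] <- cross3(axes[, 1], axes[, 2])
  structure(list(origin = origin, axes = axes, moments = moments),
            class = "inertial_frame")
}

#' @export
print.inertial_frame <- function(x, ...) {
  cat(sprintf("inertial_frame: origin (%g, %g, %g) mm\n",
              x$origin[1], x$origin[2], x$origin[3]))
  print(round(x$axes, 6))
  invisible(x)
}

#' Map an inertial frame through a pose
#'
#' The inertial frame is computed from the volume in its own (volume)
#' coordinates; perturbations are applied about the frame at the
#' bone's current world pose. This helper carries the origin and axes
#' through a rigid transform.
#'
#' @param frame an `inertial_frame`.
#' @param pose a `rigid_transform`.
#' @return An `inertial_frame` in the posed coordinates.
#' @export
frame_at_pose <- function(frame, pose) {
  stopifnot(inherits(frame, "inertial_frame"),
            inherits(pose, "rigid_transform"))
  structure(list(origin = rt_apply(pose, frame$origin),
                 axes = pose$rotation %*% frame$axes,
                 moments = frame$moments),
            class = "inertial_frame")
}

#' The seven perturbation axes
#'
#' Unit vectors, expressed in the bone's inertial frame, about which
#' rotational pose perturbations are applied: the three principal axes
#' X, Y, Z and the four distinct body diagonals of the unit cube,
#' normalised. (A signed diagonal pair counts once because both signs
#' of rotation are applied to every axis anyway.)
#'
#' @return A 7-row matrix of unit 3-vectors with rownames
#'   `X, Y, Z, D111, D11m, D1m1, Dm11`.
#' @export
perturbation_axes <- function() {
  ax <- rbind(X = c(1, 0, 0), Y = c(0, 1, 0), Z = c(0, 0, 1),
              D111 = c(1, 1, 1), D11m = c(1, 1, -1),
              D1m1 = c(1, -1, 1), Dm11 = c(-1, 1, 1))
  ax / sqrt(rowSums(ax^2))
}

#' Perturbation scheme specification
#'
#' @param magnitudes_deg positive rotation magnitudes in degrees;
#'   both signs of each magnitude are applied about every axis.
#' @param axes matrix of unit axes in the inertial frame (rows);
#'   defaults to [perturbation_axes()].
#' @return An object of class `perturbation_spec`.
#' @export
perturbation_spec <- function(magnitudes_deg = c(2, 4, 8),
                              axes = perturbation_axes()) {
  stopifnot(all(magnitudes_deg > 0))
  axes <- as.matrix(axes)
  stopifnot(ncol(axes) == 3L)
  if (any(abs(sqrt(rowSums(axes^2)) - 1) > 1e-12))
    stop("perturbation axes must have unit norm")
  if (is.null(rownames(axes)))
    rownames(axes) <- paste0("A", seq_len(nrow(axes)))
  structure(list(magnitudes_deg = as.numeric(magnitudes_deg), axes = axes),
            class = "perturbation_spec")
}

#' Generate perturbed poses around a gold-standard pose
#'
#' For every axis, magnitude and sign, the gold pose is pre-composed
#' with a world-frame rotation of the signed magnitude about the line
#' through the inertial-frame origin with direction `frame$axes %*% a`
#' (the axis expressed in world coordinates). With 7 axes, both signs
#' and the default three magnitudes this yields the 42 perturbed poses
#' applied per bone and frame.
#'
#' @param gold `rigid_transform` gold-standard pose.
#' @param frame `inertial_frame` of the bone at the gold pose.
#' @param spec `perturbation_spec`.
#' @return A data frame with columns `axis`, `sign`, `magnitude_deg`,
#'   `label` and a list-column `pose` of `rigid_transform`.
#' @export
generate_perturbations <- function(gold, frame, spec = perturbation_spec()) {
  stopifnot(inherits(gold, "rigid_transform"),
            inherits(frame, "inertial_frame"),
            inherits(spec, "perturbation_spec"))
  grid <- expand.grid(sign = c(1, -1), magnitude = spec$magnitudes_deg,
                      axis = rownames(spec$axes),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  poses <- lapply(seq_len(nrow(grid)), function(r) {
    a_world <- as.vector(frame$axes %*% spec$axes[grid$axis[r], ])
    pert <- rt_rotation(a_world, grid$sign[r] * grid$magnitude[r],
                        center = frame$origin)
    rt_compose(pert, gold)
  })
  data.frame(axis = grid$axis,
             sign = ifelse(grid$sign > 0, "+", "-"),
             magnitude_deg = grid$magnitude,
             label = sprintf("%s%s%g", ifelse(grid$sign > 0, "+", "-"),
                             grid$axis, grid$magnitude),
             pose = I(poses))
}
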