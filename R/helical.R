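#' Helical (screw) axis decomposition of a rigid displacement
#'
#' Chasles' theorem: every rigid displacement is a rotation `phi` about a
#' unique axis plus a translation along that axis. The decomposition is
#' used here as the pose error metric: `phi` (degrees) is the rotational
#' error and the absolute translation along the axis (mm) the
#' translational error.
#'
#' The angle is recovered from the rotation matrix trace; the axis from
#' the skew-symmetric part, switching to the symmetric part
#' (`(R + I)/2`) when `phi` approaches 180 degrees where the skew part
#' vanishes. If `phi` is below `degenerate_tol` degrees the displacement
#' is (numerically) a pure translation: the axis is taken along the
#' translation and the full translation norm is reported, with
#' `degenerate = TRUE`.
#'
#' @param delta a `rigid_transform` displacement.
#' @param degenerate_tol angle (degrees) below which the rotation is
#'   treated as degenerate. Default `1e-6`.
#' @return A list of class `helical_error`: `phi` (degrees, in
#'   \[0, 180\]), `translation_d` (mm, absolute translation along the
#'   axis), `axis` (unit 3-vector), `axis_point` (point on the axis
#'   closest to the world origin; `NA` when degenerate), `degenerate`.
#' @export
helical_decompose <- function(delta, degenerate_tol = 1e-6) {
  stopifnot(inherits(delta, "rigid_transform"))
  R <- delta$rotation
  t <- delta$translation
  cos_phi <- (sum(diag(R)) - 1) / 2
  cos_phi <- min(1, max(-1, cos_phi))
  phi <- acos(cos_phi)  # radians, [0, pi]

  if (phi * 180 / pi < degenerate_tol) {
    tn <- sqrt(sum(t^2))
    axis <- if (tn > 0) t / tn else c(0, 0, 0)
    return(structure(list(phi = phi * 180 / pi, translation_d = tn,
                          axis = axis, axis_point = rep(NA_real_, 3L),
                          degenerate = TRUE),
                     class = "helical_error"))
  }

  if (sin(phi) > 1e-6) {
    # axial vector of the skew part
    axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) /
      (2 * sin(phi))
  } else {
    # phi ~ pi: (R + I)/2 = a a^T; take the largest column
    S <- (R + diag(3)) / 2
    k <- which.max(diag(S))
    axis <- S[, k] / sqrt(S[k, k])
  }
  axis <- axis / sqrt(sum(axis^2))

  d <- sum(t * axis)             # signed translation along the axis
  t_perp <- t - d * axis
  # point on the axis closest to the origin:
  # p = (t_perp + axis x t_perp / tan(phi/2)) / 2, p orthogonal to axis
  axis_point <- (t_perp + cross3(axis, t_perp) / tan(phi / 2)) / 2

  structure(list(phi = phi * 180 / pi, translation_d = abs(d), axis = axis,
                 axis_point = axis_point, degenerate = FALSE),
            class = "helical_error")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Helical pose error between a gold-standard and an estimated pose
#'
#' Composes the error displacement in the world frame as
#' `estimated o invert(gold)` and decomposes it into helical
#' parameters. `phi` is frame-invariant; the along-axis translation is
#' reported under this fixed convention. Both are absolute values.
#'
#' @param gold,estimated `rigid_transform` poses.
#' @return A `helical_error` (see [helical_decompose()]).
#' @export
pose_error <- function(gold, estimated) {
  helical_decompose(rt_compose(estimated, rt_invert(gold)))
}

#' @export
print.helical_error <- function(x, ...) {
  cat(sprintf("helical_error: phi = %.6g deg, translation = %.6g mm%s\n",
              x$phi, x$translation_d,
              if (x$degenerate) " (degenerate: pure translation)" else ""))
  invisible(x)
}
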