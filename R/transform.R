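#' Rigid transforms
#'
#' A `rigid_transform` is a proper rigid-body displacement: a 3x3 rotation
#' matrix (orthonormal, determinant +1) plus a translation vector in mm.
#' It represents either a bone pose (volume coordinates to world
#' coordinates) or a pose delta. Applying the transform maps a point
#' `x` to `R x + t`.
#'
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric translation (mm).
#' @param renormalize if `TRUE`, project `rotation` onto the nearest
#'   rotation matrix (polar decomposition via SVD) before validation.
#'   Useful when the matrix has accumulated round-off.
#' @return An object of class `rigid_transform` with elements `rotation`
#'   and `translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0),
                            renormalize = FALSE) {
  rotation <- matrix(as.numeric(rotation), 3L, 3L)
  translation <- as.numeric(translation)
  stopifnot(length(translation) == 3L, all(is.finite(rotation)),
            all(is.finite(translation)))
  if (renormalize) {
    s <- svd(rotation)
    rotation <- s$u %*% t(s$v)
    if (det(rotation) < 0) rotation <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  }
  err <- max(abs(crossprod(rotation) - diag(3)))
  if (err > 1e-9 || abs(det(rotation) - 1) > 1e-9) {
    stop("rotation is not orthonormal with determinant +1 (max deviation ",
         format(err), "); consider renormalize = TRUE")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @export
rt_identity <- function() rigid_transform()

#' @export
print.rigid_transform <- function(x, ...) {
  cat("rigid_transform\n")
  m <- rt_as_matrix(x)
  print(round(m, 6))
  invisible(x)
}

#' Compose and invert rigid transforms
#'
#' `rt_compose(a, b)` returns the transform that applies `b` first and
#' then `a` (matrix product of the homogeneous forms). `rt_invert`
#' returns the inverse displacement.
#'
#' @param a,b,x `rigid_transform` objects.
#' @return A `rigid_transform`.
#' @export
rt_compose <- function(a, b) {
  stopifnot(inherits(a, "rigid_transform"), inherits(b, "rigid_transform"))
  rigid_transform(a$rotation %*% b$rotation,
                  as.vector(a$rotation %*% b$translation) + a$translation,
                  renormalize = TRUE)
}

#' @rdname rt_compose
#' @export
rt_invert <- function(x) {
  stopifnot(inherits(x, "rigid_transform"))
  rigid_transform(t(x$rotation), -as.vector(t(x$rotation) %*% x$translation))
}

#' Apply a rigid transform to points
#'
#' @param x a `rigid_transform`.
#' @param pts 3-vector or 3-column matrix of points (rows = points, mm).
#' @return Transformed points, same shape as `pts`.
#' @export
rt_apply <- function(x, pts) {
  if (is.null(dim(pts))) {
    as.vector(x$rotation %*% pts) + x$translation
  } else {
    sweep(pts %*% t(x$rotation), 2L, x$translation, "+")
  }
}

#' Rotation about an axis
#'
#' Builds the rigid transform that rotates by `angle_deg` degrees about
#' the line through `center` with unit direction `axis` (Rodrigues
#' formula). With the default `center = c(0,0,0)` this is a pure
#' rotation about the origin.
#'
#' @param axis length-3 direction (normalised internally).
#' @param angle_deg rotation angle in degrees; positive follows the
#'   right-hand rule about `axis`.
#' @param center point on the rotation axis (mm).
#' @return A `rigid_transform`.
#' @export
rt_rotation <- function(axis, angle_deg, center = c(0, 0, 0)) {
  axis <- as.numeric(axis)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("axis must be non-zero")
  axis <- axis / n
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3L, 3L)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rigid_transform(R, as.vector(center - R %*% center), renormalize = TRUE)
}

#' @rdname rt_rotation
#' @param translation translation applied after the rotation (mm).
#' @export
rt_translation <- function(translation) {
  rigid_transform(diag(3), translation)
}

#' Convert between rigid transforms and 4x4 homogeneous matrices
#'
#' @param x a `rigid_transform`.
#' @param m a 4x4 homogeneous matrix.
#' @param renormalize passed to [rigid_transform()].
#' @return `rt_as_matrix` a 4x4 matrix; `rt_from_matrix` a
#'   `rigid_transform`.
#' @export
rt_as_matrix <- function(x) {
  m <- diag(4)
  m[1:3, 1:3] <- x$rotation
  m[1:3, 4] <- x$translation
  m
}

#' @rdname rt_as_matrix
#' @export
rt_from_matrix <- function(m, renormalize = TRUE) {
  rigid_transform(m[1:3, 1:3], m[1:3, 4], renormalize = renormalize)
}

#' Read and write per-frame transform CSV files
#'
#' One row per frame with 16 comma-separated values: the row-major 4x4
#' homogeneous matrix in world mm. Lines beginning `#` are comments.
#' Values are written with 17 significant digits so that a write/read
#' round trip is bit-exact for doubles.
#'
#' @param transforms list of `rigid_transform` (one per frame).
#' @param path file path.
#' @param header optional comment line written at the top (without the
#'   leading `#`).
#' @return `read_transform_csv` returns a list of `rigid_transform`.
#' @export
write_transform_csv <- function(transforms, path, header = NULL) {
  if (inherits(transforms, "rigid_transform")) transforms <- list(transforms)
  lines <- vapply(transforms, function(tr) {
    paste(sprintf("%.17g", as.vector(t(rt_as_matrix(tr)))), collapse = ",")
  }, character(1))
  if (!is.null(header)) lines <- c(paste0("# ", header), lines)
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_transform_csv
#' @export
read_transform_csv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  lapply(lines, function(ln) {
    v <- as.numeric(strsplit(ln, ",")[[1]])
    if (length(v) != 16L) stop("expected 16 values per transform row, got ",
                               length(v))
    rt_from_matrix(matrix(v, 4L, 4L, byrow = TRUE), renormalize = FALSE)
  })
}
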