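#' Calibrated x-ray projector (pinhole camera)
#'
#' A `camera_model` holds a 3x4 projection matrix mapping homogeneous
#' world coordinates (mm) to homogeneous pixel coordinates, the x-ray
#' source position (the camera centre, which spans the null space of
#' the projection matrix) and the detector size in pixels.
#'
#' Pixel convention: 0-based, pixel centres at integer coordinates,
#' column `u` increasing to the detector right, row `v` increasing
#' downwards. `project_point` returns `c(u, v)`.
#'
#' @param projection 3x4 projection matrix.
#' @param image_size `c(rows, cols)` in pixels.
#' @param source optional camera centre (mm); recovered from the null
#'   space of `projection` when omitted.
#' @return An object of class `camera_model` with elements
#'   `projection`, `source`, `image_size` and `ray_matrix` (the inverse
#'   of the leading 3x3 block, used to back-project pixels to ray
#'   directions).
#' @export
camera_model <- function(projection, image_size, source = NULL) {
  projection <- matrix(as.numeric(projection), 3L, 4L)
  M <- projection[, 1:3]
  if (abs(det(M)) < 1e-12) stop("degenerate projection matrix")
  if (is.null(source)) source <- as.vector(-solve(M, projection[, 4]))
  resid <- max(abs(projection %*% c(source, 1)))
  if (resid > 1e-6 * max(abs(projection)))
    stop("source is not the null space of the projection matrix")
  structure(list(projection = projection, source = as.numeric(source),
                 image_size = as.integer(image_size),
                 ray_matrix = solve(M)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("camera_model: %dx%d px, source (%.1f, %.1f, %.1f) mm\n",
              x$image_size[1], x$image_size[2],
              x$source[1], x$source[2], x$source[3]))
  invisible(x)
}

#' Project a world point to pixel coordinates
#'
#' @param camera a `camera_model`.
#' @param world_point length-3 world coordinates (mm).
#' @return `c(u, v)` pixel coordinates, with attribute
#'   `behind_camera = TRUE` when the point lies on the source side away
#'   from the detector (negative projective depth).
#' @export
project_point <- function(camera, world_point) {
  p <- as.vector(camera$projection %*% c(world_point, 1))
  if (abs(p[3]) < 1e-300) stop("point at the camera centre cannot be projected")
  uv <- p[1:2] / p[3]
  if (p[3] < 0) attr(uv, "behind_camera") <- TRUE
  uv
}

#' Back-project a pixel to its world ray
#'
#' @param camera a `camera_model`.
#' @param uv pixel coordinates `c(u, v)`.
#' @return list with `origin` (the source, mm) and unit `direction`
#'   pointing from the source towards the detector.
#' @export
pixel_ray <- function(camera, uv) {
  d <- as.vector(camera$ray_matrix %*% c(uv, 1))
  list(origin = camera$source, direction = d / sqrt(sum(d^2)))
}

#' Build a calibrated biplanar camera rig
#'
#' Two pinhole x-ray projectors whose principal rays intersect at the
#' world origin, separated by `inter_view_angle` degrees about the
#' world vertical (+Z). Sources sit at `source_to_origin` mm from the
#' origin; detectors are perpendicular to the principal rays at
#' `source_to_detector` mm from the sources, with detector rows
#' pointing down (-Z) and the world origin projecting to the principal
#' point (the detector centre).
#'
#' @param image_size detector size in pixels (square detectors;
#'   `c(rows, cols)` also accepted).
#' @param pixel_pitch detector pixel size (mm).
#' @param source_to_detector source-to-detector distance (mm).
#' @param source_to_origin source-to-world-origin distance (mm).
#' @param inter_view_angle angle between the two principal rays
#'   (degrees, in (0, 180)).
#' @return A list of two `camera_model`s.
#' @export
make_camera_rig <- function(image_size = 256, pixel_pitch = 0.75,
                            source_to_detector = 1300,
                            source_to_origin = 1100,
                            inter_view_angle = 60) {
  stopifnot(inter_view_angle > 0, inter_view_angle < 180,
            pixel_pitch > 0, source_to_detector > source_to_origin / 2)
  if (length(image_size) == 1L) image_size <- c(image_size, image_size)
  f <- source_to_detector / pixel_pitch  # focal length in pixels
  pp <- (rev(image_size) - 1) / 2        # principal point (u0, v0)
  K <- matrix(c(f, 0, 0, 0, f, 0, pp[1], pp[2], 1), 3L, 3L)
  lapply(c(-1, 1) * inter_view_angle / 2, function(theta_deg) {
    th <- theta_deg * pi / 180
    d <- c(cos(th), sin(th), 0)          # origin -> source direction
    source <- source_to_origin * d
    z_cam <- -d                          # viewing direction
    x_cam <- c(-sin(th), cos(th), 0)     # detector u axis
    y_cam <- cross3(z_cam, x_cam)        # detector v axis (points down)
    Rwc <- rbind(x_cam, y_cam, z_cam)    # world -> camera rotation
    P <- K %*% cbind(Rwc, -as.vector(Rwc %*% source))
    camera_model(P, image_size, source = source)
  })
}

#' Rescale a camera to a downsampled detector
#'
#' Maps the projection matrix onto a detector shrunk by `factor`, using
#' the resampling pixel-centre convention: output pixel `i` sits at
#' input coordinate `(i + 0.5) * factor - 0.5`. Rendering a DRR through
#' the rescaled camera is then geometrically consistent with
#' downsampling the full-resolution radiograph.
#'
#' @param camera a `camera_model`.
#' @param factor integer shrink factor (>= 1).
#' @return A `camera_model` with `image_size / factor` pixels.
#' @export
camera_rescale <- function(camera, factor) {
  stopifnot(factor >= 1, all(camera$image_size %% factor == 0))
  if (factor == 1) return(camera)
  off <- (1 - factor) / (2 * factor)
  S <- matrix(c(1 / factor, 0, 0, 0, 1 / factor, 0, off, off, 1), 3L, 3L)
  camera_model(S %*% camera$projection, camera$image_size %/% factor,
               source = camera$source)
}

#' Read and write plain-text calibration files
#'
#' Primary dialect: three lines of four numbers each, the 3x4
#' projection matrix (world mm to pixels); `#` comment lines allowed.
#' A second dialect with explicit geometry (`geometry` on its first
#' non-comment line, followed by `key value...` lines for
#' `image_size`, `pixel_pitch`, `source_to_detector`,
#' `source_to_origin`, `view_angle`) is converted through the rig
#' construction.
#'
#' @param camera a `camera_model`.
#' @param path file path.
#' @param image_size detector size for the matrix dialect, which does
#'   not carry it; defaults on read to the stored `# image_size` hint
#'   if present.
#' @return `read_calibration` returns a `camera_model`.
#' @export
write_calibration <- function(camera, path) {
  lines <- c(sprintf("# image_size %d %d", camera$image_size[1],
                     camera$image_size[2]),
             apply(camera$projection, 1L,
                   function(r) paste(sprintf("%.17g", r), collapse = " ")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path, image_size = NULL) {
  lines <- readLines(path)
  hint <- grep("^#\\s*image_size", lines, value = TRUE)
  if (is.null(image_size) && length(hint))
    image_size <- as.integer(strsplit(trimws(sub("^#\\s*image_size", "",
                                                 hint[1])), "\\s+")[[1]])
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(body) && trimws(body[1]) == "geometry") {
    kv <- strsplit(trimws(body[-1]), "\\s+")
    vals <- stats::setNames(lapply(kv, function(x) as.numeric(x[-1])),
                            vapply(kv, `[`, character(1), 1L))
    rig <- make_camera_rig(image_size = vals$image_size,
                           pixel_pitch = vals$pixel_pitch,
                           source_to_detector = vals$source_to_detector,
                           source_to_origin = vals$source_to_origin,
                           inter_view_angle = abs(vals$view_angle) * 2)
    return(rig[[if (vals$view_angle < 0) 1L else 2L]])
  }
  if (length(body) != 3L) stop("expected 3 matrix rows in calibration file")
  P <- do.call(rbind, lapply(body, function(ln)
    as.numeric(strsplit(trimws(ln), "\\s+")[[1]])))
  if (ncol(P) != 4L) stop("expected 4 numbers per calibration row")
  if (is.null(image_size)) stop("image_size required for matrix calibration")
  camera_model(P, image_size)
}
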