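# Shared fixtures, built in code.

# A camera looking down the -X axis (principal ray perpendicular to the
# YZ plane), so axis-aligned volumes present a face-on chord.
axis_camera <- function(image_size = 64, pixel_pitch = 3,
                        source_to_detector = 1300,
                        source_to_origin = 1100) {
  f <- source_to_detector / pixel_pitch
  pp <- (image_size - 1) / 2
  K <- matrix(c(f, 0, 0, 0, f, 0, pp, pp, 1), 3, 3)
  source <- c(source_to_origin, 0, 0)
  Rwc <- rbind(c(0, 1, 0),    # u = +Y
               c(0, 0, -1),   # v = -Z (rows point down)
               c(-1, 0, 0))   # viewing direction -X
  P <- K %*% cbind(Rwc, -as.vector(Rwc %*% source))
  camera_model(P, c(image_size, image_size), source = source)
}

# A uniform axis-aligned cube volume: n^3 voxels of attenuation mu.
cube_volume <- function(n = 33, mu = 0.02, spacing = 1,
                        center = c(0, 0, 0)) {
  voxel_volume(array(mu, c(n, n, n)), spacing = spacing,
               origin = center - (n - 1) / 2 * spacing)
}

# Random rotation matrix via QR of a Gaussian matrix (det +1).
random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_transform <- function(t_scale = 50) {
  rigid_transform(random_rotation(), rnorm(3, sd = t_scale))
}

# Quaternion-based rotation angle/axis oracle (Shepperd's method),
# an independent code path from the trace/skew extraction used by
# helical_decompose.
quat_from_rotation <- function(R) {
  tr <- sum(diag(R))
  cand <- c(tr, R[1, 1], R[2, 2], R[3, 3])
  k <- which.max(cand)
  if (k == 1L) {
    s <- sqrt(tr + 1) * 2
    q <- c(s / 4, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- k - 1L; j <- i %% 3L + 1L; l <- j %% 3L + 1L
    s <- sqrt(R[i, i] - R[j, j] - R[l, l] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[l, j] - R[j, l]) / s
    q[i + 1] <- s / 4
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[l + 1] <- (R[l, i] + R[i, l]) / s
  }
  q / sqrt(sum(q^2))
}

quat_angle_deg <- function(R) {
  q <- quat_from_rotation(R)
  2 * atan2(sqrt(sum(q[2:4]^2)), abs(q[1])) * 180 / pi
}

quat_axis <- function(R) {
  q <- quat_from_rotation(R)
  if (q[1] < 0) q <- -q
  v <- q[2:4]
  n <- sqrt(sum(v^2))
  if (n < 1e-300) c(0, 0, 0) else v / n
}

# Tiny single-bone noiseless scene used by registration tests.
tiny_single_bone <- function(seed = 1, image_size = 64, grid_size = 32) {
  make_trial_scene(image_size = image_size, grid_size = grid_size,
                   n_frames = 1, bones = "talus", targets = "talus",
                   noise = noise_spec(enabled = FALSE), seed = seed,
                   exit_fov = FALSE)
}
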