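#' Synthetic bone volumes
#'
#' Builds a smooth superellipsoid blob with a brighter cortical shell
#' (about two voxels thick) and a dimmer trabecular interior, plus a
#' low-frequency random modulation of the surface so no two seeds give
#' the same shape. Three archetypes emulate the registration
#' difficulty classes seen at the ankle: `isolated` (calcaneus-like,
#' little overlap with neighbours), `enclosed` (talus-like, compact and
#' rounded) and `long-bone` (tibia-like, elongated at least 3:1 along
#' the third array axis).
#'
#' Attenuation values are physiologically plausible linear attenuation
#' coefficients at diagnostic x-ray energies: cortical shell 0.06/mm,
#' trabecular interior 0.028/mm.
#'
#' @param kind `"isolated"`, `"enclosed"` or `"long-bone"`.
#' @param grid_size voxels per axis (scalar or triple, >= 16).
#' @param spacing voxel spacing in mm (scalar or triple).
#' @param seed integer; the volume is deterministic given the seed.
#' @param center world position of the volume centre (mm).
#' @param mu_cortical,mu_trabecular attenuation of shell and interior
#'   (1/mm).
#' @return A `voxel_volume`.
#' @export
make_bone_volume <- function(kind = c("isolated", "enclosed", "long-bone"),
                             grid_size = 64, spacing = 1, seed = 1,
                             center = c(0, 0, 0),
                             mu_cortical = 0.06, mu_trabecular = 0.028) {
  kind <- match.arg(kind)
  if (length(grid_size) == 1L) grid_size <- rep(grid_size, 3L)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  stopifnot(all(grid_size >= 16L))
  semi <- switch(kind,
    "isolated" = c(0.70, 0.55, 0.50),
    "enclosed" = c(0.55, 0.50, 0.45),
    "long-bone" = c(0.26, 0.26, 0.95))
  p <- switch(kind, "isolated" = 2.5, "enclosed" = 2.0, "long-bone" = 2.5)

  rng <- local_rng(seed)
  on.exit(rng())
  amp <- 0.45  # surface irregularity: bones are strongly non-ellipsoidal
  ph <- stats::runif(9, 0, 2 * pi)
  fr <- sample(1:2, 6, replace = TRUE)

  n <- grid_size
  u <- (seq_len(n[1]) - (n[1] + 1) / 2) / (n[1] / 2)
  v <- (seq_len(n[2]) - (n[2] + 1) / 2) / (n[2] / 2)
  w <- (seq_len(n[3]) - (n[3] + 1) / 2) / (n[3] / 2)
  U <- array(u, n)
  V <- aperm(array(v, n[c(2, 1, 3)]), c(2, 1, 3))
  W <- aperm(array(w, n[c(3, 1, 2)]), c(2, 3, 1))

  # superellipsoid scaled radius, modulated at low spatial frequency so
  # the surface carries rotationally informative features
  rho <- (abs(U / semi[1])^p + abs(V / semi[2])^p +
            abs(W / semi[3])^p)^(1 / p)
  mod <- 1 + amp *
    (sin(fr[1] * pi * U + ph[1]) * cos(fr[2] * pi * V + ph[2]) +
       0.8 * sin(fr[3] * pi * W + ph[3]) * cos(fr[4] * pi * U + ph[4]) +
       0.6 * sin(fr[5] * pi * V + ph[5]) * sin(fr[6] * pi * W + ph[6])) / 2.4
  rho <- rho / mod

  # shell thickness ~ 2 voxels relative to the smallest semi-axis (mm),
  # capped so coarse grids keep a trabecular interior
  semi_mm <- semi * grid_size * spacing / 2
  thick <- min(2 * max(spacing) / min(semi_mm), 0.3)
  # trabecular interior: low-frequency density texture (internal edges)
  tex <- 1 + 0.35 * sin(2 * pi * U + ph[7]) * cos(1.5 * pi * V + ph[8]) +
    0.25 * sin(2.5 * pi * W + ph[9])
  intens <- array(0, n)
  inside <- rho <= 1
  intens[inside] <- pmax(mu_trabecular * tex[inside], 0.3 * mu_trabecular)
  # dense internal structures (subchondral-plate-like inclusions):
  # high-contrast interior features that make rotation identifiable in
  # projection, as real bone architecture is
  for (q in 1:3) {
    ctr <- stats::runif(3, -0.45, 0.45) * semi
    rad <- stats::runif(3, 0.12, 0.28) * semi
    dd <- ((U - ctr[1]) / rad[1])^2 + ((V - ctr[2]) / rad[2])^2 +
      ((W - ctr[3]) / rad[3])^2
    sel <- inside & dd <= 1
    intens[sel] <- 0.92 * mu_cortical
  }
  intens[inside & rho > 1 - thick] <- mu_cortical

  origin <- center - (grid_size - 1) / 2 * spacing
  voxel_volume(intens, spacing = spacing, origin = origin)
}

# Evaluate thunk-free seeded RNG: set a local seed, return a restorer.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}

#' Photon and read noise specification
#'
#' Detector counts are modelled as `I = photon_scale * exp(-integral)`
#' followed by Poisson sampling and additive Gaussian read noise,
#' clipped at zero. Applied at the native capture resolution, this
#' gives the resolution-dependent signal-to-noise behaviour of
#' photon-starved high-speed radiography: downsampling averages
#' independent noise and so raises per-pixel SNR.
#'
#' @param photon_scale expected counts at zero attenuation (> 0).
#' @param read_sigma Gaussian read-noise standard deviation (counts).
#' @param enabled disable to obtain noiseless ideal radiographs.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(photon_scale = 45, read_sigma = 3, enabled = TRUE) {
  stopifnot(photon_scale > 0, read_sigma >= 0)
  structure(list(photon_scale = photon_scale, read_sigma = read_sigma,
                 enabled = isTRUE(enabled)), class = "noise_spec")
}

#' Gold-standard hop trajectories
#'
#' A smooth hop-like motion: half-sine vertical translation plus a
#' plantarflexion-like rotation about the world X axis, shared by all
#' bones, with small per-bone relative offsets and modulation so the
#' bones move near-rigidly together but not identically. Adjacent-frame
#' pose changes stay below 3 degrees and 5 mm at the default
#' amplitudes. If `exit_bone` is set, that bone receives an extra
#' vertical excursion in the first and last ~15% of frames, pushing
#' its proximal end out of the field of view (the long-bone challenge).
#'
#' @param n_frames number of frames (>= 1).
#' @param bone_names character vector naming the bones.
#' @param amplitude_mm peak vertical translation (mm).
#' @param amplitude_deg peak rotation (degrees).
#' @param seed integer; deterministic given the seed.
#' @param pattern only `"hop"` is defined.
#' @param exit_bone name of the bone given the field-of-view exit
#'   excursion, or `NULL`.
#' @param exit_mm size of the exit excursion (mm).
#' @return Named list (per bone) of lists of `rigid_transform`, one per
#'   frame.
#' @export
make_trajectory <- function(n_frames, bone_names, pattern = "hop",
                            amplitude_mm = 8, amplitude_deg = 6, seed = 1,
                            exit_bone = NULL, exit_mm = 18) {
  stopifnot(n_frames >= 1, pattern == "hop")
  rng <- local_rng(seed + 7L)
  on.exit(rng())
  tt <- if (n_frames == 1) 0.5 else (seq_len(n_frames) - 1) / (n_frames - 1)
  s <- sin(pi * tt)
  out <- list()
  for (b in bone_names) {
    dphase <- stats::runif(1, -0.08, 0.08)
    dscale <- 1 + stats::runif(1, -0.1, 0.1)
    off_t <- stats::runif(3, -1.5, 1.5)
    off_r <- stats::runif(1, -1, 1)
    sb <- sin(pi * pmin(pmax(tt + dphase, 0), 1)) * dscale
    extra <- if (!is.null(exit_bone) && b == exit_bone) {
      exit_mm * pmax(0, (0.15 - tt) / 0.15, (tt - 0.85) / 0.15)
    } else rep(0, n_frames)
    out[[b]] <- lapply(seq_len(n_frames), function(i) {
      rot <- rt_rotation(c(1, 0, 0), amplitude_deg * sb[i] + off_r)
      rt_compose(rt_translation(c(0, 0, amplitude_mm * sb[i] + extra[i]) +
                                  off_t), rot)
    })
  }
  out
}

#' Assemble a synthetic ankle-like trial scene
#'
#' Three bones in an ankle-like arrangement: a talus-like `enclosed`
#' bone at the origin, a tibia-like `long-bone` above it (overlapping
#' it in projection and optionally exiting the field of view) and a
#' calcaneus-like `isolated` bone below. The world geometry is fixed in
#' mm; changing `image_size` or `grid_size` only changes sampling
#' density (pixel pitch and voxel spacing are derived so the field of
#' view and bone sizes stay constant), so desk- and tiny-scale scenes
#' image the same physical phantom.
#'
#' @param image_size native detector size in pixels (square).
#' @param grid_size bone volume grid (voxels per axis).
#' @param n_frames trajectory length.
#' @param bones subset of `c("talus", "tibia", "calcaneus")` to
#'   include.
#' @param targets which bones are registration targets (the others act
#'   only as enclosing neighbours); defaults to all included bones
#'   except the tibia-likes acting as neighbours.
#' @param noise a `noise_spec`.
#' @param seed integer master seed (shapes, trajectory and noise draw
#'   sub-seeds from it).
#' @param exit_fov give the tibia the field-of-view exit excursion.
#' @param detector_mm physical detector width (mm).
#' @param inter_view_angle rig angle (degrees).
#' @return An object of class `trial_scene`: `bones`, `targets`,
#'   `trajectory`, `cameras`, `noise`, `seed`, `native_size`.
#' @export
make_trial_scene <- function(image_size = 256, grid_size = 64, n_frames = 8,
                             bones = c("talus", "tibia", "calcaneus"),
                             targets = NULL, noise = noise_spec(), seed = 1,
                             exit_fov = TRUE, detector_mm = 90,
                             inter_view_angle = 60) {
  spacing <- 64 / grid_size
  specs <- list(
    talus = list(kind = "enclosed", center = c(0, 0, 0)),
    tibia = list(kind = "long-bone", center = c(0, 4, 42)),
    calcaneus = list(kind = "isolated", center = c(14, -12, -28)))
  bones <- match.arg(bones, names(specs), several.ok = TRUE)
  if (is.null(targets)) {
    targets <- setdiff(bones, "tibia")
    if (!length(targets)) targets <- bones
  }
  stopifnot(all(targets %in% bones))
  vols <- lapply(seq_along(bones), function(i) {
    sp <- specs[[bones[i]]]
    make_bone_volume(sp$kind, grid_size = grid_size, spacing = spacing,
                     seed = seed * 101L + i, center = sp$center)
  })
  names(vols) <- bones
  traj <- make_trajectory(n_frames, bones, seed = seed,
                          exit_bone = if (exit_fov && "tibia" %in% bones)
                            "tibia" else NULL)
  cams <- make_camera_rig(image_size = image_size,
                          pixel_pitch = detector_mm / image_size,
                          inter_view_angle = inter_view_angle)
  structure(list(bones = vols, targets = targets, trajectory = traj,
                 cameras = cams, noise = noise, seed = as.integer(seed),
                 native_size = as.integer(image_size)),
            class = "trial_scene")
}

#' @export
print.trial_scene <- function(x, ...) {
  cat(sprintf("trial_scene: %d bones (%s), %d frames, %dx%d px native\n",
              length(x$bones), paste(names(x$bones), collapse = ", "),
              length(x$trajectory[[1]]), x$native_size, x$native_size))
  invisible(x)
}

#' Render the captured radiographs of a trial scene
#'
#' For every frame and camera, the line integrals of all bones at their
#' gold poses are summed, converted to detector counts
#' `photon_scale * exp(-integral)`, Poisson-sampled, perturbed by
#' Gaussian read noise and clipped at zero. Deterministic given
#' `scene$seed`. With noise disabled the ideal expected counts are
#' returned.
#'
#' @param scene a `trial_scene`.
#' @param frames frame indices to render (default all).
#' @param step_mm DRR integration step (mm).
#' @return List (per frame) of lists of two count images (one per
#'   camera).
#' @export
render_trial <- function(scene, frames = NULL, step_mm = NULL) {
  stopifnot(inherits(scene, "trial_scene"))
  nf <- length(scene$trajectory[[1]])
  if (is.null(frames)) frames <- seq_len(nf)
  if (is.null(step_mm))
    step_mm <- min(vapply(scene$bones, function(v) min(v$spacing), 0)) / 2
  rng <- local_rng(scene$seed * 1009L + 17L)
  on.exit(rng())
  ns <- scene$noise
  lapply(frames, function(f) {
    lapply(scene$cameras, function(cam) {
      integ <- 0
      for (b in names(scene$bones)) {
        integ <- integ + render_drr(scene$bones[[b]],
                                    scene$trajectory[[b]][[f]], cam,
                                    step_mm = step_mm)
      }
      counts <- ns$photon_scale * exp(-integ)
      if (ns$enabled) {
        counts <- matrix(stats::rpois(length(counts), counts),
                         nrow(counts), ncol(counts))
        if (ns$read_sigma > 0)
          counts <- counts + matrix(stats::rnorm(length(counts), 0,
                                                 ns$read_sigma),
                                    nrow(counts), ncol(counts))
        counts[counts < 0] <- 0
      }
      counts
    })
  })
}
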