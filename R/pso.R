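#' Particle swarm optimiser configuration
#'
#' Canonical global-best PSO settings for the 6-DOF pose refinement.
#' The search space is a 6-vector offset from the initial pose: three
#' axis-angle rotation components (degrees, applied about the bone's
#' inertial centre) and three translations (mm).
#'
#' @param n_particles swarm size (>= 2).
#' @param n_iterations iteration budget.
#' @param w inertia weight, in (0, 1).
#' @param c1,c2 cognitive and social acceleration coefficients.
#' @param bounds `c(rotation half-range deg, translation half-range mm)`,
#'   both positive; the swarm is initialised and clamped inside
#'   `[-bounds, bounds]` per component.
#' @param seed integer RNG seed; the optimisation is fully
#'   deterministic given the seed.
#' @param early_stop_tol,early_stop_patience stop when the global best
#'   improves by less than `early_stop_tol` for
#'   `early_stop_patience` consecutive iterations (patience `Inf`
#'   disables early stopping).
#' @return An object of class `pso_config`.
#' @export
pso_config <- function(n_particles = 40, n_iterations = 60, w = 0.7,
                       c1 = 1.5, c2 = 1.5, bounds = c(10, 10), seed = 1,
                       early_stop_tol = 1e-8, early_stop_patience = 25) {
  stopifnot(n_particles >= 2, n_iterations >= 1, w > 0, w < 1,
            all(bounds >= 0), length(bounds) == 2L)
  structure(list(n_particles = as.integer(n_particles),
                 n_iterations = as.integer(n_iterations),
                 w = w, c1 = c1, c2 = c2, bounds = as.numeric(bounds),
                 seed = as.integer(seed),
                 early_stop_tol = early_stop_tol,
                 early_stop_patience = early_stop_patience),
            class = "pso_config")
}

#' Convert a 6-vector pose offset to a pose
#'
#' The offset is applied on top of `init_pose`: a rotation by
#' `|params[1:3]|` degrees about the axis `params[1:3]` through
#' `center` (the bone's inertial centre at the initial pose), followed
#' by the translation `params[4:6]` mm.
#'
#' @param params numeric 6-vector (deg, deg, deg, mm, mm, mm).
#' @param init_pose `rigid_transform`.
#' @param center world rotation centre (mm).
#' @return A `rigid_transform`.
#' @export
params_to_pose <- function(params, init_pose, center) {
  if (all(params == 0)) return(init_pose)
  rv <- params[1:3]
  ang <- sqrt(sum(rv^2))
  delta <- if (ang < 1e-12) rt_translation(params[4:6]) else
    rt_compose(rt_translation(params[4:6]),
               rt_rotation(rv, ang, center = center))
  rt_compose(delta, init_pose)
}

#' Registration cost: DRR-to-radiograph dissimilarity over both views
#'
#' Renders a DRR of the bone at the candidate pose in each view,
#' applies the preprocessing chain to it, and sums `1 - ncc` against
#' the (already preprocessed) target images, each term restricted to
#' the DRR's region of interest. Range `[0, 4]`; lower is better. If
#' the DRR falls entirely outside an image that view contributes the
#' worst value 2 and the result carries attribute `out_of_view = TRUE`.
#'
#' @param params 6-vector offset (see [params_to_pose()]).
#' @param init_pose `rigid_transform` initial pose.
#' @param center world rotation centre.
#' @param volume the target bone's `voxel_volume`.
#' @param cameras list of two `camera_model`s (already at the
#'   condition's resolution).
#' @param targets_pre list of two preprocessed target images.
#' @param chain preprocessing chain (see [preprocess()]), applied to
#'   each DRR.
#' @param roi `"silhouette"` (default) correlates over the pixels the
#'   DRR actually covers (its projected silhouette, which suppresses
#'   interference from neighbouring bones inside the bounding box);
#'   `"bbox"` uses the full projected bounding rectangle.
#' @param post_render optional function applied to each raw DRR before
#'   preprocessing (e.g. a downsampling operator when DRRs are rendered
#'   at native resolution but compared at a condition's resolution);
#'   implies the silhouette ROI.
#' @param step_mm DRR integration step.
#' @return cost in `[0, 4]`.
#' @export
registration_cost <- function(params, init_pose, center, volume, cameras,
                              targets_pre, chain = c("stretch", "sobel"),
                              roi = c("silhouette", "bbox"),
                              post_render = NULL,
                              step_mm = min(volume$spacing) / 2) {
  roi_mode <- match.arg(roi)
  cost <- 0
  oov <- FALSE
  for (k in seq_along(cameras)) {
    drr <- render_drr(volume, params_to_pose(params, init_pose, center),
                      cameras[[k]], step_mm = step_mm)
    box <- attr(drr, "roi")
    if (is.null(box) || max(drr) <= 0) {
      cost <- cost + 2
      oov <- TRUE
      next
    }
    if (!is.null(post_render)) {
      drr <- post_render(drr)
      roi_mode <- "silhouette"
      box <- c(0L, nrow(drr) - 1L, 0L, ncol(drr) - 1L)
    }
    rows <- (box[1]:box[2]) + 1L
    cols <- (box[3]:box[4]) + 1L
    if (roi_mode == "silhouette") {
      # preprocess the ROI box only; the silhouette sits at least one
      # pixel inside the box, so convolution boundary handling matches
      # the cached full-image target there
      sub <- drr[rows, cols, drop = FALSE]
      d <- preprocess(sub, chain)
      cost <- cost + (1 - ncc(d, targets_pre[[k]][rows, cols, drop = FALSE],
                              mask = abs(sub) > 1e-12))
    } else {
      d <- preprocess(drr, chain)
      cost <- cost + (1 - ncc(d[rows, cols, drop = FALSE],
                              targets_pre[[k]][rows, cols, drop = FALSE]))
    }
  }
  if (oov) attr(cost, "out_of_view") <- TRUE
  cost
}

#' Refine a pose by particle swarm optimisation
#'
#' Canonical global-best PSO over the 6-vector pose offset. Particles
#' are initialised uniformly inside the bounds with one particle pinned
#' at the zero offset (the initial pose itself); velocities update as
#' `v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)` with fresh
#' per-dimension uniforms, and positions are clamped to the bounds.
#' Deterministic given `pso$seed`.
#'
#' Note: the target images are preprocessed once here and cached for
#' every cost evaluation.
#'
#' @param init_pose `rigid_transform` starting pose (e.g. a perturbed
#'   gold pose).
#' @param volume the bone's `voxel_volume`.
#' @param cameras list of two `camera_model`s.
#' @param target_images list of two raw target images at the
#'   condition's resolution.
#' @param pso a `pso_config`.
#' @param chain preprocessing chain applied to targets and DRRs.
#' @param target_transform steps prepended to the chain for the target
#'   images only; the default `"neglog"` maps detector counts back to
#'   the line-integral domain the DRRs live in (set to `character(0)`
#'   when the targets are already line integrals, e.g. self-rendered
#'   DRRs).
#' @param roi correlation support, see [registration_cost()].
#' @param post_render optional DRR post-render hook, see
#'   [registration_cost()].
#' @param center world rotation centre; defaults to the volume's
#'   inertial centre mapped through `init_pose`.
#' @param step_mm DRR integration step.
#' @return list: `pose` (refined `rigid_transform`), `params`, `cost`,
#'   `trace` (global-best cost per iteration, non-increasing),
#'   `iterations`, `flags`.
#' @export
optimize_pose <- function(init_pose, volume, cameras, target_images,
                          pso = pso_config(), chain = c("stretch", "sobel"),
                          target_transform = "neglog",
                          roi = c("silhouette", "bbox"),
                          post_render = NULL,
                          center = NULL, step_mm = min(volume$spacing) / 2) {
  roi <- match.arg(roi)
  stopifnot(inherits(pso, "pso_config"))
  if (is.null(center))
    center <- rt_apply(init_pose, inertial_frame(volume)$origin)
  targets_pre <- lapply(target_images, preprocess,
                        chain = c(target_transform, chain))
  b <- rep(pso$bounds, each = 3L)
  np <- pso$n_particles
  fcost <- function(x) registration_cost(x, init_pose, center, volume,
                                         cameras, targets_pre, chain,
                                         roi = roi, post_render = post_render,
                                         step_mm = step_mm)

  rng <- local_rng(pso$seed)
  on.exit(rng())
  X <- t(replicate(np, stats::runif(6, -b, b)))
  X[1, ] <- 0  # pinned at the initial pose
  V <- matrix(0, np, 6L)
  pbest <- X
  pcost <- apply(X, 1L, function(x) as.numeric(fcost(x)))
  gi <- which.min(pcost)
  gbest <- pbest[gi, ]; gcost <- pcost[gi]
  trace <- numeric(0)
  stall <- 0L
  flags <- character(0)
  iter_done <- 0L

  for (it in seq_len(pso$n_iterations)) {
    r1 <- matrix(stats::runif(np * 6L), np, 6L)
    r2 <- matrix(stats::runif(np * 6L), np, 6L)
    V <- pso$w * V + pso$c1 * r1 * (pbest - X) +
      pso$c2 * r2 * (matrix(gbest, np, 6L, byrow = TRUE) - X)
    X <- X + V
    X <- pmin(pmax(X, matrix(-b, np, 6L, byrow = TRUE)),
              matrix(b, np, 6L, byrow = TRUE))
    prev <- gcost
    for (i in seq_len(np)) {
      ci <- as.numeric(fcost(X[i, ]))
      if (ci < pcost[i]) {
        pcost[i] <- ci
        pbest[i, ] <- X[i, ]
        if (ci < gcost) {
          gcost <- ci
          gbest <- X[i, ]
        }
      }
    }
    trace <- c(trace, gcost)
    iter_done <- it
    stall <- if (prev - gcost < pso$early_stop_tol) stall + 1L else 0L
    if (stall >= pso$early_stop_patience) {
      flags <- c(flags, "early_stop")
      break
    }
  }
  final <- fcost(gbest)
  if (isTRUE(attr(final, "out_of_view"))) flags <- c(flags, "out_of_view")
  list(pose = params_to_pose(gbest, init_pose, center), params = gbest,
       cost = gcost, trace = trace, iterations = iter_done, flags = flags)
}
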