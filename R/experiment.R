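#' Experiment configuration
#'
#' Bundles everything the resolution experiment needs: the synthetic
#' scene, the resolution conditions, the perturbation scheme, the
#' optimiser settings and the seeds. The three conditions share the
#' SAME noisy native images; the downsampled conditions differ only by
#' the resampling operator (no fresh noise draw), so condition
#' comparisons isolate the resolution treatment.
#'
#' @param image_size native capture resolution (pixels, square). The
#'   desk-scale default is 256 with a 4x downsample to 64, preserving
#'   the full-scale 2048 -> 512 ratio; `paper_scale = TRUE` raises the
#'   defaults towards 2048/512/35 for users with time.
#' @param downsample_factor integer shrink factor for the downsampled
#'   conditions.
#' @param grid_size bone volume grid (voxels per axis).
#' @param n_frames trajectory length.
#' @param bones,targets scene composition (see [make_trial_scene()]).
#' @param magnitudes_deg perturbation magnitudes (degrees).
#' @param conditions subset of `c("fullres", "bicubic", "nearest")`.
#' @param noise a `noise_spec`.
#' @param pso a `pso_config` (its seed is re-derived per record).
#' @param chain preprocessing chain.
#' @param drr_policy `"render_at_target"` renders DRRs directly at the
#'   condition's image size; `"downsample_rendered"` renders at native
#'   size and downsamples the DRR with the condition's method.
#' @param step_mm DRR integration step (mm); `NULL` uses half the
#'   smallest voxel spacing.
#' @param scene_seed,pso_seed integer seeds.
#' @param exit_fov give the tibia the field-of-view exit excursion.
#' @param paper_scale use full-scale sizes (2048/512, 35 frames).
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(image_size = 256, downsample_factor = 4,
                              grid_size = 64, n_frames = 8,
                              bones = c("talus", "tibia", "calcaneus"),
                              targets = NULL,
                              magnitudes_deg = c(2, 4, 8),
                              conditions = c("fullres", "bicubic", "nearest"),
                              noise = noise_spec(),
                              pso = pso_config(),
                              chain = c("stretch", "sobel"),
                              drr_policy = c("render_at_target",
                                             "downsample_rendered"),
                              step_mm = NULL,
                              scene_seed = 1, pso_seed = 1,
                              exit_fov = TRUE, paper_scale = FALSE) {
  if (paper_scale) {
    image_size <- 2048; downsample_factor <- 4
    grid_size <- 256; n_frames <- 35
  }
  if (image_size %% downsample_factor != 0)
    stop("downsample_factor must divide image_size evenly")
  conditions <- match.arg(conditions, c("fullres", "bicubic", "nearest"),
                          several.ok = TRUE)
  structure(list(image_size = as.integer(image_size),
                 downsample_factor = as.integer(downsample_factor),
                 grid_size = as.integer(grid_size),
                 n_frames = as.integer(n_frames),
                 bones = bones, targets = targets,
                 magnitudes_deg = magnitudes_deg, conditions = conditions,
                 noise = noise, pso = pso, chain = chain,
                 drr_policy = match.arg(drr_policy), step_mm = step_mm,
                 scene_seed = as.integer(scene_seed),
                 pso_seed = as.integer(pso_seed),
                 exit_fov = isTRUE(exit_fov)),
            class = "experiment_config")
}

# deterministic small-integer sub-seed from a record's coordinates
record_seed <- function(base, bone_i, frame, pert_i, cond_i) {
  as.integer((base * 2654435L + bone_i * 97003L + frame * 7907L +
                pert_i * 131L + cond_i) %% 2147483629L)
}

#' Run the full resolution experiment
#'
#' Generates the scene and its noisy native radiographs, prepares each
#' resolution condition (full resolution, bicubic and nearest-neighbour
#' downsampling of the same images), perturbs every target bone's
#' gold pose about its inertial axes, refines each perturbed pose by
#' PSO and scores the helical error against gold. Returns per-record
#' results, per-(bone x magnitude x condition x metric) summaries and
#' the nonparametric tests. Fully deterministic given the config seeds.
#'
#' Per-record failures (e.g. a pose driven out of view) are recorded in
#' the `flags` column and never abort the batch.
#'
#' @param config an `experiment_config`.
#' @param outdir optional output directory; when given, records
#'   (JSON-lines), summaries and tests (CSV) and a YAML config snapshot
#'   are written there (overwriting identically on re-run).
#' @param frames optional subset of frame indices.
#' @param progress print per-record progress lines.
#' @return list with `records` (data frame), `summaries` (data frame),
#'   `tests` (data frame), `scene`.
#' @export
run_experiment <- function(config, outdir = NULL, frames = NULL,
                           progress = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  scene <- make_trial_scene(image_size = config$image_size,
                            grid_size = config$grid_size,
                            n_frames = config$n_frames,
                            bones = config$bones, targets = config$targets,
                            noise = config$noise, seed = config$scene_seed,
                            exit_fov = config$exit_fov)
  if (is.null(frames)) frames <- seq_len(config$n_frames)
  native <- render_trial(scene, frames = frames)
  f <- config$downsample_factor
  out_size <- config$image_size %/% f

  conds <- lapply(config$conditions, function(cn) {
    imgs <- lapply(native, function(fr) switch(cn,
      fullres = fr,
      bicubic = lapply(fr, downsample_bicubic, out_size = out_size),
      nearest = lapply(fr, downsample_nearest, out_size = out_size)))
    native_render <- config$drr_policy == "downsample_rendered"
    cams <- if (cn == "fullres" || native_render) scene$cameras else
      lapply(scene$cameras, camera_rescale, factor = f)
    post <- if (cn == "fullres" || !native_render) NULL else
      switch(cn,
             bicubic = function(im) downsample_bicubic(im, out_size),
             nearest = function(im) downsample_nearest(im, out_size))
    list(name = cn, images = imgs, cameras = cams, post_render = post)
  })

  spec <- perturbation_spec(config$magnitudes_deg)
  rows <- list()
  ri <- 0L
  for (bi in seq_along(scene$targets)) {
    bone <- scene$targets[bi]
    vol <- scene$bones[[bone]]
    if_local <- inertial_frame(vol)
    for (fi in seq_along(frames)) {
      fr <- frames[fi]
      gold <- scene$trajectory[[bone]][[fr]]
      frame_world <- frame_at_pose(if_local, gold)
      perts <- generate_perturbations(gold, frame_world, spec)
      for (pi in seq_len(nrow(perts))) {
        for (ci in seq_along(conds)) {
          cond <- conds[[ci]]
          pcfg <- config$pso
          pcfg$seed <- record_seed(config$pso_seed, bi, fr, pi, ci)
          step <- if (is.null(config$step_mm)) min(vol$spacing) / 2 else
            config$step_mm
          res <- optimize_pose(perts$pose[[pi]], vol, cond$cameras,
                               cond$images[[fi]], pso = pcfg,
                               chain = config$chain,
                               post_render = cond$post_render,
                               center = frame_world$origin, step_mm = step)
          err <- pose_error(gold, res$pose)
          ri <- ri + 1L
          rows[[ri]] <- data.frame(
            bone = bone, frame = fr, condition = cond$name,
            label = perts$label[pi], axis = perts$axis[pi],
            sign = perts$sign[pi],
            magnitude_deg = perts$magnitude_deg[pi],
            cost = as.numeric(res$cost), iterations = res$iterations,
            phi_deg = err$phi, trans_mm = err$translation_d,
            flags = paste(res$flags, collapse = ";"),
            pose = I(list(rt_as_matrix(res$pose))),
            stringsAsFactors = FALSE)
          if (progress)
            message(sprintf("%s f%d %s %s: phi=%.3f deg d=%.3f mm cost=%.4f",
                            bone, fr, cond$name, perts$label[pi],
                            err$phi, err$translation_d, res$cost))
        }
      }
    }
  }
  records <- do.call(rbind, rows)
  summaries <- summarize_records(records)
  tests <- test_records(records)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_records_jsonl(records, file.path(outdir, "records.jsonl"))
    utils::write.csv(summaries, file.path(outdir, "summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(tests, file.path(outdir, "tests.csv"),
                     row.names = FALSE)
    write_config_yaml(config, file.path(outdir, "config.yaml"))
  }
  list(records = records, summaries = summaries, tests = tests,
       scene = scene)
}

#' Summarise experiment records into the condition table
#'
#' One row per bone x perturbation magnitude x condition x metric, with
#' the error observations pooled across frames and perturbation axes at
#' that magnitude.
#'
#' @param records the records data frame from [run_experiment()].
#' @return data frame with the descriptive-statistics columns of
#'   [summarize_errors()].
#' @export
summarize_records <- function(records) {
  keys <- unique(records[, c("bone", "magnitude_deg", "condition")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- records$bone == keys$bone[i] &
      records$magnitude_deg == keys$magnitude_deg[i] &
      records$condition == keys$condition[i]
    for (metric in c("rotation", "translation")) {
      x <- if (metric == "rotation") records$phi_deg[sel] else
        records$trans_mm[sel]
      s <- summarize_errors(x)
      out[[length(out) + 1L]] <- data.frame(
        bone = keys$bone[i], perturbation_deg = keys$magnitude_deg[i],
        condition = keys$condition[i], metric = metric,
        median = s$median, loa_low = s$loa_low, loa_high = s$loa_high,
        cumulative_error = s$cumulative_error, mad = s$mad,
        n_outliers = s$n_outliers, n = s$n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Nonparametric tests across conditions
#'
#' For each bone x magnitude x metric family: Kruskal-Wallis across
#' the conditions, and (when significant at 0.05) Dunn's pairwise
#' z-tests with Bonferroni correction within the family.
#'
#' @param records the records data frame from [run_experiment()].
#' @return long data frame: one row per pairwise comparison (or a
#'   single row with `NA` pairwise fields when the omnibus gate is not
#'   passed).
#' @export
test_records <- function(records) {
  keys <- unique(records[, c("bone", "magnitude_deg")])
  out <- list()
  for (i in seq_len(nrow(keys))) {
    sel0 <- records$bone == keys$bone[i] &
      records$magnitude_deg == keys$magnitude_deg[i]
    for (metric in c("rotation", "translation")) {
      vals <- if (metric == "rotation") records$phi_deg else
        records$trans_mm
      groups <- split(vals[sel0], records$condition[sel0])
      if (length(groups) < 2L) next
      ct <- condition_tests(groups)
      base <- data.frame(bone = keys$bone[i],
                         perturbation_deg = keys$magnitude_deg[i],
                         metric = metric, kw_H = ct$kw$H, kw_p = ct$kw$p,
                         stringsAsFactors = FALSE)
      out[[length(out) + 1L]] <- if (is.null(ct$dunn)) {
        cbind(base, data.frame(group_a = NA_character_,
                               group_b = NA_character_, z = NA_real_,
                               p_adjusted = NA_real_))
      } else {
        cbind(base[rep(1L, nrow(ct$dunn)), , drop = FALSE],
              ct$dunn[, c("group_a", "group_b", "z", "p_adjusted")])
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

write_records_jsonl <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    rec <- as.list(records[i, setdiff(names(records), "pose")])
    rec$pose <- as.vector(t(records$pose[[i]]))
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

write_config_yaml <- function(config, path) {
  cfg <- unclass(config)
  cfg$noise <- unclass(cfg$noise)
  cfg$pso <- unclass(cfg$pso)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Generate an on-disk fixture set
#'
#' Writes a reproducible phantom trial through the real-data file
#' formats: bone volumes as NIfTI, per-camera radiograph stacks as
#' 16-bit TIFF, gold poses as transform CSVs, calibrations as
#' plain-text projection matrices and the scene parameters as YAML.
#' `tiny` uses a 32^3 volume grid, 64 x 64 images and 3 frames; `desk`
#' the 64^3 / 256 x 256 / 8-frame defaults.
#'
#' @param size `"tiny"` or `"desk"`.
#' @param dir output directory (created if needed).
#' @param seed scene seed.
#' @return (invisibly) a list of the written paths.
#' @export
generate_fixtures <- function(size = c("tiny", "desk"), dir, seed = 1) {
  size <- match.arg(size)
  dims <- if (size == "tiny") list(img = 64L, grid = 32L, nf = 3L) else
    list(img = 256L, grid = 64L, nf = 8L)
  scene <- make_trial_scene(image_size = dims$img, grid_size = dims$grid,
                            n_frames = dims$nf, seed = seed)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (b in names(scene$bones)) {
    p <- file.path(dir, paste0(b, ".nii.gz"))
    write_volume_nifti(scene$bones[[b]], p)
    paths[[paste0("volume_", b)]] <- p
    p <- file.path(dir, paste0(b, "_gold.csv"))
    write_transform_csv(scene$trajectory[[b]], p,
                        header = paste("gold poses:", b))
    paths[[paste0("gold_", b)]] <- p
  }
  imgs <- render_trial(scene)
  scale <- scene$noise$photon_scale * 1.5
  for (k in 1:2) {
    p <- file.path(dir, sprintf("camera%d.tif", k))
    write_radiograph_tiff(lapply(imgs, `[[`, k), p, scale = scale)
    paths[[paste0("stack_", k)]] <- p
    p <- file.path(dir, sprintf("camera%d_calibration.txt", k))
    write_calibration(scene$cameras[[k]], p)
    paths[[paste0("calibration_", k)]] <- p
  }
  p <- file.path(dir, "scene.yaml")
  yaml::write_yaml(list(size = size, seed = seed, image_size = dims$img,
                        grid_size = dims$grid, n_frames = dims$nf,
                        bones = names(scene$bones),
                        targets = scene$targets,
                        intensity_scale = scale,
                        noise = unclass(scene$noise)), p)
  paths$scene <- p
  invisible(paths)
}

#' Load a fixture set written by [generate_fixtures()]
#'
#' @param dir fixture directory.
#' @return list with `volumes`, `gold` (per-bone pose lists), `images`
#'   (per frame, per camera), `cameras`, `meta`.
#' @export
load_fixtures <- function(dir) {
  meta <- yaml::read_yaml(file.path(dir, "scene.yaml"))
  volumes <- lapply(stats::setNames(meta$bones, meta$bones), function(b)
    read_volume_nifti(file.path(dir, paste0(b, ".nii.gz"))))
  gold <- lapply(stats::setNames(meta$bones, meta$bones), function(b)
    read_transform_csv(file.path(dir, paste0(b, "_gold.csv"))))
  cameras <- lapply(1:2, function(k)
    read_calibration(file.path(dir, sprintf("camera%d_calibration.txt", k))))
  stacks <- lapply(1:2, function(k)
    read_radiograph_tiff(file.path(dir, sprintf("camera%d.tif", k)),
                         scale = meta$intensity_scale))
  images <- lapply(seq_len(meta$n_frames), function(f)
    list(stacks[[1]][[f]], stacks[[2]][[f]]))
  list(volumes = volumes, gold = gold, images = images, cameras = cameras,
       meta = meta)
}
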