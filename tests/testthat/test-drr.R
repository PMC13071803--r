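# DRR rendering: line integrals through a posed attenuation volume.

test_that("zero volume renders a zero image", {
  vol <- voxel_volume(array(0, c(17, 17, 17)), origin = c(-8, -8, -8))
  img <- render_drr(vol, camera = axis_camera())
  expect_true(all(img == 0))
})

test_that("uniform cube face-on gives the analytic chord length", {
  mu <- 0.02; n <- 33; step <- 0.5
  vol <- cube_volume(n = n, mu = mu)
  cam <- axis_camera(image_size = 64, pixel_pitch = 3)
  img <- render_drr(vol, camera = cam, step_mm = step)
  # principal point is at (u, v) = (31.5, 31.5): the four centre pixels
  # see a perpendicular chord through the cube (length = n mm) up to
  # sub-milliradian obliquity
  centre <- img[32:33, 32:33]
  expect_true(all(abs(centre - mu * n) < 2 * step * mu + 0.01 * mu * n))
})

test_that("rendering is linear in attenuation", {
  vol <- make_bone_volume("enclosed", grid_size = 24, spacing = 2, seed = 4)
  cam <- axis_camera()
  img1 <- render_drr(vol, camera = cam)
  vol3 <- voxel_volume(vol$intensities * 3.5, spacing = vol$spacing,
                       origin = vol$origin)
  img3 <- render_drr(vol3, camera = cam)
  expect_equal(as.vector(img3), as.vector(3.5 * img1), tolerance = 1e-9)
})

test_that("halving the integration step changes pixels by under 1 percent", {
  vol <- make_bone_volume("enclosed", grid_size = 24, spacing = 2, seed = 4)
  cam <- axis_camera()
  a <- render_drr(vol, camera = cam, step_mm = 1)
  b <- render_drr(vol, camera = cam, step_mm = 0.5)
  expect_lt(max(abs(a - b)) / max(b), 0.01)
})

test_that("mirror symmetry: reflecting the volume mirrors the image", {
  vol <- make_bone_volume("isolated", grid_size = 24, spacing = 2, seed = 6)
  cam <- axis_camera()
  img <- render_drr(vol, camera = cam)
  # mirror across the XZ plane (the plane of the principal ray and the
  # detector vertical): flip the volume's second axis
  mirr <- voxel_volume(vol$intensities[, dim(vol$intensities)[2]:1, ],
                       spacing = vol$spacing, origin = vol$origin)
  img_m <- render_drr(mirr, camera = cam)
  expect_lt(max(abs(img_m - img[, ncol(img):1])), 0.02 * max(img))
})

test_that("rigid consistency: posing the volume equals moving its grid", {
  vol <- make_bone_volume("enclosed", grid_size = 24, spacing = 2, seed = 4)
  pose <- rt_compose(rt_translation(c(4, -6, 3)), rt_rotation(c(1, 1, 0), 20))
  cam <- axis_camera()
  a <- render_drr(vol, pose, cam)
  moved <- voxel_volume(vol$intensities, spacing = vol$spacing,
                        origin = rt_apply(pose, vol$origin),
                        direction = pose$rotation %*% vol$direction)
  b <- render_drr(moved, camera = cam)
  expect_equal(as.vector(a), as.vector(b), tolerance = 1e-9)
})

test_that("non-positive step is rejected", {
  vol <- cube_volume(17)
  expect_error(render_drr(vol, camera = axis_camera(), step_mm = 0),
               "step")
})

test_that("projection and back-projection are consistent", {
  rig <- make_camera_rig(image_size = 128, pixel_pitch = 1.5)
  for (cam in rig) {
    # world origin projects to the principal point
    expect_equal(project_point(cam, c(0, 0, 0)), c(63.5, 63.5),
                 tolerance = 1e-9)
    # source is the null space
    expect_lt(max(abs(cam$projection %*% c(cam$source, 1))),
              1e-8 * max(abs(cam$projection)))
    # a point on the source-to-principal-point ray hits the principal point
    mid <- cam$source * 0.3
    expect_equal(project_point(cam, mid), c(63.5, 63.5), tolerance = 1e-9)
    # random points lie on their back-projected rays
    set.seed(3)
    for (i in 1:20) {
      p <- rnorm(3, sd = 40)
      uv <- project_point(cam, p)
      ray <- pixel_ray(cam, uv)
      d <- p - ray$origin
      dist <- sqrt(sum((d - sum(d * ray$direction) * ray$direction)^2))
      expect_lt(dist, 1e-6)
    }
  }
})

test_that("points behind the source are flagged", {
  cam <- make_camera_rig(image_size = 64, pixel_pitch = 3)[[1]]
  behind <- cam$source * 1.5
  expect_true(isTRUE(attr(project_point(cam, behind), "behind_camera")))
})

test_that("camera rig geometry: subtended angle and principal rays", {
  rig <- make_camera_rig(image_size = 64, pixel_pitch = 3,
                         inter_view_angle = 90)
  s1 <- rig[[1]]$source; s2 <- rig[[2]]$source
  ang <- acos(sum(s1 * s2) / sqrt(sum(s1^2) * sum(s2^2))) * 180 / pi
  expect_equal(ang, 90, tolerance = 1e-9)
})

test_that("calibration files round-trip, both dialects", {
  cam <- make_camera_rig(image_size = 96, pixel_pitch = 2)[[2]]
  path <- withr::local_tempfile(fileext = ".txt")
  write_calibration(cam, path)
  back <- read_calibration(path)
  expect_identical(back$projection, cam$projection)
  expect_identical(back$image_size, cam$image_size)

  geo <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# explicit geometry dialect", "geometry",
               "image_size 96", "pixel_pitch 2",
               "source_to_detector 1300", "source_to_origin 1100",
               "view_angle 30"), geo)
  cam2 <- read_calibration(geo)
  expect_equal(cam2$projection, cam$projection, tolerance = 1e-12)
})

test_that("camera_rescale matches downsampled projection geometry", {
  cam <- make_camera_rig(image_size = 64, pixel_pitch = 3)[[1]]
  cam4 <- camera_rescale(cam, 4)
  expect_equal(cam4$image_size, c(16L, 16L))
  set.seed(5)
  for (i in 1:10) {
    p <- rnorm(3, sd = 30)
    uv <- project_point(cam, p)
    uv4 <- project_point(cam4, p)
    expect_equal(uv4, (uv + 0.5) / 4 - 0.5, tolerance = 1e-9)
  }
})
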