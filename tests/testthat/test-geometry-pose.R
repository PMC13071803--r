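# Rigid-body algebra, inertial frames and the perturbation scheme.

test_that("composition and inversion behave as a group", {
  set.seed(11)
  T1 <- random_transform()
  expect_equal(rt_as_matrix(rt_compose(rt_identity(), T1)), rt_as_matrix(T1),
               tolerance = 1e-12)
  expect_equal(rt_as_matrix(rt_compose(T1, rt_invert(T1))), diag(4),
               tolerance = 1e-9)
  # coaxial rotations add
  got <- rt_compose(rt_rotation(c(0, 0, 1), 30), rt_rotation(c(0, 0, 1), 60))
  expect_equal(rt_as_matrix(got), rt_as_matrix(rt_rotation(c(0, 0, 1), 90)),
               tolerance = 1e-12)
  # associativity
  T2 <- random_transform(); T3 <- random_transform()
  expect_equal(rt_as_matrix(rt_compose(rt_compose(T1, T2), T3)),
               rt_as_matrix(rt_compose(T1, rt_compose(T2, T3))),
               tolerance = 1e-9)
})

test_that("non-orthonormal rotations are rejected unless renormalised", {
  M <- diag(3) * 1.001
  expect_error(rigid_transform(M), "orthonormal")
  expect_silent(rigid_transform(M, renormalize = TRUE))
})

test_that("inertial frame of a uniform box: centroid and signed permutation axes", {
  vol <- voxel_volume(array(1, c(31, 21, 11)), spacing = 1,
                      origin = c(5, 5, 5) - c(15, 10, 5))
  fr <- inertial_frame(vol)
  expect_equal(fr$origin, c(5, 5, 5), tolerance = 1e-9)
  # symmetry forces principal axes along the grid: signed permutation
  perm <- abs(fr$axes)
  expect_equal(perm[order(apply(perm, 2, which.max)), ], diag(3),
               tolerance = 1e-12)
  expect_equal(det(fr$axes), 1, tolerance = 1e-12)
  # longest side has the smallest moment: X axis (first column) is the
  # smallest-moment... columns ordered by DESCENDING moment, so the
  # last column aligns with the longest box side (i axis)
  expect_equal(abs(fr$axes[1, 3]), 1, tolerance = 1e-12)
})

test_that("single-voxel volume gives its world centre and degenerate axes", {
  a <- array(0, c(16, 16, 16)); a[4, 5, 6] <- 2
  vol <- voxel_volume(a, spacing = 2, origin = c(1, 1, 1))
  expect_warning(fr <- inertial_frame(vol), "degenerate")
  expect_equal(fr$origin, c(1, 1, 1) + 2 * (c(4, 5, 6) - 1))
  expect_equal(fr$axes, diag(3))
})

test_that("empty volume is rejected", {
  vol <- voxel_volume(array(0, c(16, 16, 16)))
  expect_error(inertial_frame(vol), "empty volume")
})

test_that("rotated ellipsoid recovers the rotation's principal axes", {
  # uniform ellipsoid with distinct semi-axes a > b > c along x, y, z:
  # inertia moments are ascending in a, so descending-moment ordering
  # puts the z (smallest semi-axis) direction first.
  semi <- c(14, 9, 5)
  n <- 41
  ax <- seq(-20, 20)
  R <- rt_rotation(c(1, 2, 3), 37)$rotation
  # sample the rotated ellipsoid on the grid: x in E iff R^T x in E0
  grid <- as.matrix(expand.grid(ax, ax, ax))
  back <- grid %*% R  # rows: R^T x
  inside <- (back[, 1] / semi[1])^2 + (back[, 2] / semi[2])^2 +
    (back[, 3] / semi[3])^2 <= 1
  vol <- voxel_volume(array(as.numeric(inside), c(n, n, n)),
                      origin = c(-20, -20, -20))
  fr <- inertial_frame(vol)
  # descending moment ordering: largest moment axis = smallest semi-axis
  want <- R %*% cbind(c(0, 0, 1), c(0, 1, 0), c(1, 0, 0))
  for (k in 1:3) {
    expect_gt(abs(sum(fr$axes[, k] * want[, k])), 0.999)
  }
})

test_that("inertial frame is equivariant under rigid motion of the volume", {
  vol <- make_bone_volume("isolated", grid_size = 24, spacing = 2, seed = 5)
  fr0 <- inertial_frame(vol)
  Tm <- rt_rotation(c(1, -1, 2), 33, center = c(10, 0, -5))
  moved <- voxel_volume(vol$intensities, spacing = vol$spacing,
                        origin = rt_apply(Tm, vol$origin),
                        direction = Tm$rotation %*% vol$direction)
  fr1 <- inertial_frame(moved)
  expect_equal(fr1$origin, rt_apply(Tm, fr0$origin), tolerance = 1e-9)
  # axes rotate with the volume up to the fixed sign convention
  got <- Tm$rotation %*% fr0$axes
  for (k in 1:3)
    expect_equal(abs(sum(got[, k] * fr1$axes[, k])), 1, tolerance = 1e-9)
})

test_that("the seven perturbation axes are unit, non-parallel and canonical", {
  ax <- perturbation_axes()
  expect_equal(nrow(ax), 7L)
  expect_equal(sqrt(rowSums(ax^2)), rep(1, 7), ignore_attr = TRUE,
               tolerance = 1e-15)
  dots <- abs(ax %*% t(ax))
  expect_true(all(dots[upper.tri(dots)] < 1 - 1e-9))
  expect_equal(ax["D111", ], c(1, 1, 1) / sqrt(3), ignore_attr = TRUE)
})

test_that("generate_perturbations yields 7 x 2 x |magnitudes| labelled poses", {
  vol <- make_bone_volume("enclosed", grid_size = 24, spacing = 2, seed = 2)
  fr <- inertial_frame(vol)
  gold <- rigid_transform(rt_rotation(c(0, 1, 0), 12)$rotation, c(3, -2, 8))
  perts <- generate_perturbations(gold, fr, perturbation_spec(c(2, 4, 8)))
  expect_equal(nrow(perts), 42L)
  expect_equal(length(unique(perts$label)), 42L)
  perts1 <- generate_perturbations(gold, fr, perturbation_spec(5))
  expect_equal(nrow(perts1), 14L)
})

test_that("perturbations rotate about the inertial centre: round-trip invariant", {
  vol <- make_bone_volume("enclosed", grid_size = 24, spacing = 2, seed = 2)
  fr_local <- inertial_frame(vol)
  gold <- rigid_transform(rt_rotation(c(2, 1, 0), -25)$rotation, c(3, -2, 8))
  fr <- structure(list(origin = rt_apply(gold, fr_local$origin),
                       axes = gold$rotation %*% fr_local$axes),
                  class = "inertial_frame")
  perts <- generate_perturbations(gold, fr, perturbation_spec(c(2, 4, 8)))
  for (i in seq_len(nrow(perts))) {
    err <- pose_error(gold, perts$pose[[i]])
    expect_equal(err$phi, perts$magnitude_deg[i], tolerance = 1e-9)
    expect_lt(err$translation_d, 1e-9)
    # the inertial centre itself does not move
    expect_equal(rt_apply(perts$pose[[i]], fr_local$origin),
                 rt_apply(gold, fr_local$origin), tolerance = 1e-9)
  }
})

test_that("transform CSV round-trips bit-exactly and skips comments", {
  set.seed(99)
  trs <- replicate(5, random_transform(), simplify = FALSE)
  path <- withr::local_tempfile(fileext = ".csv")
  write_transform_csv(trs, path, header = "gold poses")
  back <- read_transform_csv(path)
  expect_length(back, 5L)
  for (i in 1:5) {
    expect_identical(back[[i]]$rotation, trs[[i]]$rotation)
    expect_identical(back[[i]]$translation, trs[[i]]$translation)
  }
})
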