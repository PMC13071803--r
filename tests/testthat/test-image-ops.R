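# Downsampling operators, edge detection, NCC and preprocessing.

# Direct-definition (non-separable) cubic resampler used as the
# independent oracle for the fast separable implementation.
brute_bicubic <- function(img, out_size, antialias = TRUE) {
  kern <- function(x, a = -0.5) {
    x <- abs(x)
    ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
           ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
  }
  axis_w <- function(n_in, i, n_out) {
    scale <- n_in / n_out
    width <- if (antialias && scale > 1) scale else 1
    x <- (i + 0.5) * scale - 0.5
    ks <- floor(x - 2 * width + 1):ceiling(x + 2 * width - 1)
    w <- kern((x - ks) / width)
    w <- w / sum(w)
    list(k = pmin(pmax(ks, 0), n_in - 1), w = w)
  }
  out <- matrix(0, out_size[1], out_size[2])
  for (i in seq_len(out_size[1])) {
    rw <- axis_w(nrow(img), i - 1, out_size[1])
    for (j in seq_len(out_size[2])) {
      cw <- axis_w(ncol(img), j - 1, out_size[2])
      acc <- 0
      for (a in seq_along(rw$k))
        for (b in seq_along(cw$k))
          acc <- acc + rw$w[a] * cw$w[b] * img[rw$k[a] + 1, cw$k[b] + 1]
      out[i, j] <- acc
    }
  }
  out
}

test_that("bicubic preserves constants and linear ramps", {
  expect_equal(downsample_bicubic(matrix(3.7, 32, 32), 8),
               matrix(3.7, 8, 8), tolerance = 1e-12)
  # a linear ramp along columns stays a ramp with the scaled gradient
  ramp <- matrix(rep(0:63, each = 64), 64, 64)  # column j has value j-1
  out <- downsample_bicubic(ramp, 16)
  grads <- diff(out[8, 4:13])
  expect_equal(grads, rep(4, 9), tolerance = 1e-9)
})

test_that("bicubic matches the direct-definition oracle", {
  set.seed(21)
  img <- matrix(runif(48 * 32), 48, 32)
  expect_equal(downsample_bicubic(img, c(12, 8)),
               brute_bicubic(img, c(12, 8)), tolerance = 1e-9)
  expect_equal(downsample_bicubic(img, c(12, 8), antialias = FALSE),
               brute_bicubic(img, c(12, 8), antialias = FALSE),
               tolerance = 1e-9)
})

test_that("bicubic matches the reference resampler on interior pixels", {
  # frozen values from an independent reference cubic resampler
  # (Keys a = -0.5, antialiased, same centre mapping) for the
  # seed-42 uniform 64x64 image, output 16x16, pixels [5:8, 5:8]
  set.seed(42)
  img <- matrix(runif(64 * 64), 64, 64)
  out <- downsample_bicubic(img, 16)
  ref <- matrix(c(
    0.5267932, 0.5358325, 0.5349238, 0.5475016,
    0.55379707, 0.5277339, 0.44433424, 0.37955305,
    0.55261046, 0.5602407, 0.49482304, 0.42068166,
    0.53464085, 0.45785117, 0.41401005, 0.5504859), 4, 4, byrow = TRUE)
  expect_equal(out[5:8, 5:8], ref, tolerance = 1e-6)
})

test_that("upsampling and degenerate sizes are rejected", {
  img <- matrix(runif(16), 4, 4)
  expect_error(downsample_bicubic(img, 8), "upsampling")
  expect_error(downsample_nearest(img, 8), "upsampling")
  expect_error(downsample_nearest(img, 1), "at least")
})

test_that("nearest neighbour introduces no new values and matches brute force", {
  img <- matrix(seq_len(64 * 64), 64, 64)  # unique integer values
  out <- downsample_nearest(img, 16)
  expect_true(all(out %in% img))
  # brute-force per-pixel lookup
  brute <- matrix(0, 16, 16)
  for (i in 0:15) for (j in 0:15) {
    r <- min(max(floor((i + 0.5) * 4 - 0.5 + 0.5), 0), 63)
    c <- min(max(floor((j + 0.5) * 4 - 0.5 + 0.5), 0), 63)
    brute[i + 1, j + 1] <- img[r + 1, c + 1]
  }
  expect_equal(out, brute, ignore_attr = TRUE)
  expect_equal(downsample_nearest(matrix(2.5, 9, 9), c(3, 3)),
               matrix(2.5, 3, 3))
})

test_that("downsampling commutes with constant shift; nearest keeps support", {
  set.seed(4)
  img <- matrix(runif(32 * 32), 32, 32)
  for (f in list(downsample_bicubic, downsample_nearest)) {
    expect_equal(f(img + 7, 8), f(img, 8) + 7, tolerance = 1e-9)
  }
  expect_true(all(downsample_nearest(img, 8) %in% img))
})

test_that("sobel: constants, step edges and rotation equivariance", {
  expect_true(all(sobel_edges(matrix(2, 8, 8)) == 0))
  h <- 1.5
  step <- cbind(matrix(0, 9, 5), matrix(h, 9, 4))
  se <- sobel_edges(step)
  # interior columns adjacent to the step carry magnitude 4h
  expect_equal(se[3:7, 5], rep(4 * h, 5))
  expect_equal(se[3:7, 6], rep(4 * h, 5))
  expect_true(all(se[, c(1:3, 8:9)] == 0))
  # rotating by 90 degrees commutes with the magnitude
  set.seed(12)
  img <- matrix(runif(100), 10, 10)
  rot90 <- function(m) t(m)[, nrow(m):1]
  expect_equal(sobel_edges(rot90(img)), rot90(sobel_edges(img)),
               tolerance = 1e-12)
})

test_that("ncc: self, negation, affine invariance, masks and flat flags", {
  set.seed(13)
  x <- matrix(runif(64), 8, 8)
  y <- matrix(runif(64), 8, 8)
  expect_equal(ncc(x, x), 1, tolerance = 1e-12)
  expect_equal(ncc(x, -x), -1, tolerance = 1e-12)
  expect_equal(ncc(x, 2.3 * x + 4), 1, tolerance = 1e-12)
  expect_equal(ncc(x, y), stats::cor(as.vector(x), as.vector(y)),
               tolerance = 1e-12)
  flat <- ncc(x, matrix(1, 8, 8))
  expect_equal(as.numeric(flat), 0)
  expect_true(isTRUE(attr(flat, "flat_image")))
  m <- matrix(FALSE, 8, 8); m[1:4, ] <- TRUE
  expect_equal(ncc(x, y, mask = m),
               stats::cor(as.vector(x[1:4, ]), as.vector(y[1:4, ])),
               tolerance = 1e-12)
})

test_that("preprocess: empty chain, default chain, unknown step", {
  img <- matrix(runif(64), 8, 8)
  expect_identical(preprocess(img, character(0)), img)
  expect_true(all(preprocess(matrix(5, 8, 8)) == 0))
  expect_error(preprocess(img, "blur"), "unknown")
  # default chain output is a non-negative edge map
  out <- preprocess(img)
  expect_true(all(out >= 0))
})

test_that("radiograph TIFF stacks round-trip within quantisation", {
  set.seed(14)
  imgs <- lapply(1:3, function(i) matrix(runif(256, 0, 300), 16, 16))
  path <- withr::local_tempfile(fileext = ".tif")
  scale <- write_radiograph_tiff(imgs, path)
  back <- read_radiograph_tiff(path, scale = scale)
  expect_length(back, 3L)
  for (i in 1:3)
    expect_equal(back[[i]], imgs[[i]], tolerance = 2 * scale / 65535,
                 ignore_attr = TRUE)
})
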