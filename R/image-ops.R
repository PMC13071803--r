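#' Image resolution treatments and similarity operators
#'
#' Images are plain numeric matrices: row 1 = detector top, column 1 =
#' detector left, pixel centres at integer coordinates (0-based in the
#' geometry convention). All processing is in floating point.
#'
#' @name image_ops
NULL

# Keys cubic convolution kernel, a = -0.5
cubic_kernel <- function(x, a = -0.5) {
  x <- abs(x)
  ifelse(x <= 1, (a + 2) * x^3 - (a + 3) * x^2 + 1,
         ifelse(x < 2, a * x^3 - 5 * a * x^2 + 8 * a * x - 4 * a, 0))
}

# One-axis resampling weight matrix (n_out x n_in).
# Output pixel centre i (0-based) maps to input coordinate
# (i + 0.5) * scale - 0.5. With antialiasing (shrinking) the kernel is
# widened by the scale factor; weights are renormalised to sum to 1 and
# out-of-range taps are clamped to the nearest valid pixel.
resample_weights <- function(n_in, n_out, antialias = TRUE) {
  scale <- n_in / n_out
  width <- if (antialias && scale > 1) scale else 1
  W <- matrix(0, n_out, n_in)
  for (i in seq_len(n_out)) {
    x <- (i - 0.5) * scale - 0.5        # input coordinate, 0-based
    ks <- floor(x - 2 * width + 1):ceiling(x + 2 * width - 1)
    w <- cubic_kernel((x - ks) / width)
    keep <- w != 0
    ks <- ks[keep]; w <- w[keep]
    w <- w / sum(w)
    ks <- pmin(pmax(ks, 0), n_in - 1)   # clamp edge taps
    for (j in seq_along(ks)) W[i, ks[j] + 1] <- W[i, ks[j] + 1] + w[j]
  }
  W
}

#' Downsample an image with bicubic interpolation
#'
#' Separable cubic-convolution resampling with the Keys kernel
#' (a = -0.5). When shrinking with `antialias = TRUE` (the default,
#' matching the behaviour of the common reference resize routines) the
#' kernel support is widened by the scale factor, so the weighted
#' neighbourhood covers the full footprint of each output pixel.
#' Output pixel `(i, j)` (0-based) is centred at input coordinate
#' `((i + 0.5) * scale - 0.5)` per axis; edge taps are clamped to the
#' nearest valid pixel. Cubic weights may overshoot: values are not
#' clipped unless `clip_zero = TRUE`.
#'
#' @param image numeric matrix.
#' @param out_size `c(rows, cols)` (or a scalar for square output); must
#'   not exceed the input size (upsampling is out of scope).
#' @param antialias widen the kernel on shrink (default `TRUE`).
#' @param clip_zero clip negative overshoot at 0.
#' @return numeric matrix of size `out_size`.
#' @export
downsample_bicubic <- function(image, out_size, antialias = TRUE,
                               clip_zero = FALSE) {
  out_size <- check_out_size(image, out_size)
  Wr <- resample_weights(nrow(image), out_size[1], antialias)
  Wc <- resample_weights(ncol(image), out_size[2], antialias)
  out <- Wr %*% image %*% t(Wc)
  if (clip_zero) out[out < 0] <- 0
  out
}

#' Downsample an image with nearest-neighbour interpolation
#'
#' Each output pixel takes the value of the single nearest input pixel
#' under the same centre mapping as [downsample_bicubic()], with no
#' anti-aliasing: no new pixel values are introduced.
#'
#' @inheritParams downsample_bicubic
#' @return numeric matrix of size `out_size`.
#' @export
downsample_nearest <- function(image, out_size) {
  out_size <- check_out_size(image, out_size)
  idx <- function(n_in, n_out) {
    x <- (seq_len(n_out) - 0.5) * (n_in / n_out) - 0.5
    pmin(pmax(floor(x + 0.5), 0), n_in - 1) + 1
  }
  image[idx(nrow(image), out_size[1]), idx(ncol(image), out_size[2]),
        drop = FALSE]
}

check_out_size <- function(image, out_size) {
  if (length(out_size) == 1L) out_size <- c(out_size, out_size)
  out_size <- as.integer(out_size)
  if (any(out_size < 2L)) stop("output size must be at least 2x2")
  if (out_size[1] > nrow(image) || out_size[2] > ncol(image))
    stop("upsampling is not supported")
  out_size
}

#' Sobel gradient magnitude
#'
#' Gradient magnitude `sqrt(gx^2 + gy^2)` with the standard 3x3 Sobel
#' kernels and reflective boundary handling.
#'
#' @param image numeric matrix, at least 3x3.
#' @return numeric matrix of the same size.
#' @export
sobel_edges <- function(image) {
  stopifnot(nrow(image) >= 3L, ncol(image) >= 3L)
  p <- image[c(1, seq_len(nrow(image)), nrow(image)),
             c(1, seq_len(ncol(image)), ncol(image))]  # reflect pad by 1
  nr <- nrow(image); nc <- ncol(image)
  sh <- function(dr, dc) p[seq_len(nr) + 1 + dr, seq_len(nc) + 1 + dc]
  # gx: horizontal derivative (along columns), gy: vertical (along rows)
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  sqrt(gx^2 + gy^2)
}

#' Normalised cross-correlation of two images
#'
#' Pearson correlation of the flattened pixel values, optionally
#' restricted to a mask (e.g. the DRR's region of interest). If either
#' image has zero variance over the evaluated pixels the correlation is
#' undefined; 0 is returned with attribute `flat_image = TRUE`.
#'
#' @param a,b numeric matrices of equal size with at least 2 pixels.
#' @param mask optional logical matrix (same size) selecting the pixels
#'   to correlate.
#' @return a number in `[-1, 1]`.
#' @export
ncc <- function(a, b, mask = NULL) {
  stopifnot(all(dim(a) == dim(b)), length(a) >= 2L)
  if (!is.null(mask)) {
    a <- a[mask]; b <- b[mask]
    if (length(a) < 2L) return(structure(0, flat_image = TRUE))
  }
  a <- a - mean(a); b <- b - mean(b)
  va <- sum(a * a); vb <- sum(b * b)
  if (va <= 0 || vb <= 0) return(structure(0, flat_image = TRUE))
  min(1, max(-1, sum(a * b) / sqrt(va * vb)))
}

#' Image preprocessing chain
#'
#' Applies a configurable sequence of steps; the same chain must be
#' applied to target radiographs and DRRs so the similarity metric
#' compares like with like. Supported steps:
#' \describe{
#'   \item{`invert`}{`max(image) - image` (radiograph polarity flip).}
#'   \item{`neglog`}{`-log(image / max(image))` (with a small floor):
#'     converts detector counts back to the line-integral domain, so
#'     count radiographs become directly comparable with DRRs. Note
#'     this is where photon starvation bites: low-count pixels behind
#'     dense bone have their noise amplified by the log.}
#'   \item{`stretch`}{linear contrast stretch of the 1st-99th
#'     percentile range onto `[0, 1]`, clipped.}
#'   \item{`sobel`}{Sobel gradient magnitude.}
#' }
#' The default chain is `c("stretch", "sobel")`: contrast
#' normalisation followed by edge extraction, emulating the
#' edge-enhancing filters applied before pose matching. (Inversion is
#' unnecessary by default because the gradient magnitude is
#' polarity-insensitive.)
#'
#' @param image numeric matrix.
#' @param chain character vector of step names, applied in order; an
#'   empty chain is the identity.
#' @return numeric matrix.
#' @export
preprocess <- function(image, chain = c("stretch", "sobel")) {
  for (step in chain) {
    image <- switch(step,
      invert = max(image) - image,
      neglog = {
        top <- max(image)
        if (top <= 0) image * 0 else -log(pmax(image, top * 1e-6) / top)
      },
      stretch = {
        q <- stats::quantile(image, c(0.01, 0.99), names = FALSE)
        if (q[2] > q[1]) {
          pmin(pmax((image - q[1]) / (q[2] - q[1]), 0), 1)
        } else {
          image * 0
        }
      },
      sobel = sobel_edges(image),
      stop("unknown preprocessing step: ", step))
  }
  image
}

#' Read and write radiograph images as TIFF
#'
#' Multi-frame stacks are written one page per frame. Pixel values are
#' scaled to `[0, 1]` by `scale` on write (16-bit by default) and
#' rescaled on read, so detector counts round-trip to within the
#' 16-bit quantisation.
#'
#' @param images a matrix or list of matrices (one per frame).
#' @param path file path.
#' @param scale value mapped to the top of the integer range; defaults
#'   to the stack maximum.
#' @param bits bits per sample (8 or 16).
#' @return `read_radiograph_tiff` returns a list of matrices with
#'   attribute `scale`.
#' @export
write_radiograph_tiff <- function(images, path, scale = NULL, bits = 16L) {
  if (is.matrix(images)) images <- list(images)
  if (is.null(scale)) scale <- max(1e-12, max(unlist(lapply(images, max))))
  tiff::writeTIFF(lapply(images, function(im) pmin(pmax(im / scale, 0), 1)),
                  path, bits.per.sample = bits)
  invisible(scale)
}

#' @rdname write_radiograph_tiff
#' @export
read_radiograph_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  out <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1L]
    p * scale
  })
  attr(out, "scale") <- scale
  out
}
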