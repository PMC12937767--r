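# Image preprocessing: Gaussian smoothing and spatial normalization to the
# 224 x 224 working resolution shared by all three feature extractors.

#' Build a normalized 2-D Gaussian kernel
#'
#' Discrete isotropic Gaussian weights on an odd square grid,
#' \eqn{w(x, y) \propto \exp(-(x^2 + y^2) / (2\sigma^2))} with integer offsets
#' \eqn{(x, y)} from the centre, renormalized to sum to one.
#'
#' @param size Odd positive integer kernel side length. Default 5.
#' @param sigma Positive standard deviation in pixels. Default 1.
#' @return A `size` x `size` numeric matrix whose entries sum to 1.
#' @examples
#' k <- make_gaussian_kernel(5, 1)
#' sum(k)  # 1
#' @export
make_gaussian_kernel <- function(size = 5L, sigma = 1.0) {
  if (length(size) != 1L || !is.numeric(size) || size < 1 || size %% 2 != 1) {
    abort("`size` must be a positive odd integer")
  }
  if (length(sigma) != 1L || !is.numeric(sigma) || sigma <= 0) {
    abort("`sigma` must be a positive number")
  }
  r <- (size - 1) / 2
  off <- seq(-r, r)
  w <- exp(-outer(off^2, off^2, `+`) / (2 * sigma^2))
  w / sum(w)
}

# Reflect (edge-inclusive symmetric) index padding: 1..n padded by k on each
# side becomes k, ..., 1, 1..n, n, ..., n-k+1.
reflect_idx <- function(n, k) {
  if (k == 0) return(seq_len(n))
  if (k > n) abort("pad width exceeds image extent")
  c(rev(seq_len(k)), seq_len(n), seq(n, n - k + 1))
}

# 2-D convolution of a single plane with reflect border padding.
convolve2d_reflect <- function(plane, kernel) {
  k <- (nrow(kernel) - 1) / 2
  n <- nrow(plane); m <- ncol(plane)
  padded <- plane[reflect_idx(n, k), reflect_idx(m, k), drop = FALSE]
  out <- matrix(0, n, m)
  for (di in seq_len(nrow(kernel))) {
    for (dj in seq_len(ncol(kernel))) {
      w <- kernel[di, dj]
      if (w == 0) next
      out <- out + w * padded[(di - 1) + seq_len(n), (dj - 1) + seq_len(m)]
    }
  }
  out
}

#' Gaussian-smooth an RGB image
#'
#' Per-channel 2-D convolution with reflect border padding. Because the
#' kernel weights are nonnegative and sum to one, the output is a convex
#' combination of input intensities and stays inside the input range.
#'
#' @param image H x W x 3 numeric array, intensities in \[0, 255\].
#' @param kernel Normalized kernel matrix from [make_gaussian_kernel()].
#' @return Smoothed array of the same dimensions (floating point; no 8-bit
#'   quantization is applied).
#' @export
smooth_image <- function(image, kernel = make_gaussian_kernel()) {
  check_image(image)
  if (!is.matrix(kernel) || nrow(kernel) != ncol(kernel) ||
      abs(sum(kernel) - 1) > 1e-8) {
    abort("`kernel` must be a square matrix with weights summing to 1")
  }
  out <- image
  for (ch in 1:3) {
    out[, , ch] <- convolve2d_reflect(image[, , ch], kernel)
  }
  # convex combination of in-range values; clamp summation dust only
  clamp(out, 0, 255)
}

# Row/column interpolation weight matrix mapping `n_in` samples onto `n_out`
# with the half-pixel-centre convention: src = (dst + 0.5) * n_in/n_out - 0.5.
bilinear_weights <- function(n_in, n_out) {
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  src <- clamp(src, 0, n_in - 1)
  lo <- floor(src)
  frac <- src - lo
  hi <- pmin(lo + 1, n_in - 1)
  w <- matrix(0, n_out, n_in)
  idx <- seq_len(n_out)
  w[cbind(idx, lo + 1)] <- w[cbind(idx, lo + 1)] + (1 - frac)
  w[cbind(idx, hi + 1)] <- w[cbind(idx, hi + 1)] + frac
  w
}

#' Resize an image to the standard 224 x 224 resolution
#'
#' Separable bilinear interpolation using half-pixel sample centres
#' (`align_corners = FALSE` convention), so resizing at native resolution is
#' an exact identity and constant images are preserved exactly.
#'
#' @param image H x W x 3 numeric array with H, W >= 2.
#' @param size Output side length. Default 224.
#' @return `size` x `size` x 3 numeric array.
#' @export
resize_to_standard <- function(image, size = 224L) {
  check_image(image)
  d <- dim(image)
  if (d[1] < 2 || d[2] < 2) {
    abort("`image` must be at least 2 x 2 to interpolate")
  }
  wr <- bilinear_weights(d[1], size)
  wc <- t(bilinear_weights(d[2], size))
  out <- array(0, c(size, size, 3L))
  for (ch in 1:3) {
    out[, , ch] <- wr %*% image[, , ch] %*% wc
  }
  # interpolation of in-range values cannot overshoot, but guard fp dust
  clamp(out, 0, 255)
}

#' Preprocess a raw image for feature extraction
#'
#' Gaussian smoothing (5 x 5 kernel, sigma 1 by default) followed by bilinear
#' resizing to 224 x 224. Single-channel input is replicated to three
#' channels with a warning.
#'
#' @param image H x W x 3 (or H x W) numeric array, intensities in \[0, 255\].
#' @param kernel_size,sigma Gaussian kernel parameters.
#' @return 224 x 224 x 3 numeric array.
#' @export
preprocess_image <- function(image, kernel_size = 5L, sigma = 1.0) {
  if (is.matrix(image) ||
      (is.array(image) && length(dim(image)) == 3L && dim(image)[3] == 1L)) {
    warn("single-channel image replicated to 3 channels")
    m <- if (is.matrix(image)) image else image[, , 1]
    image <- array(rep(m, 3L), c(dim(m), 3L))
  }
  check_image(image)
  smoothed <- smooth_image(image, make_gaussian_kernel(kernel_size, sigma))
  resize_to_standard(smoothed)
}

#' Read a PNG or JPEG image as an intensity array
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return H x W x 3 numeric array with intensities in \[0, 255\]. Grayscale
#'   files are replicated to three channels; alpha channels are dropped.
#' @export
read_lesion_image <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("cannot read image: no such file '%s'", path))
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    jpg = ,
    jpeg = jpeg::readJPEG(path),
    abort(sprintf("unsupported image format '.%s' for '%s'", ext, path))
  )
  if (is.matrix(raw)) {
    warn(sprintf("grayscale file '%s' replicated to 3 channels", basename(path)))
    raw <- array(rep(raw, 3L), c(dim(raw), 3L))
  }
  if (dim(raw)[3] > 3L) raw <- raw[, , 1:3, drop = FALSE]
  raw * 255
}

#' Write an image array to a PNG file
#'
#' Intensities are quantized to 8 bits only at export; all in-memory
#' processing stays in floating point.
#'
#' @param image H x W x 3 numeric array in \[0, 255\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lesion_image <- function(image, path) {
  check_image(image)
  png::writePNG(round(image) / 255, path)
  invisible(path)
}
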