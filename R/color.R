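# Colour module: 96-d HSV histogram descriptor.
#
# Channel ranges are fixed at H in [0, 360), S in [0, 1], V in [0, 1] with 32
# equal-width bins per channel; the last bin is closed on the right so the
# bins partition every pixel exactly once. Pixels with S = 0 (achromatic)
# contribute H = 0 so hue is always defined.

#' Convert a standardized image to HSV planes
#'
#' Standard hexcone RGB-to-HSV conversion. Hue is returned in degrees
#' \[0, 360), saturation and value in \[0, 1\]. Achromatic pixels (S = 0)
#' are assigned hue 0.
#'
#' @param image 224 x 224 x 3 numeric array in \[0, 255\].
#' @return List with matrices `h`, `s`, `v`.
#' @export
rgb_to_hsv_planes <- function(image) {
  check_standard_image(image)
  d <- dim(image)
  rgb <- rbind(
    as.vector(image[, , 1]),
    as.vector(image[, , 2]),
    as.vector(image[, , 3])
  )
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  h <- hsv[1, ] * 360
  h[h >= 360] <- 0
  h[hsv[2, ] == 0] <- 0
  list(
    h = matrix(h, d[1], d[2]),
    s = matrix(hsv[2, ], d[1], d[2]),
    v = matrix(hsv[3, ], d[1], d[2])
  )
}

#' Histogram of one channel plane
#'
#' Equal-width bins over \[`range_lo`, `range_hi`\]; bins are half-open
#' \[b_k, b_k+1) with the final bin closed so counts always sum to the pixel
#' count.
#'
#' @param plane Numeric matrix or vector of channel values.
#' @param range_lo,range_hi Channel range; `range_hi` must exceed `range_lo`.
#' @param bins Number of bins. Default 32.
#' @return Integer vector of `bins` counts.
#' @export
channel_histogram <- function(plane, range_lo, range_hi, bins = 32L) {
  if (range_hi <= range_lo) abort("`range_hi` must exceed `range_lo`")
  v <- as.vector(plane)
  if (any(v < range_lo | v > range_hi)) {
    abort("plane values fall outside [range_lo, range_hi]")
  }
  idx <- floor((v - range_lo) / (range_hi - range_lo) * bins) + 1
  idx <- pmin(idx, bins)  # close the last bin on the right
  tabulate(idx, nbins = bins)
}

#' L2-normalize a nonnegative vector
#'
#' `x / (||x||_2 + eps)`; the epsilon keeps the all-zero vector at zero
#' instead of dividing by zero, and makes the descriptor invariant to overall
#' image brightness scaling of the counts.
#'
#' @param x Numeric vector with nonnegative entries.
#' @param eps Stabilizer added to the norm. Default 1e-8.
#' @return Numeric vector of the same length with norm at most 1.
#' @export
l2_normalize <- function(x, eps = 1e-8) {
  x / (sqrt(sum(x^2)) + eps)
}

#' Extract the 96-d HSV colour histogram descriptor
#'
#' 32-bin histograms of the hue, saturation and value planes, each
#' L2-normalized, concatenated in H, S, V order.
#'
#' @param image 224 x 224 x 3 numeric array in \[0, 255\].
#' @return Named numeric vector of length 96
#'   (`colorH_00` ... `colorV_31`).
#' @export
extract_color <- function(image) {
  p <- rgb_to_hsv_planes(image)
  out <- c(
    l2_normalize(channel_histogram(p$h, 0, 360)),
    l2_normalize(channel_histogram(p$s, 0, 1)),
    l2_normalize(channel_histogram(p$v, 0, 1))
  )
  names(out) <- color_feature_names()
  out
}

color_feature_names <- function() {
  sprintf("color%s_%02d", rep(c("H", "S", "V"), each = 32L), rep(0:31, 3L))
}
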