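# Shape module: intensity-weighted image moments and the seven Hu moment
# invariants, log-stabilized to a compact dynamic range.
#
# Moments are computed on the grayscale intensity image itself (no
# binarization or segmentation step). Coordinates are 0-based with x = column
# index and y = row index.

#' Raw, central and normalized image moments through order 3
#'
#' Computes raw moments \eqn{m_{pq}}, the intensity centroid, central moments
#' \eqn{\mu_{pq} = \sum_x \sum_y (x - \bar x)^p (y - \bar y)^q I(x, y)} and
#' scale-normalized moments
#' \eqn{\eta_{pq} = \mu_{pq} / \mu_{00}^{(p+q)/2 + 1}} for \eqn{2 \le p+q \le 3}.
#'
#' @param gray Numeric or integer matrix of nonnegative intensities with at
#'   least one positive entry.
#' @return List with `m` (raw moments), `centroid` (`c(x, y)`), `mu`
#'   (central) and `eta` (normalized); `mu` and `eta` are named numeric
#'   vectors indexed like `"20"` for \eqn{p = 2, q = 0}.
#' @export
central_moments <- function(gray) {
  if (!is.matrix(gray) || !is.numeric(gray)) {
    abort("`gray` must be a numeric matrix")
  }
  if (min(gray) < 0) abort("`gray` must be nonnegative")
  total <- sum(gray)
  if (total <= 0) abort("undefined centroid: image is identically zero")
  n <- nrow(gray); m <- ncol(gray)
  X <- matrix(0:(m - 1), n, m, byrow = TRUE)  # x = column
  Y <- matrix(0:(n - 1), n, m)                # y = row

  orders <- list(c(0, 0), c(1, 0), c(0, 1), c(2, 0), c(1, 1), c(0, 2),
                 c(3, 0), c(2, 1), c(1, 2), c(0, 3))
  key <- vapply(orders, function(o) paste0(o[1], o[2]), "")

  m_raw <- vapply(orders, function(o) sum(X^o[1] * Y^o[2] * gray), 0)
  names(m_raw) <- key
  xb <- m_raw[["10"]] / total
  yb <- m_raw[["01"]] / total

  Xc <- X - xb; Yc <- Y - yb
  mu <- vapply(orders, function(o) sum(Xc^o[1] * Yc^o[2] * gray), 0)
  names(mu) <- key

  high <- key[vapply(orders, function(o) sum(o) >= 2, TRUE)]
  eta <- vapply(high, function(k) {
    p <- as.integer(substr(k, 1, 1)); q <- as.integer(substr(k, 2, 2))
    mu[[k]] / total^((p + q) / 2 + 1)
  }, 0)
  names(eta) <- high

  list(m = m_raw, centroid = c(x = xb, y = yb), mu = mu, eta = eta)
}

#' The seven Hu moment invariants
#'
#' Classic polynomial combinations of the normalized central moments,
#' invariant to translation, rotation and scale; the seventh is
#' skew-orthogonal and flips sign under reflection.
#'
#' @param moments Moment set from [central_moments()].
#' @return Numeric vector `h1` ... `h7`.
#' @export
hu_invariants <- function(moments) {
  e <- moments$eta
  n20 <- e[["20"]]; n02 <- e[["02"]]; n11 <- e[["11"]]
  n30 <- e[["30"]]; n03 <- e[["03"]]; n21 <- e[["21"]]; n12 <- e[["12"]]
  a <- n30 + n12   # x-odd combinations
  b <- n21 + n03
  c(
    h1 = n20 + n02,
    h2 = (n20 - n02)^2 + 4 * n11^2,
    h3 = (n30 - 3 * n12)^2 + (3 * n21 - n03)^2,
    h4 = a^2 + b^2,
    h5 = (n30 - 3 * n12) * a * (a^2 - 3 * b^2) +
         (3 * n21 - n03) * b * (3 * a^2 - b^2),
    h6 = (n20 - n02) * (a^2 - b^2) + 4 * n11 * a * b,
    h7 = (3 * n21 - n03) * a * (a^2 - 3 * b^2) -
         (n30 - 3 * n12) * b * (3 * a^2 - b^2)
  )
}

#' Log-stabilize Hu invariants
#'
#' \eqn{\tilde h_i = -\mathrm{sign}(h_i) \log_{10}(|h_i| + \epsilon)} with
#' `sign(0) = 0`, compressing the invariants' wide dynamic range while
#' preserving their sign.
#'
#' @param h Numeric vector of Hu invariants.
#' @param eps Stabilizer preventing `log(0)`. Default 1e-10.
#' @return Numeric vector of the same length.
#' @export
log_stabilize <- function(h, eps = 1e-10) {
  -sign(h) * log10(abs(h) + eps)
}

#' Extract the 7-d log-stabilized Hu shape descriptor
#'
#' @param image H x W x 3 numeric array in \[0, 255\].
#' @return Named numeric vector of length 7 (`hu_1` ... `hu_7`).
#' @export
extract_shape <- function(image) {
  gray <- to_gray(image)
  h <- log_stabilize(hu_invariants(central_moments(gray)))
  names(h) <- shape_feature_names()
  h
}

shape_feature_names <- function() paste0("hu_", 1:7)
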