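# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform .data
NULL

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Canonical diagnostic label ordering
#'
#' The six diagnostic categories handled by the classifier, in the fixed
#' order used for every label vector, probability matrix and confusion
#' matrix in the package.
#'
#' @return Character vector of length 6.
#' @export
lesion_classes <- function() {
  c("ACK", "BCC", "MEL", "NEV", "SCC", "SEK")
}

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# per-record RNG streams and feature-schema fingerprints without an external
# dependency; stability across platforms matters more than dispersion quality.
str_hash31 <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  m <- 2147483647  # 2^31 - 1
  for (b in utf8ToInt(x)) {
    h <- (h * 31 + b) %% m
  }
  as.integer(h)
}

# Derive a child seed below 2^31 from a base seed and arbitrary string parts.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "\x1f")
  str_hash31(parts)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Validate an H x W x 3 numeric image array with values in [0, 255].
check_image <- function(img, arg = "image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L) {
    abort(sprintf("`%s` must be an H x W x 3 numeric array", arg))
  }
  if (!is.numeric(img) || anyNA(img) || any(!is.finite(img))) {
    abort(sprintf("`%s` must contain finite numeric intensities", arg))
  }
  if (min(img) < 0 || max(img) > 255) {
    abort(sprintf("`%s` intensities must lie in [0, 255]", arg))
  }
  invisible(img)
}

# Validate a 224 x 224 x 3 standardized image.
check_standard_image <- function(img, arg = "image") {
  check_image(img, arg)
  d <- dim(img)
  if (d[1] != 224L || d[2] != 224L) {
    abort(sprintf("`%s` must be 224 x 224 x 3 (got %d x %d)", arg, d[1], d[2]))
  }
  invisible(img)
}
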