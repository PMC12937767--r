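# Synthetic lesion generator.
#
# Produces abstract stand-in images (skin-toned background, one elliptical
# blob with radial-harmonic border perturbation, class-conditional hue fill,
# correlated surface noise) plus a schema-compliant metadata table with
# patient grouping. The classes are not clinically realistic; their purpose
# is to plant recoverable class-conditional colour/texture/shape/metadata
# signal whose strength is controlled by a single `separability` dial.

#' Class recipes for the synthetic generator
#'
#' Six per-class parameter sets whose colour, texture, shape and metadata
#' distributions overlap more as `separability` decreases. At separability 1
#' the hue ranges are pairwise disjoint; near 0 they overlap heavily.
#'
#' @param separability Signal strength of the visual channels in (0, 1].
#' @param meta_separability Signal strength of the metadata priors; defaults
#'   to `separability`. Setting the two apart creates scenarios such as
#'   ambiguous images with informative clinical context.
#' @return Tibble with one row per class (`lesion_classes()` order), class
#'   `lesion_recipes`.
#' @export
default_recipes <- function(separability = 1.0,
                            meta_separability = separability) {
  for (s_chk in c(separability, meta_separability)) {
    if (length(s_chk) != 1 || s_chk <= 0 || s_chk > 1) {
      abort("`separability` must lie in (0, 1]")
    }
  }
  k <- seq_along(lesion_classes()) - 1  # 0..5
  hue_center <- 15 + k * 58              # 58 degrees apart, within [0, 360)
  hue_half <- 12 + (1 - separability) * 120
  rough <- 2 + k * 5 * separability + (1 - separability) * 8
  ecc_lo <- clamp(0.05 + k * 0.15 * separability, 0, 0.85)
  out <- tibble::tibble(
    class = lesion_classes(),
    hue_lo = hue_center - hue_half,
    hue_hi = hue_center + hue_half,
    sat_lo = 0.45, sat_hi = 0.75,
    val_lo = 0.45, val_hi = 0.75,
    noise_amp = rough,
    noise_corr = 2,
    ecc_lo = ecc_lo,
    ecc_hi = pmin(ecc_lo + 0.1, 0.9),
    border_amp = 0.02 + k * 0.035 * separability,
    age_mean = 30 + k * 9 * meta_separability,
    age_sd = 6 + (1 - meta_separability) * 14,
    diam_mean = 6 + k * 2.5 * meta_separability,
    diam_sd = 1.5 + (1 - meta_separability) * 4,
    symptom_p = clamp(0.1 + k * 0.16 * meta_separability, 0, 0.95)
  )
  attr(out, "separability") <- separability
  class(out) <- c("lesion_recipes", class(out))
  out
}

hsv_to_rgb255 <- function(h, s, v) {
  h <- (h %% 360) / 360
  grDevices::col2rgb(grDevices::hsv(h, s, v))[, 1]
}

# Correlated noise field: white noise smoothed by a Gaussian kernel whose
# sigma is the correlation length, rescaled to unit sd.
correlated_noise <- function(n, m, corr_len) {
  z <- matrix(stats::rnorm(n * m), n, m)
  if (corr_len > 0) {
    k <- make_gaussian_kernel(2 * ceiling(2 * corr_len) + 1, corr_len)
    z <- convolve2d_reflect(z, k)
    z <- z / stats::sd(as.vector(z))
  }
  z
}

#' Generate one synthetic lesion image
#'
#' Draws a skin-toned background, paints one elliptical blob whose border
#' radius is perturbed by low-order radial harmonics, fills it with a hue
#' sampled from the class recipe, and adds correlated noise inside the blob
#' to set its surface roughness. Deterministic given the RNG state.
#'
#' @param recipe One row of [default_recipes()].
#' @param size Image side length. Default 224.
#' @return `size` x `size` x 3 numeric array in \[0, 255\].
#' @export
gen_image <- function(recipe, size = 224L) {
  n <- size
  skin <- c(222, 178, 152)
  img <- array(rep(skin, each = n * n), c(n, n, 3L))
  bg_noise <- 3 * correlated_noise(n, n, 1.5)
  for (ch in 1:3) img[, , ch] <- clamp(img[, , ch] + bg_noise, 0, 255)

  cy <- n / 2 + stats::runif(1, -n * 0.08, n * 0.08)
  cx <- n / 2 + stats::runif(1, -n * 0.08, n * 0.08)
  r0 <- n * stats::runif(1, 0.2, 0.28)
  ecc <- stats::runif(1, recipe$ecc_lo, recipe$ecc_hi)
  b_over_a <- sqrt(1 - ecc^2)
  phi0 <- stats::runif(1, 0, 2 * pi)

  Y <- matrix(0:(n - 1), n, n) - cy
  X <- matrix(0:(n - 1), n, n, byrow = TRUE) - cx
  # rotate into ellipse axes
  U <- cos(phi0) * X + sin(phi0) * Y
  V <- -sin(phi0) * X + cos(phi0) * Y
  rho <- sqrt((U / 1)^2 + (V / b_over_a)^2)
  ang <- atan2(V, U)
  harmonics <- rep(0, length(ang))
  for (kk in 2:4) {
    a_k <- recipe$border_amp * stats::runif(1, 0.5, 1)
    psi <- stats::runif(1, 0, 2 * pi)
    harmonics <- harmonics + a_k * sin(kk * ang + psi)
  }
  r_border <- r0 * (1 + harmonics)
  inside <- rho <= r_border

  hue <- stats::runif(1, recipe$hue_lo, recipe$hue_hi)
  sat <- stats::runif(1, recipe$sat_lo, recipe$sat_hi)
  val <- stats::runif(1, recipe$val_lo, recipe$val_hi)
  fill <- hsv_to_rgb255(hue, sat, val)

  noise <- recipe$noise_amp * correlated_noise(n, n, recipe$noise_corr)
  for (ch in 1:3) {
    plane <- img[, , ch]
    plane[inside] <- clamp(fill[ch] + noise[inside], 0, 255)
    img[, , ch] <- plane
  }
  img
}

sample_metadata <- function(recipe, n, missing_rate = 0) {
  age <- round(clamp(stats::rnorm(n, recipe$age_mean, recipe$age_sd), 1, 95))
  d1 <- round(clamp(stats::rnorm(n, recipe$diam_mean, recipe$diam_sd), 0.5, 60), 1)
  d2 <- round(clamp(d1 * stats::runif(n, 0.6, 1), 0.5, 60), 1)
  out <- tibble::tibble(
    age = age,
    gender = sample(c("Male", "Female"), n, replace = TRUE),
    diameter_1 = d1,
    diameter_2 = d2
  )
  for (f in meta_binary) {
    out[[f]] <- stats::runif(n) < recipe$symptom_p
  }
  if (missing_rate > 0) {
    for (f in c("age", "diameter_1", "diameter_2", meta_binary)) {
      out[[f]][stats::runif(n) < missing_rate] <- NA
    }
  }
  out
}

#' Generate a synthetic multimodal lesion dataset
#'
#' `6 * n_per_class` images with a manifest in the canonical metadata schema.
#' Images are grouped into synthetic patients owning 1-3 lesions of the same
#' class, so patient-level splitting is exercised. Regeneration from the
#' same `(seed, separability)` is bit-identical.
#'
#' @param n_per_class Images per class.
#' @param separability Class-signal strength in (0, 1]. Default 1.
#' @param meta_separability Metadata signal strength; defaults to
#'   `separability`.
#' @param seed Integer seed.
#' @param missing_rate Probability that a metadata cell is missing.
#'   Default 0.
#' @param out_dir Optional directory; when given, images are written as PNG
#'   under `out_dir/images/` and the manifest as `out_dir/metadata.csv`.
#' @param size Image side length. Default 224.
#' @return List of class `lesion_dataset` with `images` (named list of
#'   arrays), `manifest` (tibble: `image_id`, `patient_id`, `label` + the 12
#'   metadata fields), `recipes`, `seed`.
#' @export
gen_dataset <- function(n_per_class, separability = 1.0, seed = 1L,
                        meta_separability = separability,
                        missing_rate = 0, out_dir = NULL, size = 224L) {
  if (n_per_class < 1) abort("`n_per_class` must be at least 1")
  recipes <- default_recipes(separability, meta_separability)

  manifest <- list(); images <- list()
  for (ci in seq_len(nrow(recipes))) {
    recipe <- recipes[ci, ]
    cls <- recipe$class
    meta <- with_seed(derive_seed(seed, "meta", cls),
                      sample_metadata(recipe, n_per_class, missing_rate))
    # patients own 1-3 consecutive lesions of this class
    sizes <- with_seed(derive_seed(seed, "patients", cls),
                       sample(1:3, n_per_class, replace = TRUE))
    pat <- rep(seq_along(sizes), times = sizes)[seq_len(n_per_class)]
    ids <- sprintf("%s_%04d", cls, seq_len(n_per_class))
    imgs <- purrr::map(seq_len(n_per_class), function(i) {
      with_seed(derive_seed(seed, "image", cls, i), gen_image(recipe, size))
    })
    names(imgs) <- ids
    images <- c(images, imgs)
    manifest[[cls]] <- dplyr::bind_cols(
      tibble::tibble(
        image_id = ids,
        patient_id = sprintf("P_%s_%03d", cls, pat),
        label = cls
      ),
      meta
    )
  }
  manifest <- dplyr::bind_rows(manifest)

  if (!is.null(out_dir)) {
    img_dir <- file.path(out_dir, "images")
    ok <- dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(img_dir)) {
      abort(sprintf("cannot create output directory '%s'", img_dir))
    }
    for (id in names(images)) {
      write_lesion_image(images[[id]], file.path(img_dir, paste0(id, ".png")))
    }
    utils::write.csv(manifest, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
  }

  structure(
    list(images = images, manifest = manifest, recipes = recipes,
         seed = seed),
    class = "lesion_dataset"
  )
}

#' @export
print.lesion_dataset <- function(x, ...) {
  cat("<lesion_dataset>", length(x$images), "images,",
      length(unique(x$manifest$patient_id)), "patients, separability",
      attr(x$recipes, "separability"), "\n")
  print(table(x$manifest$label))
  invisible(x)
}
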