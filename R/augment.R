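# Leakage-safe dataset partitioning and offline class-balancing augmentation.
#
# The split is performed on original images only, at patient granularity, so
# no patient contributes to both sides. Augmentation is applied afterwards,
# to the training side only; the test side never contains derived images.

#' Augmentation policy
#'
#' Transform parameters for offline augmentation, applied per image in the
#' fixed order horizontal flip, vertical flip, rotation, brightness, affine.
#'
#' @param hflip_p,vflip_p Flip probabilities. Default 0.5.
#' @param rotate_deg Two-element rotation range in degrees.
#'   Default c(-30, 30), always applied.
#' @param brightness Two-element multiplicative brightness factor range.
#'   Default c(0.8, 1.2), always applied; output clamped to \[0, 255\].
#' @param affine_p Probability of the affine step. Default 0.5.
#' @param translate_frac Maximum |translation| as a fraction of width/height.
#'   Default 0.1.
#' @param scale Two-element isotropic scale range. Default c(0.9, 1.1).
#' @return Object of class `augmentation_policy`.
#' @export
augmentation_policy <- function(hflip_p = 0.5, vflip_p = 0.5,
                                rotate_deg = c(-30, 30),
                                brightness = c(0.8, 1.2),
                                affine_p = 0.5, translate_frac = 0.1,
                                scale = c(0.9, 1.1)) {
  probs <- c(hflip_p, vflip_p, affine_p)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  for (rng in list(rotate_deg, brightness, scale)) {
    if (length(rng) != 2 || rng[1] > rng[2]) abort("ranges must be ordered pairs")
  }
  structure(
    list(hflip_p = hflip_p, vflip_p = vflip_p, rotate_deg = rotate_deg,
         brightness = brightness, affine_p = affine_p,
         translate_frac = translate_frac, scale = scale),
    class = "augmentation_policy"
  )
}

# Inverse-mapped affine resampling with bilinear interpolation and reflect
# fill. `A` maps output-centred coordinates to input-centred coordinates
# (row, col); `shift` is an additional input-space offset in pixels.
affine_sample <- function(image, A, shift = c(0, 0)) {
  d <- dim(image)
  n <- d[1]; m <- d[2]
  cy <- (n - 1) / 2; cx <- (m - 1) / 2
  out_r <- matrix(0:(n - 1), n, m) - cy
  out_c <- matrix(0:(m - 1), n, m, byrow = TRUE) - cx
  src_r <- A[1, 1] * out_r + A[1, 2] * out_c + cy + shift[1]
  src_c <- A[2, 1] * out_r + A[2, 2] * out_c + cx + shift[2]

  # reflect out-of-range source coordinates back into [0, n-1]
  reflect <- function(x, hi) {
    period <- 2 * hi
    x <- x %% period
    ifelse(x > hi, period - x, x)
  }
  src_r <- reflect(src_r, n - 1)
  src_c <- reflect(src_c, m - 1)

  r0 <- floor(src_r); c0 <- floor(src_c)
  fr <- src_r - r0;   fc <- src_c - c0
  r1 <- pmin(r0 + 1, n - 1); c1 <- pmin(c0 + 1, m - 1)

  out <- array(0, d)
  for (ch in seq_len(d[3])) {
    plane <- image[, , ch]
    v00 <- plane[cbind(as.vector(r0) + 1, as.vector(c0) + 1)]
    v01 <- plane[cbind(as.vector(r0) + 1, as.vector(c1) + 1)]
    v10 <- plane[cbind(as.vector(r1) + 1, as.vector(c0) + 1)]
    v11 <- plane[cbind(as.vector(r1) + 1, as.vector(c1) + 1)]
    vals <- (1 - fr) * ((1 - fc) * v00 + fc * v01) +
            fr * ((1 - fc) * v10 + fc * v11)
    out[, , ch] <- matrix(vals, n, m)
  }
  out
}

#' Apply one stochastic augmentation transform
#'
#' Draws and applies, in fixed order: horizontal flip, vertical flip,
#' rotation (uniform in the policy range), multiplicative brightness
#' (clamped to \[0, 255\]) and an optional affine translate+scale. Geometry
#' uses bilinear resampling with reflect fill so output stays 224 x 224.
#'
#' @param image 224 x 224 x 3 numeric array.
#' @param policy An [augmentation_policy()].
#' @return Transformed 224 x 224 x 3 array. Draws consume the current RNG
#'   stream; seed externally for reproducibility.
#' @export
apply_transform <- function(image, policy = augmentation_policy()) {
  check_standard_image(image)
  out <- image
  if (stats::runif(1) < policy$hflip_p) out <- out[, dim(out)[2]:1, , drop = FALSE]
  if (stats::runif(1) < policy$vflip_p) out <- out[dim(out)[1]:1, , , drop = FALSE]

  theta <- stats::runif(1, policy$rotate_deg[1], policy$rotate_deg[2]) * pi / 180
  if (theta != 0) {
    # inverse rotation matrix in (row, col) coordinates
    A <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2)
    out <- affine_sample(out, A)
  }

  factor <- stats::runif(1, policy$brightness[1], policy$brightness[2])
  out <- clamp(out * factor, 0, 255)

  if (stats::runif(1) < policy$affine_p) {
    s <- stats::runif(1, policy$scale[1], policy$scale[2])
    tr <- stats::runif(2, -policy$translate_frac, policy$translate_frac) *
      dim(out)[1:2]
    A <- diag(2) / s
    out <- affine_sample(out, A, shift = tr)
  }
  # bilinear resampling is a convex combination; clamp only fp dust
  clamp(out, 0, 255)
}

#' Patient-level stratified train/test split
#'
#' Assigns whole patients to train or test so that (a) no patient appears on
#' both sides and (b) each class's test share approaches `test_fraction` as
#' closely as patient granularity permits. Classes are processed from rarest
#' to most frequent; a patient already placed by an earlier class keeps that
#' side.
#'
#' @param index Data frame with columns `image_id`, `patient_id`, `label`
#'   (and optionally `origin`; only `origin == "original"` records may be
#'   split).
#' @param test_fraction Target test share per class. Default 0.2.
#' @param seed Integer seed controlling the patient shuffle.
#' @return Tibble: `index` plus a `split` column (`"train"`/`"test"`).
#' @export
stratified_patient_split <- function(index, test_fraction = 0.2, seed = 1L) {
  index <- tibble::as_tibble(index)
  req <- c("image_id", "patient_id", "label")
  if (!all(req %in% names(index))) {
    abort("`index` needs columns image_id, patient_id, label")
  }
  if ("origin" %in% names(index) && any(index$origin != "original")) {
    abort("split must be computed on original records only")
  }
  if (anyDuplicated(index$image_id)) abort("image_ids must be unique")

  assignment <- list()  # patient_id -> "train"/"test"
  class_sizes <- sort(table(index$label))
  with_seed(derive_seed(seed, "patient-split"), {
    for (cls in names(class_sizes)) {
      sub <- index[index$label == cls, ]
      target <- test_fraction * nrow(sub)
      pat_counts <- table(sub$patient_id)
      pats <- sample(names(pat_counts))
      if (length(pat_counts) < 2) {
        warn(sprintf(
          "class '%s' has a single patient; assigning wholly to train", cls))
        for (p in pats) if (is.null(assignment[[p]])) assignment[[p]] <- "train"
        next
      }
      # images of this class already committed to test by earlier classes
      placed <- vapply(pats, function(p) !is.null(assignment[[p]]), TRUE)
      n_test <- 0
      for (p in pats[placed]) {
        if (assignment[[p]] == "test") n_test <- n_test + pat_counts[[p]]
      }
      for (p in pats[!placed]) {
        if (n_test < target) {
          assignment[[p]] <- "test"
          n_test <- n_test + pat_counts[[p]]
        } else {
          assignment[[p]] <- "train"
        }
      }
    }
  })
  index$split <- vapply(as.character(index$patient_id),
                        function(p) assignment[[p]], "", USE.NAMES = FALSE)
  index
}

#' Balance training classes by offline augmentation
#'
#' Expands every class on the training side to exactly `target_per_class`
#' records by cycling uniformly over that class's parent images. Each new
#' record draws its transform from an RNG stream derived from
#' `(seed, parent image id, replica index)`, so regeneration is bit-stable
#' and independent of record order.
#'
#' @param train_index Data frame of training records (`image_id`,
#'   `patient_id`, `label`).
#' @param images Optional named list of 224 x 224 x 3 arrays keyed by
#'   `image_id`; when supplied, augmented pixel data is generated and
#'   returned, otherwise only the manifest is expanded.
#' @param target_per_class Target per-class record count. Default 2500.
#' @param policy An [augmentation_policy()].
#' @param seed Integer base seed.
#' @return List with `index` (tibble including `origin` and
#'   `parent_image_id`) and `images` (possibly extended named list, or NULL).
#' @export
augment_to_target <- function(train_index, images = NULL,
                              target_per_class = 2500L,
                              policy = augmentation_policy(), seed = 1L) {
  train_index <- tibble::as_tibble(train_index)
  counts <- table(train_index$label)
  if (any(counts == 0)) abort("empty class in training index")
  if (target_per_class < max(counts)) {
    abort(sprintf("target_per_class %d below largest class count %d",
                  target_per_class, max(counts)))
  }
  train_index$origin <- "original"
  train_index$parent_image_id <- NA_character_

  new_rows <- purrr::map(names(counts), function(cls) {
    need <- target_per_class - counts[[cls]]
    if (need == 0) return(NULL)
    parents <- train_index[train_index$label == cls, ]
    parents <- parents[order(parents$image_id), ]
    pick <- rep(seq_len(nrow(parents)), length.out = need)
    replica <- stats::ave(pick, pick, FUN = seq_along)
    tibble::tibble(
      image_id = sprintf("%s_aug%03d", parents$image_id[pick], replica),
      patient_id = parents$patient_id[pick],
      label = cls,
      origin = "augmented",
      parent_image_id = parents$image_id[pick],
      replica = replica
    )
  })
  new_rows <- dplyr::bind_rows(new_rows)

  if (!is.null(images) && nrow(new_rows) > 0) {
    aug_imgs <- purrr::map2(new_rows$parent_image_id, new_rows$replica,
      function(pid, rep_i) {
        if (is.null(images[[pid]])) {
          abort(sprintf("no pixel data for parent image '%s'", pid))
        }
        with_seed(derive_seed(seed, pid, rep_i),
                  apply_transform(images[[pid]], policy))
      })
    names(aug_imgs) <- new_rows$image_id
    images <- c(images, aug_imgs)
  }

  idx <- dplyr::bind_rows(
    train_index,
    dplyr::select(new_rows, -dplyr::any_of("replica"))
  )
  list(index = idx, images = images)
}

#' Assert that a split manifest is leakage-free
#'
#' Exhaustively checks that no patient spans both sides, that every
#' augmented record sits on the same side as its parent, and that the test
#' side holds only original records.
#'
#' @param index Data frame with `patient_id`, `split`, `origin`,
#'   `parent_image_id` columns.
#' @return TRUE invisibly; aborts on any violation.
#' @export
assert_leakage_free <- function(index) {
  sides <- tapply(index$split, index$patient_id,
                  function(s) length(unique(s)))
  if (any(sides > 1)) abort("patient appears on both sides of the split")
  if ("origin" %in% names(index)) {
    aug <- index[index$origin == "augmented", ]
    if (nrow(aug) > 0) {
      parent_split <- stats::setNames(index$split, index$image_id)
      if (any(aug$split != parent_split[aug$parent_image_id])) {
        abort("augmented record crosses the split boundary of its parent")
      }
    }
    if (any(index$origin[index$split == "test"] != "original")) {
      abort("test side contains augmented records")
    }
  }
  invisible(TRUE)
}
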