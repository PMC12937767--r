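# End-to-end pipeline: split -> (optional augmentation) -> preprocessing ->
# feature extraction -> metadata encoding -> ensemble training -> evaluation.

#' Run the full classification pipeline on a multimodal dataset
#'
#' Performs a leakage-safe patient-level split, optionally balances the
#' training classes by offline augmentation, preprocesses every image,
#' extracts the 116-d visual descriptor, fits metadata statistics on the
#' training side only, trains the soft-voting boosting ensemble on the fused
#' 128-d representation and evaluates on the held-out originals.
#'
#' @param dataset A `lesion_dataset` (see [gen_dataset()]) or a list with
#'   `images` (named list of H x W x 3 arrays) and `manifest` (tibble with
#'   `image_id`, `patient_id`, `label` and the 12 metadata fields).
#' @param test_fraction Held-out share per class. Default 0.2.
#' @param seed Integer seed driving the split, augmentation and boosters.
#' @param use_metadata Fuse the 12-d metadata block? Default TRUE.
#' @param augment_target Per-class training count to augment to, or NULL
#'   (default) to train on originals only.
#' @param glcm_levels Gray-level count for the texture extractor in this
#'   pipeline. Default 64.
#' @param iterations,max_depth,learning_rate Ensemble core hyperparameters
#'   (defaults 500, 6, 0.03).
#' @param vote Voting mode passed to prediction, `"soft"` or `"hard"`.
#' @return Object of class `lesion_pipeline`: the fitted `model`, `metrics`,
#'   `split` manifest, feature tables and predictions.
#' @export
run_pipeline <- function(dataset, test_fraction = 0.2, seed = 1L,
                         use_metadata = TRUE, augment_target = NULL,
                         glcm_levels = 64L, iterations = 500L,
                         max_depth = 6L, learning_rate = 0.03,
                         vote = c("soft", "hard")) {
  vote <- match.arg(vote)
  manifest <- tibble::as_tibble(dataset$manifest)
  images <- dataset$images

  split <- stratified_patient_split(
    dplyr::select(manifest, "image_id", "patient_id", "label"),
    test_fraction = test_fraction, seed = seed
  )
  split$origin <- "original"
  split$parent_image_id <- NA_character_

  train_idx <- split[split$split == "train", ]
  test_idx <- split[split$split == "test", ]

  if (!is.null(augment_target)) {
    aug <- augment_to_target(
      dplyr::select(train_idx, "image_id", "patient_id", "label"),
      images = images, target_per_class = augment_target, seed = seed
    )
    images <- aug$images
    train_idx <- aug$index
    train_idx$split <- "train"
  }
  assert_leakage_free(dplyr::bind_rows(train_idx, test_idx))

  std <- purrr::map(images[c(train_idx$image_id, test_idx$image_id)],
                    preprocess_image)
  feats <- extract_feature_table(std, glcm_levels = glcm_levels)

  meta_by_id <- NULL
  if (use_metadata) {
    # augmented records inherit the metadata row of their parent image
    source_id <- function(idx) {
      ifelse(is.na(idx$parent_image_id), idx$image_id, idx$parent_image_id)
    }
    stats <- fit_metadata_stats(
      manifest[manifest$image_id %in% unique(source_id(train_idx)), ]
    )
    meta_rows <- manifest[match(c(source_id(train_idx), source_id(test_idx)),
                                manifest$image_id), ]
    enc <- encode_metadata(meta_rows, stats)
    meta_by_id <- dplyr::bind_cols(
      tibble::tibble(image_id = c(train_idx$image_id, test_idx$image_id)),
      enc
    )
    feats <- dplyr::left_join(feats, meta_by_id, by = "image_id")
  } else {
    stats <- NULL
  }

  label_of <- stats::setNames(
    c(train_idx$label, test_idx$label),
    c(train_idx$image_id, test_idx$image_id)
  )
  train_feats <- feats[feats$image_id %in% train_idx$image_id, ]
  test_feats <- feats[feats$image_id %in% test_idx$image_id, ]

  model <- train_ensemble(
    train_feats,
    labels = label_of[train_feats$image_id],
    configs = default_booster_configs(iterations, max_depth, learning_rate,
                                      seed = seed),
    label_order = sort(unique(manifest$label))
  )
  probs <- predict_proba(model, test_feats)
  preds <- predict(model, test_feats, mode = vote)
  truth <- unname(label_of[test_feats$image_id])
  cm <- confusion(truth, preds, model$label_order)
  metrics <- compute_metrics(cm, probs = probs, y_true = truth)

  structure(list(
    model = model,
    metrics = metrics,
    split = dplyr::bind_rows(train_idx, test_idx),
    features = feats,
    meta_stats = stats,
    predictions = tibble::tibble(image_id = test_feats$image_id,
                                 truth = truth, pred = preds),
    probs = probs,
    seed = seed
  ), class = "lesion_pipeline")
}

#' @export
print.lesion_pipeline <- function(x, ...) {
  cat("<lesion_pipeline> trained on",
      sum(x$split$split == "train"), "images, tested on",
      sum(x$split$split == "test"), "\n")
  print(x$metrics)
  invisible(x)
}

#' Feature-subset ablation harness
#'
#' Trains and evaluates the ensemble on each requested feature-block subset
#' (S = shape, H = texture, C = colour, M = metadata) using one shared
#' split and one shared feature table, and reports the full metric battery
#' per configuration.
#'
#' @param dataset A `lesion_dataset` (or compatible list).
#' @param subsets Character vector of configurations; default the standard
#'   ladder `c("S", "H", "H+S", "C", "C+S", "C+H", "C+H+S", "C+H+S+M")`.
#' @param ... Passed on to [run_pipeline()] (seed, glcm_levels, iterations,
#'   ...).
#' @param seed Integer seed shared across configurations.
#' @param glcm_levels,iterations,max_depth,learning_rate As in
#'   [run_pipeline()].
#' @param test_fraction Held-out share. Default 0.2.
#' @return Tibble: one row per configuration with `config`, `n_features`
#'   and the glance metrics.
#' @export
run_ablation <- function(dataset,
                         subsets = c("S", "H", "H+S", "C", "C+S", "C+H",
                                     "C+H+S", "C+H+S+M"),
                         seed = 1L, test_fraction = 0.2, glcm_levels = 64L,
                         iterations = 500L, max_depth = 6L,
                         learning_rate = 0.03, ...) {
  full <- run_pipeline(dataset, test_fraction = test_fraction, seed = seed,
                       use_metadata = TRUE, glcm_levels = glcm_levels,
                       iterations = iterations, max_depth = max_depth,
                       learning_rate = learning_rate)
  feats <- full$features
  split <- full$split
  label_of <- stats::setNames(split$label, split$image_id)
  train_ids <- split$image_id[split$split == "train"]
  test_ids <- split$image_id[split$split == "test"]

  block_cols <- list(
    C = color_feature_names(),
    H = texture_feature_names(),
    S = shape_feature_names(),
    M = metadata_feature_names()
  )
  purrr::map_dfr(subsets, function(cfg) {
    parts <- strsplit(cfg, "+", fixed = TRUE)[[1]]
    if (!all(parts %in% names(block_cols))) {
      abort(sprintf("unknown ablation config '%s'", cfg))
    }
    cols <- unlist(block_cols[c("C", "H", "S", "M")[
      c("C", "H", "S", "M") %in% parts]], use.names = FALSE)
    sub <- feats[, c("image_id", cols)]
    model <- train_ensemble(
      sub[sub$image_id %in% train_ids, ],
      labels = label_of[sub$image_id[sub$image_id %in% train_ids]],
      configs = default_booster_configs(iterations, max_depth, learning_rate,
                                        seed = seed),
      label_order = sort(unique(split$label))
    )
    test_sub <- sub[sub$image_id %in% test_ids, ]
    preds <- predict(model, test_sub)
    probs <- predict_proba(model, test_sub)
    truth <- unname(label_of[test_sub$image_id])
    g <- glance(compute_metrics(confusion(truth, preds, model$label_order),
                                probs = probs, y_true = truth))
    dplyr::bind_cols(tibble::tibble(config = cfg, n_features = length(cols)), g)
  })
}
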