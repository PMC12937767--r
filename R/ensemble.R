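# Feature fusion and the soft-voting gradient-boosting ensemble.
#
# The classifier averages class-probability distributions from three
# gradient-boosted tree models fitted independently on identical data with
# shared core hyperparameters (500 rounds, depth 6, learning rate 0.03) but
# deliberately different tree-construction strategies, so the members make
# decorrelated errors: exact depth-wise growth, histogram depth-wise growth
# with row/column subsampling, and histogram leaf-wise (loss-guided) growth.

block_lengths <- c(color = 96L, texture = 13L, shape = 7L, meta = 12L)

#' Fuse feature blocks into the multimodal descriptor
#'
#' Concatenates the colour (96), texture (13), shape (7) and metadata (12)
#' blocks in that fixed order. Passing `meta = NULL` yields the 116-d
#' visual-only descriptor used in ablations.
#'
#' @param color,texture,shape Numeric vectors of lengths 96, 13, 7.
#' @param meta Numeric vector of length 12, or NULL for visual-only mode.
#' @return Named numeric vector of length 128 (or 116 without metadata).
#' @export
fuse_features <- function(color, texture, shape, meta = NULL) {
  blocks <- list(color = color, texture = texture, shape = shape)
  if (!is.null(meta)) blocks$meta <- meta
  for (nm in names(blocks)) {
    if (length(blocks[[nm]]) != block_lengths[[nm]]) {
      abort(sprintf("block '%s' must have length %d, got %d",
                    nm, block_lengths[[nm]], length(blocks[[nm]])))
    }
  }
  out <- unlist(blocks, use.names = FALSE)
  names(out) <- c(color_feature_names(), texture_feature_names(),
                  shape_feature_names(),
                  if (!is.null(meta)) metadata_feature_names())
  out
}

#' Extract the 116-d visual descriptor of one image
#'
#' Runs the colour, texture and shape extractors on a preprocessed image and
#' fuses their outputs.
#'
#' @param image 224 x 224 x 3 numeric array.
#' @param glcm_levels Gray-level count for the texture extractor.
#'   Default 256.
#' @return Named numeric vector of length 116.
#' @export
extract_visual <- function(image, glcm_levels = 256L) {
  check_standard_image(image)
  fuse_features(
    extract_color(image),
    extract_texture(image, levels = glcm_levels),
    extract_shape(image)
  )
}

#' Visual feature table for a set of images
#'
#' @param images Named list of 224 x 224 x 3 arrays.
#' @param glcm_levels Gray-level count for the texture extractor.
#' @return Tibble with `image_id` and 116 feature columns.
#' @export
extract_feature_table <- function(images, glcm_levels = 256L) {
  rows <- purrr::map(images, extract_visual, glcm_levels = glcm_levels)
  out <- tibble::as_tibble(do.call(rbind, rows))
  dplyr::bind_cols(tibble::tibble(image_id = names(images)), out)
}

#' Booster member configuration
#'
#' One member of the three-booster ensemble. All members share the core
#' hyperparameters (500 iterations, depth 6, learning rate 0.03); `family`
#' selects the tree-construction strategy.
#'
#' @param family One of `"exact-depthwise"`, `"hist-subsample"`,
#'   `"hist-lossguide"`.
#' @param iterations,max_depth,learning_rate Core hyperparameters.
#' @param seed Integer seed for this member.
#' @return Object of class `booster_config`.
#' @export
booster_config <- function(family = c("exact-depthwise", "hist-subsample",
                                      "hist-lossguide"),
                           iterations = 500L, max_depth = 6L,
                           learning_rate = 0.03, seed = 1L) {
  family <- match.arg(family)
  if (iterations <= 0 || max_depth <= 0 || learning_rate <= 0) {
    abort("iterations, max_depth and learning_rate must be positive")
  }
  structure(
    list(family = family, iterations = as.integer(iterations),
         max_depth = as.integer(max_depth),
         learning_rate = learning_rate, seed = as.integer(seed)),
    class = "booster_config"
  )
}

#' Default three-member ensemble configuration
#'
#' @param iterations,max_depth,learning_rate Shared core hyperparameters
#'   (defaults 500, 6, 0.03).
#' @param seed Base seed; members receive distinct derived seeds.
#' @return List of three `booster_config` objects.
#' @export
default_booster_configs <- function(iterations = 500L, max_depth = 6L,
                                    learning_rate = 0.03, seed = 1L) {
  fams <- c("exact-depthwise", "hist-subsample", "hist-lossguide")
  purrr::imap(stats::setNames(fams, fams), function(f, nm) {
    booster_config(f, iterations, max_depth, learning_rate,
                   seed = derive_seed(seed, "booster", f))
  })
}

booster_params <- function(cfg, n_classes) {
  base <- list(
    objective = "multi:softprob",
    num_class = n_classes,
    max_depth = cfg$max_depth,
    eta = cfg$learning_rate,
    nthread = 1L,
    seed = cfg$seed
  )
  extra <- switch(cfg$family,
    "exact-depthwise" = list(tree_method = "exact"),
    "hist-subsample" = list(tree_method = "hist", subsample = 0.8,
                            colsample_bytree = 0.8),
    "hist-lossguide" = list(tree_method = "hist", grow_policy = "lossguide",
                            max_leaves = 63L)
  )
  c(base, extra)
}

feature_schema_hash <- function(feature_names) {
  str_hash31(paste(feature_names, collapse = "|"))
}

# Per-member class probabilities as an n x k matrix, tolerating both the
# flat-vector and matrix return shapes of xgboost's softprob predict.
member_proba <- function(member, x, k) {
  p <- stats::predict(member, xgboost::xgb.DMatrix(x))
  if (is.matrix(p)) p else matrix(p, ncol = k, byrow = TRUE)
}

#' Train the soft-voting boosting ensemble
#'
#' Fits the three booster members independently on identical data. Training
#' is single-threaded and fully seeded, so refits are deterministic.
#'
#' @param features Numeric matrix or data frame of feature rows (an
#'   `image_id` column, if present, is dropped).
#' @param labels Character or factor vector of class labels, one per row.
#' @param configs List of three [booster_config()]s.
#'   Default [default_booster_configs()].
#' @param label_order Fixed class ordering. Default the sorted unique labels.
#' @return Object of class `lesion_ensemble`.
#' @export
train_ensemble <- function(features, labels,
                           configs = default_booster_configs(),
                           label_order = NULL) {
  x <- as_feature_matrix(features)
  labels <- as.character(labels)
  if (nrow(x) != length(labels)) abort("rows of `features` must match `labels`")
  if (is.null(label_order)) label_order <- sort(unique(labels))
  if (!all(labels %in% label_order)) abort("labels outside `label_order`")
  if (length(unique(labels)) < 2) abort("need at least 2 classes to train")

  y <- match(labels, label_order) - 1L
  n_classes <- length(label_order)
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  members <- purrr::map(configs, function(cfg) {
    xgboost::xgb.train(
      params = booster_params(cfg, n_classes),
      data = dtrain, nrounds = cfg$iterations, verbose = 0
    )
  })
  structure(
    list(members = members, configs = configs, label_order = label_order,
         feature_names = colnames(x),
         schema_hash = feature_schema_hash(colnames(x))),
    class = "lesion_ensemble"
  )
}

as_feature_matrix <- function(features, feature_names = NULL) {
  if (is.data.frame(features)) {
    features <- dplyr::select(features, -dplyr::any_of(c("image_id")))
    features <- as.matrix(features)
  }
  if (is.null(dim(features))) features <- matrix(features, nrow = 1,
                                                 dimnames = list(NULL, names(features)))
  storage.mode(features) <- "double"
  if (!is.null(feature_names)) {
    if (!identical(colnames(features), feature_names)) {
      abort("feature schema mismatch: column names differ from training schema")
    }
  }
  features
}

#' Ensemble class probabilities
#'
#' Unweighted arithmetic mean of the three members' class-probability
#' distributions; rows lie on the probability simplex.
#'
#' @param model A `lesion_ensemble`.
#' @param features Feature matrix / data frame / single named vector with the
#'   training schema.
#' @return Matrix of probabilities, one row per input, columns named by
#'   `model$label_order`.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "lesion_ensemble"))
  x <- as_feature_matrix(features, model$feature_names)
  k <- length(model$label_order)
  probs <- purrr::map(model$members, function(m) member_proba(m, x, k))
  avg <- Reduce(`+`, probs) / length(probs)
  colnames(avg) <- model$label_order
  avg
}

#' Predict class labels
#'
#' Soft voting (default) takes the argmax of the averaged probability
#' distribution; hard voting takes the majority of member argmax votes. All
#' exact ties break to the lowest label index and are reported.
#'
#' @param object A `lesion_ensemble`.
#' @param features Feature rows with the training schema.
#' @param mode `"soft"` (probability averaging, default) or `"hard"`
#'   (majority vote; remaining ties broken by averaged probabilities).
#' @param ... Unused.
#' @return Character vector of predicted labels.
#' @export
predict.lesion_ensemble <- function(object, features, mode = c("soft", "hard"),
                                    ...) {
  mode <- match.arg(mode)
  avg <- predict_proba(object, features)
  k <- ncol(avg)
  if (mode == "soft") {
    scores <- avg
  } else {
    x <- as_feature_matrix(features, object$feature_names)
    votes <- matrix(0, nrow(x), k)
    for (m in object$members) {
      p <- member_proba(m, x, k)
      win <- max.col(p, ties.method = "first")
      votes[cbind(seq_len(nrow(x)), win)] <- votes[cbind(seq_len(nrow(x)), win)] + 1
    }
    # break vote ties by the averaged probabilities (scaled to stay below 1)
    scores <- votes + avg / k
  }
  ties <- apply(scores, 1, function(r) sum(r == max(r)) > 1)
  if (any(ties)) {
    rlang::inform(sprintf(
      "predict: %d exact tie(s) broken toward the lowest label index",
      sum(ties)))
  }
  object$label_order[max.col(scores, ties.method = "first")]
}

#' @export
print.lesion_ensemble <- function(x, ...) {
  cat("<lesion_ensemble>", length(x$members), "boosters,",
      length(x$label_order), "classes:",
      paste(x$label_order, collapse = ", "), "\n")
  for (nm in names(x$configs)) {
    cfg <- x$configs[[nm]]
    cat(sprintf("  %-16s %d rounds, depth %d, lr %.3f\n",
                cfg$family, cfg$iterations, cfg$max_depth, cfg$learning_rate))
  }
  invisible(x)
}

#' Gain-based feature importance of the ensemble
#'
#' Per-member gain importances, mean-aggregated across members, ranked
#' descending and annotated with the feature block each feature belongs to.
#'
#' @param model A `lesion_ensemble`.
#' @return Tibble with `feature`, `block`, `gain` (mean importance) and
#'   `rank`.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "lesion_ensemble"))
  gains <- purrr::map(model$members, function(m) {
    imp <- xgboost::xgb.importance(model = m)
    g <- stats::setNames(rep(0, length(model$feature_names)),
                         model$feature_names)
    g[imp$Feature] <- imp$Gain
    g
  })
  mean_gain <- Reduce(`+`, gains) / length(gains)
  blocks <- dplyr::case_when(
    grepl("^color", names(mean_gain)) ~ "color",
    grepl("^haralick", names(mean_gain)) ~ "haralick",
    grepl("^hu", names(mean_gain)) ~ "hu",
    TRUE ~ "meta"
  )
  out <- tibble::tibble(feature = names(mean_gain), block = blocks,
                        gain = unname(mean_gain))
  out <- dplyr::arrange(out, dplyr::desc(.data$gain))
  out$rank <- seq_len(nrow(out))
  out
}

#' @rdname feature_importance
#' @param x A `lesion_ensemble`.
#' @param ... Unused.
#' @method tidy lesion_ensemble
#' @export
tidy.lesion_ensemble <- function(x, ...) feature_importance(x)

#' Model summary
#'
#' @param x A `lesion_ensemble`.
#' @param ... Unused.
#' @return One-row tibble with member count, class count, feature count and
#'   shared hyperparameters.
#' @method glance lesion_ensemble
#' @export
glance.lesion_ensemble <- function(x, ...) {
  cfg <- x$configs[[1]]
  tibble::tibble(
    n_members = length(x$members),
    n_classes = length(x$label_order),
    n_features = length(x$feature_names),
    iterations = cfg$iterations,
    max_depth = cfg$max_depth,
    learning_rate = cfg$learning_rate
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Save an ensemble as a model bundle directory
#'
#' Writes each member in the booster's native format plus a JSON manifest
#' (label order, feature schema and hash, member configurations), so a
#' reloaded model reproduces pre-save predictions exactly.
#'
#' @param model A `lesion_ensemble`.
#' @param dir Bundle directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_ensemble <- function(model, dir) {
  stopifnot(inherits(model, "lesion_ensemble"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(model$members)) {
    xgboost::xgb.save(model$members[[i]],
                      file.path(dir, sprintf("member_%d.ubj", i)))
  }
  manifest <- list(
    label_order = model$label_order,
    feature_names = model$feature_names,
    schema_hash = model$schema_hash,
    configs = purrr::map(model$configs, unclass)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load an ensemble bundle written by [save_ensemble()]
#'
#' @param dir Bundle directory.
#' @return A `lesion_ensemble`.
#' @export
load_ensemble <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    abort(sprintf("no manifest.json under '%s'", dir))
  }
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  paths <- sort(list.files(dir, "^member_\\d+\\.ubj$", full.names = TRUE))
  members <- purrr::map(paths, xgboost::xgb.load)
  names(members) <- names(manifest$configs)
  configs <- purrr::map(manifest$configs, function(cfg) {
    booster_config(cfg$family, cfg$iterations, cfg$max_depth,
                   cfg$learning_rate, cfg$seed)
  })
  structure(
    list(members = members, configs = configs,
         label_order = manifest$label_order,
         feature_names = manifest$feature_names,
         schema_hash = manifest$schema_hash),
    class = "lesion_ensemble"
  )
}
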