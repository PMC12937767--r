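test_that("fusion enforces block lengths and ordering", {
  fused <- fuse_features(rep(0.1, 96), rep(1, 13), rep(-1, 7), rep(0.5, 12))
  expect_length(fused, 128)
  expect_identical(names(fused)[c(1, 97, 110, 117, 128)],
                   c("colorH_00", "haralick_asm", "hu_1", "age_z",
                     "elevation"))
  expect_length(fuse_features(rep(0, 96), rep(0, 13), rep(0, 7)), 116)
  expect_equal(unname(fuse_features(rep(0, 96), rep(0, 13), rep(0, 7),
                                    rep(0, 12))),
               rep(0, 128))
  expect_error(fuse_features(rep(0, 95), rep(0, 13), rep(0, 7)), "'color'")
  expect_error(fuse_features(rep(0, 96), rep(0, 12), rep(0, 7)), "'texture'")
})

test_that("ensemble fits separable data exactly and refits deterministically", {
  set.seed(1)
  x <- matrix(rnorm(200 * 5), 200, 5)
  colnames(x) <- paste0("f", 1:5)
  y <- ifelse(x[, 1] > 0, "pos", "neg")
  x[, 1] <- x[, 1] + sign(x[, 1]) * 2  # widen the margin
  cfgs <- default_booster_configs(iterations = 60, seed = 4)
  m <- train_ensemble(x, y, configs = cfgs)
  expect_equal(mean(predict(m, x) == y), 1)

  probe <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
  m2 <- train_ensemble(x, y, configs = cfgs)
  expect_identical(predict(m, probe), predict(m2, probe))
  expect_equal(predict_proba(m, probe), predict_proba(m2, probe))

  expect_error(train_ensemble(x, rep("one", 200), configs = cfgs),
               "at least 2 classes")
})

test_that("well-separated six-class blobs are recovered on held-out data", {
  blob <- gaussian_blobs(60, seed = 2)
  train <- seq_len(nrow(blob$x)) %% 5 != 0
  m <- train_ensemble(blob$x[train, ], blob$y[train],
                      configs = default_booster_configs(iterations = 80,
                                                        seed = 7))
  acc <- mean(predict(m, blob$x[!train, ]) == blob$y[!train])
  expect_gte(acc, 0.95)
  expect_identical(m$label_order, lesion_classes())
})

test_that("soft voting averages member distributions on the simplex", {
  blob <- gaussian_blobs(20, seed = 3)
  m <- train_ensemble(blob$x, blob$y,
                      configs = default_booster_configs(iterations = 30,
                                                        seed = 5))
  p <- predict_proba(m, blob$x[1:25, ])
  expect_equal(rowSums(p), rep(1, 25), tolerance = 1e-6)
  expect_true(all(p >= 0))
  members <- lapply(m$members, function(b) {
    pm <- predict(b, xgboost::xgb.DMatrix(blob$x[1:25, ]))
    if (is.matrix(pm)) pm else matrix(pm, ncol = 6, byrow = TRUE)
  })
  expect_equal(unname(p), Reduce(`+`, members) / 3, tolerance = 1e-7)

  # schema guard
  bad <- blob$x[1:2, ]; colnames(bad)[1] <- "other"
  expect_error(predict_proba(m, bad), "schema mismatch")

  # batch prediction equals per-row prediction
  one_by_one <- vapply(1:10, function(i) predict(m, blob$x[i, , drop = FALSE]),
                       "")
  expect_identical(predict(m, blob$x[1:10, ]), one_by_one)

  # hard voting agrees with soft on confidently separated data
  expect_identical(predict(m, blob$x[1:25, ], mode = "hard"),
                   predict(m, blob$x[1:25, ], mode = "soft"))
})

test_that("degenerate inputs stay near-uniform with deterministic argmax", {
  # constant features carry no signal: the averaged distribution stays close
  # to uniform and the argmax decision is reproducible across calls
  x <- matrix(1, 30, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rep(c("A", "B", "C"), each = 10)
  m <- train_ensemble(x, y,
                      configs = default_booster_configs(iterations = 5,
                                                        seed = 1))
  p <- predict_proba(m, x[1:2, ])
  expect_equal(p[1, ], c(A = 1, B = 1, C = 1) / 3, tolerance = 0.01)
  expect_identical(suppressMessages(predict(m, x[1:2, ])),
                   suppressMessages(predict(m, x[1:2, ])))
  expect_equal(length(unique(suppressMessages(predict(m, x)))), 1L)
})

test_that("importance ranks an engineered signal feature first", {
  set.seed(9)
  x <- matrix(rnorm(400 * 6), 400, 6)
  colnames(x) <- c("colorH_00", "haralick_asm", "hu_1", "age_z", "f5", "f6")
  y <- ifelse(x[, 1] > 0, "pos", "neg")
  m <- train_ensemble(x, y, configs = default_booster_configs(iterations = 40,
                                                              seed = 2))
  imp <- feature_importance(m)
  expect_identical(imp$feature[1], "colorH_00")
  expect_identical(imp$block[1], "color")
  expect_true(all(imp$gain >= 0))
  expect_identical(tidy(m), imp)
  g <- glance(m)
  expect_equal(g$n_members, 3L)
  expect_equal(g$iterations, 40L)
})

test_that("soft voting tracks the weakest member within two points on average", {
  res <- purrr::map_dfr(1:10, function(seed) {
    blob <- gaussian_blobs(30, sep = 1.2, seed = seed)  # deliberately noisy
    train <- seq_len(nrow(blob$x)) %% 4 != 0
    m <- train_ensemble(blob$x[train, ], blob$y[train],
                        configs = default_booster_configs(iterations = 40,
                                                          seed = seed))
    xt <- blob$x[!train, ]; yt <- blob$y[!train]
    member_acc <- vapply(m$members, function(b) {
      p <- predict(b, xgboost::xgb.DMatrix(xt))
      if (!is.matrix(p)) p <- matrix(p, ncol = 6, byrow = TRUE)
      mean(m$label_order[max.col(p, ties.method = "first")] == yt)
    }, 0)
    tibble::tibble(seed = seed, ensemble = mean(predict(m, xt) == yt),
                   worst = min(member_acc))
  })
  expect_gte(mean(res$ensemble), mean(res$worst) - 0.02)
})

test_that("a saved bundle reloads and reproduces predictions exactly", {
  blob <- gaussian_blobs(15, seed = 6)
  m <- train_ensemble(blob$x, blob$y,
                      configs = default_booster_configs(iterations = 25,
                                                        seed = 3))
  dir <- withr::local_tempdir()
  save_ensemble(m, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  m2 <- load_ensemble(dir)
  expect_identical(m2$label_order, m$label_order)
  expect_identical(m2$schema_hash, m$schema_hash)
  expect_equal(predict_proba(m2, blob$x), predict_proba(m, blob$x))
  expect_identical(predict(m2, blob$x), predict(m, blob$x))
  expect_error(load_ensemble(withr::local_tempdir()), "manifest")
})
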