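test_that("recipes separate with the separability dial", {
  r1 <- default_recipes(1.0)
  expect_equal(nrow(r1), 6)
  expect_identical(r1$class, lesion_classes())
  # pairwise-disjoint hue ranges at full separability
  ord <- order(r1$hue_lo)
  expect_true(all(r1$hue_lo[ord][-1] > r1$hue_hi[ord][-6]))

  r0 <- default_recipes(0.1)
  overlaps <- sum(outer(seq_len(6), seq_len(6), Vectorize(function(i, j) {
    i < j && r0$hue_lo[j] < r0$hue_hi[i] && r0$hue_lo[i] < r0$hue_hi[j]
  })))
  expect_gt(overlaps, 5)

  # round-trip through CSV text preserves every recipe parameter
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(r1, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(as.data.frame(r1), back, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(default_recipes(0), "separability")
  expect_error(default_recipes(1.2), "separability")
})

test_that("generated images are deterministic and class-signal bearing", {
  r <- default_recipes(1.0)
  img1 <- with(list(), {set.seed(5); gen_image(r[2, ], size = 96)})
  img2 <- with(list(), {set.seed(5); gen_image(r[2, ], size = 96)})
  expect_identical(img1, img2)
  expect_equal(dim(img1), c(96L, 96L, 3L))
  expect_true(all(img1 >= 0 & img1 <= 255))

  # roughness probe: zero-noise smooth ellipse has lower Haralick contrast
  smooth_recipe <- r[1, ]
  smooth_recipe$noise_amp <- 0
  smooth_recipe$border_amp <- 0
  rough_recipe <- smooth_recipe
  rough_recipe$noise_amp <- 40
  set.seed(11); smooth_img <- gen_image(smooth_recipe, size = 96)
  set.seed(11); rough_img <- gen_image(rough_recipe, size = 96)
  c_smooth <- extract_texture(smooth_img, levels = 32)["haralick_contrast"]
  c_rough <- extract_texture(rough_img, levels = 32)["haralick_contrast"]
  expect_gt(c_rough, c_smooth)

  # eccentricity probe: elongated blobs shift the second Hu invariant
  round_recipe <- smooth_recipe
  round_recipe$ecc_lo <- 0; round_recipe$ecc_hi <- 0.01
  long_recipe <- smooth_recipe
  long_recipe$ecc_lo <- 0.85; long_recipe$ecc_hi <- 0.9
  set.seed(12); round_img <- gen_image(round_recipe, size = 96)
  set.seed(12); long_img <- gen_image(long_recipe, size = 96)
  h2_round <- extract_shape(round_img)["hu_2"]
  h2_long <- extract_shape(long_img)["hu_2"]
  # rendering is bit-deterministic here, so any separation is signal; the
  # shift is modest because the uniform background also carries moments
  expect_gt(abs(h2_long - h2_round), 0.005)
})

test_that("dataset generation respects counts, schema, grouping and seeding", {
  ds <- gen_dataset(10, separability = 0.8, seed = 42, size = 64)
  expect_length(ds$images, 60)
  expect_equal(nrow(ds$manifest), 60)
  expect_true(all(table(ds$manifest$label) == 10))
  expect_true(all(c("image_id", "patient_id", "label", "age", "gender",
                    "diameter_1", "diameter_2", "smoke", "drink", "itch",
                    "grew", "hurt", "changed", "bleed", "elevation")
                  %in% names(ds$manifest)))
  expect_false(any(is.na(ds$manifest$age)))  # missingness 0 by default

  # some synthetic patients own several lesions
  expect_gt(max(table(ds$manifest$patient_id)), 1)

  ds2 <- gen_dataset(10, separability = 0.8, seed = 42, size = 64)
  expect_identical(ds$images, ds2$images)
  expect_identical(ds$manifest, ds2$manifest)

  with_missing <- gen_dataset(20, seed = 1, missing_rate = 0.3, size = 32)
  expect_gt(sum(is.na(with_missing$manifest$age)), 0)

  dir <- withr::local_tempdir()
  gen_dataset(2, seed = 3, out_dir = dir, size = 32)
  expect_equal(length(list.files(file.path(dir, "images"), "\\.png$")), 12)
  man <- utils::read.csv(file.path(dir, "metadata.csv"))
  expect_equal(nrow(man), 12)
})
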