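make_index <- function(n_patients, images_per_patient = 1, label = "BCC") {
  tibble::tibble(
    image_id = sprintf("img%03d", seq_len(n_patients * images_per_patient)),
    patient_id = rep(sprintf("pat%02d", seq_len(n_patients)),
                     each = images_per_patient),
    label = label
  )
}

test_that("patient split is exact on divisible toys and always disjoint", {
  idx <- make_index(10)
  for (seed in 1:5) {
    sp <- stratified_patient_split(idx, test_fraction = 0.2, seed = seed)
    expect_equal(sum(sp$split == "test"), 2)
    expect_length(intersect(sp$patient_id[sp$split == "train"],
                            sp$patient_id[sp$split == "test"]), 0)
  }
})

test_that("all images of a patient land on the same side", {
  idx <- make_index(5, images_per_patient = 3)
  sp <- stratified_patient_split(idx, test_fraction = 0.2, seed = 3)
  by_patient <- tapply(sp$split, sp$patient_id, function(s) length(unique(s)))
  expect_true(all(by_patient == 1))
  expect_silent(assert_leakage_free(sp))
})

test_that("multi-class splits approximate the class-wise fraction", {
  set.seed(42)
  idx <- dplyr::bind_rows(purrr::map(lesion_classes(), function(cls) {
    n_pat <- 30
    sizes <- sample(1:3, n_pat, replace = TRUE)
    tibble::tibble(
      image_id = sprintf("%s_im%03d", cls, seq_len(sum(sizes))),
      patient_id = rep(sprintf("%s_p%02d", cls, seq_len(n_pat)), times = sizes),
      label = cls
    )
  }))
  sp <- stratified_patient_split(idx, test_fraction = 0.2, seed = 11)
  shares <- tapply(sp$split == "test", sp$label, mean)
  expect_true(all(shares > 0.1 & shares < 0.35))
  expect_silent(assert_leakage_free(sp))

  # a class owned by a single patient goes wholly to train, with a warning
  rare <- tibble::tibble(
    image_id = c("x1", "x2", sprintf("y%02d", 1:10)),
    patient_id = c("p1", "p1", sprintf("q%02d", 1:10)),
    label = c("MEL", "MEL", rep("BCC", 10))
  )
  expect_warning(sp2 <- stratified_patient_split(rare, seed = 1),
                 "single patient")
  expect_true(all(sp2$split[sp2$label == "MEL"] == "train"))
})

test_that("balancing the published class counts yields 15,000 records", {
  counts <- c(ACK = 730, BCC = 845, MEL = 52, NEV = 244, SCC = 192, SEK = 235)
  idx <- dplyr::bind_rows(purrr::imap(counts, function(n, cls) {
    tibble::tibble(
      image_id = sprintf("%s_%04d", cls, seq_len(n)),
      patient_id = sprintf("%s_p%04d", cls, seq_len(n)),
      label = cls
    )
  }))
  expect_equal(nrow(idx), 2298L)
  aug <- augment_to_target(idx, target_per_class = 2500L, seed = 1)
  expect_equal(nrow(aug$index), 15000L)
  expect_true(all(table(aug$index$label) == 2500L))
  expect_false(anyDuplicated(aug$index$image_id) > 0)
  # every augmented record points at a parent in the index
  augd <- aug$index[aug$index$origin == "augmented", ]
  expect_true(all(augd$parent_image_id %in% idx$image_id))
  # a class already at target gains no records
  at_target <- augment_to_target(
    tibble::tibble(image_id = c("a", "b"), patient_id = c("p1", "p2"),
                   label = "NEV"),
    target_per_class = 2L
  )
  expect_equal(nrow(at_target$index), 2L)
})

test_that("augmented pixels regenerate bit-identically under a fixed seed", {
  imgs <- list(a1 = rand_standard_image(1), a2 = rand_standard_image(2))
  idx <- tibble::tibble(image_id = c("a1", "a2"),
                        patient_id = c("p1", "p2"), label = "MEL")
  run <- function() augment_to_target(idx, images = imgs,
                                      target_per_class = 6L, seed = 99)
  r1 <- run(); r2 <- run()
  expect_identical(r1$index, r2$index)
  expect_identical(r1$images, r2$images)
  expect_length(r1$images, 6)
})

test_that("transform composition honours policy probabilities and ranges", {
  img <- rand_standard_image(8)
  ident <- augmentation_policy(hflip_p = 0, vflip_p = 0,
                               rotate_deg = c(0, 0), brightness = c(1, 1),
                               affine_p = 0)
  set.seed(1)
  expect_equal(apply_transform(img, ident), img)

  # forced horizontal flip twice is the identity
  flip_only <- augmentation_policy(hflip_p = 1, vflip_p = 0,
                                   rotate_deg = c(0, 0), brightness = c(1, 1),
                                   affine_p = 0)
  set.seed(2)
  once <- apply_transform(img, flip_only)
  set.seed(2)
  twice <- apply_transform(once, flip_only)
  expect_equal(twice, img)

  # brightness factor pinned at 1.2 scales a constant image multiplicatively
  bright <- augmentation_policy(hflip_p = 0, vflip_p = 0,
                                rotate_deg = c(0, 0),
                                brightness = c(1.2, 1.2), affine_p = 0)
  set.seed(3)
  expect_equal(apply_transform(const_image(100), bright), const_image(120))
  set.seed(4)
  expect_equal(max(apply_transform(const_image(250), bright)), 255)  # clamp

  out <- with(list(), {set.seed(5); apply_transform(img)})
  expect_equal(dim(out), c(224L, 224L, 3L))
  expect_true(all(out >= 0 & out <= 255))

  expect_error(augmentation_policy(hflip_p = 1.5), "probabilities")
  expect_error(augmentation_policy(scale = c(1.1, 0.9)), "ordered")
})
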