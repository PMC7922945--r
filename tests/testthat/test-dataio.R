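test_that("cine slices round-trip through NIfTI bit-identically", {
  ph <- phantom_tiny(seed = 31, n_slices = 1)
  sl <- ph$slice[[1]]
  path <- file.path(withr::local_tempdir(), "s.nii.gz")
  write_cine_slice(sl, path)
  back <- read_cine_slice(path)
  expect_identical(back$frames, sl$frames)
  expect_equal(back$pixel_spacing_mm, as.numeric(sl$pixel_spacing_mm))
  expect_equal(back$rr_ms, sl$rr_ms)
  expect_identical(back$slice_id, sl$slice_id)

  mpath <- file.path(dirname(path), "m.nii.gz")
  write_myo_mask(ph$mask[[1]], mpath)
  mk <- read_myo_mask(mpath)
  expect_identical(mk$labels, ph$mask[[1]]$labels)
  expect_identical(mk$provenance, "manual")
})

test_that("malformed cine files raise format errors naming the field", {
  dir <- withr::local_tempdir()
  p3 <- file.path(dir, "three.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(16, 16, 5, 3))), p3)
  expect_error(read_cine_slice(p3), "channels", class = "mvm_format_error")

  p2 <- file.path(dir, "flat.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(16, 16, 5))), p2)
  expect_error(read_cine_slice(p2), class = "mvm_format_error")

  # valid image but no metadata sidecar
  p4 <- file.path(dir, "nosidecar.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(array(0, c(16, 16, 5, 4))), p4)
  expect_error(read_cine_slice(p4), "sidecar", class = "mvm_format_error")

  expect_error(read_cine_slice(file.path(dir, "absent.nii.gz")),
               class = "mvm_data_error")
})

test_that("augmentation applies the same transform to image and mask", {
  ph <- phantom_tiny(seed = 32, n_slices = 1)
  fr <- ph$slice[[1]]$frames[, , 1, ]
  mk <- ph$mask[[1]]$labels[, , 1]
  # identity transform
  id <- apply_augmentation(fr, mk, flip = FALSE, angle_deg = 0)
  expect_equal(id$frame, fr)
  expect_identical(id$mask, mk)
  # masks stay binary for arbitrary draws and the draw is seed-deterministic
  withr::with_seed(7, a1 <- augment_frame(fr, mk))
  withr::with_seed(7, a2 <- augment_frame(fr, mk))
  expect_identical(a1, a2)
  expect_true(all(a1$mask %in% c(0L, 1L)))
  expect_gte(a1$angle_deg, 0)
  expect_lte(a1$angle_deg, 90)
  # a flipped/rotated ring stays ring-like: roughly the same pixel count
  expect_lt(abs(sum(a1$mask) - sum(mk)) / sum(mk), 0.2)
})

test_that("training pool counts follow the stacking rule", {
  # clinical layout: 121 slices of 50 frames, 4 augmentations
  index <- tibble::tibble(slice_id = sprintf("s%03d", 1:121), n_frames = 50L)
  expect_identical(sum(index$n_frames), 6050L)
  pool <- build_training_pool(index, n_aug = 4, seed = 1)
  expect_identical(pool_size(pool), 30250L)
  expect_identical(pool_size(build_training_pool(index[1, ], n_aug = 0)), 50L)
  expect_identical(pool_size(build_training_pool(index[1:2, ], n_aug = 4)), 500L)
  expect_error(pool_frame(pool, 1), class = "mvm_data_error")  # index only
  expect_error(build_training_pool(list()), class = "mvm_data_error")
})

test_that("pool count identity holds for fuzzed layouts and originals are unmodified", {
  withr::local_seed(14)
  for (rep in 1:10) {
    ns <- sample(1:6, 1)
    frames <- sample(8:20, ns, replace = TRUE)
    n_aug <- sample(0:5, 1)
    index <- tibble::tibble(slice_id = sprintf("s%d", seq_len(ns)),
                            n_frames = frames)
    pool <- build_training_pool(index, n_aug = n_aug, seed = rep)
    expect_identical(pool_size(pool), as.integer((n_aug + 1) * sum(frames)))
  }
  ph <- phantom_tiny(seed = 33, n_slices = 2)
  pool <- build_training_pool(ph, n_aug = 2, seed = 3)
  orig <- pool$manifest[pool$manifest$aug_id == 0, ]
  row <- orig[orig$slice_id == ph$slice_id[2] & orig$frame == 3, ]
  pf <- pool_frame(pool, row$idx)
  expect_identical(pf$frame, ph$slice[[2]]$frames[, , 3, ])
  expect_identical(pf$mask, ph$mask[[2]]$labels[, , 3])
})

test_that("cross-validation folds are balanced, deterministic and leak-free", {
  ids <- sprintf("s%03d", 1:121)
  f <- make_cv_folds(ids, k = 5, seed = 2)
  expect_setequal(f$slice_id, ids)
  expect_identical(sort(as.integer(table(f$fold)), decreasing = TRUE),
                   c(25L, 24L, 24L, 24L, 24L))
  expect_identical(f, make_cv_folds(ids, k = 5, seed = 2))
  expect_false(identical(f, make_cv_folds(ids, k = 5, seed = 3)))

  expect_identical(as.integer(table(make_cv_folds(sprintf("s%d", 1:10), 5, 1)$fold)),
                   rep(2L, 5))
  expect_identical(as.integer(table(make_cv_folds(sprintf("s%d", 1:5), 5, 1)$fold)),
                   rep(1L, 5))
  expect_error(make_cv_folds(sprintf("s%d", 1:3), k = 5), class = "mvm_data_error")

  index <- tibble::tibble(slice_id = ids, n_frames = 10L)
  held <- f$slice_id[f$fold == 1]
  pool <- build_training_pool(index[!index$slice_id %in% held, ], n_aug = 1)
  expect_true(audit_pool_leakage(pool, held))
  bad_pool <- build_training_pool(index, n_aug = 1)
  expect_error(audit_pool_leakage(bad_pool, held), "leakage",
               class = "mvm_data_error")
})
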