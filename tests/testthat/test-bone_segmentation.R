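# Per-bone segmentation, the ground-truth oracle, contour tracing and
# area computation.

test_that("segmenters reach the held-out Dice contract", {
  segs <- ak_models()$segmenters
  expect_gte(segs$femur$validation_dice, 0.90)
  expect_gte(segs$tibia$validation_dice, 0.90)
})

test_that("soft-tissue-only crops give near-empty masks", {
  seg <- ak_models()$segmenters$femur
  crop <- matrix(60L, 160, 160)  # uniform soft tissue
  out <- segment_knee_slices(seg, list(crop))[[1]]
  expect_lte(mean(out > 0), 0.01)
})

test_that("segmentation output is strictly binary at the training size", {
  tc <- ak_test_case()
  os <- ak_oracle_stacks()
  kr <- os$knee_range
  crops <- lapply(tc$volume$slices[kr[1]:kr[2]], crop_matrix, roi = os$roi)
  for (bone in c("femur", "tibia")) {
    masks <- segment_knee_slices(ak_models()$segmenters[[bone]], crops)
    expect_true(all(vapply(masks, function(m) all(m %in% c(0L, 1L)), TRUE)))
    # Dice against the oracle over the knee crops
    d <- vapply(seq_along(masks), function(i) {
      gt <- oracle_segmenter(tc$truth, kr[1] + i - 1, bone, os$roi)
      autoknee:::dice_coef(masks[[i]], gt)
    }, 0)
    expect_gte(mean(d), 0.90)
  }
  small <- lapply(crops[1:2], function(m) m[1:80, 1:80])
  expect_error(segment_knee_slices(ak_models()$segmenters$femur, small),
               "crop size")
})

test_that("degenerate training data is rejected", {
  fix <- ak_fixtures()$segmentation$femur$train
  empty <- list(train = list(images = fix$images[1:4],
                             masks = replicate(4, matrix(0L, 160, 160),
                                               simplify = FALSE)))
  expect_error(train_bone_segmenter("femur", empty), "no positive pixels")
  mism <- list(train = list(images = fix$images[1:2],
                            masks = list(fix$masks[[1]],
                                         matrix(0L, 10, 10))))
  expect_error(train_bone_segmenter("femur", mism), "shape mismatch")
})

test_that("the oracle segmenter reproduces ground truth exactly", {
  tc <- ak_test_case()
  os <- ak_oracle_stacks()
  k <- tc$truth$transition_slice + 6
  m <- oracle_segmenter(tc$truth, k, "femur", os$roi)
  gt_full <- tc$truth$masks$femur[[k]]
  expect_equal(sum(m), sum(crop_matrix(gt_full, os$roi)))
  expect_equal(autoknee:::dice_coef(m, m), 1)
  # femur is absent far below the joint
  low <- oracle_segmenter(tc$truth, 5, "femur", os$roi)
  expect_equal(sum(low), 0)
  expect_equal(mask_area_mm2(m, tc$truth$pixel_spacing),
               sum(m) * prod(tc$truth$pixel_spacing))
})

test_that("contour tracing follows mask boundaries with length filtering", {
  mask <- matrix(0L, 30, 30)
  mask[10:19, 8:17] <- 1L  # 10 x 10 square
  cs <- extract_bone_contours(mask, min_length_px = 10)
  expect_length(cs, 1)
  expect_true(cs[[1]]$closed)
  expect_lt(abs(cs[[1]]$length - 36), 4)  # 9 px sides traced at centres
  # every contour point lies on the mask boundary support
  pts <- cs[[1]]$points
  expect_true(all(mask[pts] == 1L))
  inner <- mask
  inner[11:18, 9:16] <- 0L  # interior removed: boundary ring unchanged
  expect_true(all(inner[pts] == 1L))

  two <- mask
  two[2:3, 2:3] <- 1L  # tiny blob below the length filter
  cs2 <- extract_bone_contours(two, min_length_px = 10)
  expect_length(cs2, 1)
  cs3 <- extract_bone_contours(two, min_length_px = 2)
  expect_length(cs3, 2)

  expect_length(extract_bone_contours(matrix(0L, 5, 5), 10), 0)
  expect_error(extract_bone_contours(matrix(2L, 3, 3)), "binary")
})

test_that("raising the length filter never adds contours", {
  set.seed(8)
  for (rep in 1:5) {
    mask <- matrix(as.integer(runif(400) > 0.6), 20, 20)
    counts <- vapply(c(0, 5, 10, 20, 40), function(l) {
      length(extract_bone_contours(mask, l))
    }, 0)
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("mask areas scale with pixel size and are flip invariant", {
  mask <- matrix(0L, 20, 20)
  mask[3:12, 5:14] <- 1L
  expect_equal(mask_area_mm2(mask, c(0.8, 0.8)), 64)
  expect_equal(mask_area_mm2(matrix(0L, 4, 4), c(0.8, 0.8)), 0)
  expect_equal(mask_area_mm2(flip_slice_horizontal(mask), c(0.8, 0.8)),
               mask_area_mm2(mask, c(0.8, 0.8)))
})
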