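# Four-class slice classification, label smoothing, bone order and knee
# region delimitation.

test_that("classifier reaches the held-out accuracy contract", {
  m <- ak_models()$classifier
  expect_gte(m$validation_accuracy, 0.95)
})

test_that("class probabilities are normalised and consistent with labels", {
  res <- classify_volume(ak_models()$classifier, ak_test_case()$volume)
  expect_equal(rowSums(res$probabilities), rep(1, length(res$labels)),
               tolerance = 1e-6)
  am <- colnames(res$probabilities)[max.col(res$probabilities,
                                            ties.method = "first")]
  expect_identical(am, res$labels)
})

test_that("phantom volumes classify per-slice at >= 0.95 agreement", {
  tc <- ak_test_case()
  res <- classify_volume(ak_models()$classifier, tc$volume)
  expect_gte(mean(res$labels == tc$truth$labels), 0.95)
})

test_that("an all-air volume classifies as OTHER throughout", {
  vol <- ct_volume(replicate(6, matrix(0L, 64, 64), simplify = FALSE),
                   c(0.8, 0.8), 1)
  res <- classify_volume(ak_models()$classifier, vol)
  expect_true(all(res$labels == "OTHER"))
})

test_that("training requires every class", {
  fix <- ak_fixtures()$classifier
  keep <- fix$train$labels != "FEMUR"
  broken <- list(train = list(images = fix$train$images[keep],
                              labels = fix$train$labels[keep]))
  expect_error(train_slice_classifier(broken), "class coverage")
})

test_that("smoothing takes the window majority and keeps ties", {
  s <- slice_labels(c("KNEE", "KNEE", "FEMUR", "KNEE", "KNEE"))
  expect_identical(smooth_labels(s, 3)$labels, rep("KNEE", 5))
  expect_identical(smooth_labels(s, 1)$labels, s$labels)
  expect_error(smooth_labels(s, 4), "odd")
  # brute-force majority oracle on random sequences
  set.seed(12)
  vote_oracle <- function(labs, w) {
    half <- (w - 1) / 2
    vapply(seq_along(labs), function(i) {
      win <- labs[max(1, i - half):min(length(labs), i + half)]
      tab <- table(win)
      top <- names(tab)[tab == max(tab)]
      if (length(top) == 1) top else if (labs[i] %in% top) labs[i]
      else top[1]
    }, "")
  }
  for (rep in 1:5) {
    labs <- sample(autoknee:::AK_CLASSES, 15, replace = TRUE)
    for (w in c(3, 5)) {
      sm <- smooth_labels(slice_labels(labs), w)$labels
      expect_identical(sm, vote_oracle(labs, w))
      # never introduces a class absent from the window
      for (i in seq_along(labs)) {
        half <- (w - 1) / 2
        win <- labs[max(1, i - half):min(length(labs), i + half)]
        expect_true(sm[i] %in% win)
      }
    }
  }
})

test_that("bone order follows the relative run positions", {
  t2f <- slice_labels(c("FIBULA_TIBIA", "FIBULA_TIBIA", "KNEE", "KNEE",
                        "FEMUR", "FEMUR"))
  expect_identical(determine_bone_order(t2f), "tibia_to_femur")
  f2t <- slice_labels(rev(t2f$labels))
  expect_identical(determine_bone_order(f2t), "femur_to_tibia")
  expect_error(determine_bone_order(slice_labels(c("KNEE", "OTHER"))),
               "indeterminate order")
  # one mislabel agrees with the smoothed oracle
  noisy <- c("FIBULA_TIBIA", "FIBULA_TIBIA", "FEMUR", "FIBULA_TIBIA",
             "KNEE", "KNEE", "FEMUR", "FEMUR")
  sm <- smooth_labels(slice_labels(noisy), 3)
  expect_identical(determine_bone_order(slice_labels(noisy)),
                   determine_bone_order(sm))
})

test_that("knee range is the longest contiguous run", {
  s <- slice_labels(c("OTHER", "KNEE", "KNEE", "KNEE", "OTHER"))
  expect_equal(unname(knee_slice_range(s)), c(2, 4))
  s2 <- slice_labels(c("KNEE", "OTHER", "KNEE", "KNEE"))
  expect_equal(unname(knee_slice_range(s2)), c(3, 4))
  expect_error(knee_slice_range(slice_labels(rep("OTHER", 4))),
               "no knee region")
  # contiguity and maximality over random sequences
  set.seed(3)
  for (rep in 1:10) {
    labs <- sample(c("KNEE", "OTHER"), 20, replace = TRUE)
    if (!any(labs == "KNEE")) labs[7] <- "KNEE"
    r <- knee_slice_range(slice_labels(labs))
    expect_true(all(labs[r[1]:r[2]] == "KNEE"))
    runs <- rle(labs == "KNEE")
    expect_equal(unname(r[2] - r[1] + 1), max(runs$lengths[runs$values]))
  }
})
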