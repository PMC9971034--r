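# Phantom generator: correspondence, determinism, mode statistics and
# voxelisation consistency.

test_that("zero-variance population collapses to the template", {
  pp <- population_params(n_subjects = 3,
                          mode_sds = c(scale = 0, condyle = 0,
                                       slope_deg = 0),
                          noise_sd_mm = 0, seed = 5)
  pop <- generate_bone_population(pp)
  expect_equal(pop[[1]]$femur$vertices, pop[[2]]$femur$vertices)
  expect_equal(pop[[2]]$tibia$vertices, pop[[3]]$tibia$vertices)
})

test_that("generation is deterministic given the seed", {
  a <- generate_bone_population(population_params(n_subjects = 3, seed = 8))
  b <- generate_bone_population(population_params(n_subjects = 3, seed = 8))
  expect_identical(a[[2]]$femur$vertices, b[[2]]$femur$vertices)
  expect_identical(a[[3]]$mode_weights, b[[3]]$mode_weights)
})

test_that("meshes are corresponded and watertight with plateau below condyles", {
  pop <- ak_population()
  expect_identical(pop[[1]]$femur$faces, pop[[5]]$femur$faces)
  expect_identical(pop[[2]]$tibia$faces, pop[[7]]$tibia$faces)
  for (s in pop[c(1, 4)]) {
    expect_gt(mesh_volume(s$femur), 0)
    expect_gt(mesh_volume(s$tibia), 0)
    expect_lt(max(s$tibia$vertices[, 3]), min(s$femur$vertices[, 3]))
  }
})

test_that("scale-mode spread reproduces the configured sd (Monte Carlo)", {
  sd_scale <- 0.04
  pp <- population_params(n_subjects = 200,
                          mode_sds = c(scale = sd_scale, condyle = 0,
                                       slope_deg = 0),
                          noise_sd_mm = 0, seed = 21)
  pop <- generate_bone_population(pp)
  widths <- vapply(pop, function(s) diff(range(s$femur$vertices[, 1])), 0)
  w0 <- diff(range(ak_template_femur()$vertices[, 1]))
  expected_sd <- w0 * sd_scale
  se <- expected_sd / sqrt(2 * (length(pop) - 1))
  expect_lt(abs(sd(widths) - expected_sd), 3 * se)
})

test_that("voxelised sphere cross-sections match the analytic area", {
  s <- uv_sphere(20, n_lat = 40, n_lon = 64)
  for (z in c(0, 5, 12)) {
    loops <- slice_mesh_z(s, z)
    mask <- autoknee:::rasterize_loops(loops, 80, 80, c(-32, -32), c(1, 1))
    analytic <- pi * (400 - z^2)
    expect_lt(abs(sum(mask) * 1 - analytic) / analytic, 0.05)
  }
})

test_that("noise-free volumes contain exactly the three tissue intensities", {
  subj <- ak_test_case()$subject
  vx <- voxelize_subject(subj, noise_sd = 0, seed = 1)
  vals <- sort(unique(unlist(lapply(vx$volume$slices, unique))))
  expect_identical(vals, c(0L, 60L, 220L))
})

test_that("mask volumes agree with mesh volumes within 5%", {
  tc <- ak_test_case()
  vx_area <- tc$truth
  for (bone in c("femur", "tibia")) {
    mask_vol <- sum(vapply(vx_area$masks[[bone]], sum, 0)) *
      prod(vx_area$pixel_spacing) * vx_area$slice_spacing
    mesh_vol <- mesh_volume(tc$subject[[bone]])
    expect_lt(abs(mask_vol - mesh_vol) / mesh_vol, 0.05)
  }
})

test_that("per-slice mask areas match mask_area_mm2", {
  truth <- ak_test_case()$truth
  k <- truth$transition_slice + 5
  m <- truth$masks$femur[[k]]
  expect_equal(mask_area_mm2(m, truth$pixel_spacing),
               sum(m > 0) * 0.64)
})

test_that("out-of-field bones raise an FOV overflow error", {
  subj <- ak_test_case()$subject
  subj$offset_mm <- c(65, 0)
  expect_error(voxelize_subject(subj, seed = 1), "FOV overflow")
})

test_that("degenerate template scale is rejected", {
  expect_error(autoknee:::phantom_meshes(-0.99, 0, 0, 0),
               "degenerate phantom")
})

test_that("training fixtures split by subject with full class coverage", {
  fix <- ak_fixtures()
  expect_length(intersect(fix$train_subjects, fix$validation_subjects), 0)
  expect_length(c(fix$train_subjects, fix$validation_subjects), 8)
  expect_true(all(table(factor(fix$classifier$train$labels,
                               levels = autoknee:::AK_CLASSES)) >= 1))
  # every segmentation pair aligned; non-empty masks exist for both bones
  for (bone in c("femur", "tibia")) {
    tr <- fix$segmentation[[bone]]$train
    expect_true(all(vapply(seq_along(tr$images), function(i) {
      identical(dim(tr$images[[i]]), dim(tr$masks[[i]]))
    }, TRUE)))
    expect_gt(sum(vapply(tr$masks, function(m) sum(m > 0), 0) > 0), 0)
  }
  expect_error(make_training_fixtures(ak_population(), split = c(0.5, 0.3)),
               "sum to 1")
})
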