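# Shared fixtures, built once per test session and cached.  All fixture
# parameters are the generator's defaults (the package's stated study
# conditions); only population sizes are test-scale.

.ak_cache <- new.env(parent = emptyenv())

ak_cached <- function(key, builder) {
  if (is.null(.ak_cache[[key]])) .ak_cache[[key]] <- builder()
  .ak_cache[[key]]
}

# 8-subject training population and fixtures for the learned stages
ak_population <- function() {
  ak_cached("pop", function() {
    generate_bone_population(population_params(n_subjects = 8, seed = 11))
  })
}

ak_fixtures <- function() {
  ak_cached("fixtures", function() {
    make_training_fixtures(ak_population(), split = c(0.75, 0.25), seed = 2)
  })
}

ak_models <- function() {
  ak_cached("models", function() train_pipeline_models(ak_fixtures(),
                                                       seed = 3))
}

ak_ssms <- function() {
  ak_cached("ssms", function() {
    pop <- ak_population()
    list(femur = shape_model(lapply(pop, `[[`, "femur"), smooth_iters = 2),
         tibia = shape_model(lapply(pop, `[[`, "tibia"), smooth_iters = 2))
  })
}

# one held-out voxelised subject (left knee) with ground truth
ak_test_case <- function() {
  ak_cached("test_case", function() {
    subj <- generate_bone_population(
      population_params(n_subjects = 2, seed = 77))[[1]]
    c(list(subject = subj), voxelize_subject(subj, seed = 51))
  })
}

# oracle-mask contour stacks for the held-out subject
ak_oracle_stacks <- function() {
  ak_cached("oracle_stacks", function() {
    truth <- ak_test_case()$truth
    kr <- range(which(truth$labels == "KNEE"))
    kn <- which(!vapply(truth$boxes, is.null, TRUE))
    roi <- median_roi_box(lapply(kn, function(k) truth$boxes[[k]]$centre),
                          size = 160, image_dim = c(176, 176))
    fm <- lapply(kr[1]:kr[2], oracle_segmenter, truth = truth,
                 bone = "femur", roi = roi)
    tm <- lapply(kr[1]:kr[2], oracle_segmenter, truth = truth,
                 bone = "tibia", roi = roi)
    prof <- area_profiles(fm, tm, truth$pixel_spacing)
    tr <- find_transition_slice(prof)
    stacks <- split_and_build_stacks(
      lapply(fm, extract_bone_contours),
      lapply(tm, extract_bone_contours),
      tr, kr, trim = 5, pixel_spacing = truth$pixel_spacing,
      slice_spacing = truth$slice_spacing)
    list(stacks = stacks, roi = roi, knee_range = kr, transition = tr,
         profile = prof)
  })
}

# small random mesh fixture for ICP tests: template femur surface
ak_template_femur <- function() {
  ak_cached("template_femur", function() {
    generate_bone_population(
      population_params(n_subjects = 2,
                        mode_sds = c(scale = 0, condyle = 0, slope_deg = 0),
                        noise_sd_mm = 0, seed = 1))[[1]]$femur
  })
}
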