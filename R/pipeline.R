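# End-to-end orchestration: ingest -> classify -> ROI -> segment ->
# contours -> transition -> stacks -> align -> morph -> implant design,
# plus cohort evaluation.  A stage failure aborts the run with a
# diagnostic object naming the stage, never an R error escaping the
# pipeline.

#' Pipeline configuration
#'
#' Defaults follow the constants the method is defined with: a 160 px
#' square ROI, 5 trimmed slices at each stack end, 2 morphable principal
#' components, a 5 mm tibial plate, a 2 mm section offset below the
#' widest medial-condyle point, and the inclusive 3 mm clinical OUH
#' threshold.
#'
#' @param roi_size ROI square side, px.
#' @param trim Slices trimmed from each outer stack end.
#' @param n_pc Principal components used when morphing.
#' @param plate_thickness_mm Tibial plate extrusion thickness.
#' @param section_offset_mm Tibial profile offset below the widest point.
#' @param ouh_threshold_mm Clinical flag threshold (inclusive).
#' @param smoothing_window Label smoothing window (odd).
#' @param min_contour_px Contour length filter.
#' @param shell_mm Femoral bone-facing tolerance.
#' @param window Stored-intensity display window for PNG export.
#' @param seed Default RNG seed for stochastic steps.
#' @return `pipeline_config`.
#' @export
pipeline_config <- function(roi_size = 160, trim = 5, n_pc = 2,
                            plate_thickness_mm = 5, section_offset_mm = 2,
                            ouh_threshold_mm = 3, smoothing_window = 5,
                            min_contour_px = 20, shell_mm = 1,
                            window = ak_default_window(), seed = 1L) {
  structure(list(roi_size = roi_size, trim = trim, n_pc = n_pc,
                 plate_thickness_mm = plate_thickness_mm,
                 section_offset_mm = section_offset_mm,
                 ouh_threshold_mm = ouh_threshold_mm,
                 smoothing_window = smoothing_window,
                 min_contour_px = min_contour_px, shell_mm = shell_mm,
                 window = window, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Train all learned pipeline stages from fixtures
#'
#' @param fixtures Output of [make_training_fixtures()].
#' @param seed RNG seed.
#' @return List: `classifier`, `detector`, `segmenters` (femur, tibia).
#' @export
train_pipeline_models <- function(fixtures, seed = 1L) {
  list(classifier = train_slice_classifier(fixtures$classifier,
                                           seed = seed),
       detector = train_roi_detector(fixtures$detector, seed = seed + 1L),
       segmenters = list(
         femur = train_bone_segmenter("femur", fixtures$segmentation$femur,
                                      seed = seed + 2L),
         tibia = train_bone_segmenter("tibia", fixtures$segmentation$tibia,
                                      seed = seed + 3L)))
}

pipeline_failure <- function(stage, message) {
  structure(list(stage = stage, message = conditionMessage_or(message)),
            class = "pipeline_failure")
}

conditionMessage_or <- function(x) {
  if (inherits(x, "condition")) conditionMessage(x) else as.character(x)
}

#' @export
print.pipeline_failure <- function(x, ...) {
  cat(sprintf("pipeline failure at stage '%s': %s\n", x$stage, x$message))
  invisible(x)
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) pipeline_failure(stage, e))
}

failed <- function(x) inherits(x, "pipeline_failure")

#' Run the full CT-to-implant pipeline
#'
#' Executes every stage from DICOM ingest to implant design and returns
#' the two bone predictions, the two components and the per-stage
#' details.  On a stage error a `pipeline_failure` naming the stage is
#' returned instead.
#'
#' @param input DICOM series directory or a `ct_volume`.
#' @param side `"left"` or `"right"` knee.
#' @param models [train_pipeline_models()] output.
#' @param ssms List with `femur` and `tibia` [shape_model()]s.
#' @param config [pipeline_config()].
#' @return `pipeline_result` (or `pipeline_failure`): femur/tibia
#'   predictions (`ak_mesh`), femur component and tibia plate
#'   (`implant_component`), and `details` (labels, roi, transition,
#'   stacks, transforms).
#' @export
run_pipeline <- function(input, side = "left", models, ssms,
                         config = pipeline_config()) {
  log <- character(0)
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  vol <- run_stage("ingest", {
    if (inherits(input, "ct_volume")) input else load_dicom_series(input)
  })
  if (failed(vol)) return(vol)
  note("ingest: %d slices", n_slices(vol))

  seq_raw <- run_stage("classify", classify_volume(models$classifier, vol))
  if (failed(seq_raw)) return(seq_raw)
  seq_sm <- smooth_labels(seq_raw, config$smoothing_window)
  order_dir <- run_stage("bone_order", determine_bone_order(seq_sm))
  if (failed(order_dir)) return(order_dir)
  if (order_dir == "femur_to_tibia") {
    # renormalise so slice index increases tibia -> femur
    vol$slices <- rev(vol$slices)
    seq_sm <- slice_labels(rev(seq_sm$labels),
                           seq_sm$probabilities[rev(seq_len(n_slices(vol))), ,
                                                drop = FALSE])
    note("bone order: reversed stack to tibia->femur")
  }
  kr <- run_stage("knee_range", knee_slice_range(seq_sm))
  if (failed(kr)) return(kr)
  note("knee range: slices %d..%d", kr[1], kr[2])

  knee_idx <- kr[1]:kr[2]
  knee_imgs <- vol$slices[knee_idx]
  if (identical(side, "right"))
    knee_imgs <- lapply(knee_imgs, flip_slice_horizontal)
  roi <- run_stage("roi", {
    ctrs <- predict_roi_centres(models$detector, knee_imgs)
    median_roi_box(ctrs, size = config$roi_size,
                   image_dim = dim(knee_imgs[[1]]))
  })
  if (failed(roi)) return(roi)
  crops <- lapply(knee_imgs, crop_matrix, roi = roi)

  masks <- run_stage("segment", list(
    femur = segment_knee_slices(models$segmenters$femur, crops),
    tibia = segment_knee_slices(models$segmenters$tibia, crops)))
  if (failed(masks)) return(masks)

  contours <- run_stage("contours", list(
    femur = lapply(masks$femur, extract_bone_contours,
                   min_length_px = config$min_contour_px),
    tibia = lapply(masks$tibia, extract_bone_contours,
                   min_length_px = config$min_contour_px)))
  if (failed(contours)) return(contours)

  transition <- run_stage("transition", {
    prof <- area_profiles(masks$femur, masks$tibia, vol$pixel_spacing)
    find_transition_slice(prof, "tibia_to_femur")
  })
  if (failed(transition)) return(transition)
  note("transition at knee-relative slice %d", transition)

  stacks <- run_stage("stacks", split_and_build_stacks(
    contours$femur, contours$tibia, transition, kr, trim = config$trim,
    pixel_spacing = vol$pixel_spacing, slice_spacing = vol$slice_spacing))
  if (failed(stacks)) return(stacks)

  fits <- list()
  for (bone in c("femur", "tibia")) {
    fit <- run_stage(paste0("morph_", bone), {
      al <- align_stack_to_base(stacks[[bone]], ssms[[bone]])
      pred <- morph_to_stack(ssms[[bone]], al$points, n_pc = config$n_pc)
      list(prediction = pred, alignment = al)
    })
    if (failed(fit)) return(fit)
    fits[[bone]] <- fit
    note("%s morph rms %.3f mm", bone, attr(fit$prediction, "rms"))
  }

  design <- run_stage("design", {
    meas <- measure_ap_ml(fits$femur$prediction)
    plan <- plan_femur_cuts(meas)
    femc <- design_femur_component(fits$femur$prediction, plan,
                                   shell_mm = config$shell_mm)
    prof <- extract_tibia_profile(fits$tibia$prediction,
                                  offset_mm = config$section_offset_mm)
    plate <- design_tibia_plate(prof, plate_spec(
      thickness_mm = config$plate_thickness_mm,
      section_offset_mm = config$section_offset_mm))
    list(femur_component = femc, tibia_plate = plate)
  })
  if (failed(design)) return(design)

  structure(list(
    femur_prediction = fits$femur$prediction,
    tibia_prediction = fits$tibia$prediction,
    femur_component = design$femur_component,
    tibia_plate = design$tibia_plate,
    details = list(labels = seq_sm, knee_range = kr, roi = roi,
                   transition = transition, stacks = stacks,
                   alignments = lapply(fits, `[[`, "alignment"),
                   side = side, log = log)),
    class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result\n")
  for (l in x$details$log) cat(" -", l, "\n")
  invisible(x)
}

prediction_region <- function(result, bone) {
  pts <- result$details$alignments[[bone]]$points
  range(pts[, 3])
}

#' Prediction-vs-ground-truth RMSE for one pipeline result
#'
#' Surface RMSE over the fitted (contour-stack) z band, after rigid ICP.
#'
#' @param result `pipeline_result`.
#' @param truth `knee_ground_truth`.
#' @param bone `"femur"` or `"tibia"`.
#' @param n_samples,seed Sampling controls.
#' @return RMSE in mm.
#' @export
prediction_rmse <- function(result, truth, bone, n_samples = 1500,
                            seed = NULL) {
  pred <- result[[paste0(bone, "_prediction")]]
  surface_rmse(pred, truth$meshes[[bone]],
               region = prediction_region(result, bone),
               n_samples = n_samples, seed = seed)
}

#' Evaluate a cohort of pipeline results
#'
#' Computes per-subject prediction RMSE, component RMSE and maximum OUH
#' per bone, aggregates mean (sd) and OUH >= threshold counts, and runs
#' the attribute comparisons via [cohort_stats()].
#'
#' @param results List of `pipeline_result`s (failures allowed; counted).
#' @param truths Matching list of `knee_ground_truth`s.
#' @param config `pipeline_config`.
#' @param seed Sampling seed.
#' @return List: `per_subject` data frame, `summary` data frame,
#'   `stats` (attribute comparisons), `n_failed`.
#' @export
evaluate_cohort <- function(results, truths, config = pipeline_config(),
                            seed = 1L) {
  if (!length(results)) stop("empty cohort")
  rows <- list()
  n_failed <- 0L
  for (i in seq_along(results)) {
    res <- results[[i]]; truth <- truths[[i]]
    if (failed(res)) { n_failed <- n_failed + 1L; next }
    for (bone in c("femur", "tibia")) {
      comp <- if (bone == "femur") res$femur_component else res$tibia_plate
      fit <- component_fit(comp, truth$meshes[[bone]],
                           threshold = config$ouh_threshold_mm,
                           seed = seed + i)
      rows[[length(rows) + 1]] <- data.frame(
        subject = truth$subject_id, bone = bone,
        sex = truth$metadata$sex, side = truth$side,
        age = truth$metadata$age, height_cm = truth$metadata$height_cm,
        prediction_rmse_mm = prediction_rmse(res, truth, bone,
                                             seed = seed + i),
        component_rmse_mm = fit$rmse_mm,
        max_ouh_mm = fit$max_ouh_mm,
        ouh_flagged = fit$ouh_flag)
    }
  }
  per_subject <- do.call(rbind, rows)
  if (is.null(per_subject)) stop("no successful pipeline runs to evaluate")
  summarise_bone <- function(df) {
    data.frame(bone = df$bone[1], n = nrow(df),
               prediction_rmse_mean = mean(df$prediction_rmse_mm),
               prediction_rmse_sd = stats::sd(df$prediction_rmse_mm),
               component_rmse_mean = mean(df$component_rmse_mm),
               component_rmse_sd = stats::sd(df$component_rmse_mm),
               ouh_flagged_n = sum(df$ouh_flagged),
               ouh_flagged_pct = round(100 * mean(df$ouh_flagged), 1))
  }
  summary <- do.call(rbind, lapply(split(per_subject, per_subject$bone),
                                   summarise_bone))
  stats <- cohort_stats(per_subject,
                        metrics = c("prediction_rmse_mm",
                                    "component_rmse_mm", "max_ouh_mm"),
                        groups = c("sex", "side"),
                        covariates = c("age", "height_cm"))
  list(per_subject = per_subject, summary = summary, stats = stats,
       n_failed = n_failed)
}
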